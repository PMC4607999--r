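Gene	Location	Strand	Size	Intergenic	StartStop
trnI(gat)	1-66	J	66	-3	
trnQ(ttg)	64-132	N	69	55	
trnM(cat)	188-256	J	69		
nad2	257-1279	J	1023	12	ATT/TAA
trnW(tca)	1292-1360	J	69	-8	
trnC(gca)	1353-1416	N	64	33	
trnY(gta)	1450-1516	N	67	-2	
cox1	1515-3049	J	1535		TCG/TA
trnL2(taa)	3050-3115	J	66	4	
cox2	3120-3809	J	690	3	ATG/TAA
trnK(ctt)	3813-3882	J	70		
trnD(gtc)	3883-3949	J	67		
atp8	3950-4111	J	162	-7	GTG/TAA
atp6	4105-4782	J	678	-1	ATG/TAA
cox3	4782-5570	J	789	9	ATG/TAA
trnG(tcc)	5580-5644	J	65		
nad3	5645-5996	J	352		ATT/T
trnA(tgc)	5997-6061	J	65	7	
trnR(tcg)	6069-6132	J	64	25	
trnN(gtt)	6158-6222	J	65		
trnS1(gct)	6223-6290	J	68		
trnE(ttc)	6291-6357	J	67	18	
trnF(gaa)	6376-6440	N	65	5	
nad5	6446-8158	N	1713	15	ATC/TAA
trnH(gtg)	8174-8239	N	66		
nad4	8240-9580	N	1341	-7	ATG/TAG
nad4l	9574-9870	N	297	2	ATG/TAA
trnT(tgt)	9873-9937	J	65		
trnP(tgg)	9938-10003	N	66	2	
nad6	10006-10530	J	525	-1	ATT/TAA
cob	10530-11666	J	1137	-2	ATG/TAG
trnS2(tga)	11665-11731	J	67	15	
nad1	11747-12686	N	940	10	ATA/T
trnL1(tag)	12697-12761	N	65	4	
rrnL	12766-14088	N	1323		
trnV(tac)	14089-14160	N	72		
rrnS	14161-14948	N	788		
control_region	14949-15900	J	952		
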