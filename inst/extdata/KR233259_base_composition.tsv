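Region	A	C	G	T	AT	GC	ATskew	GCskew
whole_genome	39.0	17.5	10.3	33.2	72.3	27.7	0.080	-0.259
nad2	33.3	19.5	9.1	38.1	71.5	28.5	-0.067	-0.364
cox1	29.9	20.5	16.1	33.4	63.3	36.7	-0.055	-0.120
cox2	33.5	19.4	13.6	33.5	67.0	33.0	0	-0.176
atp8	35.2	20.4	9.2	35.2	70.4	29.6	0	-0.378
atp6	30.5	20.1	11.8	37.6	68.1	31.9	-0.104	-0.259
cox3	29.9	20.6	15.0	34.5	64.4	35.6	-0.071	-0.157
nad3	32.4	19.0	9.7	38.9	71.3	28.7	-0.091	-0.324
nad5	45.3	18.7	9.2	26.8	72.2	27.8	0.257	-0.341
nad4	48.5	16.7	8.5	26.3	74.8	25.2	0.297	-0.325
nad4l	51.2	14.8	6.4	27.6	78.8	21.2	0.299	-0.396
nad6	38.1	17.7	6.1	38.1	76.2	23.8	0	-0.487
cob	31.3	21.3	13.3	34.1	65.4	34.6	-0.043	-0.231
nad1	48.0	18.7	9.8	23.5	71.5	28.5	0.343	-0.312
rrnS	43.1	14.3	6.8	35.8	78.8	21.2	0.093	-0.355
rrnL	40.7	16.8	9.0	33.5	74.2	25.8	0.097	-0.302
control_region	45.6	7.9	6.1	40.4	86.0	14.0	0.060	-0.129
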