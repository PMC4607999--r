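kr_table_path <- function() {
  system.file("extdata", "KR233259_feature_table.tsv", package = "mitoprofile")
}
kr_composition_path <- function() {
  system.file("extdata", "KR233259_base_composition.tsv",
              package = "mitoprofile")
}

kr_genome <- function() parse_feature_table(kr_table_path(), id = "KR233259")

# small fully-sequenced genome with a PCG, two tRNAs and a control region
toy_genome <- function() {
  trna1 <- generate_trna(trna_arm_spec("GAT"), seed = 101)
  trna2 <- generate_trna(trna_arm_spec("TTG"), seed = 102)
  pcg <- "ATGAAACCCGGGTTTACATAA"           # 21 nt, clean ORF
  cr <- paste0(strrep("AT", 20), strrep("T", 8), strrep("CA", 10))
  seqs <- c(trna1, pcg, "ACGTA", trna2, cr)  # 5-nt spacer after pcg
  starts <- cumsum(c(1, nchar(trna1), nchar(pcg) + 5, nchar(trna2)))
  ends <- starts + c(nchar(trna1), nchar(pcg), nchar(trna2), nchar(cr)) - 1
  mito_genome(
    "toy", sequence = paste(seqs, collapse = ""),
    features = mito_features(
      name = c("trnI", "fake1", "trnQ", "control_region"),
      type = c("tRNA", "PCG", "tRNA", "control_region"),
      start = starts, end = ends,
      strand = c("J", "J", "N", "J"),
      anticodon = c("GAT", NA, "TTG", NA)))
}

# a tiny 8-leaf binary tree (unrooted: trifurcating root) for simulations
eight_leaf_tree <- function(scale = 1) {
  txt <- paste0("((A:%1$f,B:%1$f):%1$f,((C:%1$f,D:%1$f):%1$f,",
                "(E:%1$f,F:%1$f):%1$f):%1$f,(G:%1$f,H:%1$f):%1$f);")
  ape::read.tree(text = sprintf(txt, 0.03 * scale))
}
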