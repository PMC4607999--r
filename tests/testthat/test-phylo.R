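test_that("center-star alignment handles identical and gapped inputs", {
  m <- align_gene(c(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT"))
  expect_equal(unique(m$seqs), "ACGTACGT")
  expect_equal(m$labels, c("x", "y", "z"))
  m2 <- align_gene(c(a = "ACGT", b = "AGT"))
  expect_equal(nchar(m2$seqs[1]), 4L)
  expect_equal(m2$seqs[1], "ACGT")
  expect_equal(m2$seqs[2], "A-GT")
  expect_error(align_gene(c(a = "ACGT", b = "")), "empty")
  # ungapping recovers inputs
  set.seed(3)
  ins <- c(p = random_dna(40), q = random_dna(35), r = random_dna(38))
  m3 <- align_gene(ins)
  expect_equal(gsub("-", "", m3$seqs), unname(ins))
  expect_equal(length(unique(nchar(m3$seqs))), 1L)
})

test_that("pairwise alignment scores match the exhaustive DP oracle", {
  set.seed(13)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  for (i in 1:10) {
    a <- random_dna(sample(3:6, 1)); b <- random_dna(sample(3:6, 1))
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = submat,
      gapOpening = 4, gapExtension = 1)
    expect_equal(Biostrings::score(pa), oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("supermatrix concatenates per-gene alignments with a partition map", {
  g <- generate_mitogenome(seed = 41)
  tips <- evolve_on_tree(g, "((A:0.02,B:0.02):0.02,C:0.04,D:0.05);", seed = 2)
  sm <- build_supermatrix(tips)
  expect_equal(nrow(sm$partitions), 13L)
  expect_equal(sm$partitions$start[1], 1L)
  expect_equal(sm$partitions$end[nrow(sm$partitions)], nchar(sm$seqs[1]))
  expect_true(all(sm$partitions$start[-1] ==
                    head(sm$partitions$end, -1) + 1L))
  # single gene: supermatrix equals that gene's MSA
  sm1 <- build_supermatrix(tips, genes = "cox1")
  msa1 <- align_gene(vapply(tips, extract_feature_sequence, character(1),
                            feature = "cox1"), gene = "cox1")
  expect_equal(sm1$seqs, unname(msa1$seqs))
  # missing gene errors by default, gap-fills on request
  tips2 <- tips
  keep <- tips2$A$features$name != "cox1"
  tips2$A <- mito_genome("A", sequence = tips2$A$sequence,
                         features = tips2$A$features[keep, ])
  expect_error(build_supermatrix(tips2, genes = c("cox1", "cox2")), "cox1")
  expect_message(smf <- build_supermatrix(tips2, genes = c("cox1", "cox2"),
                                          gap_fill = TRUE), "gap-filling")
  expect_equal(substr(smf$seqs[1], 1, 5), strrep("-", 5))
})

test_that("p-distance uses pairwise deletion and is a metric", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGA"))["a", "b"], 25.0)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0.0)
  # gap and ambiguity columns deleted pairwise
  expect_equal(p_distance(c(a = "AC-TN", b = "ACGAA"))["a", "b"], 100 / 3)
  expect_error(p_distance(c(a = "---A", b = "AC--")), "no comparable")
  # cross-check against the reference distance implementation in ape
  set.seed(17)
  seqs <- c(w = random_dna(200), x = random_dna(200), y = random_dna(200))
  d <- p_distance(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  d_ape <- 100 * as.matrix(ape::dist.dna(bin, model = "raw",
                                         pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(d_ape[rownames(d), colnames(d)]))
  # metric properties on random gapped alignments
  for (i in 1:10) {
    m <- vapply(1:4, function(k)
      paste(sample(c("A", "C", "G", "T", "-"), 100, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
      character(1))
    names(m) <- letters[1:4]
    d <- p_distance(m)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 100))
    for (a in 1:4) for (b in 1:4) for (cc in 1:4)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-9)
  }
})

test_that("NJ solves the 3-taxon closed form and recovers additive trees", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  # additive 4-taxon matrix from a known tree: ((a,b),(c,d)) with known edges
  tree <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  dm4 <- ape::cophenetic.phylo(tree)
  got <- nj_tree(dm4)
  expect_equal(rf_distance(got, tree), 0L)
  # four-point condition singles out the same quartet
  expect_equal(oracle_quartet(dm4, "a", "b", "c", "d"), 1L)
  expect_true(all(got$edge.length >= 0))
  expect_error(nj_tree(dm[1:2, 1:2]), "three taxa")
})

test_that("RF distance matches hand-enumerated bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  # the two distinct 4-taxon resolutions share no internal bipartition
  expect_equal(rf_distance(t1, t2), 2L)
  # caterpillar splits {ab|cdef, abc|def, abcd|ef}; balanced splits
  # {ab|cdef, cd|abef, ef|abcd}; shared {ab|cdef, abcd|ef} -> RF = 1 + 1 = 2
  cat6 <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  bal6 <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  expect_equal(rf_distance(cat6, bal6), 2L)
})

test_that("bootstrap support is seeded, bounded and sharp for clean signal", {
  g <- generate_mitogenome(seed = 43)
  tips <- evolve_on_tree(
    g, "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05,(E:0.05,F:0.05):0.05);",
    seed = 3)
  sm <- build_supermatrix(tips, genes = c("cox1", "nad2"))
  b1 <- bootstrap_support(sm, replicates = 30, seed = 99)
  b2 <- bootstrap_support(sm, replicates = 30, seed = 99)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 100))
  # strong signal: every internal bipartition near 100%
  expect_true(all(b1$node.label[-1] >= 90))
  # one replicate: supports are 0 or 100
  b3 <- bootstrap_support(sm, replicates = 1, seed = 1)
  expect_true(all(b3$node.label %in% c(0, 100)))
})

test_that("star-like signal earns lower support than resolved signal", {
  g <- generate_mitogenome(seed = 47)
  resolved <- evolve_on_tree(
    g, "((A:0.02,B:0.02):0.06,(C:0.02,D:0.02):0.06,(E:0.02,F:0.02):0.06);",
    seed = 5)
  star <- evolve_on_tree(
    g, "((A:0.05,B:0.05):0.0001,(C:0.05,D:0.05):0.0001,(E:0.05,F:0.05):0.0001);",
    seed = 5)
  genes <- c("cox1", "nad5")
  s_res <- bootstrap_support(build_supermatrix(resolved, genes),
                             replicates = 40, seed = 7)
  s_star <- bootstrap_support(build_supermatrix(star, genes),
                              replicates = 40, seed = 7)
  expect_lt(mean(s_star$node.label[-1]), mean(s_res$node.label[-1]))
})

test_that("PHYLIP export is rectangular and labelled", {
  m <- align_gene(c(a = "ACGT", b = "AGT"))
  lines <- write_phylip(m)
  expect_equal(lines[1], "2 4")
  expect_match(lines[2], "^a  ACGT$")
})
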