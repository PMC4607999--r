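test_that("the default synthetic genome mirrors the canonical layout", {
  g <- generate_mitogenome(seed = 1)
  expect_equal(nrow(g$features), 38L)
  cen <- strand_census(g)
  expect_equal(unname(cen["J", "PCG"]), 9L)
  expect_equal(unname(cen["N", "PCG"]), 4L)
  expect_equal(unname(cen["N", "total"]), 14L)
  expect_equal(unname(control_region_flanks(g)), c("rrnS", "trnI"))
  expect_equal(g$features$name[1], "trnI")
  # tiling conservation: sizes + gaps = length
  expect_equal(sum(feature_sizes(g)) + sum(junction_gaps(g)$gap_bp),
               g$length)
})

test_that("generation is deterministic: same seed, byte-identical FASTA", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(generate_mitogenome(seed = 77), f1)
  write_fasta(generate_mitogenome(seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_mitogenome(seed = 78)
  expect_false(identical(generate_mitogenome(seed = 77)$sequence,
                         g3$sequence))
  expect_error(generate_mitogenome(), "seed")
})

test_that("PCGs carry the requested codons and are internally stop-free", {
  g <- generate_mitogenome(seed = 13)
  tab <- report_features(g)
  pcg <- tab[tab$StartStop != "", ]
  expect_equal(nrow(pcg), 13L)
  tl <- tally_codons(pcg$StartStop)
  expect_equal(as.integer(tl$start[c("ATG", "ATT", "ATA", "ATC", "GTG",
                                     "TCG")]), c(6L, 3L, 1L, 1L, 1L, 1L))
  expect_equal(as.integer(tl$stop[c("TAA", "TAG", "TA", "T")]),
               c(8L, 2L, 1L, 2L))
  for (nm in pcg$Gene)
    expect_equal(validate_cds(extract_feature_sequence(g, nm)), integer(0),
                 info = nm)
})

test_that("an impossible stop mode is rejected", {
  reg <- default_spec_regions()
  reg$stop_mode[reg$name == "cox1"] <- "TAA"  # cox1 length % 3 == 2
  expect_error(genome_spec(regions = reg), "cox1")
})

test_that("realized composition approaches the target as length grows", {
  spec_s <- genome_spec(cr_length = 400L)
  spec_l <- genome_spec(cr_length = 4000L)
  dev <- function(spec, seed) {
    g <- generate_mitogenome(spec, seed = seed)
    cs <- composition(extract_feature_sequence(g, "control_region"))
    abs(cs$at_pct - 86.0)
  }
  d_s <- mean(vapply(1:5, function(s) dev(spec_s, s), numeric(1)))
  d_l <- mean(vapply(1:5, function(s) dev(spec_l, s), numeric(1)))
  expect_lt(d_l, d_s)
  # at the default length the target is hit within binomial sampling
  # tolerance (3 SEs of A+T% at 952 bp, plus the planted poly-T offset)
  tol <- 3 * 100 * sqrt(0.86 * 0.14 / 952) + 100 * 32 / 952
  expect_lt(dev(genome_spec(), 99), tol)
})

test_that("the control region carries the planted poly-T stretches", {
  g <- generate_mitogenome(seed = 55)
  cr <- extract_feature_sequence(g, "control_region")
  runs <- poly_t_stretches(cr, min_len = 7)
  expect_true(all(c(25L, 7L) %in% runs$length))
})

test_that("planted spacer stem-loops are detectable", {
  g <- generate_mitogenome(seed = 57)
  sp <- spacer_sequences(g)
  big <- sp[sp$length >= 18, ]
  expect_gt(nrow(big), 0L)
  for (k in seq_len(nrow(big))) {
    hits <- find_stem_loops(big$sequence[k], min_stem = 4)
    expect_gt(nrow(hits), 0L)
    expect_true(any(hits$stem_len >= 6L & hits$mismatches == 0L))
  }
})

test_that("zero-length branches copy the parent exactly", {
  g <- generate_mitogenome(seed = 61)
  tips <- evolve_on_tree(g, "(A:0,B:0.1);", seed = 4)
  expect_identical(tips$A$sequence, g$sequence)
  expect_false(identical(tips$B$sequence, g$sequence))
  expect_equal(as.data.frame(tips$B$features), as.data.frame(g$features))
  expect_error(evolve_on_tree(g, "(A:-0.1,B:0.1);", seed = 1), "negative")
})

test_that("single-branch divergence matches the Jukes-Cantor expectation", {
  g <- generate_mitogenome(seed = 63)
  L <- g$length
  for (b in c(0.05, 0.2)) {
    tips <- evolve_on_tree(g, sprintf("(A:%f,B:0);", b), seed = 8)
    p_obs <- p_distance(c(A = tips$A$sequence, B = tips$B$sequence))[1, 2] / 100
    p_exp <- 0.75 * (1 - exp(-4 * b / 3))
    se <- sqrt(p_exp * (1 - p_exp) / L)
    expect_lt(abs(p_obs - p_exp), 3 * se)
  }
})

test_that("per-gene rate multipliers scale divergence regionally", {
  g <- generate_mitogenome(seed = 65)
  tips <- evolve_on_tree(g, "(A:0.05,B:0);", seed = 9,
                         rate_multipliers = c(cox1 = 4))
  d_cox1 <- p_distance(c(A = extract_feature_sequence(tips$A, "cox1"),
                         B = extract_feature_sequence(tips$B, "cox1")))[1, 2]
  d_nad2 <- p_distance(c(A = extract_feature_sequence(tips$A, "nad2"),
                         B = extract_feature_sequence(tips$B, "nad2")))[1, 2]
  expect_gt(d_cox1, 2 * d_nad2)
})

test_that("expected p-distance increases with path length on the tree", {
  g <- generate_mitogenome(seed = 67)
  tree <- ape::read.tree(
    text = "((A:0.01,B:0.02):0.01,(C:0.05,D:0.09):0.02,E:0.15);")
  tips <- evolve_on_tree(g, tree, seed = 10)
  sm <- build_supermatrix(tips)
  d_obs <- p_distance(sm)
  d_true <- ape::cophenetic.phylo(tree)[rownames(d_obs), colnames(d_obs)]
  ut <- upper.tri(d_obs)
  expect_gt(cor(d_obs[ut], d_true[ut], method = "spearman"), 0.95)
})

test_that("generate -> report pipeline closes without errors", {
  g <- generate_mitogenome(seed = 71)
  ft <- report_features(g)
  expect_equal(nrow(ft), 38L)
  comp <- report_composition(g)
  expect_equal(nrow(comp), 17L)  # whole genome + 13 PCGs + 2 rRNA + CR
  expect_true(all(abs(comp$A + comp$C + comp$G + comp$T - 100) < 0.21))
  tr <- report_trna(g)
  expect_equal(length(tr), 22L)
  expect_true(all(vapply(tr, function(x) x$anticodon_match, logical(1))))
  expect_identical(tr$trnS1$d_arm, "absent")
  expect_identical(tr$trnN$t_arm, "absent")
  expect_identical(tr$trnF$t_arm, "absent")
  sl <- report_stemloops(g, min_stem = 4)
  expect_gt(length(sl), 0L)
  js <- report_junctions(g)
  expect_equal(sum(js$strand_census$total), 38L)
})
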