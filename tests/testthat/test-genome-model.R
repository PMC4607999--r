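test_that("the published 38-row feature table parses with consistent sizes", {
  g <- kr_genome()
  expect_s3_class(g, "mitogenome")
  expect_equal(nrow(g$features), 38L)
  expect_equal(g$length, 15900L)
  sz <- feature_sizes(g)
  expect_false(any(attr(g, "size_flags")))
  expect_equal(unname(sz["cox1"]), 3049L - 1515L + 1L)
  expect_equal(unname(sz["control_region"]), 952L)
  expect_equal(g$features$anticodon[g$features$name == "trnI"], "GAT")
  expect_equal(sum(g$features$type == "PCG"), 13L)
  expect_equal(sum(g$features$type == "tRNA"), 22L)
})

test_that("feature-table parsing accepts en-dashes and flags bad rows", {
  txt <- c("Gene\tLocation\tStrand\tSize",
           "cox1\t1515–3049\tJ\t1535",
           "trnA(tgc)\t10–20\tJ\t99")
  g <- parse_feature_table(txt)
  expect_false(attr(g, "size_flags")[["cox1"]])
  expect_true(attr(g, "size_flags")[["trnA"]])
  expect_error(parse_feature_table(character(0)), "no features")
  expect_error(parse_feature_table(c("Gene\tLocation\tStrand",
                                     "cox1\toops\tJ")), "malformed location")
  expect_error(parse_feature_table(c("Gene\tLocation\tStrand",
                                     "cox1\t1-10\t+")), "strand")
})

test_that("feature extraction is strand-aware and handles the origin", {
  g <- mito_genome("t", sequence = "ACGTACGTAC",
                   features = mito_features(
                     c("f1", "f2", "f3"), c("PCG", "tRNA", "rRNA"),
                     start = c(1, 3, 9), end = c(4, 6, 2),
                     strand = c("J", "N", "J"),
                     wraps_origin = c(FALSE, FALSE, TRUE)))
  expect_equal(extract_feature_sequence(g, "f1"), "ACGT")
  # N strand: revcomp of GTAC
  expect_equal(extract_feature_sequence(g, "f2"), "GTAC")
  # wraps: positions 9,10,1,2
  expect_equal(extract_feature_sequence(g, "f3"), "ACAC")
  expect_equal(unname(feature_sizes(g)["f3"]), 4L)
})

test_that("extraction on a mirrored genome gives reverse complements", {
  set.seed(42)
  s <- random_dna(60)
  g <- mito_genome("fwd", sequence = s,
                   features = mito_features("x", "PCG", 11, 31, "J"))
  # mirror: reverse complement genome, feature flips strand and coordinates
  g2 <- mito_genome("rev", sequence = revcomp(s),
                    features = mito_features("x", "PCG", 60 - 31 + 1,
                                             60 - 11 + 1, "N"))
  expect_equal(extract_feature_sequence(g2, "x"),
               extract_feature_sequence(g, "x"))
})

test_that("GenBank round-trip preserves features, coordinates and sequence", {
  g <- toy_genome()
  lines <- write_genbank(g)
  g2 <- read_genbank(lines)
  expect_equal(g2$length, g$length)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(as.data.frame(g2$features), as.data.frame(g$features))
  expect_true(g2$circular)
})

test_that("GenBank reader handles complement, join and D-loop/misc_feature", {
  gb <- c(
    "LOCUS       test                 100 bp    DNA     circular     INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             complement(10..30)",
    '                     /gene="nad5"',
    "     tRNA            join(95..100,1..5)",
    '                     /gene="trnI(gat)"',
    "     misc_feature    40..80",
    '                     /note="A+T-rich region"',
    "     STS             60..61",
    "//")
  expect_warning(g <- read_genbank(gb), "STS")
  f <- g$features
  expect_equal(f$strand[f$name == "nad5"], "N")
  expect_true(f$wraps_origin[f$name == "trnI"])
  expect_equal(f$anticodon[f$name == "trnI"], "GAT")
  expect_equal(f$type[f$name == "control_region"], "control_region")
})

test_that("GFF and BED exports use consistent coordinate conventions", {
  g <- toy_genome()
  gff <- write_gff(g)
  bed <- write_bed(g)
  gff_rows <- read.delim(text = gff[-(1:2)], header = FALSE)
  bed_rows <- read.delim(text = bed, header = FALSE)
  # GFF is 1-based inclusive, BED 0-based half-open
  expect_equal(gff_rows$V4, bed_rows$V2 + 1L)
  expect_equal(gff_rows$V5, bed_rows$V3)
  # first feature trnI starts at 1 -> BED start 0
  expect_equal(bed_rows$V2[1], 0L)
  # N-strand feature maps to "-"
  expect_equal(unique(gff_rows$V7[grepl("ID=trnQ", gff_rows$V9)]), "-")
  expect_equal(bed_rows$V6[bed_rows$V4 == "trnQ"], "-")
})

test_that("feature table writer round-trips through the parser", {
  g <- toy_genome()
  g2 <- parse_feature_table(write_feature_table(g), id = g$id)
  expect_equal(as.data.frame(g2$features)[, c("name", "start", "end", "strand")],
               as.data.frame(g$features)[, c("name", "start", "end", "strand")])
  expect_equal(g2$features$anticodon, g$features$anticodon)
})

test_that("FASTA export writes the genome sequence verbatim", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, path)
  x <- Biostrings::readDNAStringSet(path)
  expect_equal(names(x), "toy")
  expect_equal(as.character(x[[1]]), g$sequence)
})

test_that("constructor enforces the container invariants", {
  expect_error(mito_genome("x", length = 10, sequence = "ACGT"), "length")
  expect_error(
    mito_genome("x", length = 10, features = mito_features(
      c("a", "b"), c("control_region", "control_region"),
      c(1, 5), c(4, 8), c("J", "J"))),
    "control_region")
  expect_error(
    mito_features("cox1", "PCG", 1, 10, "J", anticodon = "GAT"),
    "anticodon")
  expect_error(mito_features("cr", "control_region", 1, 10, "N"), "J strand")
  # invertebrate mito code: AGA/AGG are serine, not stop
  code <- genetic_code(5)
  expect_equal(unname(code$map[c("AGA", "AGG")]), c("S", "S"))
  expect_equal(sort(code$stops), c("TAA", "TAG"))
  expect_equal(length(code$map), 64L)
})
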