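#' Specification for a synthetic mitogenome
#'
#' Describes the genome the generator emulates: the canonical insect
#' mitochondrial layout of 37 genes plus control region, with per-region
#' composition targets, codon rules for the PCGs, arm geometries for the
#' tRNAs, planted poly-T stretches in the control region and planted
#' stem-loops in the larger spacers.
#'
#' The default layout follows the published annotation of the
#' *Bactrocera arecae* mitogenome (GenBank KR233259): its gene order,
#' strands, PCG/rRNA lengths, start/stop codons (including the incomplete
#' TA stop of *cox1* and T stops of *nad1*/*nad3*), anticodons, the 952-bp
#' control region with 25-bp and 7-bp poly-T stretches, and its positive
#' intergenic spacers. Overlapping junctions of the real record are laid
#' out as abutting (gap 0) — a synthetic overlap would need one stretch of
#' sequence to satisfy two coding constraints at once. tRNA lengths are
#' derived from their arm specifications rather than copied, so the folded
#' structure matches the spec exactly; *trnS1* lacks the D arm and
#' *trnN*/*trnF* lack the T arm, and *trnC*/*trnH*/*trnP*/*trnS1* get 4-bp
#' (rather than 5-bp) T stems, as in the real record.
#'
#' @param regions optional data.frame overriding the layout: columns `name`,
#'   `type`, `strand`, `length`, `gap_after` (and optionally `start_codon`,
#'   `stop_mode`, `anticodon`).
#' @param composition length-4 named numeric (a, c, g, t fractions summing
#'   to 1) used for genes and spacers.
#' @param cr_composition composition targets for the control region.
#' @param cr_length control-region length in bp.
#' @param poly_t lengths of the poly-T stretches planted in the control
#'   region.
#' @param stemloop_min_spacer plant a stem-loop in every spacer at least
#'   this long.
#' @param stemloop_stem,stemloop_loop geometry of planted stem-loops.
#' @return a list of class `genome_spec`.
#' @export
genome_spec <- function(regions = NULL,
                        composition = c(a = 0.390, c = 0.175, g = 0.103,
                                        t = 0.332),
                        cr_composition = c(a = 0.456, c = 0.079, g = 0.061,
                                           t = 0.404),
                        cr_length = 952L,
                        poly_t = c(25L, 7L),
                        stemloop_min_spacer = 18L,
                        stemloop_stem = 6L,
                        stemloop_loop = 5L) {
  if (is.null(regions)) regions <- default_layout(cr_length)
  stopifnot(abs(sum(composition) - 1) < 1e-8,
            abs(sum(cr_composition) - 1) < 1e-8)
  # consistency: stop mode vs length remainder
  pcg <- regions[regions$type == "PCG", , drop = FALSE]
  need <- c(TAA = 0L, TAG = 0L, TA = 2L, T = 1L)
  bad <- pcg$length %% 3L != need[pcg$stop_mode]
  if (any(bad))
    stop("stop mode inconsistent with length remainder for: ",
         paste(pcg$name[bad], collapse = ", "), call. = FALSE)
  structure(list(regions = regions, composition = composition,
                 cr_composition = cr_composition, poly_t = poly_t,
                 stemloop_min_spacer = stemloop_min_spacer,
                 stemloop_stem = stemloop_stem,
                 stemloop_loop = stemloop_loop),
            class = "genome_spec")
}

#' Default region layout for the synthetic generator
#'
#' The canonical 38-region layout (the KR233259 annotation summary shipped
#' with the package): gene order, strands, PCG/rRNA lengths, codons and
#' anticodons, with overlapping junctions flattened to gap 0 and per-tRNA
#' arm geometry columns. Useful as a starting point for customized
#' [genome_spec()] layouts.
#'
#' @param cr_length control-region length in bp.
#' @return a data.frame with one row per region.
#' @export
default_spec_regions <- function(cr_length = 952L) default_layout(cr_length)

default_layout <- function(cr_length = 952L) {
  path <- system.file("extdata", "KR233259_feature_table.tsv",
                      package = "mitoprofile")
  g <- parse_feature_table(path, id = "layout")
  f <- g$features
  gaps <- junction_gaps(g)
  codons <- attr(g, "codons")
  sizes <- feature_sizes(g)
  stop_mode <- sub("^.*/", "", codons[f$name])
  start_codon <- sub("/.*$", "", codons[f$name])
  lay <- data.frame(
    name = f$name, type = f$type, strand = f$strand,
    length = unname(sizes[f$name]),
    gap_after = pmax(gaps$gap_bp[match(f$name, gaps$upstream_feature)], 0L),
    start_codon = unname(start_codon), stop_mode = unname(stop_mode),
    anticodon = f$anticodon, stringsAsFactors = FALSE
  )
  lay$length[lay$type == "control_region"] <- as.integer(cr_length)
  # arm geometry per tRNA
  lay$d_present <- ifelse(lay$type == "tRNA", lay$name != "trnS1", NA)
  lay$t_present <- ifelse(lay$type == "tRNA",
                          !lay$name %in% c("trnN", "trnF"), NA)
  lay$t_stem <- ifelse(lay$type == "tRNA",
                       ifelse(lay$name %in% c("trnC", "trnH", "trnP", "trnS1"),
                              4L, 5L), NA_integer_)
  lay$d_stem <- ifelse(lay$type == "tRNA", 4L, NA_integer_)
  lay
}

#' Arm-level specification of one tRNA
#'
#' @param anticodon 3-nt anticodon placed at the anticodon-loop centre.
#' @param d_stem,d_loop DHU-arm stem (bp) and loop (nt); mitochondrial DHU
#'   stems run 3-4 bp.
#' @param t_stem,t_loop T-arm stem (4-5 bp) and loop.
#' @param var_nt variable-region length.
#' @param d_present,t_present set `FALSE` to delete the whole arm; the arm
#'   is replaced by an unpairable 9-nt linker so the sequence stays
#'   foldable.
#' @param discriminator_nt 0 or 1 unpaired 3' nt.
#' @return a list of class `trna_arm_spec`.
#' @export
trna_arm_spec <- function(anticodon, d_stem = 4L, d_loop = 8L,
                          t_stem = 5L, t_loop = 7L, var_nt = 4L,
                          d_present = TRUE, t_present = TRUE,
                          discriminator_nt = 0L) {
  stopifnot(d_stem %in% 3:4, t_stem %in% 4:5,
            d_loop >= 3, d_loop <= 11, t_loop >= 3, t_loop <= 11,
            var_nt >= 3, var_nt <= 9, nchar(anticodon) == 3)
  structure(list(anticodon = toupper(anticodon), d_stem = d_stem,
                 d_loop = d_loop, t_stem = t_stem, t_loop = t_loop,
                 var_nt = var_nt, d_present = isTRUE(d_present),
                 t_present = isTRUE(t_present),
                 discriminator_nt = discriminator_nt),
            class = "trna_arm_spec")
}

sample_bases <- function(n, comp) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = comp)
}

# a stem arm and its perfect reverse complement
sample_stem <- function(len, comp) {
  arm5 <- sample_bases(len, comp)
  list(arm5 = arm5, arm3 = rev(chartr_vec(arm5)))
}

chartr_vec <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

#' Generate one tRNA sequence from an arm specification
#'
#' Builds the cloverleaf from the inside out: every stem is a perfect
#' Watson-Crick duplex, loops are sampled from the composition, and the
#' anticodon sits at the anticodon-loop centre. A deleted arm is replaced
#' by a 9-nt A/C-only linker (A and C cannot pair with each other, so the
#' linker cannot fold into a stem). [fold_trna()] on the result recovers
#' the specification exactly when no mutations are planted.
#'
#' @param arm_spec a [trna_arm_spec()].
#' @param seed optional integer seed (uses the current RNG state when
#'   missing, so the genome generator can drive it).
#' @param composition base sampling weights for loops.
#' @return nucleotide string.
#' @export
generate_trna <- function(arm_spec, seed = NULL,
                          composition = c(a = 0.39, c = 0.175, g = 0.103,
                                          t = 0.332)) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  # rare constructs admit a second, equally-scoring segmentation (a loop
  # base happening to pair against a shifted stem); resample until the
  # fold-back is unambiguous so the generator honours its contract
  for (try in 1:25) {
    s <- generate_trna_once(arm_spec, composition)
    if (trna_folds_back(s, arm_spec)) return(s)
  }
  s
}

trna_folds_back <- function(s, sp) {
  f <- tryCatch(fold_trna(s), error = function(e) NULL)
  if (is.null(f)) return(FALSE)
  f$acceptor_stem == 7L &&
    identical(f$anticodon_arm$anticodon, chartr("U", "T", sp$anticodon)) &&
    f$anticodon_arm$pairs == 5L &&
    (if (sp$d_present) !is.null(f$d_arm) && f$d_arm$stem_bp == sp$d_stem &&
       f$d_arm$loop_nt == sp$d_loop && f$d_arm$pairs == sp$d_stem
     else is.null(f$d_arm)) &&
    (if (sp$t_present) !is.null(f$t_arm) && f$t_arm$stem_bp == sp$t_stem &&
       f$t_arm$loop_nt == sp$t_loop && f$t_arm$pairs == sp$t_stem &&
       f$variable_nt == sp$var_nt
     else is.null(f$t_arm))
}

generate_trna_once <- function(arm_spec, composition) {
  sp <- arm_spec
  acc <- sample_stem(7L, composition)
  linker <- function(n) sample(c("A", "C"), n, replace = TRUE,
                               prob = c(0.7, 0.3))
  d_seg <- if (sp$d_present) {
    st <- sample_stem(sp$d_stem, composition)
    c(st$arm5, sample_loop(sp$d_loop, composition), st$arm3)
  } else linker(9L)
  ac_st <- sample_stem(5L, composition)
  ac_loop <- c(sample_loop(2L, composition),
               strsplit(chartr("U", "T", sp$anticodon), "")[[1]],
               sample_loop(2L, composition))
  t_seg <- if (sp$t_present) {
    st <- sample_stem(sp$t_stem, composition)
    c(st$arm5, sample_loop(sp$t_loop, composition), st$arm3)
  } else linker(9L)
  paste(c(acc$arm5, d_seg, ac_st$arm5, ac_loop, ac_st$arm3,
          sample_loop(sp$var_nt, composition), t_seg, acc$arm3,
          if (sp$discriminator_nt > 0L) sample_bases(sp$discriminator_nt,
                                                     composition)),
        collapse = "")
}

# loop bases: A/C only — A and C cannot pair with each other (nor G-U
# wobble), so planted loops can never extend a stem by accident and the
# template fold recovers the generated geometry unambiguously
sample_loop <- function(n, comp) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C"), n, replace = TRUE, prob = c(0.7, 0.3))
}

# one PCG on its coding strand: given start codon, internal codons free of
# in-frame stops under table 5, and the requested (possibly incomplete) stop
generate_pcg <- function(len, start_codon, stop_mode, comp) {
  rem <- len %% 3L
  need <- c(TAA = 0L, TAG = 0L, TA = 2L, T = 1L)[[stop_mode]]
  if (rem != need)
    stop("stop mode ", stop_mode, " impossible at length ", len, call. = FALSE)
  tail_len <- nchar(stop_mode)
  n_internal <- (len - 3L - tail_len) %/% 3L
  codons <- character(n_internal)
  i <- 1L
  while (i <= n_internal) {
    cd <- paste(sample_bases(3L, comp), collapse = "")
    if (cd %in% c("TAA", "TAG")) next   # rejection keeps the frame stop-free
    codons[i] <- cd
    i <- i + 1L
  }
  paste0(start_codon, paste(codons, collapse = ""), stop_mode)
}

plant_run <- function(chars, at, len, base = "T", flank = "A") {
  n <- length(chars)
  chars[at:(at + len - 1L)] <- base
  if (at > 1L && chars[at - 1L] == base) chars[at - 1L] <- flank
  if (at + len <= n && chars[at + len] == base) chars[at + len] <- flank
  chars
}

generate_control_region <- function(len, comp, poly_t) {
  chars <- sample_bases(len, comp)
  if (length(poly_t)) {
    anchors <- round(len * seq_along(poly_t) / (length(poly_t) + 1))
    for (k in seq_along(poly_t))
      chars <- plant_run(chars, anchors[k], poly_t[k])
  }
  paste(chars, collapse = "")
}

generate_spacer <- function(len, spec) {
  if (len <= 0L) return("")
  chars <- sample_bases(len, spec$composition)
  need <- 2L * spec$stemloop_stem + spec$stemloop_loop
  if (len >= spec$stemloop_min_spacer && len >= need) {
    st <- sample_stem(spec$stemloop_stem, spec$composition)
    hp <- c(st$arm5, sample_loop(spec$stemloop_loop, spec$composition),
            st$arm3)
    chars[seq_along(hp)] <- hp
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic annotated mitogenome
#'
#' Lays the regions of a [genome_spec()] onto a circular molecule:
#' protein-coding genes get the requested start codon, a stop-free reading
#' frame under the invertebrate mitochondrial code and the requested
#' complete or incomplete stop; tRNAs are built from their arm
#' specifications so [fold_trna()] recovers them; the control region
#' carries the requested poly-T stretches; larger spacers carry planted
#' stem-loops. Minority-strand genes are generated on their coding strand
#' and reverse-complemented into the genome, so genome-level skew emerges
#' from strand placement as in real mitogenomes. The same seed always
#' yields the identical genome.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed (required).
#' @param id genome label.
#' @return a [mito_genome()] with sequence.
#' @export
generate_mitogenome <- function(spec = genome_spec(), seed, id = "synthetic") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  reg <- spec$regions
  pieces <- character(0)
  pos <- 1L
  n <- nrow(reg)
  name <- character(n); type <- character(n); strand <- character(n)
  start <- integer(n); end <- integer(n); anticodon <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- reg[i, ]
    coding <- switch(r$type,
      PCG = generate_pcg(r$length, r$start_codon, r$stop_mode,
                         spec$composition),
      tRNA = generate_trna(trna_arm_spec(
        anticodon = r$anticodon, d_stem = r$d_stem %||% 4L,
        t_stem = r$t_stem %||% 5L,
        d_present = !isFALSE(r$d_present %||% TRUE),
        t_present = !isFALSE(r$t_present %||% TRUE)),
        composition = spec$composition),
      rRNA = paste(sample_bases(r$length, spec$composition), collapse = ""),
      control_region = generate_control_region(r$length,
                                               spec$cr_composition,
                                               spec$poly_t))
    genomic <- if (r$strand == "N") revcomp(coding) else coding
    len_i <- nchar(genomic)
    name[i] <- r$name; type[i] <- r$type; strand[i] <- r$strand
    start[i] <- pos; end[i] <- pos + len_i - 1L
    anticodon[i] <- if (r$type == "tRNA") r$anticodon else NA_character_
    pieces <- c(pieces, genomic)
    pos <- pos + len_i
    gap <- r$gap_after
    if (!is.na(gap) && gap > 0L) {
      pieces <- c(pieces, generate_spacer(gap, spec))
      pos <- pos + gap
    }
  }
  sequence <- paste(pieces, collapse = "")
  mito_genome(id, sequence = sequence, circular = TRUE,
              features = mito_features(name, type, start, end, strand,
                                       anticodon = anticodon))
}

#' Evolve a mitogenome along a tree by site substitutions
#'
#' Drops the root genome down a phylogeny, applying independent per-site
#' substitutions on every branch under a single-parameter (Jukes-Cantor)
#' model: on a branch of expected length `b` substitutions/site (times an
#' optional per-gene rate multiplier), each site changes with probability
#' `3/4 * (1 - exp(-4 b / 3))`, uniformly to one of the other three bases.
#' No indels, so annotations carry over unchanged and the tip genomes stay
#' column-homologous with the root.
#'
#' @param root a [mito_genome()] with sequence.
#' @param tree a `phylo` object or newick string with branch lengths in
#'   expected substitutions per site.
#' @param seed integer seed (required).
#' @param rate_multipliers optional named numeric (> 0), gene name ->
#'   relative rate applied to the sites of that feature.
#' @return a named list of [mito_genome()] objects, one per tip.
#' @export
evolve_on_tree <- function(root, tree, seed, rate_multipliers = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(root$sequence)) stop("root genome carries no sequence")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (!is.null(rate_multipliers) && any(rate_multipliers <= 0))
    stop("rate multipliers must be > 0", call. = FALSE)
  set.seed(as.integer(seed))

  L <- root$length
  rates <- rep(1, L)
  if (!is.null(rate_multipliers)) {
    f <- root$features
    for (g in names(rate_multipliers)) {
      i <- match(g, f$name)
      if (is.na(i)) next
      idx <- if (f$wraps_origin[i]) c(f$start[i]:L, 1:f$end[i]) else
        f$start[i]:f$end[i]
      rates[idx] <- rate_multipliers[[g]]
    }
  }
  bases <- c("A", "C", "G", "T")
  mutate <- function(chars, b) {
    if (b == 0) return(chars)
    p <- 0.75 * (1 - exp(-4 * b * rates / 3))
    hit <- stats::runif(L) < p & chars %in% bases
    k <- sum(hit)
    if (k > 0L) {
      cur <- match(chars[hit], bases)
      shift <- sample.int(3L, k, replace = TRUE)
      chars[hit] <- bases[(cur - 1L + shift) %% 4L + 1L]
    }
    chars
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root_node <- ntip + 1L
  seqs[[root_node]] <- strsplit(toupper(root$sequence), "", fixed = TRUE)[[1]]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[[child]] <- mutate(seqs[[par]], tree$edge.length[e])
  }
  out <- list()
  for (t in seq_len(ntip)) {
    lab <- tree$tip.label[t]
    out[[lab]] <- mito_genome(lab, sequence = paste(seqs[[t]], collapse = ""),
                              circular = root$circular,
                              features = root$features)
  }
  out
}
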