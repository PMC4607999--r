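#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

REGION_TYPES <- c("PCG", "tRNA", "rRNA", "control_region")

#' Construct an annotated mitochondrial genome
#'
#' The central container consumed by every analysis stage: a circular (or
#' linear) molecule of known length, an optional nucleotide sequence, and an
#' ordered table of annotated features (protein-coding genes, tRNAs, rRNAs
#' and the control region).
#'
#' @param id character label for the genome (e.g. a species name or accession).
#' @param length total length in bp. Defaults to `nchar(sequence)` when a
#'   sequence is given, otherwise to the maximum feature end coordinate.
#' @param features a data.frame as returned by [mito_features()], or a list of
#'   rows coercible to one. Sorted by start coordinate on construction.
#' @param sequence optional nucleotide string (A/C/G/T plus IUPAC ambiguity
#'   codes) of exactly `length` characters.
#' @param circular logical; insect mitogenomes are circular.
#'
#' @return an object of class `mitogenome`: a list with elements `id`,
#'   `length`, `circular`, `sequence` (or `NULL`) and `features`.
#'
#' @details Coordinates are 1-based inclusive throughout (the GenBank
#'   convention); conversion to 0-based half-open happens only in
#'   [write_bed()]. Strands are stored with the mitogenome vocabulary
#'   `"J"` (majority strand) / `"N"` (minority strand) and mapped to `+`/`-`
#'   only at export. A feature whose `wraps_origin` flag is set spans the
#'   origin of the circular molecule: it occupies `[start, length]` followed
#'   by `[1, end]`.
#'
#' @examples
#' feats <- mito_features(
#'   name  = c("trnI", "nad2", "control_region"),
#'   type  = c("tRNA", "PCG", "control_region"),
#'   start = c(1, 70, 1100), end = c(66, 1092, 1500),
#'   strand = c("J", "J", "J"), anticodon = c("GAT", NA, NA)
#' )
#' g <- mito_genome("toy", length = 1500, features = feats)
#' g
#' @export
mito_genome <- function(id, length = NULL, features = empty_features(),
                        sequence = NULL, circular = TRUE) {
  features <- as_mito_features(features)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (is.null(length)) length <- nchar(sequence)
    if (nchar(sequence) != length)
      stop("sequence has ", nchar(sequence), " characters but length is ",
           length, call. = FALSE)
  }
  if (is.null(length)) {
    if (nrow(features) == 0L) stop("length required when no features given")
    length <- max(features$end, features$start)
  }
  length <- as.integer(length)
  if (nrow(features) > 0L) {
    bad <- features$start < 1L | features$start > length |
      features$end < 1L | features$end > length
    if (any(bad))
      stop("feature coordinates outside [1, ", length, "]: ",
           paste(features$name[bad], collapse = ", "), call. = FALSE)
    ok_order <- features$start <= features$end | features$wraps_origin
    if (!all(ok_order))
      stop("start > end without wraps_origin: ",
           paste(features$name[!ok_order], collapse = ", "), call. = FALSE)
    if (sum(features$type == "control_region") > 1L)
      stop("more than one control_region feature", call. = FALSE)
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(
    list(id = as.character(id), length = length, circular = isTRUE(circular),
         sequence = sequence, features = features),
    class = "mitogenome"
  )
}

#' Build a feature table for a mitogenome
#'
#' @param name gene/region labels (`cox1`, `trnI`, `rrnL`, `control_region`, ...).
#' @param type region types, each one of `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"J"` (majority) or `"N"` (minority) per feature.
#' @param wraps_origin logical; `TRUE` for a feature spanning the circular
#'   origin (then `start > end` is allowed).
#' @param anticodon optional 3-nt anticodon, only for tRNA features.
#' @return a data.frame of class `mito_features`.
#' @export
mito_features <- function(name, type, start, end, strand,
                          wraps_origin = FALSE, anticodon = NA_character_) {
  df <- data.frame(
    name = as.character(name),
    type = as.character(type),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    wraps_origin = as.logical(rep_len(wraps_origin, length(name))),
    anticodon = toupper(as.character(rep_len(anticodon, length(name)))),
    stringsAsFactors = FALSE
  )
  as_mito_features(df)
}

empty_features <- function() {
  as_mito_features(data.frame(
    name = character(), type = character(), start = integer(),
    end = integer(), strand = character(), wraps_origin = logical(),
    anticodon = character(), stringsAsFactors = FALSE
  ))
}

as_mito_features <- function(x) {
  if (inherits(x, "mito_features")) return(x)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"wraps_origin" %in% names(x)) x$wraps_origin <- FALSE
  if (!"anticodon" %in% names(x)) x$anticodon <- NA_character_
  need <- c("name", "type", "start", "end", "strand", "wraps_origin", "anticodon")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- x[, need, drop = FALSE]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$anticodon <- toupper(x$anticodon)
  if (nrow(x) > 0L) {
    if (!all(x$type %in% REGION_TYPES))
      stop("unknown region type(s): ",
           paste(unique(setdiff(x$type, REGION_TYPES)), collapse = ", "),
           call. = FALSE)
    if (!all(x$strand %in% c("J", "N")))
      stop("strand must be J or N; got: ",
           paste(unique(setdiff(x$strand, c("J", "N"))), collapse = ", "),
           call. = FALSE)
    has_ac <- !is.na(x$anticodon) & nzchar(x$anticodon)
    if (any(has_ac & x$type != "tRNA"))
      stop("anticodon given for non-tRNA feature(s): ",
           paste(x$name[has_ac & x$type != "tRNA"], collapse = ", "),
           call. = FALSE)
    if (any(x$type == "control_region" & x$strand != "J"))
      stop("control region must lie on the J strand", call. = FALSE)
  }
  class(x) <- c("mito_features", "data.frame")
  x
}

#' Feature sizes in bp
#'
#' Size of each feature in base pairs, honouring origin-wrapping features on
#' circular molecules (`size = length - start + 1 + end`).
#'
#' @param genome a [mito_genome()] object.
#' @return integer vector named by feature.
#' @export
feature_sizes <- function(genome) {
  f <- genome$features
  sz <- ifelse(f$wraps_origin,
               genome$length - f$start + 1L + f$end,
               f$end - f$start + 1L)
  setNames(as.integer(sz), f$name)
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp, %s, %d features%s\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (is.null(x$sequence)) " (coordinates only)" else ""))
  if (nrow(x$features) > 0L) {
    tab <- table(factor(x$features$type, levels = REGION_TYPES))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.mitogenome <- function(object, ...) {
  print(object)
  if (nrow(object$features) >= 2L) {
    js <- summarize_junctions(junction_gaps(object))
    cat(sprintf("  junctions: %d spacers (max %s bp), %d overlaps (max %s bp)\n",
                js$n_spacers, js$spacer_max %||% 0,
                js$n_overlaps, js$overlap_max %||% 0))
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (IUPAC codes allowed).
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the coding-strand sequence of a feature
#'
#' Returns the forward slice for J-strand features and the reverse complement
#' for N-strand features, so the result always reads 5'-3' on the feature's
#' coding strand. Origin-wrapping features concatenate the `[start, length]`
#' and `[1, end]` slices before strand handling.
#'
#' @param genome a [mito_genome()] with a sequence.
#' @param feature a feature name present in the genome, or a one-row slice of
#'   `genome$features`.
#' @return nucleotide string.
#' @export
extract_feature_sequence <- function(genome, feature) {
  if (is.null(genome$sequence))
    stop("genome '", genome$id, "' carries no sequence", call. = FALSE)
  if (is.character(feature)) {
    i <- match(feature, genome$features$name)
    if (is.na(i)) stop("no feature named '", feature, "'", call. = FALSE)
    feature <- genome$features[i, , drop = FALSE]
  }
  st <- feature$start[1]; en <- feature$end[1]
  if (st < 1L || st > genome$length || en < 1L || en > genome$length)
    stop("coordinates outside [1, ", genome$length, "]", call. = FALSE)
  s <- if (isTRUE(feature$wraps_origin[1])) {
    paste0(substr(genome$sequence, st, genome$length),
           substr(genome$sequence, 1L, en))
  } else {
    substr(genome$sequence, st, en)
  }
  if (feature$strand[1] == "N") revcomp(s) else s
}

#' Invertebrate mitochondrial (and other) genetic codes
#'
#' A thin wrapper around the NCBI translation tables as shipped with
#' Biostrings. The default, table 5, is the invertebrate mitochondrial code,
#' in which AGA and AGG encode serine rather than acting as stop codons.
#'
#' @param table_id NCBI translation table number (default 5).
#' @return a list with elements `table_id`, `map` (named character vector over
#'   all 64 codons) and `stops` (stop-codon set).
#' @export
genetic_code <- function(table_id = 5) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  list(table_id = as.integer(table_id),
       map = setNames(as.character(map), names(map)),
       stops = names(map)[map == "*"])
}
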