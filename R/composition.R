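#' Base composition and strand skew of a sequence
#'
#' Percentages are computed over counted A/C/G/T only; IUPAC ambiguity codes
#' are preserved in the input but excluded from the denominator, so the four
#' percentages always sum to 100. Skews follow the standard strand-asymmetry
#' convention: `AT skew = (A - T) / (A + T)` and `GC skew = (G - C) / (G + C)`
#' on counts. Values are kept at full precision; see [round_half_up()] for
#' report rounding.
#'
#' @param seq nucleotide string.
#' @return a list of class `composition_stats`: `a_pct`, `c_pct`, `g_pct`,
#'   `t_pct`, `at_pct`, `gc_pct`, `at_skew`, `gc_skew`, `n_counted`.
#' @examples
#' composition("AAAATT")
#' @export
composition <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  cnt <- c(A = sum(chars == "A"), C = sum(chars == "C"),
           G = sum(chars == "G"), T = sum(chars == "T"))
  n <- sum(cnt)
  if (n == 0L) stop("no unambiguous A/C/G/T bases in sequence", call. = FALSE)
  pct <- 100 * cnt / n
  at <- cnt[["A"]] + cnt[["T"]]; gc <- cnt[["G"]] + cnt[["C"]]
  structure(list(
    a_pct = pct[["A"]], c_pct = pct[["C"]], g_pct = pct[["G"]],
    t_pct = pct[["T"]],
    at_pct = pct[["A"]] + pct[["T"]], gc_pct = pct[["G"]] + pct[["C"]],
    at_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NaN,
    gc_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NaN,
    n_counted = as.integer(n)
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%%  A+T %.1f%%  AT skew %.3f  GC skew %.3f (n=%d)\n",
    x$a_pct, x$c_pct, x$g_pct, x$t_pct, x$at_pct, x$at_skew, x$gc_skew,
    x$n_counted))
  invisible(x)
}

#' Skews from printed base percentages
#'
#' Applies the skew formulas directly to four base percentages as printed in
#' a composition table (no re-normalization), e.g. to check a published
#' table's skew columns against its own percentage columns.
#'
#' @param a_pct,c_pct,g_pct,t_pct base percentages (non-negative).
#' @return `c(at_skew, gc_skew)`.
#' @export
skews_from_percentages <- function(a_pct, c_pct, g_pct, t_pct) {
  if (any(c(a_pct, c_pct, g_pct, t_pct) < 0)) stop("negative percentage")
  at <- a_pct + t_pct; gc <- g_pct + c_pct
  if (at == 0 || gc == 0) stop("skew undefined: A+T or G+C is zero",
                               call. = FALSE)
  c(at_skew = (a_pct - t_pct) / at, gc_skew = (g_pct - c_pct) / gc)
}

#' Round half away from zero
#'
#' Decimal rounding as used in printed composition tables (R's `round()`
#' rounds half to even instead).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Start/stop codon assignment for an annotated CDS
#'
#' Mitochondrial protein-coding genes are frequently annotated with
#' incomplete stop codons — a terminal `TA` or bare `T` completed to `TAA`
#' by post-transcriptional polyadenylation. The assignment is made purely
#' from the annotated length: a CDS of length `3k` must end in a complete
#' `TAA`/`TAG`; length `3k + 2` must end in `TA`; length `3k + 1` in `T`.
#'
#' @param cds_seq coding-strand nucleotide string of the annotated CDS
#'   (length >= 6).
#' @param gene optional gene name used in error messages.
#' @return a list of class `codon_assignment`: `start_codon` (first triplet,
#'   verbatim), `stop_codon` (`"TAA"`, `"TAG"`, `"TA"`, `"T"`, or the
#'   terminal triplet when a complete stop is non-canonical), `stop_complete`,
#'   `frame_remainder` (0, 1 or 2) and `start_canonical` (`FALSE` for
#'   non-`ATN` starts such as GTG or TCG, which are flagged, not rejected).
#' @examples
#' codon_assignment("ATGAAATAA")
#' @export
codon_assignment <- function(cds_seq, gene = "CDS") {
  s <- toupper(cds_seq)
  n <- nchar(s)
  if (n < 6L) stop(gene, ": CDS shorter than 6 nt", call. = FALSE)
  start <- substr(s, 1L, 3L)
  rem <- n %% 3L
  if (rem == 0L) {
    stop_codon <- substr(s, n - 2L, n)
    complete <- TRUE
    if (!stop_codon %in% c("TAA", "TAG"))
      warning(gene, ": non-canonical complete stop '", stop_codon, "'",
              call. = FALSE)
  } else if (rem == 2L) {
    stop_codon <- substr(s, n - 1L, n)
    complete <- FALSE
    if (stop_codon != "TA")
      stop(gene, ": length remainder 2 but trailing dinucleotide is '",
           stop_codon, "', not TA — inconsistent annotation", call. = FALSE)
  } else {
    stop_codon <- substr(s, n, n)
    complete <- FALSE
    if (stop_codon != "T")
      stop(gene, ": length remainder 1 but trailing nucleotide is '",
           stop_codon, "', not T — inconsistent annotation", call. = FALSE)
  }
  structure(list(
    start_codon = start, stop_codon = stop_codon, stop_complete = complete,
    frame_remainder = as.integer(rem),
    start_canonical = grepl("^AT[ACGT]$", start)
  ), class = "codon_assignment")
}

#' Tally start and stop codons over a set of assignments
#'
#' @param rows a list of [codon_assignment()] results, or a character vector
#'   of `"START/STOP"` strings as found in a feature table's codon column.
#' @return a list with `start` and `stop` tables (counts sum to the number
#'   of rows).
#' @export
tally_codons <- function(rows) {
  if (is.character(rows)) {
    rows <- rows[!is.na(rows) & nzchar(rows)]
    parts <- strsplit(toupper(rows), "/", fixed = TRUE)
    starts <- vapply(parts, `[`, character(1), 1L)
    stops <- vapply(parts, `[`, character(1), 2L)
  } else {
    starts <- vapply(rows, function(r) r$start_codon, character(1))
    stops <- vapply(rows, function(r) r$stop_codon, character(1))
  }
  list(start = table(starts), stop = table(stops))
}

#' Internal stop codons in a CDS
#'
#' Scans the reading frame for premature stop codons under the given genetic
#' code (default: invertebrate mitochondrial, table 5, where AGA/AGG are
#' serine). The terminal — possibly incomplete — codon is excluded.
#'
#' @param cds_seq coding-strand nucleotide string (length >= 6).
#' @param code a [genetic_code()]; default table 5.
#' @return integer vector of 1-based codon indices holding internal stops;
#'   `integer(0)` means the CDS is clean.
#' @export
validate_cds <- function(cds_seq, code = genetic_code(5)) {
  s <- toupper(cds_seq)
  n <- nchar(s)
  if (n < 6L) stop("CDS shorter than 6 nt", call. = FALSE)
  n_codon <- n %/% 3L
  if (n %% 3L == 0L) n_codon <- n_codon - 1L  # terminal full codon excluded
  if (n_codon < 1L) return(integer(0))
  pos <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(s, pos, pos + 2L)
  aa <- code$map[codons]
  unname(which(!is.na(aa) & aa == "*"))
}

#' Maximal poly-T stretches
#'
#' Finds maximal runs of T of at least `min_len` bases, left to right — the
#' characteristic motif of the insect mitochondrial control region.
#'
#' @param seq nucleotide string.
#' @param min_len minimum run length (>= 2); insect control-region surveys
#'   conventionally report runs of 7 or more.
#' @return a data.frame with columns `start` (1-based within `seq`) and
#'   `length`; zero rows when there is no qualifying run.
#' @export
poly_t_stretches <- function(seq, min_len = 7) {
  if (min_len < 2) stop("min_len must be >= 2", call. = FALSE)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  r <- rle(chars == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], length = r$lengths[keep])
}
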