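#' Inter-feature junction gaps and overlaps
#'
#' For each adjacent pair of features in circular genome order, the signed
#' gap between them: positive values are intergenic spacers, negative values
#' overlaps, zero abutting genes. The gap is attributed to the junction
#' *after* each feature, i.e. `gap_bp = downstream$start - upstream$end - 1`;
#' for the last-to-first junction the genome length enters the arithmetic.
#'
#' @param genome a [mito_genome()] with at least two features.
#' @return a data.frame with columns `upstream_feature`, `downstream_feature`,
#'   `gap_bp` — one row per junction (`n` features give `n` junctions on a
#'   circular genome, `n - 1` on a linear one).
#' @export
junction_gaps <- function(genome) {
  f <- genome$features
  if (nrow(f) < 2L) stop("need at least two features", call. = FALSE)
  f <- f[order(f$start, f$end), , drop = FALSE]
  if (anyDuplicated(f[, c("start", "end")]))
    warning("duplicate feature coordinates", call. = FALSE)
  end_eff <- ifelse(f$wraps_origin, f$start + feature_sizes(genome)[f$name] - 1L,
                    f$end)
  n <- nrow(f)
  up <- seq_len(if (genome$circular) n else n - 1L)
  down <- up %% n + 1L
  gap <- f$start[down] - end_eff[up] - 1L
  if (genome$circular) gap[n] <- gap[n] + genome$length
  data.frame(upstream_feature = f$name[up],
             downstream_feature = f$name[down],
             gap_bp = as.integer(gap),
             stringsAsFactors = FALSE)
}

#' Summarize spacers and overlaps over a set of junctions
#'
#' Spacer statistics are computed over junctions with `gap_bp > 0`, overlap
#' statistics over `gap_bp < 0` (reported as positive magnitudes).
#'
#' @param junctions a data.frame from [junction_gaps()].
#' @return a list: `n_spacers`, `spacer_min`, `spacer_max`,
#'   `spacer_argmax` (the `"upstream|downstream"` pair holding the largest
#'   spacer), and the corresponding `n_overlaps`, `overlap_min`,
#'   `overlap_max`, `overlap_argmax`.
#' @export
summarize_junctions <- function(junctions) {
  sp <- junctions[junctions$gap_bp > 0L, , drop = FALSE]
  ov <- junctions[junctions$gap_bp < 0L, , drop = FALSE]
  pair <- function(d, i) paste(d$upstream_feature[i], d$downstream_feature[i],
                               sep = "|")
  list(
    n_spacers = nrow(sp),
    spacer_min = if (nrow(sp)) min(sp$gap_bp) else NA_integer_,
    spacer_max = if (nrow(sp)) max(sp$gap_bp) else NA_integer_,
    spacer_argmax = if (nrow(sp)) pair(sp, which.max(sp$gap_bp)) else NA_character_,
    n_overlaps = nrow(ov),
    overlap_min = if (nrow(ov)) min(-ov$gap_bp) else NA_integer_,
    overlap_max = if (nrow(ov)) max(-ov$gap_bp) else NA_integer_,
    overlap_argmax = if (nrow(ov)) pair(ov, which.min(ov$gap_bp)) else NA_character_
  )
}

#' Strand-by-region-type census
#'
#' Counts features per (strand, region type): how many PCGs, tRNAs, rRNAs
#' and control regions lie on the majority (J) and minority (N) strands.
#'
#' @param genome a [mito_genome()].
#' @return an integer matrix with rows `J`, `N` and one column per region
#'   type, plus a `total` column.
#' @export
strand_census <- function(genome) {
  f <- genome$features
  tab <- table(factor(f$strand, levels = c("J", "N")),
               factor(f$type, levels = REGION_TYPES))
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(c("J", "N"), REGION_TYPES))
  cbind(m, total = rowSums(m))
}

#' Genes flanking the control region
#'
#' The circular neighbours of the control region; for a control region at
#' either end of the linearized order the neighbour is found by wrapping.
#'
#' @param genome a [mito_genome()] with an annotated control region.
#' @return a character vector `c(upstream, downstream)` of gene names.
#' @export
control_region_flanks <- function(genome) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  i <- which(f$type == "control_region")
  if (length(i) == 0L) stop("no control region annotated", call. = FALSE)
  n <- nrow(f)
  if (n < 2L) stop("no flanking features", call. = FALSE)
  c(upstream = f$name[(i - 2L) %% n + 1L],
    downstream = f$name[i %% n + 1L])
}
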