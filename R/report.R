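#' Feature-table report
#'
#' One row per annotated region in genome order with the derived columns of
#' a mitogenome description table: location, strand, size, the intergenic
#' gap to the next feature in circular order (positive = spacer, negative =
#' overlap, blank = abutting), and — when the genome carries sequence — the
#' start/stop codon assignment of each PCG.
#'
#' @param genome a [mito_genome()].
#' @param path optional TSV output file.
#' @return a data.frame (invisibly when written) with columns `Gene`,
#'   `Location`, `Strand`, `Size`, `Intergenic`, `StartStop`.
#' @export
report_features <- function(genome, path = NULL) {
  f <- genome$features
  sizes <- feature_sizes(genome)
  gaps <- rep(NA_integer_, nrow(f))
  if (nrow(f) >= 2L) {
    j <- junction_gaps(genome)
    gaps <- j$gap_bp[match(f$name, j$upstream_feature)]
  }
  codon_str <- rep("", nrow(f))
  if (!is.null(genome$sequence)) {
    for (i in which(f$type == "PCG")) {
      ca <- codon_assignment(extract_feature_sequence(genome, f$name[i]),
                             gene = f$name[i])
      codon_str[i] <- paste0(ca$start_codon, "/", ca$stop_codon)
    }
  }
  out <- data.frame(
    Gene = ifelse(!is.na(f$anticodon) & nzchar(f$anticodon),
                  sprintf("%s(%s)", f$name, tolower(f$anticodon)), f$name),
    Location = sprintf("%d-%d", f$start, f$end),
    Strand = f$strand,
    Size = unname(sizes),
    Intergenic = ifelse(is.na(gaps) | gaps == 0L, "", as.character(gaps)),
    StartStop = codon_str,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Junction and strand summary as JSON-ready list
#'
#' @param genome a [mito_genome()].
#' @param path optional JSON output file.
#' @return a list with elements `junctions` (from [summarize_junctions()])
#'   and `strand_census`.
#' @export
report_junctions <- function(genome, path = NULL) {
  out <- list(junctions = summarize_junctions(junction_gaps(genome)),
              strand_census = as.data.frame(strand_census(genome)))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Base-composition report
#'
#' One row per region — whole genome, each protein-coding gene in genome
#' order, the rRNAs, and the control region — with base percentages (1
#' decimal), A+T and G+C content, and AT/GC skews (3 decimals), rounded
#' half away from zero as in printed composition tables.
#'
#' @param genome a [mito_genome()] with sequence.
#' @param path optional TSV output file.
#' @return a data.frame with columns `Region`, `A`, `C`, `G`, `T`, `AT`,
#'   `GC`, `ATskew`, `GCskew`.
#' @export
report_composition <- function(genome, path = NULL) {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  f <- genome$features
  keep <- f$type %in% c("PCG", "rRNA", "control_region")
  if (!any(f$type == "control_region"))
    warning("no control region annotated; row omitted", call. = FALSE)
  regions <- c("whole_genome", f$name[keep])
  rows <- lapply(regions, function(r) {
    s <- if (r == "whole_genome") genome$sequence else
      extract_feature_sequence(genome, r)
    cs <- composition(s)
    data.frame(Region = r,
               A = round_half_up(cs$a_pct, 1), C = round_half_up(cs$c_pct, 1),
               G = round_half_up(cs$g_pct, 1), T = round_half_up(cs$t_pct, 1),
               AT = round_half_up(cs$at_pct, 1),
               GC = round_half_up(cs$gc_pct, 1),
               ATskew = round_half_up(cs$at_skew, 3),
               GCskew = round_half_up(cs$gc_skew, 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Cloverleaf report for all tRNAs of a genome
#'
#' @param genome a [mito_genome()] with sequence.
#' @param path optional JSON output file.
#' @return a named list, one entry per tRNA: the [fold_trna()] structure
#'   (arms, anticodon, fold score) plus its dot-bracket string and whether
#'   the folded anticodon matches the annotation.
#' @export
report_trna <- function(genome, path = NULL) {
  f <- genome$features[genome$features$type == "tRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(f))) {
    fold <- fold_trna(extract_feature_sequence(genome, f$name[i]),
                      expected_anticodon = f$anticodon[i])
    out[[f$name[i]]] <- list(
      length = fold$length,
      acceptor_pairs = fold$acceptor_stem,
      d_arm = fold$d_arm %||% "absent",
      anticodon_arm = fold$anticodon_arm,
      t_arm = fold$t_arm %||% "absent",
      fold_score = fold$fold_score,
      dot_bracket = dot_bracket(fold),
      anticodon_match = identical(
        chartr("U", "T", toupper(f$anticodon[i] %||% "")),
        fold$anticodon_arm$anticodon)
    )
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Spacer sequences of a genome
#'
#' The intergenic spacer sequence (forward strand) for every junction with
#' a positive gap.
#'
#' @param genome a [mito_genome()] with sequence.
#' @return a data.frame with columns `junction`, `length`, `sequence`.
#' @export
spacer_sequences <- function(genome) {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  j <- junction_gaps(genome)
  j <- j[j$gap_bp > 0L, , drop = FALSE]
  f <- genome$features
  seqs <- character(nrow(j))
  for (k in seq_len(nrow(j))) {
    up_end <- f$end[match(j$upstream_feature[k], f$name)]
    if (up_end + j$gap_bp[k] <= genome$length) {
      seqs[k] <- substr(genome$sequence, up_end + 1L, up_end + j$gap_bp[k])
    } else {                      # spacer wraps the origin
      seqs[k] <- paste0(substr(genome$sequence, up_end + 1L, genome$length),
                        substr(genome$sequence, 1L,
                               j$gap_bp[k] - (genome$length - up_end)))
    }
  }
  data.frame(junction = paste(j$upstream_feature, j$downstream_feature,
                              sep = "|"),
             length = j$gap_bp, sequence = seqs, stringsAsFactors = FALSE)
}

#' Stem-loop report over all spacers
#'
#' Runs [find_stem_loops()] on every intergenic spacer.
#'
#' @param genome a [mito_genome()] with sequence.
#' @param ... passed to [find_stem_loops()].
#' @param path optional JSON output file.
#' @return a named list, one entry per spacer with at least one hit.
#' @export
report_stemloops <- function(genome, ..., path = NULL) {
  sp <- spacer_sequences(genome)
  out <- list()
  for (k in seq_len(nrow(sp))) {
    hits <- find_stem_loops(sp$sequence[k], ...)
    if (nrow(hits) > 0L)
      out[[sp$junction[k]]] <- list(spacer_length = sp$length[k],
                                    hits = hits)
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
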