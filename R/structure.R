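base_pairs_ok <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (allow_gu) wc | (a == "G" & b == "T") | (a == "T" & b == "G") else wc
}

#' Find stem-loop (hairpin) structures in a sequence
#'
#' Scans for inverted repeats that can fold back into a hairpin: a stem of at
#' least `min_stem` base pairs (Watson-Crick, plus G-T wobble when
#' `allow_gu`) enclosing a loop whose length lies in `loop_range`. A hit is
#' *maximal*: its stem cannot be extended by one further pair either outward
#' or inward (into the loop) without violating the mismatch budget or the
#' loop range. Overlapping hits are allowed.
#'
#' @param seq nucleotide string.
#' @param min_stem minimum stem length in bp.
#' @param loop_range `c(min, max)` loop length in nt.
#' @param allow_gu count G-T (G-U in the RNA) wobble pairs as paired.
#' @param max_mismatch mismatches tolerated in the stem.
#' @return a data.frame sorted by (stem_len desc, start asc) with columns
#'   `start` (1-based), `stem_len`, `loop_len`, `mismatches`. Zero rows when
#'   nothing qualifies.
#' @examples
#' find_stem_loops(paste0("GGGGC", "AAAA", "GCCCC"), min_stem = 4)
#' @export
find_stem_loops <- function(seq, min_stem = 4, loop_range = c(3, 10),
                            allow_gu = TRUE, max_mismatch = 0) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  lmin <- loop_range[1]; lmax <- loop_range[2]
  mm_count <- function(i, s, l) {
    # stem arm1 = i..i+s-1, loop, arm2 = i+s+l..i+2s+l-1 (arm2 read 3'->5')
    k <- seq_len(s)
    sum(!base_pairs_ok(chars[i + k - 1L], chars[i + 2L * s + l - k], allow_gu))
  }
  hits <- list()
  for (i in seq_len(n)) {
    for (l in lmin:lmax) {
      for (s in min_stem:((n - i + 1L - l) %/% 2L)) {
        if (s < min_stem) break
        j_end <- i + 2L * s + l - 1L
        if (j_end > n) break
        mm <- mm_count(i, s, l)
        if (mm > max_mismatch) next
        # maximality: outward extension
        ext_out <- i > 1L && j_end < n &&
          mm_count(i - 1L, s + 1L, l) <= max_mismatch
        # inward extension (consumes two loop bases)
        ext_in <- (l - 2L) >= lmin &&
          mm_count(i, s + 1L, l - 2L) <= max_mismatch
        if (ext_out || ext_in) next
        hits[[length(hits) + 1L]] <-
          c(start = i, stem_len = s, loop_len = l, mismatches = mm)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), mismatches = integer()))
  out <- as.data.frame(do.call(rbind, hits))
  out <- out[order(-out$stem_len, out$start, out$loop_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# enumerate candidate cloverleaf segmentations for a sequence of length L
trna_candidates <- function(L) {
  acc <- 7L; ac_seg <- 17L
  out <- list()
  # a stem of 0 means the whole arm is replaced by an unpaired linker, which
  # may be as long as the largest arm it stands in for (2*4+8 = 16 on the D
  # side, 2*5+7 = 17 on the T side)
  for (disc in 0:1) for (d in c(4L, 3L, 0L)) {
    dls <- if (d > 0L) 3:11 else 0:16
    for (dl in dls) for (t in c(5L, 4L, 0L)) for (v in 3:9) {
      tl <- L - (2L * acc + ac_seg + 2L * d + dl + v + 2L * t + disc)
      if (t > 0L) { if (tl < 3L || tl > 11L) next } else {
        if (tl < 0L || tl > 17L) next }
      out[[length(out) + 1L]] <- c(d = d, dl = dl, t = t, tl = tl,
                                   v = v, disc = disc)
    }
  }
  out
}

#' Fold a tRNA sequence onto the cloverleaf template
#'
#' Searches a constrained cloverleaf template rather than minimizing free
#' energy: a 7-bp acceptor stem, a DHU (D) arm with 0/3/4-bp stem and a
#' 3-11 nt loop, a 5-bp anticodon stem with a 7-nt loop carrying the
#' anticodon at its centre, a 3-9 nt variable region, a T (TPsiC) arm with
#' 0/4/5-bp stem and 3-11 nt loop, and an optional 1-nt discriminator.
#' G-U wobble counts as a pair; each stem tolerates at most one mismatch.
#' The segmentation maximizing the total number of paired stem positions is
#' selected, deterministically (ties broken toward no discriminator, then a
#' longer D stem). Mitochondrial tRNAs often lack an entire D or T arm: an
#' arm whose best stem pairs fewer than 3 bases is reported absent.
#'
#' @param seq tRNA sequence, 55-95 nt (T or U accepted).
#' @param expected_anticodon optional 3-nt anticodon; segmentations placing
#'   it at the anticodon-loop centre take priority.
#' @param allow_gu count G-U wobble pairs (default TRUE).
#' @return an object of class `cloverleaf`: a list with `acceptor_stem`
#'   (paired bases of 7), `d_arm` (`list(stem_bp, loop_nt, pairs)` or `NULL`
#'   when absent), `anticodon_arm` (`list(stem_bp, loop_nt, pairs,
#'   anticodon)`), `t_arm` (as `d_arm`), `variable_nt`, `fold_score` (total
#'   paired stem positions) and the chosen `segments`.
#' @export
fold_trna <- function(seq, expected_anticodon = NULL, allow_gu = TRUE) {
  s <- chartr("Uu", "Tt", toupper(seq))
  L <- nchar(s)
  if (L < 55L || L > 95L)
    stop("tRNA sequence length ", L, " outside [55, 95]", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!is.null(expected_anticodon))
    expected_anticodon <- chartr("U", "T", toupper(expected_anticodon))

  stem_pairs <- function(i5, i3_last, len) {
    if (len == 0L) return(0L)
    k <- seq_len(len)
    sum(base_pairs_ok(chars[i5 + k - 1L], chars[i3_last - k + 1L], allow_gu))
  }
  best <- NULL
  for (cand in trna_candidates(L)) {
    d <- cand[["d"]]; dl <- cand[["dl"]]; t <- cand[["t"]]
    tl <- cand[["tl"]]; v <- cand[["v"]]; disc <- cand[["disc"]]
    # segment starts (1-based)
    p_acc5 <- 1L
    p_d5 <- 8L
    p_dloop <- p_d5 + d
    p_d3 <- p_dloop + dl
    p_ac5 <- p_d3 + d
    p_acloop <- p_ac5 + 5L
    p_ac3 <- p_acloop + 7L
    p_var <- p_ac3 + 5L
    p_t5 <- p_var + v
    p_tloop <- p_t5 + t
    p_t3 <- p_tloop + tl
    p_acc3 <- p_t3 + t
    acc_p <- stem_pairs(p_acc5, p_acc3 + 6L, 7L)
    if (acc_p < 6L) next                       # <=1 mismatch in acceptor
    ac_p <- stem_pairs(p_ac5, p_ac3 + 4L, 5L)
    if (ac_p < 4L) next                        # <=1 mismatch in anticodon stem
    d_p <- stem_pairs(p_d5, p_d3 + d - 1L, d)
    if (d > 0L && d - d_p > 1L) next
    t_p <- stem_pairs(p_t5, p_t3 + t - 1L, t)
    if (t > 0L && t - t_p > 1L) next
    anticodon <- substr(s, p_acloop + 2L, p_acloop + 4L)
    score <- acc_p + ac_p + d_p + t_p
    mm <- (7L - acc_p) + (5L - ac_p) + (d - d_p) + (t - t_p)
    ac_match <- !is.null(expected_anticodon) &&
      identical(anticodon, expected_anticodon)
    # lexicographic: anticodon match, most paired bases, fewest mismatches,
    # then enumeration order (no discriminator first, longer D stem first)
    key <- c(as.integer(ac_match), score, -mm)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] &&
         key[3] > best$key[3])) {
      best <- list(key = key, d = d, dl = dl, t = t, tl = tl, v = v,
                   disc = disc, acc_p = acc_p, ac_p = ac_p, d_p = d_p,
                   t_p = t_p, anticodon = anticodon,
                   starts = c(acc5 = p_acc5, d5 = p_d5, dloop = p_dloop,
                              d3 = p_d3, ac5 = p_ac5, acloop = p_acloop,
                              ac3 = p_ac3, var = p_var, t5 = p_t5,
                              tloop = p_tloop, t3 = p_t3, acc3 = p_acc3))
    }
  }
  if (is.null(best))
    stop("no cloverleaf fold with an anticodon stem of >= 4 paired bases",
         call. = FALSE)
  d_present <- best$d > 0L && best$d_p >= 3L
  t_present <- best$t > 0L && best$t_p >= 3L
  structure(list(
    length = L,
    acceptor_stem = best$acc_p,
    d_arm = if (d_present) list(stem_bp = best$d, loop_nt = best$dl,
                                pairs = best$d_p) else NULL,
    anticodon_arm = list(stem_bp = 5L, loop_nt = 7L, pairs = best$ac_p,
                         anticodon = best$anticodon),
    t_arm = if (t_present) list(stem_bp = best$t, loop_nt = best$tl,
                                pairs = best$t_p) else NULL,
    variable_nt = best$v,
    discriminator_nt = best$disc,
    fold_score = best$acc_p + best$ac_p + best$d_p + best$t_p,
    segments = best$starts,
    stem_lens = c(d = best$d, dl = best$dl, t = best$t, tl = best$tl)
  ), class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  arm <- function(a, what) {
    if (is.null(a)) sprintf("%s absent", what)
    else sprintf("%s %d bp stem (%d paired) / %d nt loop",
                 what, a$stem_bp, a$pairs, a$loop_nt)
  }
  cat(sprintf("<cloverleaf> %d nt, fold score %d\n", x$length, x$fold_score))
  cat(sprintf("  acceptor stem: 7 bp (%d paired)\n", x$acceptor_stem))
  cat("  ", arm(x$d_arm, "D arm"), "\n")
  cat(sprintf("  anticodon arm: 5 bp stem (%d paired), anticodon %s\n",
              x$anticodon_arm$pairs, x$anticodon_arm$anticodon))
  cat("  ", arm(x$t_arm, "T arm"), "\n")
  invisible(x)
}

#' Dot-bracket secondary-structure string for a folded tRNA
#'
#' @param fold a [fold_trna()] result.
#' @return a string of `(`, `)` and `.` of the sequence length, marking the
#'   stem positions of the present arms.
#' @export
dot_bracket <- function(fold) {
  out <- rep(".", fold$length)
  p <- fold$segments
  mark <- function(i5, len, i3) {
    if (len > 0L) {
      out[i5:(i5 + len - 1L)] <<- "("
      out[i3:(i3 + len - 1L)] <<- ")"
    }
  }
  mark(p[["acc5"]], 7L, p[["acc3"]])
  if (!is.null(fold$d_arm)) mark(p[["d5"]], fold$d_arm$stem_bp, p[["d3"]])
  mark(p[["ac5"]], 5L, p[["ac3"]])
  if (!is.null(fold$t_arm)) mark(p[["t5"]], fold$t_arm$stem_bp, p[["t3"]])
  paste(out, collapse = "")
}

#' Check annotated anticodons against folded anticodons
#'
#' Folds every tRNA of an annotated genome and compares the anticodon read
#' from the folded anticodon loop with the annotated one (case-insensitive,
#' T and U equivalent).
#'
#' @param genome a [mito_genome()] with sequence.
#' @return a data.frame with columns `trna`, `annotated`, `folded`, `match`.
#' @export
anticodon_consistency <- function(genome) {
  f <- genome$features[genome$features$type == "tRNA", , drop = FALSE]
  out <- data.frame(trna = character(), annotated = character(),
                    folded = character(), match = logical(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(f))) {
    seq <- extract_feature_sequence(genome, f$name[i])
    fold <- fold_trna(seq)
    ann <- f$anticodon[i]
    folded <- fold$anticodon_arm$anticodon
    out[nrow(out) + 1L, ] <- list(
      f$name[i], ann, folded,
      !is.na(ann) && nzchar(ann) &&
        identical(chartr("U", "T", toupper(ann)), folded))
  }
  out
}
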