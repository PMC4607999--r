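# Independent oracles used to freeze expected values; each deliberately
# uses a different mechanism than the implementation it checks.

# Exhaustive inverted-repeat scan: arm2 must equal the Biostrings reverse
# complement of arm1 (Watson-Crick only, no mismatches). Maximality by the
# same outward/inward extension rule, re-expressed through string equality.
oracle_stem_loops <- function(seq, min_stem, loop_range) {
  n <- nchar(seq)
  is_stem <- function(i, s, l) {
    j <- i + 2 * s + l - 1
    if (i < 1 || j > n || s < 1) return(FALSE)
    arm1 <- substr(seq, i, i + s - 1)
    arm2 <- substr(seq, i + s + l, j)
    identical(arm2, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(arm1))))
  }
  out <- list()
  for (i in seq_len(n)) for (s in min_stem:n) for (l in loop_range[1]:loop_range[2]) {
    if (i + 2 * s + l - 1 > n) next
    if (!is_stem(i, s, l)) next
    if (is_stem(i - 1, s + 1, l)) next                      # outward
    if (l - 2 >= loop_range[1] && is_stem(i, s + 1, l - 2)) next  # inward
    out[[length(out) + 1]] <- c(i, s, l)
  }
  if (!length(out)) return(data.frame(start = integer(), stem_len = integer(),
                                      loop_len = integer()))
  m <- as.data.frame(do.call(rbind, out))
  names(m) <- c("start", "stem_len", "loop_len")
  m[order(-m$stem_len, m$start, m$loop_len), , drop = FALSE]
}

# Exhaustive global alignment score by enumerating every monotone edit
# script (tiny inputs only): match +1, mismatch -1, affine gaps where a
# length-L gap costs open + L * extend (the convention of the alignment
# engine behind align_gene: the first gap position pays open + extend,
# later positions pay extend).
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 4, gap_extend = 1) {
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > nchar(a) && j > nchar(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      rec(i + 1, j + 1, score + s, "m")
    }
    if (i <= nchar(a))
      rec(i + 1, j,
          score - gap_extend - (if (state == "da") 0 else gap_open), "da")
    if (j <= nchar(b))
      rec(i, j + 1,
          score - gap_extend - (if (state == "db") 0 else gap_open), "db")
  }
  rec(1, 1, 0, "m")
  best
}

# four-point condition: which of the three quartet topologies an additive
# distance matrix supports (1: ab|cd, 2: ac|bd, 3: ad|bc)
oracle_quartet <- function(d, a, b, c4, e) {
  s1 <- d[a, b] + d[c4, e]
  s2 <- d[a, c4] + d[b, e]
  s3 <- d[a, e] + d[b, c4]
  which.min(c(s1, s2, s3))
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
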