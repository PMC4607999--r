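#' Align one gene across taxa (center-star progressive alignment)
#'
#' Global multiple alignment by the center-star method: the center is the
#' sequence minimizing the total pairwise edit distance to all others; every
#' other sequence is aligned to it globally (match +1, mismatch -1, gap open
#' -4, gap extend -1) and the pairwise alignments are merged
#' "once a gap, always a gap" onto the growing master. Deterministic; ties
#' for the center go to the earliest input sequence.
#'
#' @param seqs named character vector (or list) of nucleotide sequences,
#'   length >= 2.
#' @param gene gene name recorded in the result.
#' @return an object of class `msa`: `list(labels, seqs, gene)` where `seqs`
#'   are equal-length gapped strings in the input label order; removing the
#'   gaps of any row recovers its input sequence.
#' @export
align_gene <- function(seqs, gene = NA_character_) {
  seqs <- vapply(seqs, toupper, character(1))
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  labels <- names(seqs)
  if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  dmat <- utils::adist(seqs)
  center <- which.min(rowSums(dmat))[1]

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  master_c <- strsplit(seqs[[center]], "", fixed = TRUE)[[1]]
  rows <- list()
  rows[[center]] <- master_c
  for (i in setdiff(seq_len(n), center)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[[i]], subject = seqs[[center]], type = "global",
      substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
    ai <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    ac <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    merged <- merge_onto_master(master_c, ac, ai)
    if (length(merged$master) > length(master_c)) {
      # new gaps opened in the center: propagate to already-merged rows
      for (j in seq_along(rows)) {
        if (!is.null(rows[[j]]) && j != i)
          rows[[j]] <- insert_gaps(rows[[j]], merged$new_gap_cols)
      }
      master_c <- merged$master
    }
    rows[[i]] <- merged$row
  }
  structure(list(labels = labels,
                 seqs = vapply(rows, paste, character(1), collapse = ""),
                 gene = gene),
            class = "msa")
}

# merge a pairwise alignment (center_aln, other_aln) onto the master gapped
# center; returns the updated master, the other row on master columns, and
# the master columns (in the *new* master) that were newly inserted
merge_onto_master <- function(master, center_aln, other_aln) {
  mi <- 1L; ci <- 1L
  new_master <- character(); new_row <- character(); new_cols <- integer()
  nm <- length(master); nc <- length(center_aln)
  while (mi <= nm || ci <= nc) {
    m_gap <- mi <= nm && master[mi] == "-"
    c_gap <- ci <= nc && center_aln[ci] == "-"
    if (mi <= nm && ci <= nc && !m_gap && !c_gap) {
      new_master <- c(new_master, master[mi])
      new_row <- c(new_row, other_aln[ci])
      mi <- mi + 1L; ci <- ci + 1L
    } else if (m_gap) {
      new_master <- c(new_master, "-")
      new_row <- c(new_row, "-")
      mi <- mi + 1L
    } else if (c_gap) {
      new_master <- c(new_master, "-")
      new_row <- c(new_row, other_aln[ci])
      new_cols <- c(new_cols, length(new_master))
      ci <- ci + 1L
    } else break
  }
  list(master = new_master, row = new_row, new_gap_cols = new_cols)
}

insert_gaps <- function(row, cols) {
  if (length(cols) == 0L) return(row)
  out <- character(length(row) + length(cols))
  out[cols] <- "-"
  out[setdiff(seq_along(out), cols)] <- row
  out
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa>%s %d sequences x %d columns\n",
              if (!is.na(x$gene)) paste0(" [", x$gene, "]") else "",
              length(x$seqs), nchar(x$seqs[1])))
  invisible(x)
}

#' Concatenated multi-gene supermatrix
#'
#' Extracts each requested gene from every genome (coding strand), aligns
#' it across taxa with [align_gene()], and concatenates the per-gene
#' alignments in the order genes appear in the first genome's annotation,
#' recording a partition map. The usual input is the 13 mitochondrial
#' protein-coding genes.
#'
#' @param genomes list of [mito_genome()] objects with sequences.
#' @param genes character vector of gene names; default: all PCGs of the
#'   first genome, in genome order.
#' @param gap_fill if `TRUE`, a gene missing from some taxon is filled with
#'   gaps (with a message) instead of raising an error.
#' @return an object of class `supermatrix`: `list(labels, seqs, partitions)`
#'   with `partitions` a data.frame (`gene`, `start`, `end`) tiling the
#'   columns.
#' @export
build_supermatrix <- function(genomes, genes = NULL, gap_fill = FALSE) {
  labels <- vapply(genomes, function(g) g$id, character(1))
  if (anyDuplicated(labels)) stop("duplicate genome ids", call. = FALSE)
  if (is.null(genes)) {
    f1 <- genomes[[1]]$features
    genes <- f1$name[f1$type == "PCG"]
  }
  aligned <- list()
  for (gene in genes) {
    seqs <- setNames(rep(NA_character_, length(genomes)), labels)
    for (k in seq_along(genomes)) {
      g <- genomes[[k]]
      if (gene %in% g$features$name)
        seqs[k] <- extract_feature_sequence(g, gene)
    }
    if (anyNA(seqs)) {
      miss <- labels[is.na(seqs)]
      if (!gap_fill)
        stop("gene '", gene, "' missing in: ", paste(miss, collapse = ", "),
             call. = FALSE)
      message("gap-filling '", gene, "' for: ", paste(miss, collapse = ", "))
      msa <- align_gene(seqs[!is.na(seqs)], gene = gene)
      w <- nchar(msa$seqs[1])
      full <- setNames(rep(strrep("-", w), length(labels)), labels)
      full[msa$labels] <- msa$seqs
      aligned[[gene]] <- list(labels = labels, seqs = unname(full), gene = gene)
    } else {
      aligned[[gene]] <- align_gene(seqs, gene = gene)
    }
  }
  widths <- vapply(aligned, function(a) nchar(a$seqs[1]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  seqs <- vapply(seq_along(labels), function(k) {
    paste(vapply(aligned, function(a) {
      a$seqs[match(labels[k], a$labels)]
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(labels = labels, seqs = seqs,
                 partitions = data.frame(gene = genes, start = starts,
                                         end = ends,
                                         stringsAsFactors = FALSE)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$seqs), nchar(x$seqs[1]), nrow(x$partitions)))
  invisible(x)
}

as_char_matrix <- function(x) {
  if (inherits(x, c("msa", "supermatrix"))) {
    m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
    rownames(m) <- x$labels
    m
  } else if (is.matrix(x) && is.character(x)) {
    x
  } else if (is.character(x)) {
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x) %||% paste0("seq", seq_len(nrow(m)))
    m
  } else stop("cannot interpret input as an alignment", call. = FALSE)
}

#' Uncorrected p-distance matrix
#'
#' For every pair of aligned rows, the proportion of differing sites over
#' the sites comparable in that pair, in percent. Columns where either row
#' carries a gap or an ambiguity code are deleted pairwise (not globally).
#'
#' @param x an `msa`, `supermatrix`, character vector of equal-length
#'   aligned strings, or a character matrix (taxa x sites).
#' @return a symmetric numeric matrix of percent distances with zero
#'   diagonal, labelled by taxon.
#' @examples
#' p_distance(c(a = "ACGT", b = "ACGA"))
#' @export
p_distance <- function(x) {
  m <- as_char_matrix(x)
  if (nrow(m) < 2L) stop("need at least two rows", call. = FALSE)
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok))
      stop("no comparable sites between '", rownames(m)[i], "' and '",
           rownames(m)[j], "'", call. = FALSE)
    d[i, j] <- d[j, i] <- 100 * sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a percent p-distance
#' matrix. The matrix is put into sorted label order first so the result is
#' deterministic with ties broken by label order; negative branch lengths
#' are clamped to zero.
#'
#' @param dm symmetric labelled distance matrix (e.g. from [p_distance()]).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least three taxa", call. = FALSE)
  ord <- order(rownames(dm))
  tr <- ape::nj(dm[ord, ord])
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Bootstrap support for the NJ tree of a supermatrix
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance/neighbor-joining tree per replicate, and reports for each
#' internal bipartition of the full-data tree the percentage of replicate
#' trees containing it, attached as node labels.
#'
#' @param sm a `supermatrix` (or `msa`).
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; required, there is no hidden RNG state.
#' @return the full-data `phylo` tree with `node.label` support percentages.
#' @export
bootstrap_support <- function(sm, replicates = 1000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  m <- as_char_matrix(sm)
  full <- nj_tree(p_distance(m))
  set.seed(as.integer(seed))
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[b]] <- nj_tree(p_distance(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- round_half_up(100 * counts / replicates, 1)
  full
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the internal bipartitions of two unrooted trees
#' over the same leaf set; 0 means identical unrooted topologies.
#'
#' @param t1,t2 `phylo` trees.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param x an `msa` or `supermatrix`.
#' @param path optional output file.
#' @return the lines, invisibly when written.
#' @export
write_phylip <- function(x, path = NULL) {
  lines <- c(sprintf("%d %d", length(x$seqs), nchar(x$seqs[1])),
             sprintf("%s  %s", x$labels, x$seqs))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
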