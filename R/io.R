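#' Parse a tab-delimited mitogenome feature table
#'
#' Reads the compact table dialect used in mitogenome descriptions: one row
#' per gene/region with columns Gene, Location ("start-end", hyphen or
#' en-dash), Strand (J/N), and optionally Size, Intergenic and Start/stop
#' codon. Gene names may carry the anticodon in parentheses, e.g.
#' `trnI(gat)`. Region types are inferred from the gene name: `trn*` is a
#' tRNA, `rrn*` an rRNA, a control-region synonym (`control_region`,
#' `D-loop`, `A+T-rich`, `misc_feature`) the control region, anything else a
#' protein-coding gene.
#'
#' @param x path to a TSV file, or a character vector of its lines.
#' @param id genome label for the result.
#' @return a [mito_genome()] without sequence, of length equal to the largest
#'   end coordinate. When a Size column is present, rows whose printed size
#'   disagrees with `end - start + 1` are flagged in the
#'   `"size_flags"` attribute; the annotated codon column, if present, is kept
#'   in the `"codons"` attribute (named `start/stop` strings).
#' @export
parse_feature_table <- function(x, id = "feature_table") {
  lines <- if (length(x) == 1L && !grepl("\t|\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no features", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(cells[[1]]))
  has_header <- any(grepl("gene|location", header))
  col <- function(key, default = NA_integer_) {
    i <- grep(key, header)[1]
    if (has_header && !is.na(i)) i else default
  }
  i_gene <- if (has_header) col("gene", 1L) else 1L
  i_loc <- if (has_header) col("location", 2L) else 2L
  i_strand <- if (has_header) col("strand", 3L) else 3L
  i_size <- col("size")
  i_inter <- col("intergenic")
  i_codon <- col("codon|start/stop|startstop")
  rows <- if (has_header) cells[-1] else cells
  if (length(rows) == 0L) stop("no features", call. = FALSE)

  get <- function(r, i) if (!is.na(i) && length(r) >= i) trimws(r[[i]]) else ""
  n <- length(rows)
  name <- character(n); start <- integer(n); end <- integer(n)
  strand <- character(n); anticodon <- rep(NA_character_, n)
  size_col <- rep(NA_integer_, n); inter_col <- rep(NA_integer_, n)
  codon_col <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    r <- rows[[k]]
    gene <- get(r, i_gene)
    m <- regmatches(gene, regexec("^([^()]+)\\(([A-Za-z]{3})\\)$", gene))[[1]]
    if (length(m) == 3L) {
      name[k] <- trimws(m[2]); anticodon[k] <- toupper(m[3])
    } else name[k] <- gene
    loc <- get(r, i_loc)
    lm <- regmatches(loc, regexec(
      "^\\s*([0-9,]+)\\s*[-–—]\\s*([0-9,]+)\\s*$", loc))[[1]]
    if (length(lm) != 3L)
      stop("row ", k, " ('", gene, "'): malformed location '", loc, "'",
           call. = FALSE)
    start[k] <- as.integer(gsub(",", "", lm[2], fixed = TRUE))
    end[k] <- as.integer(gsub(",", "", lm[3], fixed = TRUE))
    strand[k] <- get(r, i_strand)
    if (!strand[k] %in% c("J", "N"))
      stop("row ", k, " ('", gene, "'): strand must be J or N, got '",
           strand[k], "'", call. = FALSE)
    sv <- get(r, i_size)
    if (nzchar(sv)) size_col[k] <- as.integer(gsub(",", "", sv, fixed = TRUE))
    iv <- get(r, i_inter)
    if (nzchar(iv))
      inter_col[k] <- as.integer(gsub("−", "-", iv))  # minus sign
    cv <- get(r, i_codon)
    if (nzchar(cv)) codon_col[k] <- toupper(cv)
  }
  type <- infer_region_type(name)
  name[type == "control_region"] <- "control_region"
  feats <- mito_features(name, type, start, end, strand,
                         anticodon = anticodon)
  g <- mito_genome(id, length = max(end, start), features = feats)
  sz <- feature_sizes(g)
  ord <- match(g$features$name, name)
  flags <- !is.na(size_col[ord]) & size_col[ord] != unname(sz)
  attr(g, "size_flags") <- setNames(flags, g$features$name)
  attr(g, "printed_intergenic") <- setNames(inter_col[ord], g$features$name)
  attr(g, "codons") <- setNames(codon_col[ord], g$features$name)
  g
}

infer_region_type <- function(name) {
  low <- tolower(name)
  ifelse(grepl("^trn", low), "tRNA",
  ifelse(grepl("^rrn|^12s|^16s", low), "rRNA",
  ifelse(grepl("control|d-loop|dloop|a\\+t|misc_feature", low),
         "control_region", "PCG")))
}

#' Write a mitogenome feature table
#'
#' Inverse of [parse_feature_table()]: emits the tab-delimited dialect with
#' Gene (anticodon in parentheses for tRNAs), Location, Strand, Size,
#' Intergenic (gap to the next feature in circular order) and Start/stop
#' codon columns.
#'
#' @param genome a [mito_genome()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @param codons optional named character vector `gene -> "START/STOP"`; when
#'   the genome has a sequence these are computed for PCGs automatically.
#' @return the table lines, invisibly when written to a file.
#' @export
write_feature_table <- function(genome, path = NULL, codons = NULL) {
  f <- genome$features
  gene <- ifelse(!is.na(f$anticodon) & nzchar(f$anticodon),
                 sprintf("%s(%s)", f$name, tolower(f$anticodon)), f$name)
  sizes <- feature_sizes(genome)
  gaps <- if (nrow(f) >= 2L) {
    j <- junction_gaps(genome)
    c(j$gap_bp)
  } else rep(NA_integer_, nrow(f))
  if (is.null(codons) && !is.null(genome$sequence)) {
    pcg <- which(f$type == "PCG")
    codons <- setNames(vapply(pcg, function(i) {
      ca <- codon_assignment(extract_feature_sequence(genome, f$name[i]))
      paste0(ca$start_codon, "/", ca$stop_codon)
    }, character(1)), f$name[pcg])
  }
  codon_str <- if (is.null(codons)) rep("", nrow(f)) else {
    out <- codons[f$name]; out[is.na(out)] <- ""; out
  }
  lines <- c(
    "Gene\tLocation\tStrand\tSize\tIntergenic\tStartStop",
    sprintf("%s\t%d-%d\t%s\t%d\t%s\t%s",
            gene, f$start, f$end, f$strand, sizes,
            ifelse(is.na(gaps) | gaps == 0L, "", as.character(gaps)),
            codon_str)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a GenBank flat file into a mitogenome
#'
#' A minimal reader for GenBank-format records of annotated mitogenomes. It
#' understands `CDS`, `tRNA`, `rRNA`, `D-loop` and `misc_feature` keys (the
#' control region is deposited under either of the last two names),
#' `complement(..)` for minority-strand genes, `join(a..b,c..d)` for features
#' spanning the circular origin, `/gene`, `/product` and `/note` qualifiers
#' for naming, and the `ORIGIN` sequence block. Any other feature key
#' triggers a warning and is skipped.
#'
#' @param x path to a GenBank file, or a character vector of its lines.
#' @return a [mito_genome()] with sequence (when an ORIGIN block is present).
#' @export
read_genbank <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "\\s+")[[1]][1] else "genbank"
  circular <- length(locus) > 0 && grepl("circular", locus[1])

  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- fend[fend > fstart[1]][1]
  if (length(fstart) == 0L || is.na(fend)) stop("no FEATURES block")
  fl <- lines[(fstart[1] + 1L):(fend - 1L)]
  is_key <- grepl("^ {1,10}\\S", fl) & !grepl("^ {12,}", fl)
  idx <- which(is_key)
  keymap <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
              `D-loop` = "control_region", misc_feature = "control_region")
  name <- character(); type <- character(); start <- integer()
  end <- integer(); strand <- character(); wraps <- logical()
  anticodon <- character()
  for (k in seq_along(idx)) {
    first <- fl[idx[k]]
    last <- if (k < length(idx)) idx[k + 1L] - 1L else length(fl)
    block <- fl[idx[k]:last]
    key <- strsplit(trimws(first), "\\s+")[[1]][1]
    if (identical(key, "source")) next
    if (!key %in% names(keymap)) {
      warning("skipping unknown feature key '", key, "'", call. = FALSE)
      next
    }
    loc <- sub("^\\S+\\s+", "", trimws(first))
    neg <- grepl("complement", loc)
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    joined <- grepl("join", loc)
    if (length(nums) < 2L) stop("cannot parse location '", loc, "'")
    st <- as.integer(nums[1])
    en <- as.integer(nums[length(nums)])
    qual <- paste(trimws(block[-1]), collapse = " ")
    getq <- function(q) {
      m <- regmatches(qual, regexec(paste0("/", q, '="?([^"/]+)"?'), qual))[[1]]
      if (length(m) == 2L) trimws(m[2]) else NA_character_
    }
    nm <- getq("gene")
    if (is.na(nm)) nm <- getq("product")
    if (is.na(nm)) nm <- getq("note")
    ty <- keymap[[key]]
    if (ty == "control_region") nm <- "control_region"
    if (is.na(nm)) nm <- key
    ac <- NA_character_
    m <- regmatches(nm, regexec("^([^()]+)\\(([A-Za-z]{3})\\)$", nm))[[1]]
    if (length(m) == 3L) { nm <- m[2]; ac <- toupper(m[3]) }
    name <- c(name, nm); type <- c(type, ty)
    start <- c(start, st); end <- c(end, en)
    strand <- c(strand, if (neg) "N" else "J")
    wraps <- c(wraps, joined && st > en)
    anticodon <- c(anticodon, if (ty == "tRNA") ac else NA_character_)
  }

  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    oend <- grep("^//", lines)
    oend <- if (length(oend)) oend[oend > ostart[1]][1] - 1L else length(lines)
    seq <- toupper(gsub("[^A-Za-z]", "", paste(
      lines[(ostart[1] + 1L):oend], collapse = "")))
    if (!nzchar(seq)) seq <- NULL
  }
  len_m <- regmatches(locus[1], regexec("([0-9]+)\\s+bp", locus[1]))[[1]]
  len <- if (length(len_m) == 2L) as.integer(len_m[2]) else NULL
  mito_genome(id, length = len %||% NULL, sequence = seq, circular = circular,
              features = mito_features(name, type, start, end, strand,
                                       wraps_origin = wraps,
                                       anticodon = anticodon))
}

#' Write a mitogenome as a GenBank flat file
#'
#' Companion to [read_genbank()]; `read_genbank(write_genbank(g))` preserves
#' every feature and coordinate (and the sequence, when present).
#'
#' @param genome a [mito_genome()].
#' @param path optional output file.
#' @return the record lines, invisibly when written to a file.
#' @export
write_genbank <- function(genome, path = NULL) {
  f <- genome$features
  keymap <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control_region = "D-loop")
  out <- c(sprintf("LOCUS       %s%17d bp    DNA     %s     INV",
                   genome$id, genome$length,
                   if (genome$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrion.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", genome$length))
  for (i in seq_len(nrow(f))) {
    loc <- if (f$wraps_origin[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i], genome$length, f$end[i])
    } else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    key <- keymap[[f$type[i]]]
    out <- c(out, sprintf("     %-16s%s", key, loc))
    nm <- f$name[i]
    if (!is.na(f$anticodon[i]) && nzchar(f$anticodon[i]))
      nm <- sprintf("%s(%s)", nm, tolower(f$anticodon[i]))
    out <- c(out, sprintf('                     /gene="%s"', nm))
  }
  if (!is.null(genome$sequence)) {
    out <- c(out, "ORIGIN")
    s <- genome$sequence
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))))
    }
  }
  out <- c(out, "//")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Export annotations as GFF3
#'
#' GFF3 uses 1-based inclusive coordinates, matching the internal convention;
#' strand J maps to `+` and N to `-`. Origin-wrapping features are emitted as
#' two lines sharing one `ID`.
#'
#' @param genome a [mito_genome()].
#' @param path optional output file.
#' @return GFF3 lines, invisibly when written to a file.
#' @export
write_gff <- function(genome, path = NULL) {
  f <- genome$features
  somap <- c(PCG = "gene", tRNA = "tRNA", rRNA = "rRNA",
             control_region = "D_loop")
  out <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", genome$id, genome$length))
  for (i in seq_len(nrow(f))) {
    strand <- if (f$strand[i] == "J") "+" else "-"
    attrs <- sprintf("ID=%s;Name=%s", f$name[i], f$name[i])
    if (!is.na(f$anticodon[i]) && nzchar(f$anticodon[i]))
      attrs <- paste0(attrs, ";anticodon=", f$anticodon[i])
    seg <- if (f$wraps_origin[i]) {
      rbind(c(f$start[i], genome$length), c(1L, f$end[i]))
    } else rbind(c(f$start[i], f$end[i]))
    for (r in seq_len(nrow(seg)))
      out <- c(out, paste(genome$id, "mitoprofile", somap[[f$type[i]]],
                          seg[r, 1], seg[r, 2], ".", strand, ".", attrs,
                          sep = "\t"))
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Export annotations as BED6
#'
#' BED uses 0-based half-open coordinates: a feature at 1-based `[start, end]`
#' becomes BED `start-1`, `end`. Origin-wrapping features are emitted as two
#' lines with the same name.
#'
#' @inheritParams write_gff
#' @return BED lines, invisibly when written to a file.
#' @export
write_bed <- function(genome, path = NULL) {
  f <- genome$features
  out <- character()
  for (i in seq_len(nrow(f))) {
    strand <- if (f$strand[i] == "J") "+" else "-"
    seg <- if (f$wraps_origin[i]) {
      rbind(c(f$start[i], genome$length), c(1L, f$end[i]))
    } else rbind(c(f$start[i], f$end[i]))
    for (r in seq_len(nrow(seg)))
      out <- c(out, paste(genome$id, seg[r, 1] - 1L, seg[r, 2],
                          f$name[i], 0L, strand, sep = "\t"))
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Write the genome sequence as FASTA
#'
#' @param genome a [mito_genome()] with sequence.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
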