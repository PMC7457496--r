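#' @title Gene feature and feature table containers
#' @description A `feature` is one annotated gene element: a kind (CDS, tRNA,
#'   rRNA or other), a strand, a `codon_start` frame offset for CDS, and one
#'   or more non-overlapping intervals (multi-exon features).  Intervals are
#'   stored 0-based half-open in ascending genome order; strand decides
#'   transcription direction downstream.
#' @param gene gene symbol
#' @param kind one of "CDS", "tRNA", "rRNA", "other"
#' @param intervals data.frame with integer columns start, end (0-based
#'   half-open), ascending and non-overlapping
#' @param strand "+" or "-"
#' @param codon_start reading-frame offset 1..3 (CDS only)
#' @return an object of class `feature`
#' @export
feature <- function(gene, kind = "CDS", intervals, strand = "+",
                    codon_start = 1L) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "other"))
  intervals <- data.frame(start = as.integer(intervals$start),
                          end = as.integer(intervals$end))
  if (nrow(intervals) == 0L) stop("feature needs at least one interval")
  o <- order(intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  if (any(intervals$end <= intervals$start))
    stop("feature '", gene, "': invalid interval bounds")
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)]))
    stop("feature '", gene, "': overlapping intervals")
  structure(list(gene = as.character(gene), kind = kind,
                 intervals = intervals, strand = strand,
                 codon_start = as.integer(codon_start)),
            class = "feature")
}

#' @rdname feature
#' @param seq_id id of the annotated sequence
#' @param features list of `feature` objects
#' @param seq_length optional sequence length used to validate coordinates
#' @export
feature_table <- function(seq_id, features, seq_length = NULL) {
  stopifnot(all(vapply(features, inherits, TRUE, "feature")))
  if (!is.null(seq_length)) {
    for (f in features)
      if (any(f$intervals$end > seq_length))
        stop("feature '", f$gene, "' extends past sequence end (",
             seq_length, " nt)")
  }
  structure(list(seq_id = as.character(seq_id), features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  kinds <- table(vapply(x$features, `[[`, "", "kind"))
  cat(sprintf("<feature_table> %s: %d features (%s)\n", x$seq_id,
              length(x$features),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}

# Parse a GenBank location string like "join(10..18,30..38)" or
# "complement(5..10)".  Returns list(intervals = 0-based df, strand).
parse_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    if (grepl("^complement", sub("^(join|order)\\(", "", loc)))
      strand <- "-"
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)(\\.\\.(\\d+))?$", parts))
  if (any(vapply(m, length, 0L) == 0L))
    stop("cannot parse location: ", loc)
  starts <- as.integer(vapply(m, `[`, "", 2L))
  ends_chr <- vapply(m, `[`, "", 4L)
  ends <- ifelse(nzchar(ends_chr) & !is.na(ends_chr),
                 suppressWarnings(as.integer(ends_chr)), starts)
  list(intervals = data.frame(start = starts - 1L, end = ends), strand = strand)
}

#' Read a feature table
#'
#' Accepts either the feature-table portion of a GenBank flat file or the
#' NCBI 5-column tabular dialect (`>Feature seqid` header).  `join()`
#' locations are decomposed into ordered intervals, `complement()` maps to
#' strand "-", and coordinates are converted to 0-based half-open.
#' @param path input path
#' @param seq_length optional length for coordinate validation
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path, seq_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^>Feature", lines[1]))
    return(read_tbl_features(lines, seq_length))
  read_genbank_features(lines, seq_length)
}

read_genbank_features <- function(lines, seq_length = NULL) {
  seqid <- "seq"
  loc_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(loc_line))
    seqid <- strsplit(trimws(sub("^LOCUS", "", loc_line[1])), "\\s+")[[1]][1]
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) fstart <- 0L
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
  body <- lines[seq(fstart[1] + 1L, fend - 1L)]
  body <- body[nzchar(trimws(body))]
  # feature starts: key in columns 6-20 (i.e. 5 leading spaces then non-space)
  is_new <- grepl("^ {2,8}\\S", body) & !grepl("^ {10,}", body)
  feats <- list()
  i <- 1L
  while (i <= length(body)) {
    if (!is_new[i]) { i <- i + 1L; next }
    toks <- strsplit(trimws(body[i]), "\\s+")[[1]]
    key <- toks[1]
    loc <- if (length(toks) > 1L) paste(toks[-1], collapse = "") else ""
    j <- i + 1L
    while (j <= length(body) && !is_new[j] &&
           !grepl("^\\s+/", body[j])) {          # location continuation
      loc <- paste0(loc, trimws(body[j]))
      j <- j + 1L
    }
    quals <- character(0)
    while (j <= length(body) && !is_new[j]) {
      quals <- c(quals, trimws(body[j]))
      j <- j + 1L
    }
    gene <- sub('^/gene="?([^"]*)"?$', "\\1",
                grep("^/gene=", quals, value = TRUE))
    cs <- sub("^/codon_start=([0-9]).*$", "\\1",
              grep("^/codon_start=", quals, value = TRUE))
    kind <- if (key %in% c("CDS", "tRNA", "rRNA")) key else "other"
    if (key %in% c("CDS", "tRNA", "rRNA")) {
      p <- parse_location(loc)
      feats[[length(feats) + 1L]] <- feature(
        gene = if (length(gene)) gene[1] else key,
        kind = kind, intervals = p$intervals, strand = p$strand,
        codon_start = if (length(cs)) as.integer(cs[1]) else 1L)
    }
    i <- j
  }
  feature_table(seqid, feats, seq_length = seq_length)
}

read_tbl_features <- function(lines, seq_length = NULL) {
  seqid <- trimws(sub("^>Feature\\s*", "", lines[1]))
  feats <- list()
  cur <- NULL
  flush <- function(cur, feats) {
    if (is.null(cur)) return(feats)
    strand <- if (cur$starts[1] > cur$ends[1]) "-" else "+"
    s0 <- pmin(cur$starts, cur$ends) - 1L
    e0 <- pmax(cur$starts, cur$ends)
    feats[[length(feats) + 1L]] <- feature(
      gene = if (nzchar(cur$gene)) cur$gene else cur$key,
      kind = if (cur$key %in% c("CDS", "tRNA", "rRNA")) cur$key else "other",
      intervals = data.frame(start = s0, end = e0), strand = strand,
      codon_start = cur$codon_start)
    feats
  }
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 3L && nzchar(f[1]) && nzchar(f[3])) {
      feats <- flush(cur, feats)
      cur <- list(key = f[3], starts = as.integer(f[1]),
                  ends = as.integer(f[2]), gene = "", codon_start = 1L)
    } else if (length(f) >= 2L && nzchar(f[1])) {
      cur$starts <- c(cur$starts, as.integer(f[1]))
      cur$ends <- c(cur$ends, as.integer(f[2]))
    } else if (length(f) >= 5L) {
      if (f[4] == "gene") cur$gene <- f[5]
      if (f[4] == "codon_start") cur$codon_start <- as.integer(f[5])
    }
  }
  feats <- flush(cur, feats)
  feature_table(seqid, feats, seq_length = seq_length)
}

#' Write a feature table in the NCBI 5-column dialect
#' @param ft a [feature_table()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_feature_table <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">Feature ", ft$seq_id), con)
  for (f in ft$features) {
    iv <- f$intervals
    s1 <- iv$start + 1L
    e1 <- iv$end
    if (f$strand == "-") { tmp <- s1; s1 <- e1; e1 <- tmp }
    key <- if (f$kind == "other") "misc_feature" else f$kind
    writeLines(paste0(s1[1], "\t", e1[1], "\t", key), con)
    if (nrow(iv) > 1L)
      writeLines(paste0(s1[-1], "\t", e1[-1]), con)
    writeLines(paste0("\t\t\tgene\t", f$gene), con)
    if (f$kind == "CDS")
      writeLines(paste0("\t\t\tcodon_start\t", f$codon_start), con)
  }
  invisible(path)
}
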