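#' @title Nucleotide sequence container
#' @description Lightweight container for a single nucleotide sequence:
#'   an id, upper-cased residues over the IUPAC alphabet, a circular flag and
#'   a free-text description.  All plastidkit operations accept either an
#'   `nt_seq` or a bare character string.
#' @param id sequence identifier (single string)
#' @param residues nucleotide string; case-normalized to upper on ingest
#' @param circular is the molecule circular?
#' @param description free-text description (FASTA header remainder)
#' @return an object of class `nt_seq`
#' @export
nt_seq <- function(id, residues, circular = FALSE, description = "") {
  residues <- toupper(as.character(residues))
  if (length(residues) != 1L || !nzchar(residues))
    stop("residues must be a single non-empty string")
  bad <- gsub("[ACGTUNRYSWKMBDHV]", "", residues)
  if (nzchar(bad))
    stop("invalid residue characters: ", paste(unique(strsplit(bad, "")[[1]]),
                                               collapse = ""))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  structure(list(id = as.character(id), residues = residues,
                 circular = isTRUE(circular),
                 description = as.character(description)),
            class = "nt_seq")
}

#' @export
print.nt_seq <- function(x, ...) {
  cat(sprintf("<nt_seq> %s: %s nt%s\n", x$id,
              format(nchar(x$residues), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Extract the residue string from a sequence-like object
#' @param x an `nt_seq` or character scalar
#' @return upper-case residue string
#' @export
residues <- function(x) {
  if (inherits(x, "nt_seq")) return(x$residues)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected an nt_seq or a single character string")
}

seq_id <- function(x, default = "seq") {
  if (inherits(x, "nt_seq")) x$id else default
}

#' Read a FASTA file
#'
#' @param path path to a (multi-)FASTA file
#' @param circular mark all records circular?
#' @return list of [nt_seq] objects, in file order
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    first_bad <- which(!hdr & nzchar(lines))[1]
    stop("malformed FASTA: line ", first_bad, " precedes any header")
  }
  grp <- cumsum(hdr)
  out <- vector("list", sum(hdr))
  hidx <- which(hdr)
  for (k in seq_along(hidx)) {
    h <- sub("^>", "", lines[hidx[k]])
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body <- lines[grp == k & !hdr]
    res <- paste(body, collapse = "")
    if (!nzchar(res))
      stop("malformed FASTA: empty record '", id, "' at line ", hidx[k])
    out[[k]] <- nt_seq(id, res, circular = circular, description = desc)
  }
  out
}

#' Write sequences to FASTA
#' @param seqs an `nt_seq`, character vector, or list of either
#' @param path output path
#' @param width line wrap width
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "nt_seq") || is.character(seqs)) seqs <- as.list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    id <- if (inherits(s, "nt_seq")) s$id else
      if (!is.null(names(seqs)) && nzchar(names(seqs)[k])) names(seqs)[k] else
        paste0("seq", k)
    desc <- if (inherits(s, "nt_seq") && nzchar(s$description))
      paste0(" ", s$description) else ""
    res <- residues(s)
    writeLines(paste0(">", id, desc), con)
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Standard complement including IUPAC ambiguity codes; the input container
#' type (string or [nt_seq]) is preserved.
#' @param x sequence-like object
#' @return reverse complement, same type as input
#' @export
reverse_complement <- function(x) {
  s <- residues(x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (inherits(x, "nt_seq"))
    nt_seq(x$id, rc, circular = x$circular, description = x$description)
  else rc
}

#' GC content
#'
#' Fraction (G + C) / (A + C + G + T); N and other ambiguity codes are
#' excluded from both numerator and denominator.
#' @param x sequence-like object
#' @param as_percent return a percentage rounded to 2 decimals?
#' @return fraction in \[0, 1\] (or percent)
#' @export
gc_content <- function(x, as_percent = FALSE) {
  s <- residues(x)
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  denom <- sum(cnt)
  if (denom == 0) stop("gc_content undefined: no unambiguous bases")
  f <- unname((cnt[["C"]] + cnt[["G"]]) / denom)
  if (as_percent) round(100 * f, 2) else f
}

# ---- genome regions -------------------------------------------------------

#' Construct a genome-region table
#'
#' Regions use 0-based half-open coordinates internally; human-facing reports
#' are 1-based inclusive.  Intervals crossing a circular origin are split into
#' two rows sharing a label.
#' @param seq_id reference sequence id
#' @param start,end 0-based half-open bounds
#' @param strand "+" or "-"
#' @param label region labels (LSC/IRa/SSC/IRb/other)
#' @return data.frame with columns seq_id, start, end, strand, label
#' @export
genome_region <- function(seq_id, start, end, strand = "+", label = "other") {
  df <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$end <= df$start))
    stop("invalid region bounds: require 0 <= start < end")
  df
}

#' Write regions as BED6
#' @param regions region data.frame (see [genome_region()])
#' @param path output path
#' @return invisibly, `path`
#' @export
write_region_bed <- function(regions, path) {
  if (is.null(regions) || nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(regions$seq_id, regions$start, regions$end,
                    regions$label, ".", regions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into a region table
#' @param path BED file path
#' @return region data.frame
#' @export
read_region_bed <- function(path) {
  if (file.size(path) == 0L)
    return(genome_region(character(0), integer(0), integer(0))[0, ])
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  genome_region(df[[1]], df[[2]], df[[3]], df[[6]], df[[4]])
}
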