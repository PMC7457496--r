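#' Dispersed-repeat search parameters
#' @param min_length minimum repeat length (nt), default 30
#' @param max_hamming maximum Hamming distance between copies, default 3
#' @param kinds subset of forward/reverse/complement/palindromic
#' @param exclude_ir_duplicate drop hits that are merely the IRa/IRb
#'   duplication seen at mirrored offsets
#' @return validated parameter list
#' @export
repeat_search_params <- function(min_length = 30L, max_hamming = 3L,
                                 kinds = c("forward", "reverse", "complement",
                                           "palindromic"),
                                 exclude_ir_duplicate = TRUE) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  stopifnot(min_length > max_hamming, max_hamming >= 0L)
  list(min_length = as.integer(min_length),
       max_hamming = as.integer(max_hamming), kinds = kinds,
       exclude_ir_duplicate = isTRUE(exclude_ir_duplicate))
}

complement_seq <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
}

reverse_seq <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

#' Find maximal dispersed repeat pairs
#'
#' Enumerates, for each requested kind, every maximal pair of segments whose
#' copies match within `max_hamming` mismatches at length >= `min_length`
#' (REPuter's four-kind taxonomy: forward = direct copy, palindromic =
#' reverse complement, reverse = reversed only, complement = complemented
#' only).  Maximality means the pair cannot be extended on either side
#' without exceeding the Hamming budget.  Each unordered pair is reported
#' once, with `start1 <= start2`.  When `exclude_ir_duplicate` and a
#' structure is supplied, hits whose two copies sit at mirrored offsets of
#' IRa and IRb (the quadripartite duplication itself) are dropped.
#' @param genome sequence-like object
#' @param params [repeat_search_params()]
#' @param structure optional [quadripartite_structure()] for IR exclusion
#' @return data.frame: kind, start1, start2 (0-based), length, hamming
#' @export
find_maximal_repeats <- function(genome, params = repeat_search_params(),
                                 structure = NULL) {
  s <- residues(genome)
  n <- nchar(s)
  if (n < 2L * params$min_length) stop("genome too short for repeat search")
  out <- list()
  scan_kind <- function(kind) {
    if (kind == "forward") {
      d <- cpp_diag_repeats(s, s, params$min_length, params$max_hamming, 1L)
      if (nrow(d) == 0L) return(NULL)
      data.frame(kind = kind, start1 = d$i, start2 = d$j, length = d$len,
                 hamming = d$ham, stringsAsFactors = FALSE)
    } else if (kind == "complement") {
      d <- cpp_diag_repeats(s, complement_seq(s), params$min_length,
                            params$max_hamming, 1L)
      if (nrow(d) == 0L) return(NULL)
      data.frame(kind = kind, start1 = d$i, start2 = d$j, length = d$len,
                 hamming = d$ham, stringsAsFactors = FALSE)
    } else {
      t <- if (kind == "palindromic") reverse_complement(s) else reverse_seq(s)
      d <- cpp_diag_repeats(s, t, params$min_length, params$max_hamming,
                            -(n - 1L))
      if (nrow(d) == 0L) return(NULL)
      # map the transformed copy back to genome coordinates
      data.frame(kind = kind, start1 = d$i, start2 = n - d$j - d$len,
                 length = d$len, hamming = d$ham, stringsAsFactors = FALSE)
    }
  }
  for (kind in params$kinds) out[[kind]] <- scan_kind(kind)
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(kind = character(0), start1 = integer(0),
                      start2 = integer(0), length = integer(0),
                      hamming = integer(0)))
  # canonical unordered pair: start1 <= start2, then de-duplicate the
  # symmetric twin every self-comparison produces
  swap <- hits$start1 > hits$start2
  tmp <- hits$start1[swap]
  hits$start1[swap] <- hits$start2[swap]
  hits$start2[swap] <- tmp
  hits <- unique(hits)
  hits <- hits[!(hits$start1 == hits$start2), , drop = FALSE]  # degenerate
  if (params$exclude_ir_duplicate && !is.null(structure)) {
    r <- structure$regions
    ira <- r[r$label == "IRa", , drop = FALSE]
    irb <- r[r$label == "IRb", , drop = FALSE]
    if (nrow(ira) == 1L && nrow(irb) == 1L) {
      # slack: a maximal window can chance-extend a few bases past the IR
      # boundary while absorbing its Hamming budget
      slack <- params$max_hamming + 5L
      in_ira <- hits$start1 >= ira$start - slack &
        hits$start1 + hits$length <= ira$end + slack
      in_irb <- hits$start2 >= irb$start - slack &
        hits$start2 + hits$length <= irb$end + slack
      mirrored <- abs((hits$start1 - ira$start) -
                        (irb$end - (hits$start2 + hits$length))) <= slack
      hits <- hits[!(in_ira & in_irb & mirrored), , drop = FALSE]
    }
  }
  hits <- hits[order(hits$kind, hits$start1, hits$start2), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assign repeats to genomic context
#'
#' Each hit is placed by the midpoint of its first copy: exon when inside a
#' feature interval, intron when inside a feature's span but between its
#' intervals, intergenic otherwise.
#' @param hits output of [find_maximal_repeats()]
#' @param features a [feature_table()]
#' @return list(per_hit, counts, percentages)
#' @export
classify_repeat_locations <- function(hits, features) {
  spans <- lapply(features$features, function(f)
    c(min(f$intervals$start), max(f$intervals$end)))
  label_one <- function(mid) {
    for (k in seq_along(features$features)) {
      f <- features$features[[k]]
      if (mid >= spans[[k]][1] && mid < spans[[k]][2]) {
        inside <- any(mid >= f$intervals$start & mid < f$intervals$end)
        return(if (inside) "exon" else "intron")
      }
    }
    "intergenic"
  }
  mids <- hits$start1 + hits$length %/% 2L
  lab <- vapply(mids, label_one, "")
  counts <- c(intergenic = sum(lab == "intergenic"),
              exon = sum(lab == "exon"), intron = sum(lab == "intron"))
  pct <- if (sum(counts) > 0) round(100 * counts / sum(counts), 2) else counts * 0
  list(per_hit = lab, counts = counts, percentages = pct)
}

#' Write repeat hits as TSV
#' @param hits output of [find_maximal_repeats()]
#' @param path output path
#' @param context optional per-hit context labels
#' @return invisibly, `path`
#' @export
write_repeat_tsv <- function(hits, path, context = NULL) {
  out <- data.frame(kind = hits$kind, pos1 = hits$start1 + 1L,
                    pos2 = hits$start2 + 1L, length = hits$length,
                    hamming = hits$hamming)
  if (!is.null(context)) out$context <- context
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
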