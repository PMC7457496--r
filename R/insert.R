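#' Detect foreign (mitochondrion-derived) inserts by windowed homology
#'
#' Slides a window along the genome and scores each window against a plastid
#' and a mitochondrial reference collection by shared 31-mer fraction
#' (strand-agnostic), converted to an approximate per-base identity
#' (`fraction^(1/k)`).  Windows are labeled plastid, mito-like (mitochondrial
#' identity exceeds the plastid identity and the 70% threshold) or
#' unclassified; adjacent non-plastid windows are merged and runs of at
#' least `min_insert` nt are reported, with boundaries refined to base
#' resolution (maximal run of bases not covered by any plastid-shared
#' k-mer) and flanking genes looked up when annotations are supplied.
#' @param genome sequence-like object
#' @param plastid_refs,mito_refs lists of sequence-like reference collections
#' @param window,step sliding-window geometry (nt)
#' @param min_insert shortest reportable insert (nt)
#' @param identity_threshold homology call threshold (approximate identity)
#' @param features optional [feature_table()] for flanking-gene lookup
#' @param k seed length
#' @return data.frame of calls: start, end (0-based half-open), length,
#'   classification, mito_identity, plastid_identity, flank_gene_left,
#'   flank_gene_right
#' @export
detect_foreign_insert <- function(genome, plastid_refs, mito_refs,
                                  window = 500L, step = 250L,
                                  min_insert = 1000L,
                                  identity_threshold = 0.7,
                                  features = NULL, k = 31L) {
  if (length(plastid_refs) == 0L || length(mito_refs) == 0L)
    stop("both reference collections must be non-empty")
  s <- residues(genome)
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), classification = character(0),
                      mito_identity = numeric(0), plastid_identity = numeric(0),
                      flank_gene_left = character(0),
                      flank_gene_right = character(0))
  if (n < window) return(empty)
  mem_p <- cpp_kmer_member(s, vapply(plastid_refs, residues, ""), k)
  mem_m <- cpp_kmer_member(s, vapply(mito_refs, residues, ""), k)
  np <- length(mem_p)
  cs_p <- c(0L, cumsum(as.integer(mem_p)))
  cs_m <- c(0L, cumsum(as.integer(mem_m)))
  win_start <- seq(0L, n - window, by = step)          # 0-based
  frac <- function(cs, w0) {
    lo <- w0 + 1L
    hi <- min(np, w0 + window - k + 1L)
    if (hi < lo) return(0)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  id_p <- vapply(win_start, function(w) frac(cs_p, w), 0)^(1 / k)
  id_m <- vapply(win_start, function(w) frac(cs_m, w), 0)^(1 / k)
  label <- ifelse(id_m > id_p & id_m > identity_threshold, "mito-like",
                  ifelse(id_p >= identity_threshold, "plastid", "unclassified"))
  nonp <- label != "plastid"
  if (!any(nonp)) return(empty)
  # per-base plastid k-mer coverage for boundary refinement
  cov_p <- logical(n)
  if (any(mem_p)) {
    t1 <- tabulate(which(mem_p), n + 1L)
    t2 <- tabulate(which(mem_p) + k, n + 1L)
    cov_p <- cumsum(t1 - t2)[seq_len(n)] > 0L
  }
  r <- rle(nonp)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  calls <- list()
  for (w in which(r$values)) {
    i0 <- win_start[starts[w]]                       # run span, 0-based
    i1 <- win_start[ends[w]] + window
    # refine: maximal run of non-plastid-covered bases intersecting the span
    lo <- i0; hi <- min(i1, n)
    while (lo > 0L && !cov_p[lo]) lo <- lo - 1L      # cov_p is 1-based
    while (lo < n && cov_p[lo + 1L]) lo <- lo + 1L
    while (hi < n && !cov_p[hi + 1L]) hi <- hi + 1L
    while (hi > lo && cov_p[hi]) hi <- hi - 1L
    if (hi - lo < min_insert) next
    widx <- starts[w]:ends[w]
    mito_id <- mean(id_m[widx]); plast_id <- mean(id_p[widx])
    cls <- if (mito_id > identity_threshold) "mito-like" else "unclassified"
    fg <- c(NA_character_, NA_character_)
    if (!is.null(features)) {
      fstarts <- vapply(features$features, function(f) min(f$intervals$start), 0L)
      fends <- vapply(features$features, function(f) max(f$intervals$end), 0L)
      gnames <- vapply(features$features, `[[`, "", "gene")
      left <- which(fends <= lo)
      right <- which(fstarts >= hi)
      if (length(left)) fg[1] <- gnames[left[which.max(fends[left])]]
      if (length(right)) fg[2] <- gnames[right[which.min(fstarts[right])]]
    }
    calls[[length(calls) + 1L]] <- data.frame(
      start = lo, end = hi, length = hi - lo, classification = cls,
      mito_identity = round(mito_id, 4), plastid_identity = round(plast_id, 4),
      flank_gene_left = fg[1], flank_gene_right = fg[2],
      stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) return(empty)
  do.call(rbind, calls)
}

#' Coverage consistency check for an insert call
#'
#' Compares the mean read depth inside the insert with the mean depth of its
#' flanking regions.  "consistent" (ratio within a factor of 2) supports
#' genuine residency in the plastome rather than an assembly artifact.
#' @param insert_call one row of [detect_foreign_insert()] output (or any
#'   list with start/end, 0-based half-open)
#' @param coverage_profile a `coverage_profile` over the same genome
#' @param flank flank size examined on each side (nt)
#' @return list(verdict, ratio, insert_mean, flank_mean)
#' @export
coverage_consistency_check <- function(insert_call, coverage_profile,
                                       flank = 5000L) {
  d <- coverage_profile$depth
  n <- length(d)
  i0 <- insert_call$start; i1 <- insert_call$end
  stopifnot(i0 >= 0L, i1 <= n, i1 > i0)
  insert_mean <- mean(d[(i0 + 1L):i1])
  left <- if (i0 > 0L) d[max(1L, i0 - flank + 1L):i0] else numeric(0)
  right <- if (i1 < n) d[(i1 + 1L):min(n, i1 + flank)] else numeric(0)
  flank_mean <- mean(c(left, right))
  ratio <- if (flank_mean > 0) insert_mean / flank_mean else
    if (insert_mean > 0) Inf else 0
  verdict <- if (is.finite(ratio) && ratio >= 0.5 && ratio <= 2) "consistent"
    else "inconsistent"
  list(verdict = verdict, ratio = ratio, insert_mean = insert_mean,
       flank_mean = flank_mean)
}
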