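# Independent oracles used by the unit and acceptance tests.  These re-derive
# expected values by different algorithmic routes than the package code.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random DNA containing no SSR at the standard thresholds (rejection sampled)
ssr_free_dna <- function(n) {
  repeat {
    s <- rand_dna(n)
    if (nrow(oracle_ssrs(s)) == 0L) return(s)
  }
}

mutate_seq <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

oracle_complement <- function(v) {
  c(A = "T", C = "G", G = "C", T = "A")[v]
}

# Maximal repeat pairs by per-diagonal prefix sums + binary search over the
# mismatch counts (left/right maximality from the monotone v_max sequence).
oracle_repeats <- function(s, kind, min_len, max_ham) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  t <- switch(kind,
              forward = v,
              complement = unname(oracle_complement(v)),
              palindromic = rev(unname(oracle_complement(v))),
              reverse = rev(v))
  diags <- if (kind %in% c("forward", "complement")) 1:(n - 1) else
    -(n - 1):(n - 1)
  hits <- list()
  for (d in diags) {
    i0 <- max(0L, -d)
    L <- min(n - i0, n - (i0 + d))
    if (L < min_len) next
    a <- v[(i0 + 1):(i0 + L)]
    b <- t[(i0 + d + 1):(i0 + d + L)]
    cmm <- c(0L, cumsum(as.integer(a != b)))
    # v_max[u] = largest end position with ham(interval [u, v]) <= max_ham;
    # cmm is nondecreasing so a single findInterval gives all of them
    u <- seq_len(L)
    cnt <- findInterval(cmm[u] + max_ham, cmm) - u
    vmax <- u - 1L + pmax(0L, cnt)
    keep <- (vmax - u + 1L >= min_len) &
      (u == 1L | c(-1L, vmax[-L]) < vmax)           # not left-extendable
    if (any(keep)) {
      uu <- u[keep]
      hits[[length(hits) + 1L]] <- data.frame(
        kind = kind, i = i0 + uu - 1L, j = i0 + d + uu - 1L,
        length = vmax[keep] - uu + 1L,
        hamming = cmm[vmax[keep] + 1L] - cmm[uu])
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(kind = character(0), start1 = integer(0),
                                      start2 = integer(0), length = integer(0),
                                      hamming = integer(0)))
  # map the transformed copy back, canonicalize and de-duplicate like the
  # package contract (each unordered pair once)
  if (kind %in% c("palindromic", "reverse")) {
    out$start1 <- out$i
    out$start2 <- n - out$j - out$length
  } else {
    out$start1 <- out$i
    out$start2 <- out$j
  }
  swap <- out$start1 > out$start2
  tmp <- out$start1[swap]
  out$start1[swap] <- out$start2[swap]
  out$start2[swap] <- tmp
  out <- unique(out[, c("kind", "start1", "start2", "length", "hamming")])
  out <- out[out$start1 != out$start2, , drop = FALSE]
  out[order(out$start1, out$start2), , drop = FALSE]
}

# Regex-engine SSR oracle: maximal whole-unit tandem runs per unit size.
oracle_ssrs <- function(s, min_reps = c(10L, 6L, 5L, 3L, 3L, 3L)) {
  hits <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_reps[u] - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      motif <- substring(s, m[k], m[k] + u - 1L)
      # minimal motif: no divisor period
      minimal <- TRUE
      for (dd in seq_len(u - 1L)) {
        if (u %% dd == 0L &&
            motif == strrep(substring(motif, 1L, dd), u / dd)) minimal <- FALSE
      }
      if (!minimal) next
      reps <- lens[k] %/% u
      hits[[length(hits) + 1L]] <- data.frame(
        start = m[k] - 1L, unit = u, repeats = reps, motif = motif)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(start = integer(0), unit = integer(0),
                                      repeats = integer(0),
                                      motif = character(0)))
  out[order(out$start, out$unit), , drop = FALSE]
}

# Exhaustive local-alignment DP (match +1, mismatch -cost, gap -cost), the
# same scoring contract as the read mapper but a plain R implementation.
oracle_sw_score <- function(read, ref, mismatch = 2L, gapcost = 3L) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0L, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- H[i, j] + if (a[i] == b[j]) 1L else -mismatch
      H[i + 1L, j + 1L] <- max(0L, sub, H[i, j + 1L] - gapcost,
                               H[i + 1L, j] - gapcost)
    }
  }
  max(H)
}

# best local alignment of read against ref on either strand
oracle_best_score <- function(read, ref, mismatch = 2L, gapcost = 3L) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  max(oracle_sw_score(read, ref, mismatch, gapcost),
      oracle_sw_score(rc, ref, mismatch, gapcost))
}

# tiny deterministic plastome specs for fast tests
small_spec <- function(seed, ...) {
  plastome_spec(lsc_length = 12000L, ssc_length = 4000L, ir_length = 2500L,
                seed = seed, ...)
}
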