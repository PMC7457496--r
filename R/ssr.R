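#' MISA-style microsatellite thresholds
#'
#' Minimum numbers of tandem repeats per unit size (mono 10, di 6, tri 5,
#' tetra/penta/hexa 3) and the maximum interruption between two qualifying
#' SSRs merged into a compound locus (100 nt).
#' @param min_repeats integer vector of length 6 (unit sizes 1..6)
#' @param compound_max_gap maximum distance between compound members (nt)
#' @return validated threshold list
#' @export
ssr_thresholds <- function(min_repeats = c(10L, 6L, 5L, 3L, 3L, 3L),
                           compound_max_gap = 100L) {
  stopifnot(length(min_repeats) == 6L, all(min_repeats >= 1L),
            compound_max_gap >= 0L)
  list(min_repeats = as.integer(min_repeats),
       compound_max_gap = as.integer(compound_max_gap))
}

#' Scan a genome for microsatellites
#'
#' Maximal perfect tandem runs of 1-6 nt motifs meeting the per-unit-size
#' minimum repeat counts.  Motifs are minimal (a run of (AT)n is di-, never
#' mono- or tetra-nucleotide); partial trailing units are not counted.  Two
#' or more qualifying runs separated by at most `compound_max_gap` nt are
#' merged into one compound locus whose members stay listed in the `members`
#' column.  Coordinates in the returned table are 1-based inclusive.
#' @param genome sequence-like object
#' @param thresholds [ssr_thresholds()]
#' @return data.frame: klass (p1..p6/compound), motif, repeat_number, start,
#'   end, n_members, members (list-column of simple-run data.frames)
#' @export
find_ssrs <- function(genome, thresholds = ssr_thresholds()) {
  s <- residues(genome)
  runs <- cpp_scan_ssrs(s, thresholds$min_repeats)
  empty <- data.frame(klass = character(0), motif = character(0),
                      repeat_number = integer(0), start = integer(0),
                      end = integer(0), n_members = integer(0))
  empty$members <- list()
  if (nrow(runs) == 0L) return(empty)
  runs <- runs[order(runs$start, runs$unit), , drop = FALSE]
  runs$end0 <- runs$start + runs$unit * runs$repeats     # half-open
  # group runs whose interruption is at most compound_max_gap
  grp <- integer(nrow(runs))
  g <- 1L
  grp[1] <- g
  grp_end <- runs$end0[1]
  for (k in seq_len(nrow(runs))[-1]) {
    if (runs$start[k] - grp_end <= thresholds$compound_max_gap) {
      grp[k] <- g
    } else {
      g <- g + 1L
      grp[k] <- g
    }
    grp_end <- max(grp_end, runs$end0[k])
  }
  rows <- lapply(split(seq_len(nrow(runs)), grp), function(idx) {
    m <- runs[idx, c("start", "unit", "repeats", "motif", "end0")]
    if (length(idx) == 1L) {
      data.frame(klass = paste0("p", m$unit), motif = m$motif,
                 repeat_number = m$repeats, start = m$start + 1L,
                 end = m$end0, n_members = 1L, stringsAsFactors = FALSE)
    } else {
      data.frame(klass = "compound",
                 motif = paste(sprintf("(%s)%d", m$motif, m$repeats),
                               collapse = "-"),
                 repeat_number = NA_integer_, start = min(m$start) + 1L,
                 end = max(m$end0), n_members = length(idx),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(split(seq_len(nrow(runs)), grp), function(idx) {
    m <- runs[idx, c("start", "unit", "repeats", "motif")]
    m$start <- m$start + 1L          # 1-based for reporting
    rownames(m) <- NULL
    m
  })
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize SSR hits per class
#'
#' Counts per unit-size class plus compound loci; a compound is counted once
#' (its members are not double-counted).
#' @param hits output of [find_ssrs()]
#' @return named integer vector: p1..p6, compound, total
#' @export
summarize_ssrs <- function(hits) {
  classes <- c(paste0("p", 1:6), "compound")
  counts <- vapply(classes, function(k) sum(hits$klass == k), 0L)
  c(counts, total = sum(counts))
}

#' Write SSR hits as a MISA-style TSV
#' @param hits output of [find_ssrs()]
#' @param path output path
#' @param seq_id sequence id column
#' @return invisibly, `path`
#' @export
write_misa <- function(hits, path, seq_id = "genome") {
  out <- data.frame(ID = seq_id, SSR_nr = seq_len(max(1L, nrow(hits)))[seq_len(nrow(hits))],
                    SSR_type = hits$klass,
                    SSR = ifelse(hits$klass == "compound", hits$motif,
                                 sprintf("(%s)%d", hits$motif,
                                         hits$repeat_number)),
                    size = hits$end - hits$start + 1L,
                    start = hits$start, end = hits$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cyclic_rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n) - 1L, function(r)
    paste0(substring(motif, r + 1L, n), substring(motif, 1L, r)), "")
}

#' Pair SSR loci of two genomes and report polymorphisms
#'
#' Each simple SSR locus of `genomeA` is anchored in `genomeB` by exact
#' occurrence of its flanking sequence (`anchor_flank` nt each side, left
#' flank preferred); a B locus of the same unit size and cyclically
#' equivalent motif near the anchored position is taken as the partner.
#' Paired loci with differing repeat numbers are polymorphic; loci whose
#' flanks cannot be anchored are reported as unpaired.  Genomes should be
#' orientation-normalized first (see [normalize_orientation()]).
#' @param genomeA,genomeB sequence-like objects
#' @param anchor_flank flank length used for anchoring (nt)
#' @param thresholds [ssr_thresholds()]
#' @param all also return conserved (equal-count) pairs?
#' @return data.frame: motif, unit, startA, endA, repeatsA, startB, endB,
#'   repeatsB, status
#' @export
compare_ssrs <- function(genomeA, genomeB, anchor_flank = 200L,
                         thresholds = ssr_thresholds(), all = FALSE) {
  a <- residues(genomeA)
  b <- residues(genomeB)
  hitsA <- find_ssrs(a, thresholds)
  hitsB <- find_ssrs(b, thresholds)
  simpleA <- hitsA[hitsA$klass != "compound", , drop = FALSE]
  simpleB <- hitsB[hitsB$klass != "compound", , drop = FALSE]
  bs <- Biostrings::DNAString(b)
  anchor <- function(flank) {
    if (nchar(flank) < 20L) return(integer(0))
    m <- Biostrings::matchPattern(flank, bs)
    if (length(m) == 0L || length(m) > 4L) return(integer(0))
    BiocGenerics::start(m)    # IR loci legitimately anchor at both copies
  }
  rows <- lapply(seq_len(nrow(simpleA)), function(k) {
    h <- simpleA[k, ]
    unit <- nchar(h$motif)
    fl <- substring(a, max(1L, h$start - anchor_flank), h$start - 1L)
    expected <- anchor(fl) + nchar(fl)
    if (length(expected) == 0L) {
      fr <- substring(a, h$end + 1L, min(nchar(a), h$end + anchor_flank))
      expected <- anchor(fr) - (h$end - h$start + 1L)
    }
    base <- data.frame(motif = h$motif, unit = unit, startA = h$start,
                       endA = h$end, repeatsA = h$repeat_number,
                       startB = NA_integer_, endB = NA_integer_,
                       repeatsB = NA_integer_, status = "unpaired",
                       stringsAsFactors = FALSE)
    if (length(expected) == 0L) return(base)
    rot <- cyclic_rotations(h$motif)
    dist <- vapply(simpleB$start, function(s0) min(abs(s0 - expected)), 0)
    cand <- simpleB[nchar(simpleB$motif) == unit &
                      simpleB$motif %in% rot & dist <= anchor_flank, ,
                    drop = FALSE]
    if (nrow(cand) == 0L) return(base)
    cand <- cand[which.min(vapply(cand$start, function(s0)
      min(abs(s0 - expected)), 0)), ]
    base$startB <- cand$start; base$endB <- cand$end
    base$repeatsB <- cand$repeat_number
    base$status <- if (cand$repeat_number == h$repeat_number) "conserved"
      else "polymorphic"
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  if (!all) out <- out[out$status != "conserved", , drop = FALSE]
  rownames(out) <- NULL
  out
}
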