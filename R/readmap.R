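#' Read-mapping parameters
#'
#' Cost and acceptance-fraction settings for short-read mapping.  Defaults
#' are the standard mapping stringency (length fraction 0.8, similarity
#' fraction 0.9, mismatch cost 2, insertion/deletion cost 3); see
#' [strict_mapping_parameters()] for the 0.99/0.99 remapping stringency.
#' @param mismatch_cost,insertion_cost,deletion_cost positive integer costs
#' @param length_fraction minimum aligned fraction of the read
#' @param similarity_fraction minimum identity of the aligned portion
#' @return validated parameter list
#' @export
mapping_parameters <- function(mismatch_cost = 2L, insertion_cost = 3L,
                               deletion_cost = 3L, length_fraction = 0.8,
                               similarity_fraction = 0.9) {
  stopifnot(mismatch_cost > 0L, insertion_cost > 0L, deletion_cost > 0L,
            length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1)
  if (insertion_cost != deletion_cost)
    stop("distinct insertion and deletion costs are not supported")
  list(mismatch_cost = as.integer(mismatch_cost),
       insertion_cost = as.integer(insertion_cost),
       deletion_cost = as.integer(deletion_cost),
       length_fraction = length_fraction,
       similarity_fraction = similarity_fraction)
}

#' @rdname mapping_parameters
#' @export
strict_mapping_parameters <- function() {
  mapping_parameters(length_fraction = 0.99, similarity_fraction = 0.99)
}

reads_to_chr <- function(reads) {
  if (length(reads) == 0L) return(setNames(character(0), character(0)))
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- paste0("read", seq_along(reads))
    return(toupper(reads))
  }
  out <- vapply(reads, residues, "")
  names(out) <- vapply(seq_along(reads), function(k)
    seq_id(reads[[k]], paste0("read", k)), "")
  out
}

#' Map reads to a reference
#'
#' Seed-and-extend local alignment of every read (both strands) under unit
#' match bonus and the parameterized mismatch/gap penalties; read ends may be
#' clipped (clipped bases reduce `aligned_read_fraction`).  A read aligning
#' equally well at several reference positions (the two IR copies) is
#' reported at every co-optimal placement; `primary` marks the
#' leftmost-start, plus-strand-preferred one.
#' @param reads character vector (or list of [nt_seq]) of reads
#' @param reference sequence-like reference
#' @param params [mapping_parameters()]
#' @param seed_k exact seed length (reads without a seed hit fall back to a
#'   full-width alignment only when the reference is under `brute_max` nt)
#' @param brute_max see above
#' @return data.frame of placements with identity, aligned_read_fraction and
#'   accepted columns
#' @export
map_reads <- function(reads, reference, params = mapping_parameters(),
                      seed_k = 21L, brute_max = 5000L) {
  rd <- reads_to_chr(reads)
  hits <- cpp_map_reads(unname(rd), residues(reference), seed_k,
                        1L, params$mismatch_cost, params$insertion_cost,
                        brute_max)
  hits$read_id <- names(rd)[hits$read]
  hits$read_length <- nchar(rd)[hits$read]
  cols <- hits$matches + hits$mismatches + hits$insertions + hits$deletions
  hits$identity <- ifelse(cols > 0, hits$matches / cols, 0)
  hits$aligned_read_fraction <- hits$aligned_read_bases / hits$read_length
  hits$accepted <- accept_alignment(hits, params)
  hits
}

#' Best alignment of a single read
#' @param read sequence-like read (>= 20 nt)
#' @param reference sequence-like reference
#' @inheritParams map_reads
#' @return one-row alignment data.frame (the primary placement) or NULL when
#'   the read is unalignable
#' @export
align_read <- function(read, reference, params = mapping_parameters(),
                       seed_k = 21L, brute_max = 5000L) {
  if (nchar(residues(read)) < 20L) stop("read shorter than 20 nt")
  hits <- map_reads(setNames(residues(read), seq_id(read, "read")), reference,
                    params, seed_k, brute_max)
  if (nrow(hits) == 0L) return(NULL)
  hits[hits$primary == 1L, , drop = FALSE][1, , drop = FALSE]
}

#' Acceptance test for alignments
#'
#' TRUE iff `aligned_read_fraction >= length_fraction` and
#' `identity >= similarity_fraction` (both inclusive).
#' @param aln alignment row(s) with aligned_read_fraction and identity
#' @param params [mapping_parameters()]
#' @return logical vector
#' @export
accept_alignment <- function(aln, params = mapping_parameters()) {
  aln$aligned_read_fraction >= params$length_fraction &
    aln$identity >= params$similarity_fraction
}

#' Per-base coverage profile
#'
#' Depth counts every reference base consumed by an accepted alignment
#' (matches, mismatches and deletions).  Co-optimal multi-placements each
#' contribute depth 1, mirroring the double-placement behavior of common
#' mappers over the identical IR copies.
#' @param reads reads (see [map_reads()]) or an already-computed placement
#'   data.frame
#' @param reference sequence-like reference
#' @param params [mapping_parameters()]
#' @param multi how to place multi-mapping reads: "all" (default) or
#'   "primary" (single placement)
#' @return a `coverage_profile`: list(depth, min_depth, max_depth,
#'   mean_depth, mapped_read_count, total_read_count)
#' @export
compute_coverage <- function(reads, reference, params = mapping_parameters(),
                             multi = c("all", "primary")) {
  multi <- match.arg(multi)
  if (is.data.frame(reads)) {
    hits <- reads
    total <- length(unique(hits$read))
  } else {
    rd <- reads_to_chr(reads)
    total <- length(rd)
    hits <- map_reads(rd, reference, params)
  }
  n <- nchar(residues(reference))
  acc <- hits[hits$accepted, , drop = FALSE]
  if (multi == "primary") acc <- acc[acc$primary == 1L, , drop = FALSE]
  depth <- integer(n)
  if (nrow(acc) > 0L) {
    t1 <- tabulate(acc$start + 1L, n + 1L)
    t2 <- tabulate(acc$end + 1L, n + 1L)
    depth <- cumsum(t1 - t2)[seq_len(n)]
  }
  structure(list(depth = depth,
                 min_depth = if (n) min(depth) else 0L,
                 max_depth = if (n) max(depth) else 0L,
                 mean_depth = if (n) mean(depth) else 0,
                 mapped_read_count = length(unique(acc$read)),
                 total_read_count = total),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s bases: min %d / mean %.1f / max %d (%d/%d reads mapped)\n",
              format(length(x$depth), big.mark = ","), x$min_depth,
              x$mean_depth, x$max_depth, x$mapped_read_count,
              x$total_read_count))
  invisible(x)
}

#' Screen for low-coverage regions
#'
#' Maximal runs of bases with depth strictly below `threshold`.
#' @param profile a `coverage_profile`
#' @param threshold minimum acceptable depth (default 40)
#' @param seq_id reference id for the emitted regions
#' @return data.frame of regions (0-based half-open) with min depth inside
#' @export
screen_low_coverage <- function(profile, threshold = 40L, seq_id = "genome") {
  low <- profile$depth < threshold
  if (!any(low))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), min_depth_in_interval = integer(0),
                      threshold = integer(0)))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  out <- data.frame(seq_id = seq_id, start = starts[keep], end = ends[keep])
  out$min_depth_in_interval <- vapply(seq_len(nrow(out)), function(k)
    min(profile$depth[(out$start[k] + 1L):out$end[k]]), 0L)
  out$threshold <- as.integer(threshold)
  out
}

#' Verify the circular IRb-LSC junction by concatenated remapping
#'
#' Builds the last `window` nt of IRb joined to the first `window` nt of LSC
#' as one linear segment and remaps the reads to it.  This resolves the
#' artifactual coverage drop at the terminal bases of a linear
#' representation of a circular genome.
#' @param reads reads
#' @param genome sequence-like genome
#' @param structure its [quadripartite_structure()]
#' @param window nt taken from each side of the junction
#' @param params [mapping_parameters()]
#' @return `coverage_profile` over the concatenated segment
#' @export
remap_circular_junction <- function(reads, genome, structure, window = 2000L,
                                    params = mapping_parameters()) {
  irb <- region_seq(genome, structure, "IRb")
  lsc <- region_seq(genome, structure, "LSC")
  if (window > nchar(irb) || window > nchar(lsc)) {
    warning("window exceeds a region length; truncating")
    window <- min(window, nchar(irb), nchar(lsc))
  }
  segment <- paste0(substring(irb, nchar(irb) - window + 1L),
                    substring(lsc, 1L, window))
  compute_coverage(reads, segment, params)
}

#' Coverage at default and strict remapping stringency
#'
#' Maps once, then filters the placements at the default (0.8 length / 0.9
#' similarity) and strict (0.99/0.99) acceptance thresholds, returning both
#' profiles plus the min/mean coverage deltas (default minus strict).
#' @param reads reads
#' @param genome sequence-like genome
#' @param params,strict_params the two stringencies
#' @return list(default, strict, delta_min, delta_mean)
#' @export
dual_stringency_report <- function(reads, genome,
                                   params = mapping_parameters(),
                                   strict_params = strict_mapping_parameters()) {
  hits <- map_reads(reads, genome, params)
  total <- length(reads_to_chr(reads))
  prof <- function(p) {
    h <- hits
    h$accepted <- accept_alignment(h, p)
    pr <- compute_coverage(h, genome, p)
    pr$total_read_count <- total
    pr
  }
  d <- prof(params)
  s <- prof(strict_params)
  list(default = d, strict = s,
       delta_min = d$min_depth - s$min_depth,
       delta_mean = d$mean_depth - s$mean_depth)
}

#' Assembly mapping summary table
#'
#' One-row summary mirroring the usual per-library report: total reads, mean
#' read length, min/max/mean coverage, and percent of reads mapped.
#' @param profile a `coverage_profile`
#' @param reads the read set the profile was computed from
#' @return one-row data.frame
#' @export
mapping_summary <- function(profile, reads) {
  rd <- reads_to_chr(reads)
  data.frame(total_reads = profile$total_read_count,
             mean_read_length = round(mean(nchar(rd)), 2),
             min_coverage = profile$min_depth,
             max_coverage = profile$max_depth,
             mean_coverage = round(profile$mean_depth, 2),
             pct_reads_mapped = round(100 * profile$mapped_read_count /
                                        max(1L, profile$total_read_count), 2))
}

#' Write a coverage profile as bedGraph
#' @param profile a `coverage_profile`
#' @param path output path
#' @param seq_id reference name
#' @return invisibly, `path`
#' @export
write_bedgraph <- function(profile, path, seq_id = "genome") {
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  write.table(data.frame(seq_id, starts, ends, r$values), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path (uncompressed)
#' @return named character vector of read sequences
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  setNames(toupper(lines[seq(2L, length(lines), by = 4L)]), ids)
}

#' Write reads as FASTQ with uniform quality
#' @param reads named character vector
#' @param path output path
#' @param qual_char quality character applied to every base
#' @return invisibly, `path`
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  rd <- reads_to_chr(reads)
  out <- character(4L * length(rd))
  out[seq(1L, length(out), 4L)] <- paste0("@", names(rd))
  out[seq(2L, length(out), 4L)] <- unname(rd)
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- strrep(qual_char, nchar(rd))
  writeLines(out, path)
  invisible(path)
}
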