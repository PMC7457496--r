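#' Region length, GC and coding-fraction metrics
#'
#' Lengths and GC content for the whole genome and each region, plus (when
#' annotations are supplied) coding fractions computed over interval unions
#' so overlapping features are counted once.
#' @param genome sequence-like object
#' @param structure its [quadripartite_structure()]
#' @param features optional [feature_table()]
#' @return list(lengths, gc_percent, coding) where coding holds percent
#'   coding / protein-coding / RNA-coding
#' @export
region_metrics <- function(genome, structure, features = NULL) {
  s <- residues(genome)
  n <- nchar(s)
  labs <- c("LSC", "IRa", "SSC", "IRb")
  lens <- vapply(labs, region_length, 0L, structure = structure)
  stopifnot(sum(lens) == n)
  gc <- c(whole = gc_content(s, as_percent = TRUE),
          vapply(labs, function(l)
            gc_content(region_seq(s, structure, l), as_percent = TRUE), 0))
  coding <- NULL
  if (!is.null(features)) {
    union_bases <- function(kinds) {
      iv <- do.call(rbind, lapply(features$features, function(f)
        if (f$kind %in% kinds) f$intervals else NULL))
      if (is.null(iv) || nrow(iv) == 0L) return(0L)
      r <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
      sum(IRanges::width(r))
    }
    coding <- c(
      percent_coding = round(100 * union_bases(c("CDS", "tRNA", "rRNA")) / n, 2),
      percent_protein_coding = round(100 * union_bases("CDS") / n, 2),
      percent_rna_coding = round(100 * union_bases(c("tRNA", "rRNA")) / n, 2))
  }
  list(lengths = c(whole = n, lens), gc_percent = gc, coding = coding)
}

# Extract the coding sequence of a feature, honoring strand, codon_start and
# circular-origin splits (an interval ending at the sequence end precedes one
# starting at base 0).
cds_sequence <- function(genome, f) {
  s <- residues(genome)
  n <- nchar(s)
  iv <- f$intervals
  if (nrow(iv) > 1L && iv$start[1] == 0L && iv$end[nrow(iv)] == n)
    iv <- iv[c(nrow(iv), seq_len(nrow(iv) - 1L)), , drop = FALSE]
  parts <- substring(s, iv$start + 1L, iv$end)
  seq <- paste(parts, collapse = "")
  if (f$strand == "-") seq <- reverse_complement(seq)
  substring(seq, f$codon_start)
}

#' Scan annotated CDS features for internal stop codons
#'
#' Each CDS is translated in its annotated frame under the bacterial/plastid
#' genetic code (table 11); every in-frame stop before the final codon is
#' reported.  A CDS whose adjusted length is not divisible by 3 is flagged as
#' a frame anomaly but still scanned.
#' @param genome sequence-like object
#' @param features a [feature_table()]
#' @return data.frame: gene, internal_stop_count, stop_codon_positions
#'   (list-column of 1-based codon indices), frame_used, frame_anomaly
#' @export
scan_pseudogenes <- function(genome, features) {
  code <- Biostrings::getGeneticCode("11")
  cds <- Filter(function(f) f$kind == "CDS", features$features)
  rows <- lapply(cds, function(f) {
    seq <- cds_sequence(genome, f)
    anomaly <- (nchar(seq) %% 3L) != 0L
    ncod <- nchar(seq) %/% 3L
    if (ncod < 2L)
      return(data.frame(gene = f$gene, internal_stop_count = 0L,
                        frame_used = f$codon_start, frame_anomaly = anomaly))
    codons <- substring(seq, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"                      # ambiguity codes
    internal <- which(aa[-ncod] == "*")
    data.frame(gene = f$gene, internal_stop_count = length(internal),
               frame_used = f$codon_start, frame_anomaly = anomaly)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(0), internal_stop_count = integer(0),
                      frame_used = integer(0), frame_anomaly = logical(0)))
  out$stop_codon_positions <- lapply(cds, function(f) {
    seq <- cds_sequence(genome, f)
    ncod <- nchar(seq) %/% 3L
    if (ncod < 2L) return(integer(0))
    codons <- substring(seq, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
    aa <- unname(Biostrings::getGeneticCode("11")[codons])
    which(aa[-ncod] == "*")
  })
  rownames(out) <- NULL
  out
}

#' Inverted-repeat boundary and expansion report
#'
#' Reports the genes overlapping each of the four junctions, measures any
#' IR-internal copy of a designated boundary gene (default ycf1) by k-mer
#' coverage of the full single-copy gene against the IR sequence, and flags
#' IR expansion when the IR exceeds a comparator length by more than 1 kb.
#' @param genome sequence-like object
#' @param structure its [quadripartite_structure()]
#' @param features a [feature_table()]
#' @param boundary_gene gene measured inside the IR
#' @param comparator_ir_length optional IR length (nt) of a comparator genome
#' @return list(junction_genes, boundary_gene, status, copy_length,
#'   ir_expansion_flag, expansion_length)
#' @export
analyze_ir_boundaries <- function(genome, structure, features,
                                  boundary_gene = "ycf1",
                                  comparator_ir_length = NULL) {
  r <- structure$regions
  ord <- r[order(r$start), , drop = FALSE]
  jpos <- list()
  labs_sorted <- ord$label
  for (k in seq_len(nrow(ord) - 1L)) {
    nm <- paste0(labs_sorted[k], "-", labs_sorted[k + 1L])
    jpos[[nm]] <- ord$end[k]
  }
  junction_genes <- lapply(jpos, function(p) {
    hits <- Filter(function(f)
      min(f$intervals$start) < p && max(f$intervals$end) > p,
      features$features)
    vapply(hits, `[[`, "", "gene")
  })
  # circular origin junction: a feature crossing it is split into an
  # interval ending at the sequence end plus one starting at base 0
  glen_total <- structure$genome_length
  origin_hits <- Filter(function(f)
    nrow(f$intervals) > 1L && f$intervals$start[1] == 0L &&
      f$intervals$end[nrow(f$intervals)] == glen_total,
    features$features)
  junction_genes[[paste0(labs_sorted[nrow(ord)], "-", labs_sorted[1])]] <-
    vapply(origin_hits, `[[`, "", "gene")
  cand <- Filter(function(f) f$gene == boundary_gene, features$features)
  status <- "absent"; copy_length <- 0L
  if (length(cand) > 0L) {
    spans <- vapply(cand, function(f)
      max(f$intervals$end) - min(f$intervals$start), 0L)
    full <- cand[[which.max(spans)]]
    gene_seq <- cds_sequence(genome, full)
    ir_seq <- region_seq(genome, structure, "IRa")
    k <- 31L
    if (nchar(gene_seq) >= k) {
      member <- cpp_kmer_member(gene_seq, ir_seq, k)
      cs <- c(0L, cumsum(as.integer(member)))
      np <- length(member)
      covered <- vapply(seq_len(nchar(gene_seq)), function(i) {
        lo <- max(1L, i - k + 1L); hi <- min(np, i)
        hi >= lo && (cs[hi + 1L] - cs[lo]) > 0L
      }, TRUE)
      copy_length <- sum(covered)
    }
    status <- if (copy_length >= 0.95 * nchar(gene_seq)) "full copy"
      else if (copy_length >= 200L) "partial pseudogene" else "absent"
  }
  ir_len <- region_length(structure, "IRa")
  exp_flag <- FALSE; exp_len <- NA_integer_
  if (!is.null(comparator_ir_length)) {
    exp_len <- ir_len - as.integer(comparator_ir_length)
    exp_flag <- exp_len > 1000L
  }
  list(junction_genes = junction_genes, boundary_gene = boundary_gene,
       status = status, copy_length = as.integer(copy_length),
       ir_expansion_flag = exp_flag, expansion_length = exp_len)
}

# longest strictly-increasing subsequence (indices) -- O(n log n)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- integer(n)      # values of the active tails
  tidx <- integer(n)       # index of each tail element
  prev <- integer(n)
  L <- 0L
  for (i in seq_len(n)) {
    p <- findInterval(x[i] - 1L, tails[seq_len(L)]) + 1L  # first tail >= x[i]
    tails[p] <- x[i]; tidx[p] <- i
    if (p > L) L <- p
    prev[i] <- if (p > 1L) tidx[p - 1L] else 0L
  }
  out <- integer(L)
  k <- tidx[L]
  for (j in rev(seq_len(L))) { out[j] <- k; k <- prev[k] }
  out
}

# Anchor-chained global comparison of two long, highly similar sequences.
# Returns matches, aligned columns, SNPs and indel events.
anchored_align <- function(a, b, k = 31L, max_seg = 20000L, depth = 0L,
                           a_off = 0L, b_off = 0L) {
  res <- list(matches = 0, columns = 0, snps = NULL, indels = NULL)
  add_pa <- function(res, aseg, bseg, a0, b0) {
    # small-segment global alignment
    if (nchar(aseg) == 0L && nchar(bseg) == 0L) return(res)
    if (nchar(aseg) == 0L || nchar(bseg) == 0L) {
      len <- max(nchar(aseg), nchar(bseg))
      res$columns <- res$columns + len
      res$indels <- rbind(res$indels, data.frame(
        pos_a = a0, length = len,
        type = if (nchar(aseg) > 0L) "deletion_in_b" else "insertion_in_b"))
      return(res)
    }
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(aseg, bseg, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 3)
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    res$columns <- res$columns + length(pat)
    gap <- pat == "-" | sub == "-"
    res$matches <- res$matches + sum(!gap & pat == sub)
    snp <- which(!gap & pat != sub & pat %in% c("A", "C", "G", "T") &
                   sub %in% c("A", "C", "G", "T"))
    if (length(snp)) {
      apos <- cumsum(pat != "-")
      res$snps <- rbind(res$snps, data.frame(
        pos_a = a0 + apos[snp], ref = pat[snp], alt = sub[snp]))
    }
    if (any(gap)) {
      r <- rle(gap)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      apos <- cumsum(pat != "-")
      for (w in which(r$values)) {
        res$indels <- rbind(res$indels, data.frame(
          pos_a = a0 + if (starts[w] > 1L) apos[starts[w] - 1L] else 0L,
          length = r$lengths[w],
          type = if (all(pat[starts[w]:ends[w]] == "-")) "insertion_in_b"
            else "deletion_in_b"))
      }
    }
    res
  }
  do_seg <- function(res, aseg, bseg, a0, b0) {
    if (identical(aseg, bseg)) {
      res$matches <- res$matches + nchar(aseg)
      res$columns <- res$columns + nchar(aseg)
      return(res)
    }
    if (max(nchar(aseg), nchar(bseg)) <= max_seg || depth >= 3L)
      return(add_pa(res, aseg, bseg, a0, b0))
    sub <- anchored_align(aseg, bseg, k, max_seg, depth + 1L, a0, b0)
    res$matches <- res$matches + sub$matches
    res$columns <- res$columns + sub$columns
    res$snps <- rbind(res$snps, sub$snps)
    res$indels <- rbind(res$indels, sub$indels)
    res
  }
  na <- nchar(a); nb <- nchar(b)
  if (na < k + 1L || nb < k + 1L) return(do_seg(res, a, b, a_off, b_off))
  ka <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  bmap <- match(ka, kb)
  sel <- which(ua & !is.na(bmap) & ub[pmax(bmap, 1L)])
  if (length(sel) == 0L) return(do_seg(res, a, b, a_off, b_off))
  apos <- sel; bpos <- bmap[sel]
  keep <- lis_indices(bpos)
  apos <- apos[keep]; bpos <- bpos[keep]
  # thin anchors into exact blocks (same diagonal, step <= k)
  blocks <- list()
  cur <- c(apos[1], bpos[1], apos[1], bpos[1])  # a0 b0 alast blast
  for (i in seq_along(apos)[-1]) {
    same_diag <- (apos[i] - bpos[i]) == (cur[3] - cur[4])
    if (same_diag && apos[i] - cur[3] <= k) {
      cur[3] <- apos[i]; cur[4] <- bpos[i]
    } else if (apos[i] >= cur[3] + k && bpos[i] >= cur[4] + k) {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- c(apos[i], bpos[i], apos[i], bpos[i])
    }  # else: skip anchor inconsistent with the chain
  }
  blocks[[length(blocks) + 1L]] <- cur
  # walk: head segment, blocks, inter-block segments, tail segment
  pa_end <- 0L; pb_end <- 0L   # 0-based ends (half-open) of consumed prefix
  for (bl in blocks) {
    a0 <- bl[1] - 1L; b0 <- bl[2] - 1L          # 0-based block starts
    aend <- bl[3] - 1L + k; bend <- bl[4] - 1L + k
    res <- do_seg(res, substring(a, pa_end + 1L, a0),
                  substring(b, pb_end + 1L, b0),
                  a_off + pa_end, b_off + pb_end)
    blen <- aend - a0
    res$matches <- res$matches + blen
    res$columns <- res$columns + blen
    pa_end <- aend; pb_end <- bend
  }
  res <- do_seg(res, substring(a, pa_end + 1L, na),
                substring(b, pb_end + 1L, nb),
                a_off + pa_end, b_off + pb_end)
  res
}

#' Pairwise whole-genome comparison
#'
#' Rotates both genomes to their LSC start, orients `genomeB` against
#' `genomeA` (independent LSC/SSC flips), then aligns by chaining unique
#' shared 31-mers into exact blocks and aligning the residual segments
#' globally.  SNPs are aligned columns with differing unambiguous bases;
#' an indel event is a maximal run of gap columns.
#' @param genomeA,genomeB sequence-like objects
#' @return list(snp_count, indel_event_count, indel_bases, percent_identity,
#'   applied_flips, variants)
#' @export
pairwise_compare <- function(genomeA, genomeB) {
  stA <- detect_inverted_repeats(genomeA)
  a <- rotate_left(residues(genomeA),
                   stA$regions$start[stA$regions$label == "LSC" &
                                       stA$regions$piece == 1L][1])
  stB <- detect_inverted_repeats(genomeB)
  nb <- normalize_orientation(genomeB, stB, reference = a)
  b <- residues(nb$genome)
  res <- anchored_align(a, b)
  if (res$columns == 0L) stop("comparison failed: nothing aligned")
  identity <- 100 * res$matches / res$columns
  if (identity < 60) stop("genomes too diverged to compare (identity ",
                          round(identity, 1), "%)")
  snps <- res$snps
  indels <- res$indels
  variants <- rbind(
    if (!is.null(snps))
      data.frame(pos = snps$pos_a, type = "SNP", ref = snps$ref,
                 alt = snps$alt, length = 1L),
    if (!is.null(indels))
      data.frame(pos = indels$pos_a, type = indels$type, ref = ".", alt = ".",
                 length = indels$length))
  if (!is.null(variants) && nrow(variants))
    variants <- variants[order(variants$pos), , drop = FALSE]
  list(snp_count = if (is.null(snps)) 0L else nrow(snps),
       indel_event_count = if (is.null(indels)) 0L else nrow(indels),
       indel_bases = if (is.null(indels)) 0L else sum(indels$length),
       percent_identity = identity,
       applied_flips = nb$applied_flips,
       variants = variants)
}
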