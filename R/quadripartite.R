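#' Inverted-repeat detection parameters
#' @param min_ir_length shortest segment pair accepted as an IR (nt)
#' @param seed_length exact seed k-mer length for the self-comparison
#' @param max_mismatch_fraction tolerated divergence between the two IR copies
#' @return list of validated parameters
#' @export
ir_detection_params <- function(min_ir_length = 1000L, seed_length = 31L,
                                max_mismatch_fraction = 0.001) {
  stopifnot(min_ir_length > seed_length, seed_length > 0L,
            max_mismatch_fraction >= 0, max_mismatch_fraction < 1)
  list(min_ir_length = as.integer(min_ir_length),
       seed_length = as.integer(seed_length),
       max_mismatch_fraction = max_mismatch_fraction)
}

#' Quadripartite structure container
#'
#' Holds the LSC/IRa/SSC/IRb regions of a circular plastome in genome order.
#' A region crossing the circular origin is represented by two rows sharing a
#' label, with `piece` giving circular order within the region.
#' @param regions region data.frame with columns seq_id, start, end, strand,
#'   label, piece
#' @param genome_length total genome length (nt)
#' @param ir_mismatches mismatches observed between the two IR copies
#' @return object of class `quadripartite_structure`
#' @export
quadripartite_structure <- function(regions, genome_length,
                                    ir_mismatches = 0L) {
  stopifnot(all(c("LSC", "IRa", "SSC", "IRb") %in% regions$label))
  lens <- vapply(c("LSC", "IRa", "SSC", "IRb"), function(lab)
    sum(regions$end[regions$label == lab] - regions$start[regions$label == lab]),
    0)
  if (sum(lens) != genome_length)
    stop("region lengths (", sum(lens), ") do not sum to genome length (",
         genome_length, ")")
  if (lens[["LSC"]] < lens[["SSC"]])
    stop("LSC shorter than SSC; labels inconsistent")
  structure(list(regions = regions, genome_length = as.integer(genome_length),
                 ir_mismatches = as.integer(ir_mismatches)),
            class = "quadripartite_structure")
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  cat(sprintf("<quadripartite_structure> %s nt: LSC %d | IRa %d | SSC %d | IRb %d\n",
              format(x$genome_length, big.mark = ","),
              region_length(x, "LSC"), region_length(x, "IRa"),
              region_length(x, "SSC"), region_length(x, "IRb")))
  invisible(x)
}

#' Total length of one labeled region
#' @param structure a [quadripartite_structure()]
#' @param label region label
#' @return length in nt
#' @export
region_length <- function(structure, label) {
  r <- structure$regions
  sum(r$end[r$label == label] - r$start[r$label == label])
}

#' Extract the sequence of one labeled region
#' @param genome sequence-like object the structure refers to
#' @param structure a [quadripartite_structure()]
#' @param label region label
#' @return residue string (origin-crossing pieces joined in circular order)
#' @export
region_seq <- function(genome, structure, label) {
  s <- residues(genome)
  r <- structure$regions
  r <- r[r$label == label, , drop = FALSE]
  r <- r[order(r$piece), , drop = FALSE]
  paste(substring(s, r$start + 1L, r$end), collapse = "")
}

rotate_left <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0L) return(s)
  paste0(substring(s, r + 1L, n), substring(s, 1L, r))
}

#' Detect the inverted repeat pair and derive the quadripartite structure
#'
#' Seeds exact k-mers of the genome against its own reverse complement,
#' merges co-linear runs on a shared diagonal (allowing the configured
#' mismatch fraction), and takes the maximal reverse-complement-identical
#' segment pair of at least `min_ir_length` as the IR.  The longer of the two
#' single-copy regions is labeled LSC; IRa is the IR copy following the LSC
#' in genome order.
#' @param genome sequence-like object (assumed circular)
#' @param params see [ir_detection_params()]
#' @return a [quadripartite_structure()]
#' @export
detect_inverted_repeats <- function(genome, params = ir_detection_params()) {
  s <- residues(genome)
  n <- nchar(s)
  if (n <= 2L * params$min_ir_length)
    stop("genome too short for IR detection (", n, " nt)")
  rc <- reverse_complement(s)
  runs <- cpp_exact_runs(s, rc, params$seed_length,
                         min_len = max(100L, params$seed_length))
  if (nrow(runs) == 0L) stop("no inverted repeat detected")
  # merge co-linear runs on the same diagonal within the mismatch tolerance
  runs$diag <- runs$j - runs$i
  merged <- do.call(rbind, lapply(split(runs, runs$diag), function(d) {
    d <- d[order(d$i), , drop = FALSE]
    out <- d[1, c("i", "j", "len", "diag")]
    out$mism <- 0L
    for (k in seq_len(nrow(d))[-1]) {
      gap <- d$i[k] - (out$i + out$len)
      new_len <- d$i[k] + d$len[k] - out$i
      if (gap >= 0 && (out$mism + gap) / new_len <= params$max_mismatch_fraction) {
        out$mism <- out$mism + gap
        out$len <- new_len
      } else if (d$len[k] > out$len) {
        out <- d[k, c("i", "j", "len", "diag")]; out$mism <- 0L
      }
    }
    out
  }))
  # map the rc-space copy back to genome coordinates and de-duplicate the
  # symmetric twin (each physical pair is seen from both copies)
  a1 <- merged$i
  b1 <- merged$i + merged$len
  a2 <- n - merged$j - merged$len
  b2 <- n - merged$j
  keep <- a1 < a2 & b1 <= a2 & merged$len >= params$min_ir_length
  if (!any(keep)) stop("no inverted repeat detected")
  cand <- which(keep)[which.max(merged$len[keep])]
  ia <- c(a1[cand], a2[cand]); ib <- c(b1[cand], b2[cand])
  len <- merged$len[cand]
  sc1 <- c(ib[1], ia[2])                       # between the two copies
  sc1_len <- sc1[2] - sc1[1]
  sc2_len <- n - len * 2L - sc1_len            # wraps the origin in general
  if (sc1_len == 0L || sc2_len == 0L)
    stop("degenerate structure: a single-copy region has zero length")
  if (sc1_len == sc2_len)
    stop("cannot disambiguate LSC/SSC: single-copy regions have equal length")
  lsc_is_sc1 <- sc1_len > sc2_len
  id <- seq_id(genome)
  rows <- list()
  add <- function(start, end, label, piece = 1L) {
    genome_region(id, start, end, "+", label) -> g
    g$piece <- piece
    rows[[length(rows) + 1L]] <<- g
  }
  # copy1 at ia[1], copy2 at ia[2]; single-copy 2 = [ib[2], n) + [0, ia[1])
  if (lsc_is_sc1) {
    # LSC between the copies; the IR after it in genome order is copy2 = IRa
    add(ia[1], ib[1], "IRb")
    add(sc1[1], sc1[2], "LSC")
    add(ia[2], ib[2], "IRa")
    if (ib[2] < n) add(ib[2], n, "SSC", 1L)
    if (ia[1] > 0) add(0L, ia[1], "SSC", if (ib[2] < n) 2L else 1L)
  } else {
    add(ia[1], ib[1], "IRa")
    add(sc1[1], sc1[2], "SSC")
    add(ia[2], ib[2], "IRb")
    if (ib[2] < n) add(ib[2], n, "LSC", if (ia[1] > 0) 1L else 1L)
    if (ia[1] > 0) add(0L, ia[1], "LSC", if (ib[2] < n) 2L else 1L)
  }
  regions <- do.call(rbind, rows)
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  st <- quadripartite_structure(regions, n, ir_mismatches = merged$mism[cand])
  ira <- region_seq(s, st, "IRa")
  irb <- region_seq(s, st, "IRb")
  mm <- sum(strsplit(ira, "")[[1]] != strsplit(reverse_complement(irb), "")[[1]])
  if (mm / len > params$max_mismatch_fraction)
    stop("no inverted repeat detected: candidate pair exceeds mismatch tolerance")
  st$ir_mismatches <- mm
  st
}

#' Longest suffix-prefix junction overlap between two contigs
#'
#' Finds the longest suffix of `left` equal (up to `max_mismatches`) to a
#' prefix of `right`, searched within `[min_overlap, max_overlap]`.
#' `in_expected_range` flags lengths in the empirically typical 19-51 nt
#' band; it is diagnostic only, never a constraint.
#' @param left,right sequence-like objects
#' @param min_overlap,max_overlap search bounds (nt)
#' @param max_mismatches tolerated mismatches inside the overlap
#' @return list(junction fields) or NULL when no overlap qualifies
#' @export
find_junction_overlap <- function(left, right, min_overlap = 15L,
                                  max_overlap = 200L, max_mismatches = 0L) {
  l <- residues(left); r <- residues(right)
  nl <- nchar(l); nr <- nchar(r)
  if (nl <= min_overlap || nr <= min_overlap) return(NULL)
  lim <- min(max_overlap, nl - 1L, nr - 1L)
  if (lim < min_overlap) return(NULL)
  lt <- strsplit(substring(l, nl - lim + 1L, nl), "")[[1]]
  rt <- strsplit(substring(r, 1L, lim), "")[[1]]
  for (len in seq(lim, min_overlap)) {
    mm <- sum(lt[(lim - len + 1L):lim] != rt[1:len])
    if (mm <= max_mismatches) {
      return(list(length = len,
                  sequence = substring(r, 1L, len),
                  mismatches = as.integer(mm),
                  in_expected_range = len >= 19L && len <= 51L))
    }
  }
  NULL
}

#' Classify draft contigs as LSC, IR and SSC
#'
#' With a finished reference, contigs are labeled by strand-agnostic k-mer
#' sharing with the reference's detected regions.  Without one, the three
#' longest contigs (after dropping fragments below `min_length`) are labeled
#' by length ordering - longest LSC, shortest SSC, middle IR - which matches
#' the region size ordering of every finished plastome.  All remaining
#' contigs are labeled "other".
#' @param contigs list of sequence-like objects (>= 3)
#' @param reference optional finished plastome
#' @param min_length contigs below this are labeled "other" outright
#' @return list with `labels` (character, per contig) and `contigs` (named
#'   list LSC/IR/SSC)
#' @export
classify_contigs <- function(contigs, reference = NULL, min_length = 1000L) {
  if (length(contigs) < 3L) stop("need at least 3 contigs")
  lens <- vapply(contigs, function(x) nchar(residues(x)), 0L)
  labels <- rep("other", length(contigs))
  cand <- which(lens >= min_length)
  if (!is.null(reference)) {
    st <- detect_inverted_repeats(reference)
    refseqs <- list(LSC = region_seq(reference, st, "LSC"),
                    IR = region_seq(reference, st, "IRa"),
                    SSC = region_seq(reference, st, "SSC"))
    for (i in cand) {
      shares <- vapply(refseqs, function(rs)
        mean(cpp_kmer_member(residues(contigs[[i]]), rs, 31L)), 0)
      if (max(shares) > 0.5) labels[i] <- names(shares)[which.max(shares)]
    }
  } else {
    top3 <- cand[order(lens[cand], decreasing = TRUE)][1:min(3L, length(cand))]
    if (length(top3) < 3L) stop("fewer than 3 contigs pass the length filter")
    if (anyDuplicated(lens[top3]))
      stop("ambiguous classification: contigs of equal length among ",
           paste(lens[top3], collapse = ", "))
    labels[top3[1]] <- "LSC"
    # IR vs SSC among the two smaller contigs: the IR contig's termini each
    # overlap both single-copy contigs, so the assignment with junction
    # overlaps at more of the four junctions wins; ties fall back to length
    # ordering (IR longer than SSC in every finished plastome)
    evidence <- function(L, I, S) {
      score <- function(Io) {
        Irc <- reverse_complement(Io)
        sum(!vapply(list(find_junction_overlap(L, Io),
                         find_junction_overlap(Io, S),
                         find_junction_overlap(S, Irc),
                         find_junction_overlap(Irc, L)), is.null, TRUE))
      }
      max(score(I), score(reverse_complement(I)))
    }
    L <- residues(contigs[[top3[1]]])
    x <- residues(contigs[[top3[2]]])
    y <- residues(contigs[[top3[3]]])
    e_x_ir <- evidence(L, x, y)
    e_y_ir <- evidence(L, y, x)
    if (e_y_ir > e_x_ir) {
      labels[top3[3]] <- "IR"
      labels[top3[2]] <- "SSC"
    } else {
      labels[top3[2]] <- "IR"
      labels[top3[3]] <- "SSC"
    }
  }
  for (lab in c("LSC", "IR", "SSC"))
    if (sum(labels == lab) > 1L)
      stop("ambiguous classification: multiple contigs labeled ", lab,
           " (lengths ", paste(lens[labels == lab], collapse = ", "), ")")
  if (!all(c("LSC", "IR", "SSC") %in% labels))
    stop("classification incomplete: got labels ",
         paste(sort(unique(labels)), collapse = ", "))
  list(labels = labels,
       contigs = list(LSC = contigs[[which(labels == "LSC")]],
                      IR = contigs[[which(labels == "IR")]],
                      SSC = contigs[[which(labels == "SSC")]]))
}

junction_names <- c("LSC-IRa", "IRa-SSC", "SSC-IRb", "IRb-LSC")

#' Stitch a complete quadripartite genome from three contigs
#'
#' Emits LSC + IRa + SSC + IRb with IRb the reverse complement of IRa.  Both
#' orientations of the IR contig are tried; the one yielding overlaps at more
#' junctions (including the circular IRb-LSC junction) wins.  Each overlap is
#' merged exactly once; a junction without an overlap yields a gap record
#' with flanking windows for primer design, and a short N placeholder is
#' inserted at the join.
#' @param lsc,ir,ssc the labeled contigs
#' @param min_overlap,max_overlap,max_mismatches see [find_junction_overlap()]
#' @param gap_flank flanking-window size for gap records (nt)
#' @param gap_placeholder N run inserted at gapped junctions
#' @return a `stitch_report`: list(genome, structure, overlaps, gaps,
#'   ir_orientation)
#' @export
stitch_quadripartite <- function(lsc, ir, ssc, min_overlap = 15L,
                                 max_overlap = 200L, max_mismatches = 0L,
                                 gap_flank = 300L, gap_placeholder = 10L) {
  L <- residues(lsc); S <- residues(ssc); I0 <- residues(ir)
  try_orient <- function(I) {
    Irc <- reverse_complement(I)
    list(
      find_junction_overlap(L, I, min_overlap, max_overlap, max_mismatches),
      find_junction_overlap(I, S, min_overlap, max_overlap, max_mismatches),
      find_junction_overlap(S, Irc, min_overlap, max_overlap, max_mismatches),
      find_junction_overlap(Irc, L, min_overlap, max_overlap, max_mismatches))
  }
  o_fwd <- try_orient(I0)
  o_rev <- try_orient(reverse_complement(I0))
  n_fwd <- sum(!vapply(o_fwd, is.null, TRUE))
  n_rev <- sum(!vapply(o_rev, is.null, TRUE))
  if (max(n_fwd, n_rev) < 2L)
    stop("stitching failed: only ", n_fwd, " junction overlap(s) as given and ",
         n_rev, " with the IR reverse-complemented (need >= 2)")
  use_rev <- n_rev > n_fwd
  ov <- if (use_rev) o_rev else o_fwd
  I <- if (use_rev) reverse_complement(I0) else I0
  Irc <- reverse_complement(I)
  contig_ids <- c(seq_id(lsc, "LSC"), seq_id(ir, "IR"), seq_id(ssc, "SSC"))

  gaps <- list()
  note_gap <- function(jn, left_seq, left_id, right_seq, right_id) {
    nl <- nchar(left_seq)
    lw <- genome_region(left_id, max(0L, nl - gap_flank), nl, "+", "gap_flank")
    rw <- genome_region(right_id, 0L, min(gap_flank, nchar(right_seq)), "+",
                        "gap_flank")
    gaps[[length(gaps) + 1L]] <<- list(
      junction = jn, left_flank_window = lw, right_flank_window = rw,
      note = paste0("no overlap >= ", min_overlap,
                    " nt; close by primer walking"))
  }
  join <- function(g, nxt, jn_idx, left_seq, left_id, right_id) {
    o <- ov[[jn_idx]]
    if (is.null(o)) {
      note_gap(junction_names[jn_idx], left_seq, left_id, nxt, right_id)
      paste0(g, strrep("N", gap_placeholder), nxt)
    } else {
      paste0(g, substring(nxt, o$length + 1L))
    }
  }
  g <- L
  g <- join(g, I, 1L, L, contig_ids[1], contig_ids[2])
  g <- join(g, S, 2L, I, contig_ids[2], contig_ids[3])
  g <- join(g, Irc, 3L, S, contig_ids[3], contig_ids[2])
  if (is.null(ov[[4]])) {
    note_gap(junction_names[4], Irc, contig_ids[2], L, contig_ids[1])
  } else {
    g <- substring(g, ov[[4]]$length + 1L)  # circular duplicate of the start
  }
  overlaps <- do.call(rbind, lapply(seq_along(ov), function(k) {
    o <- ov[[k]]
    if (is.null(o)) return(NULL)
    data.frame(junction = junction_names[k], length = o$length,
               sequence = o$sequence, mismatches = o$mismatches,
               in_expected_range = o$in_expected_range,
               stringsAsFactors = FALSE)
  }))
  structure_out <- if (length(gaps) == 0L)
    tryCatch(detect_inverted_repeats(nt_seq("stitched", g, circular = TRUE)),
             error = function(e) NULL) else NULL
  structure(list(
    genome = nt_seq("stitched", g, circular = TRUE,
                    description = "LSC+IRa+SSC+IRb"),
    structure = structure_out,
    overlaps = overlaps,
    gaps = gaps,
    ir_orientation = if (use_rev) "reverse-complemented" else "as-given"),
    class = "stitch_report")
}

#' @export
print.stitch_report <- function(x, ...) {
  cat(sprintf("<stitch_report> %s nt, %d overlaps, %d gaps (IR %s)\n",
              format(nchar(x$genome$residues), big.mark = ","),
              if (is.null(x$overlaps)) 0L else nrow(x$overlaps),
              length(x$gaps), x$ir_orientation))
  invisible(x)
}

# strand-specific k-mer identity estimate between two region sequences
orientation_identity <- function(query, ref, k = 15L) {
  if (nchar(query) < k || nchar(ref) < k) return(c(fwd = 0, rev = 0))
  f_fwd <- mean(cpp_kmer_member_stranded(query, ref, k))
  f_rev <- mean(cpp_kmer_member_stranded(reverse_complement(query), ref, k))
  c(fwd = f_fwd^(1 / k), rev = f_rev^(1 / k))
}

#' Rotate and orient a plastome canonically
#'
#' Rotates the circular genome to start at LSC base 1.  With a reference,
#' the LSC and SSC are flipped independently so each region's forward strand
#' matches the reference (decided by strand-specific k-mer identity of the
#' two orientations).  Without one, the whole-genome strand is chosen as the
#' lexicographically smaller of the two canonical rotations, which makes the
#' operation deterministic and idempotent.
#' @param genome sequence-like object
#' @param structure its [quadripartite_structure()]
#' @param reference optional reference plastome
#' @return list(genome = nt_seq, structure, applied_flips)
#' @export
normalize_orientation <- function(genome, structure, reference = NULL) {
  s <- residues(genome)
  n <- nchar(s)
  r <- structure$regions
  lsc <- r[r$label == "LSC", , drop = FALSE]
  lsc <- lsc[order(lsc$piece), , drop = FALSE]
  rot <- lsc$start[1]
  g <- rotate_left(s, rot)
  st <- detect_inverted_repeats(g)
  flips <- list(rotation = as.integer(rot), lsc_flipped = FALSE,
                ssc_flipped = FALSE, genome_flipped = FALSE)
  if (!is.null(reference)) {
    ref_st <- detect_inverted_repeats(reference)
    for (lab in c("LSC", "SSC")) {
      qs <- region_seq(g, st, lab)
      rs <- region_seq(reference, ref_st, lab)
      idt <- orientation_identity(qs, rs)
      if (max(idt) < 0.6)
        stop("cannot orient ", lab, ": both orientations below 60% identity (",
             sprintf("%.2f/%.2f", idt[1], idt[2]), ")")
      if (idt["rev"] > idt["fwd"]) {
        rr <- st$regions[st$regions$label == lab, , drop = FALSE]
        stopifnot(nrow(rr) == 1L)  # canonical rotation: no wrap
        g <- paste0(substring(g, 1L, rr$start),
                    reverse_complement(substring(g, rr$start + 1L, rr$end)),
                    substring(g, rr$end + 1L, n))
        flips[[paste0(tolower(lab), "_flipped")]] <- TRUE
      }
    }
    if (flips$lsc_flipped || flips$ssc_flipped)
      st <- detect_inverted_repeats(g)
  } else {
    alt <- reverse_complement(s)
    alt_st <- detect_inverted_repeats(alt)
    alt_r <- alt_st$regions[alt_st$regions$label == "LSC", , drop = FALSE]
    alt_r <- alt_r[order(alt_r$piece), , drop = FALSE]
    alt_g <- rotate_left(alt, alt_r$start[1])
    if (alt_g < g) {
      g <- alt_g
      st <- detect_inverted_repeats(g)
      flips$genome_flipped <- TRUE
    }
  }
  list(genome = nt_seq(seq_id(genome), g, circular = TRUE),
       structure = st, applied_flips = flips)
}
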