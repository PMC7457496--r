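## Deterministic synthetic plastomes with known ground truth.
##
## Planting conventions that make recovery exact:
##  * SSR runs get flank bases forced to break the period on both sides, and
##    a 110 nt buffer around each planted run is scrubbed of chance tandem
##    runs, so the scanner reports the planted locus at its exact
##    coordinates.
##  * dispersed-repeat copies get their immediately flanking base pairs
##    forced to mismatch under the kind's alignment geometry, so the planted
##    pair is a maximal hit when searched at max_hamming equal to the
##    planted distance.
##  * the mito donor is drawn at a distinct GC and screened to share no
##    31-mer with the host, so homology classification is exact.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(len, gc) {
  sample(c("A", "C", "G", "T"), len, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

other_base <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), avoid)[1]
}

#' Synthetic plastome specification
#'
#' Region sizes default to the middle of the range seen in finished
#' Chenopodiaceae-type plastomes (LSC 80-85 kb, IRs 23-29 kb, SSC 18-19 kb)
#' at a genome-wide GC of 36%.
#' @param lsc_length,ssc_length,ir_length region sizes (nt)
#' @param gc_target background GC fraction
#' @param region_gc optional named overrides, e.g. `list(SSC = 0.29, IR = 0.43)`
#' @param planted_ssrs list of `list(motif=, repeats=, region=)`
#' @param planted_repeats list of
#'   `list(kind=, length=, hamming=, regions=c(r1, r2))`
#' @param planted_insert optional `list(label=, length=, region=)`
#' @param planted_boundary_gene optional `list(status="full"|"partial",
#'   length=)`
#' @param seed RNG seed (integer)
#' @return validated spec list
#' @export
plastome_spec <- function(lsc_length = 84000L, ssc_length = 18500L,
                          ir_length = 25000L, gc_target = 0.36,
                          region_gc = NULL, planted_ssrs = list(),
                          planted_repeats = list(), planted_insert = NULL,
                          planted_boundary_gene = NULL, seed = 1L) {
  stopifnot(lsc_length > 0L, ssc_length > 0L, ir_length > 0L,
            lsc_length >= ssc_length, gc_target > 0, gc_target < 1)
  list(lsc_length = as.integer(lsc_length),
       ssc_length = as.integer(ssc_length),
       ir_length = as.integer(ir_length), gc_target = gc_target,
       region_gc = region_gc, planted_ssrs = planted_ssrs,
       planted_repeats = planted_repeats, planted_insert = planted_insert,
       planted_boundary_gene = planted_boundary_gene,
       seed = as.integer(seed))
}

# pick a placement start inside [0, cap - len), >= margin away from existing
# occupied intervals (matrix with columns start, end)
pick_slot <- function(cap, len, occupied, margin) {
  for (try in 1:200) {
    p <- sample.int(cap - len - 2L * margin, 1L) + margin
    ok <- TRUE
    if (nrow(occupied)) {
      ok <- all(p + len + margin <= occupied[, 1] |
                  p - margin >= occupied[, 2])
    }
    if (ok) return(p)
  }
  stop("cannot place a planted element of length ", len,
       ": region too crowded")
}

# break chance tandem runs (any unit 1..6 reaching its threshold) inside a
# window of a character vector, leaving [keep_lo, keep_hi) untouched
scrub_ssrs <- function(v, lo, hi, keep_lo, keep_hi,
                       thresholds = ssr_thresholds()) {
  lo <- max(1L, lo); hi <- min(length(v), hi)
  if (hi <= lo) return(v)
  repeat {
    seg <- paste(v[lo:hi], collapse = "")
    runs <- cpp_scan_ssrs(seg, pmax(thresholds$min_repeats - 1L, 2L))
    if (nrow(runs) == 0L) return(v)
    changed <- FALSE
    for (k in seq_len(nrow(runs))) {
      mid <- lo + runs$start[k] + (runs$unit[k] * runs$repeats[k]) %/% 2L
      if (mid >= keep_lo && mid < keep_hi) next
      v[mid] <- other_base(c(v[mid],
                             if (mid > 1L) v[mid - 1L],
                             if (mid < length(v)) v[mid + 1L]))
      changed <- TRUE
    }
    if (!changed) return(v)
  }
}

#' Generate a synthetic quadripartite plastome with known truth
#'
#' Builds LSC + IRa + SSC + IRb with IRb the exact reverse complement of
#' IRa, i.i.d. background at the target GC, and all requested elements
#' planted at recorded coordinates.  Identical seeds give byte-identical
#' output.
#' @param spec a [plastome_spec()]
#' @return list(genome = [nt_seq], structure = truth
#'   [quadripartite_structure()], features = truth [feature_table()],
#'   truth = element registry)
#' @export
generate_plastome <- function(spec = plastome_spec()) {
  with_seed(spec$seed, {
    n <- spec$lsc_length + spec$ssc_length + 2L * spec$ir_length
    gc_of <- function(lab) {
      if (!is.null(spec$region_gc) && !is.null(spec$region_gc[[lab]]))
        spec$region_gc[[lab]] else spec$gc_target
    }
    reg <- list(LSC = random_bases(spec$lsc_length, gc_of("LSC")),
                IR = random_bases(spec$ir_length, gc_of("IR")),
                SSC = random_bases(spec$ssc_length, gc_of("SSC")))
    occupied <- list(LSC = matrix(0L, 0, 2), IR = matrix(0L, 0, 2),
                     SSC = matrix(0L, 0, 2))
    note <- function(region, s, e) {
      occupied[[region]] <<- rbind(occupied[[region]], c(s, e))
    }
    reg_key <- function(r) if (r %in% c("IRa", "IR", "IRb")) "IR" else r
    truth <- list(ssrs = NULL, repeats = NULL, insert = NULL,
                  boundary_gene = NULL, seed = spec$seed)

    # ---- boundary gene first: it owns fixed positions at the IRa-SSC edge ----
    features <- list()
    if (!is.null(spec$planted_boundary_gene)) {
      bg <- spec$planted_boundary_gene
      glen <- 3L * (bg$length %/% 3L)
      codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste, collapse = "")
      sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
      body <- sample(sense, glen / 3L - 2L, replace = TRUE)
      orf <- strsplit(paste(c("ATG", body, "TAA"), collapse = ""), "")[[1]]
      ir_len <- spec$ir_length
      if (identical(bg$status, "full")) {
        # entire gene inside IRa (duplicated into IRb by construction)
        p <- ir_len - glen - 200L
        stopifnot(p > 0L)
        reg$IR[(p + 1L):(p + glen)] <- orf
        note("IR", p, p + glen)
        gene_start <- spec$lsc_length + p     # genome coords, 0-based
        iv <- data.frame(start = gene_start, end = gene_start + glen)
        bg_in_ir <- glen
      } else {
        # gene spans the IRa-SSC junction; 'in_ir' bases sit inside the IR
        in_ir <- as.integer(bg$in_ir %||% 1200L)
        stopifnot(in_ir < glen, in_ir < ir_len)
        reg$IR[(ir_len - in_ir + 1L):ir_len] <- orf[1:in_ir]
        reg$SSC[1:(glen - in_ir)] <- orf[(in_ir + 1L):glen]
        note("IR", ir_len - in_ir, ir_len)
        note("SSC", 0L, glen - in_ir)
        gene_start <- spec$lsc_length + ir_len - in_ir
        iv <- data.frame(start = gene_start, end = gene_start + glen)
        bg_in_ir <- in_ir
      }
      features[[1]] <- feature("ycf1", "CDS", iv, strand = "+",
                               codon_start = 1L)
      truth$boundary_gene <- list(status = bg$status, length = glen,
                                  start = gene_start, in_ir = bg_in_ir)
    }

    # ---- foreign insert (replaces background; region length preserved) ----
    if (!is.null(spec$planted_insert)) {
      pi <- spec$planted_insert
      key <- reg_key(pi$region)
      donor <- random_bases(pi$length, 0.45)
      p <- pick_slot(length(reg[[key]]), pi$length, occupied[[key]], 50L)
      # the donor's edge bases must differ from the host bases adjacent to
      # the junctions, or a junction k-mer coincides with a host k-mer and
      # boundary refinement shifts by one base
      donor[1] <- other_base(reg[[key]][p + pi$length + 1L])
      donor[pi$length] <- other_base(reg[[key]][p])
      reg[[key]][(p + 1L):(p + pi$length)] <- donor
      note(key, p, p + pi$length)
      truth$insert <- list(label = pi$label, region = pi$region,
                           start_in_region = p, length = pi$length,
                           donor = paste(donor, collapse = ""))
    }

    # ---- dispersed repeats ----
    for (pr in spec$planted_repeats) {
      r1 <- reg_key(pr$regions[1]); r2 <- reg_key(pr$regions[2])
      L <- pr$length; h <- pr$hamming
      core <- random_bases(L, spec$gc_target)
      copy2 <- switch(pr$kind,
        forward = core,
        complement = strsplit(complement_seq(paste(core, collapse = "")), "")[[1]],
        palindromic = strsplit(reverse_complement(paste(core, collapse = "")), "")[[1]],
        reverse = rev(core))
      if (h > 0L) {
        pos <- round(seq(4L, L - 3L, length.out = h))
        for (q in pos) copy2[q] <- other_base(copy2[q])
      }
      p1 <- pick_slot(length(reg[[r1]]), L, occupied[[r1]], 40L)
      note(r1, p1, p1 + L)
      p2 <- pick_slot(length(reg[[r2]]), L, occupied[[r2]], 40L)
      note(r2, p2, p2 + L)
      reg[[r1]][(p1 + 1L):(p1 + L)] <- core
      reg[[r2]][(p2 + 1L):(p2 + L)] <- copy2
      # force the immediately flanking alignment pairs to mismatch so the
      # planted pair is maximal at max_hamming == h
      flank <- function(region, idx, avoid) {
        if (idx >= 1L && idx <= length(reg[[region]]))
          reg[[region]][idx] <<- other_base(avoid)
      }
      g1l <- if (p1 >= 1L) reg[[r1]][p1] else "N"
      g1r <- if (p1 + L < length(reg[[r1]])) reg[[r1]][p1 + L + 1L] else "N"
      if (pr$kind == "forward") {
        flank(r2, p2, g1l); flank(r2, p2 + L + 1L, g1r)
      } else if (pr$kind == "complement") {
        flank(r2, p2, complement_seq(g1l)); flank(r2, p2 + L + 1L, complement_seq(g1r))
      } else if (pr$kind == "palindromic") {
        flank(r2, p2 + L + 1L, complement_seq(g1l)); flank(r2, p2, complement_seq(g1r))
      } else {  # reverse
        flank(r2, p2 + L + 1L, g1l); flank(r2, p2, g1r)
      }
      truth$repeats <- rbind(truth$repeats, data.frame(
        kind = pr$kind, region1 = r1, start_in_region1 = p1,
        region2 = r2, start_in_region2 = p2, length = L, hamming = h,
        stringsAsFactors = FALSE))
    }

    # ---- microsatellites ----
    for (ps in spec$planted_ssrs) {
      key <- reg_key(ps$region)
      u <- nchar(ps$motif)
      run <- strsplit(strrep(ps$motif, ps$repeats), "")[[1]]
      L <- length(run)
      p <- pick_slot(length(reg[[key]]), L, occupied[[key]], 130L)
      reg[[key]][(p + 1L):(p + L)] <- run
      # block extension by one unit on either side
      mot <- strsplit(ps$motif, "")[[1]]
      if (p >= 1L) reg[[key]][p] <- other_base(mot[u])
      if (p + L < length(reg[[key]]))
        reg[[key]][p + L + 1L] <- other_base(mot[1])
      reg[[key]] <- scrub_ssrs(reg[[key]], p - 115L, p + L + 116L,
                               keep_lo = p + 1L, keep_hi = p + L + 1L)
      note(key, p, p + L)
      truth$ssrs <- rbind(truth$ssrs, data.frame(
        motif = ps$motif, repeats = ps$repeats, region = ps$region,
        start_in_region = p, stringsAsFactors = FALSE))
    }

    # the maximal palindrome must end exactly at the IR boundaries: a chance
    # complementarity of the first and last SSC bases would otherwise extend
    # the detected IR one base into the SSC
    nss <- length(reg$SSC)
    if (reg$SSC[nss] == complement_seq(reg$SSC[1]))
      reg$SSC[nss] <- other_base(c(reg$SSC[nss], complement_seq(reg$SSC[1])))
    lsc <- paste(reg$LSC, collapse = "")
    ira <- paste(reg$IR, collapse = "")
    ssc <- paste(reg$SSC, collapse = "")
    g <- paste0(lsc, ira, ssc, reverse_complement(ira))
    l <- spec$lsc_length; ir <- spec$ir_length; sc <- spec$ssc_length
    regions <- rbind(
      cbind(genome_region("synthetic", 0L, l, "+", "LSC"), piece = 1L),
      cbind(genome_region("synthetic", l, l + ir, "+", "IRa"), piece = 1L),
      cbind(genome_region("synthetic", l + ir, l + ir + sc, "+", "SSC"),
            piece = 1L),
      cbind(genome_region("synthetic", l + ir + sc, n, "+", "IRb"),
            piece = 1L))
    st <- quadripartite_structure(regions, n)
    # genome-coordinate translation for planted elements
    off <- c(LSC = 0L, IR = l, SSC = l + ir)
    if (!is.null(truth$ssrs))
      truth$ssrs$start <- truth$ssrs$start_in_region +
        off[vapply(truth$ssrs$region, reg_key, "")]
    if (!is.null(truth$repeats)) {
      truth$repeats$start1 <- truth$repeats$start_in_region1 +
        off[truth$repeats$region1]
      truth$repeats$start2 <- truth$repeats$start_in_region2 +
        off[truth$repeats$region2]
    }
    if (!is.null(truth$insert))
      truth$insert$start <- truth$insert$start_in_region +
        off[[reg_key(truth$insert$region)]]
    list(genome = nt_seq("synthetic", g, circular = TRUE,
                         description = "synthetic quadripartite plastome"),
         structure = st,
         features = feature_table("synthetic", features, seq_length = n),
         truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contig fragmentation specification
#' @param overlap_lengths per-junction overlap lengths (named or length-4
#'   vector in junction order LSC-IRa, IRa-SSC, SSC-IRb, IRb-LSC); NULL draws
#'   each uniformly from 19..51
#' @param revcomp_ir_contig emit the IR contig reverse-complemented?
#' @param drop_overlaps_at junction names whose overlaps are removed (gap
#'   planting)
#' @param truncation nt additionally removed from the single-copy contig at
#'   each dropped junction
#' @param seed RNG seed
#' @return validated spec list
#' @export
fragmentation_spec <- function(overlap_lengths = NULL,
                               revcomp_ir_contig = TRUE,
                               drop_overlaps_at = character(0),
                               truncation = 1475L, seed = 1L) {
  if (!is.null(overlap_lengths)) {
    stopifnot(length(overlap_lengths) == 4L)
    overlap_lengths <- as.integer(overlap_lengths)
  }
  stopifnot(all(drop_overlaps_at %in% junction_names))
  list(overlap_lengths = overlap_lengths,
       revcomp_ir_contig = isTRUE(revcomp_ir_contig),
       drop_overlaps_at = drop_overlaps_at,
       truncation = as.integer(truncation), seed = as.integer(seed))
}

#' Fragment a plastome into three overlapping contigs
#'
#' Emits LSC, IR and SSC contigs, each extended into its true neighbors by
#' the per-junction overlap lengths, reproducing the overlap geometry of a
#' three-contig draft assembly.  Junctions named in `drop_overlaps_at` get no
#' overlap and lose `truncation` nt of single-copy sequence, planting a gap
#' the stitcher must report.
#' @param genome sequence-like object in canonical LSC+IRa+SSC+IRb order
#' @param structure its [quadripartite_structure()]
#' @param fspec a [fragmentation_spec()]
#' @return list(contigs = list(LSC, IR, SSC) of [nt_seq],
#'   overlaps = named lengths, gaps = dropped junctions)
#' @export
fragment_into_contigs <- function(genome, structure,
                                  fspec = fragmentation_spec()) {
  with_seed(fspec$seed, {
    ov <- fspec$overlap_lengths
    if (is.null(ov)) ov <- sample(19:51, 4L, replace = TRUE)
    names(ov) <- junction_names
    L <- region_seq(genome, structure, "LSC")
    A <- region_seq(genome, structure, "IRa")
    S <- region_seq(genome, structure, "SSC")
    B <- region_seq(genome, structure, "IRb")
    stopifnot(all(ov < min(nchar(L), nchar(A), nchar(S))))
    drop <- fspec$drop_overlaps_at
    ov[drop] <- 0L
    tr <- fspec$truncation
    lsc_lo <- if ("IRb-LSC" %in% drop) tr + 1L else 1L
    lsc_hi <- if ("LSC-IRa" %in% drop) nchar(L) - tr else nchar(L)
    ssc_lo <- if ("IRa-SSC" %in% drop) tr + 1L else 1L
    ssc_hi <- if ("SSC-IRb" %in% drop) nchar(S) - tr else nchar(S)
    contig_L <- paste0(
      if (ov["IRb-LSC"] > 0L) substring(B, nchar(B) - ov["IRb-LSC"] + 1L) else "",
      substring(L, lsc_lo, lsc_hi),
      if (ov["LSC-IRa"] > 0L) substring(A, 1L, ov["LSC-IRa"]) else "")
    contig_S <- paste0(
      if (ov["IRa-SSC"] > 0L) substring(A, nchar(A) - ov["IRa-SSC"] + 1L) else "",
      substring(S, ssc_lo, ssc_hi),
      if (ov["SSC-IRb"] > 0L) substring(B, 1L, ov["SSC-IRb"]) else "")
    contig_I <- if (fspec$revcomp_ir_contig) reverse_complement(A) else A
    list(contigs = list(LSC = nt_seq("contig_LSC", contig_L),
                        IR = nt_seq("contig_IR", contig_I),
                        SSC = nt_seq("contig_SSC", contig_S)),
         overlaps = ov, gaps = drop)
  })
}

#' Read-simulation specification
#' @param read_length read length (nt), default 79 as in typical trimmed
#'   HiSeq plastome libraries
#' @param depth target fold-coverage
#' @param substitution_rate i.i.d. per-base substitution error rate
#' @param seed RNG seed
#' @return validated spec list
#' @export
read_sim_spec <- function(read_length = 79L, depth = 100,
                          substitution_rate = 0.005, seed = 1L) {
  stopifnot(read_length >= 20L, depth > 0, substitution_rate >= 0,
            substitution_rate < 1)
  list(read_length = as.integer(read_length), depth = depth,
       substitution_rate = substitution_rate, seed = as.integer(seed))
}

#' Simulate uniform shotgun reads from a circular genome
#'
#' Reads start uniformly on the circular genome, on either strand, with
#' i.i.d. substitution errors; the read count is
#' `round(depth * genome_length / read_length)`.
#' @param genome sequence-like object
#' @param rspec a [read_sim_spec()]
#' @return named character vector of reads
#' @export
simulate_reads <- function(genome, rspec = read_sim_spec()) {
  with_seed(rspec$seed, {
    s <- residues(genome)
    n <- nchar(s)
    m <- rspec$read_length
    stopifnot(n >= m)
    count <- round(rspec$depth * n / m)
    ext <- paste0(s, substring(s, 1L, m))     # circular wrap
    starts <- sample.int(n, count, replace = TRUE)   # 1-based
    reads <- substring(ext, starts, starts + m - 1L)
    minus <- sample(c(TRUE, FALSE), count, replace = TRUE)
    if (any(minus)) {
      rc <- Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[minus]))
      reads[minus] <- as.character(rc)
    }
    if (rspec$substitution_rate > 0) {
      nerr <- stats::rbinom(count, m, rspec$substitution_rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(m, nerr[i])
        v <- strsplit(reads[i], "")[[1]]
        for (p in pos) v[p] <- other_base(v[p])
        reads[i] <- paste(v, collapse = "")
      }
    }
    setNames(reads, sprintf("read%06d_%d_%s", seq_len(count), starts,
                            ifelse(minus, "m", "p")))
  })
}

#' Write a truth registry as JSON
#' @param truth the `truth` element of [generate_plastome()] output
#' @param path output path
#' @return invisibly, `path`
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
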