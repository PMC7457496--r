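test_that("sub-threshold duplicates are not reported", {
  set.seed(71)
  seg <- rand_dna(29)
  g <- paste0(rand_dna(400), seg, rand_dna(400), seg, rand_dna(400))
  hits <- find_maximal_repeats(g, repeat_search_params(min_length = 30L,
                                                      max_hamming = 0L,
                                                      kinds = "forward"))
  expect_equal(nrow(hits), 0L)
})

test_that("planted repeats of every kind are recovered at exact coordinates", {
  for (kind in c("forward", "reverse", "complement", "palindromic")) {
    for (h in c(0L, 2L)) {
      px <- generate_plastome(plastome_spec(
        lsc_length = 8000L, ssc_length = 3000L, ir_length = 1500L,
        seed = 100L + h + match(kind, c("forward", "reverse", "complement",
                                        "palindromic")),
        planted_repeats = list(list(kind = kind, length = 40L, hamming = h,
                                    regions = c("LSC", "SSC")))))
      hits <- find_maximal_repeats(
        px$genome, repeat_search_params(max_hamming = h, kinds = kind),
        structure = px$structure)
      tr <- px$truth$repeats
      found <- hits[hits$start1 == tr$start1 & hits$start2 == tr$start2 &
                      hits$length == tr$length & hits$hamming == tr$hamming, ]
      expect_equal(nrow(found), 1L,
                   info = sprintf("%s h=%d", kind, h))
    }
  }
})

test_that("repeat finder matches the independent enumeration oracle", {
  set.seed(72)
  for (case in 1:3) {
    # random background with planted structure so hits actually exist
    core <- rand_dna(60)
    s <- paste0(rand_dna(300), core, rand_dna(200),
                mutate_seq(core, c(10L, 30L, 50L)), rand_dna(150),
                reverse_complement(core), rand_dna(150),
                complement_seq(core), rand_dna(100),
                paste(rev(strsplit(core, "")[[1]]), collapse = ""),
                rand_dna(200))
    for (kind in c("forward", "reverse", "complement", "palindromic")) {
      for (h in c(0L, 3L)) {
        got <- find_maximal_repeats(s, repeat_search_params(
          min_length = 30L, max_hamming = h, kinds = kind,
          exclude_ir_duplicate = FALSE))
        want <- oracle_repeats(s, kind, 30L, h)
        got <- got[order(got$start1, got$start2, got$length), ]
        want <- want[order(want$start1, want$start2, want$length), ]
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got[, c("start1", "start2", "length", "hamming")],
                     want[, c("start1", "start2", "length", "hamming")],
                     info = sprintf("case %d %s h=%d", case, kind, h))
      }
    }
  }
})

test_that("IR-duplicate exclusion removes the quadripartite mega-repeat", {
  px <- generate_plastome(plastome_spec(lsc_length = 8000L,
                                        ssc_length = 3000L,
                                        ir_length = 1500L, seed = 73))
  with_ir <- find_maximal_repeats(
    px$genome, repeat_search_params(kinds = "palindromic",
                                    exclude_ir_duplicate = FALSE))
  expect_true(any(with_ir$length >= 1500L))
  without <- find_maximal_repeats(
    px$genome, repeat_search_params(kinds = "palindromic"),
    structure = px$structure)
  expect_false(any(without$length >= 1500L))
})

test_that("repeat location classification uses the copy-1 midpoint", {
  ft <- feature_table("g", list(
    feature("two_exon", "CDS",
            data.frame(start = c(100L, 300L), end = c(200L, 400L)), "+", 1L)))
  hits <- data.frame(kind = "forward",
                     start1 = c(120L, 220L, 500L),
                     start2 = c(1000L, 1100L, 1200L),
                     length = 40L, hamming = 0L)
  cls <- classify_repeat_locations(hits, ft)
  expect_equal(unname(cls$per_hit), c("exon", "intron", "intergenic"))
  expect_equal(unname(cls$counts), c(1L, 1L, 1L))
  expect_lt(abs(sum(cls$percentages) - 100), 0.05)   # up to rounding
})

test_that("SSR scanner obeys MISA thresholds and motif minimality", {
  set.seed(74)
  bg <- ssr_free_dna(200)
  # "C" breakers stop the run from extending into the background
  g <- paste0(bg, "C", strrep("T", 12), "C", bg)
  hits <- find_ssrs(g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "T")
  expect_equal(hits$repeat_number, 12L)
  expect_equal(hits$start, 202L)
  expect_equal(hits$end, 213L)
  # below-threshold run is not reported
  g9 <- paste0(bg, "C", strrep("T", 9), "C", bg)
  expect_equal(nrow(find_ssrs(g9)), 0L)
  # an (AT)8 run is di-, never mono- or tetra-
  gat <- paste0(bg, "C", strrep("AT", 8), "C", bg)
  h2 <- find_ssrs(gat)
  expect_equal(h2$klass, "p2")
  expect_equal(h2$motif, "AT")
  expect_equal(h2$repeat_number, 8L)
})

test_that("SSR scanner matches the regex oracle on random 20 kb sequences", {
  set.seed(75)
  for (case in 1:2) {
    s <- paste0(rand_dna(9000, gc = 0.3),
                strrep("T", 12), rand_dna(500),
                strrep("AT", 8), rand_dna(500),
                strrep("TTA", 6), rand_dna(500),
                strrep("AATC", 4), rand_dna(500),
                strrep("AATAG", 3), rand_dna(500),
                strrep("AATCAG", 3), rand_dna(8000, gc = 0.3))
    got <- plastidkit:::cpp_scan_ssrs(s, ssr_thresholds()$min_repeats)
    got <- got[order(got$start, got$unit), ]
    want <- oracle_ssrs(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("start", "unit", "repeats", "motif")],
                 want[, c("start", "unit", "repeats", "motif")],
                 info = paste("case", case))
  }
})

test_that("compound SSRs merge within 100 nt and are counted once", {
  set.seed(76)
  bg <- ssr_free_dna(400)
  gap50 <- paste0("C", ssr_free_dna(48), "C")
  g <- paste0(bg, "C", strrep("T", 12), gap50, strrep("AT", 8), "C", bg)
  hits <- find_ssrs(g)
  expect_equal(hits$klass, "compound")
  expect_equal(hits$n_members, 2L)
  expect_equal(hits$members[[1]]$motif, c("T", "AT"))
  expect_equal(summarize_ssrs(hits)[["compound"]], 1L)
  expect_equal(summarize_ssrs(hits)[["total"]], 1L)
  # beyond the merge distance they stay separate
  gap150 <- paste0("C", ssr_free_dna(148), "C")
  g2 <- paste0(bg, "C", strrep("T", 12), gap150, strrep("AT", 8), "C", bg)
  hits2 <- find_ssrs(g2)
  expect_equal(sort(hits2$klass), c("p1", "p2"))
})

test_that("SSR summaries count planted classes exactly", {
  planted <- c(list(list(motif = "T", repeats = 12L, region = "LSC"),
                    list(motif = "A", repeats = 10L, region = "LSC"),
                    list(motif = "G", repeats = 11L, region = "LSC"),
                    list(motif = "C", repeats = 13L, region = "SSC"),
                    list(motif = "T", repeats = 15L, region = "SSC")),
               list(list(motif = "AT", repeats = 7L, region = "LSC"),
                    list(motif = "TA", repeats = 6L, region = "SSC")))
  px <- generate_plastome(plastome_spec(lsc_length = 12000L,
                                        ssc_length = 6000L,
                                        ir_length = 1500L, seed = 77,
                                        planted_ssrs = planted))
  hits <- find_ssrs(px$genome)
  tr <- px$truth$ssrs
  for (k in seq_len(nrow(tr))) {
    match_row <- hits[hits$start == tr$start[k] + 1L &
                        hits$motif == tr$motif[k] &
                        hits$repeat_number == tr$repeats[k], ]
    expect_equal(nrow(match_row), 1L, info = paste("planted", k))
  }
  sm <- summarize_ssrs(hits)
  expect_gte(sm[["p1"]], 5L)
  expect_gte(sm[["p2"]], 2L)
  expect_equal(sm[["total"]], sum(sm[names(sm) != "total"]))
  set.seed(79)
  expect_equal(unname(summarize_ssrs(find_ssrs(ssr_free_dna(400)))["total"]), 0L)
})

test_that("SSR comparison pairs loci by flank anchoring", {
  px <- generate_plastome(plastome_spec(
    lsc_length = 12000L, ssc_length = 4000L, ir_length = 2500L, seed = 78,
    planted_ssrs = list(list(motif = "T", repeats = 12L, region = "LSC"))))
  a <- residues(px$genome)
  expect_equal(nrow(compare_ssrs(a, a)), 0L)      # self: no polymorphism
  p <- px$truth$ssrs$start
  b <- paste0(substring(a, 1, p), strrep("T", 14), substring(a, p + 13L))
  pol <- compare_ssrs(a, b)
  expect_equal(nrow(pol), 1L)
  expect_equal(pol$repeatsA, 12L)
  expect_equal(pol$repeatsB, 14L)
  expect_equal(pol$repeatsB - pol$repeatsA, 2L)
  expect_equal(pol$status, "polymorphic")
})
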