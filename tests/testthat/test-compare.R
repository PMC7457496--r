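test_that("region metrics satisfy the quadripartite length identity", {
  # the printed arithmetic the identity mirrors
  expect_equal(84541 + 18916 + 2 * 24942, 153341)
  px <- generate_plastome(small_spec(81))
  m <- region_metrics(px$genome, px$structure)
  expect_equal(unname(m$lengths["whole"]),
               unname(m$lengths["LSC"] + m$lengths["SSC"] + 2 * m$lengths["IRa"]))
  expect_equal(unname(m$lengths["IRa"]), unname(m$lengths["IRb"]))
  expect_true(all(m$gc_percent >= 0 & m$gc_percent <= 100))
})

test_that("constructed GC content is reported exactly", {
  g <- paste0(strrep("GC", 2500), strrep("AT", 2000),
              strrep("G", 500), strrep("T", 500))
  expect_equal(gc_content(g, as_percent = TRUE),
               round(100 * (5000 + 500) / 10000, 2))
})

test_that("coding fractions count overlapping features once", {
  px <- generate_plastome(small_spec(82))
  n <- nchar(residues(px$genome))
  ft <- feature_table("synthetic", list(
    feature("a", "CDS", data.frame(start = 100L, end = 400L)),
    feature("b", "CDS", data.frame(start = 300L, end = 600L)),  # overlaps a
    feature("t", "tRNA", data.frame(start = 1000L, end = 1072L))), n)
  m <- region_metrics(px$genome, px$structure, ft)
  expect_equal(unname(m$coding["percent_protein_coding"]),
               round(100 * 500 / n, 2))
  expect_equal(unname(m$coding["percent_rna_coding"]), round(100 * 72 / n, 2))
  expect_equal(unname(m$coding["percent_coding"]), round(100 * 572 / n, 2))
})

test_that("pseudogene scan reports internal stops only", {
  g <- paste0("ATGAAATAA",                 # terminal stop only
              "ATGTAAAAATAA",              # one internal stop at codon 2
              strrep("A", 9))
  ft <- feature_table("x", list(
    feature("clean", "CDS", data.frame(start = 0L, end = 9L)),
    feature("pseudo", "CDS", data.frame(start = 9L, end = 21L))), 30)
  out <- scan_pseudogenes(g, ft)
  expect_equal(out$internal_stop_count, c(0L, 1L))
  expect_equal(out$stop_codon_positions[[2]], 2L)
  expect_false(any(out$frame_anomaly))
})

test_that("pseudogene scan honors strand, codon_start and planted stops", {
  set.seed(83)
  body <- paste(sample(c("AAA", "GAT", "CTG", "TGC", "GGA"), 40,
                       replace = TRUE), collapse = "")
  coding <- paste0("ATG", substring(body, 1, 30), "TAG",
                   substring(body, 31, 60), "TGA", substring(body, 61, 90),
                   "TAA", substring(body, 91), "TAA")
  g <- paste0("GG", reverse_complement(coding), "CCCC")
  ft <- feature_table("x", list(
    feature("minus4", "CDS", data.frame(start = 2L, end = 2L + nchar(coding)),
            strand = "-", codon_start = 1L)), nchar(g))
  out <- scan_pseudogenes(g, ft)
  expect_equal(out$internal_stop_count, 3L)
  # codon_start shifts the frame
  g2 <- paste0("TT", coding)
  ft2 <- feature_table("x", list(
    feature("shift", "CDS", data.frame(start = 0L, end = 2L + nchar(coding)),
            strand = "+", codon_start = 3L)), nchar(g2))
  expect_equal(scan_pseudogenes(g2, ft2)$internal_stop_count, 3L)
  # length not divisible by three is flagged but scanned
  ft3 <- feature_table("x", list(
    feature("ragged", "CDS", data.frame(start = 0L, end = 10L)))  , 30)
  expect_true(scan_pseudogenes(paste0("ATGTAAAAAT", strrep("C", 20)),
                               ft3)$frame_anomaly)
})

test_that("IR boundary analysis measures partial and full boundary-gene copies", {
  pxp <- generate_plastome(plastome_spec(
    lsc_length = 15000L, ssc_length = 6000L, ir_length = 3000L, seed = 84,
    planted_boundary_gene = list(status = "partial", length = 5400L,
                                 in_ir = 1200L)))
  bd <- analyze_ir_boundaries(pxp$genome, pxp$structure, pxp$features,
                              comparator_ir_length = 3000L)
  expect_equal(bd$status, "partial pseudogene")
  expect_equal(bd$copy_length, 1200L)
  expect_false(bd$ir_expansion_flag)
  expect_true("ycf1" %in% bd$junction_genes[["IRa-SSC"]])

  pxf <- generate_plastome(plastome_spec(
    lsc_length = 15000L, ssc_length = 6000L, ir_length = 8000L, seed = 85,
    planted_boundary_gene = list(status = "full", length = 5400L)))
  bdf <- analyze_ir_boundaries(pxf$genome, pxf$structure, pxf$features,
                               comparator_ir_length = 3000L)
  expect_equal(bdf$status, "full copy")
  expect_true(bdf$ir_expansion_flag)
  expect_equal(bdf$expansion_length, 5000L)

  # designated gene absent
  bda <- analyze_ir_boundaries(pxf$genome, pxf$structure,
                               feature_table("synthetic", list()),
                               comparator_ir_length = 3000L)
  expect_equal(bda$status, "absent")
  expect_length(bda$junction_genes[["LSC-IRa"]], 0L)
})

test_that("pairwise comparison of a genome with itself is clean", {
  px <- generate_plastome(small_spec(86))
  cmp <- pairwise_compare(px$genome, px$genome)
  expect_equal(cmp$snp_count, 0L)
  expect_equal(cmp$indel_event_count, 0L)
  expect_equal(cmp$percent_identity, 100)
})

test_that("planted substitutions and deletions are recovered exactly", {
  px <- generate_plastome(small_spec(87))
  a <- residues(px$genome)
  snp_pos <- c(2000L, 5000L, 8000L, 13500L, 20500L)   # >= 50 nt apart
  b <- mutate_seq(a, snp_pos)
  b <- paste0(substring(b, 1, 3000), substring(b, 3004))          # 3 nt del
  b <- paste0(substring(b, 1, 9997), substring(b, 10005))         # 7 nt del
  cmp <- pairwise_compare(a, b)
  expect_equal(cmp$snp_count, 5L)
  expect_equal(cmp$indel_event_count, 2L)
  expect_equal(cmp$indel_bases, 10L)
  expect_setequal(cmp$variants$pos[cmp$variants$type == "SNP"], snp_pos)
  # symmetry of the headline counts
  cmp2 <- pairwise_compare(b, a)
  expect_equal(cmp2$snp_count, cmp$snp_count)
  expect_equal(cmp2$indel_event_count, cmp$indel_event_count)
})

test_that("comparison survives an SSC flip in the second genome", {
  px <- generate_plastome(small_spec(88))
  a <- residues(px$genome)
  r <- px$structure$regions
  ssc <- r[r$label == "SSC", ]
  b <- paste0(substring(a, 1, ssc$start),
              reverse_complement(substring(a, ssc$start + 1, ssc$end)),
              substring(a, ssc$end + 1))
  cmp <- pairwise_compare(a, b)
  expect_equal(cmp$snp_count, 0L)
  expect_true(cmp$applied_flips$ssc_flipped)
  expect_equal(cmp$percent_identity, 100)
})

test_that("foreign insert detection recovers planted boundaries exactly", {
  px <- generate_plastome(plastome_spec(
    lsc_length = 15000L, ssc_length = 5000L, ir_length = 3000L, seed = 89,
    planted_insert = list(label = "mito", length = 4800L, region = "LSC")))
  g <- residues(px$genome)
  tr <- px$truth$insert
  host <- paste0(substring(g, 1, tr$start),
                 substring(g, tr$start + tr$length + 1L))  # insert excised
  calls <- detect_foreign_insert(px$genome, plastid_refs = list(host),
                                 mito_refs = list(tr$donor),
                                 features = px$features)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$classification, "mito-like")
  expect_equal(calls$start, tr$start)
  expect_equal(calls$end, tr$start + tr$length)
  # a genome drawn entirely from the plastid reference yields no call
  clean <- detect_foreign_insert(host, plastid_refs = list(host),
                                 mito_refs = list(tr$donor))
  expect_equal(nrow(clean), 0L)
})

test_that("short inserts fall below the reporting threshold", {
  px <- generate_plastome(plastome_spec(
    lsc_length = 15000L, ssc_length = 5000L, ir_length = 3000L, seed = 90,
    planted_insert = list(label = "mito", length = 600L, region = "LSC")))
  g <- residues(px$genome)
  tr <- px$truth$insert
  host <- paste0(substring(g, 1, tr$start),
                 substring(g, tr$start + tr$length + 1L))
  calls <- detect_foreign_insert(px$genome, plastid_refs = list(host),
                                 mito_refs = list(tr$donor),
                                 min_insert = 1000L)
  expect_equal(nrow(calls), 0L)
  expect_error(detect_foreign_insert(g, list(), list(host)), "non-empty")
})

test_that("coverage consistency verdicts follow the depth ratio", {
  prof <- structure(list(depth = rep(100L, 20000L)), class = "coverage_profile")
  call <- list(start = 8000L, end = 12000L)
  ok <- coverage_consistency_check(call, prof)
  expect_equal(ok$verdict, "consistent")
  expect_equal(ok$ratio, 1)
  prof$depth[8001:12000] <- 500L
  bad <- coverage_consistency_check(call, prof)
  expect_equal(bad$verdict, "inconsistent")
  expect_equal(bad$ratio, 5)
  prof$depth[8001:12000] <- 0L
  zero <- coverage_consistency_check(call, prof)
  expect_equal(zero$verdict, "inconsistent")
  expect_equal(zero$ratio, 0)
})
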