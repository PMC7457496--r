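mutate_at <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

test_that("exact substring reads align with full identity", {
  set.seed(51)
  ref <- rand_dna(5000)
  read <- substring(ref, 1001, 1079)
  aln <- align_read(read, ref)
  expect_equal(aln$identity, 1.0)
  expect_equal(aln$aligned_read_fraction, 1.0)
  expect_equal(aln$start, 1000L)
  expect_equal(aln$strand, 1L)
  # reverse-complement placement is found too
  aln2 <- align_read(reverse_complement(read), ref)
  expect_equal(aln2$identity, 1.0)
  expect_equal(aln2$strand, -1L)
  expect_equal(aln2$start, 1000L)
})

test_that("substituted reads match the printed identity arithmetic", {
  set.seed(52)
  ref <- rand_dna(5000)
  read80 <- substring(ref, 2001, 2080)
  r3 <- mutate_at(read80, c(15L, 40L, 66L))
  aln <- align_read(r3, ref)
  expect_equal(aln$identity, 77 / 80)           # 0.9625
  expect_true(accept_alignment(aln, mapping_parameters()))
  r9 <- mutate_at(read80, c(8L, 16L, 24L, 32L, 40L, 48L, 56L, 64L, 72L))
  aln9 <- align_read(r9, ref)
  expect_equal(aln9$identity, 71 / 80)          # 0.8875
  expect_false(accept_alignment(aln9, mapping_parameters()))
})

test_that("acceptance thresholds are inclusive", {
  p <- mapping_parameters()
  fake <- function(arf, idt) data.frame(aligned_read_fraction = arf,
                                        identity = idt)
  expect_true(accept_alignment(fake(1.0, 1.0), p))
  expect_false(accept_alignment(fake(0.79, 0.95), p))
  expect_true(accept_alignment(fake(0.80, 0.90), p))
})

test_that("mapper agrees with the exhaustive DP oracle on a small grid", {
  set.seed(53)
  for (case in 1:25) {
    ref <- rand_dna(sample(80:200, 1))
    rl <- sample(20:30, 1)
    p0 <- sample(nchar(ref) - rl, 1)
    read <- substring(ref, p0, p0 + rl - 1L)
    nmut <- sample(0:3, 1)
    if (nmut > 0) read <- mutate_at(read, sample(rl, nmut))
    if (runif(1) < 0.5) read <- reverse_complement(read)
    aln <- align_read(read, ref)
    oracle <- oracle_best_score(read, ref)
    expect_equal(aln$score, oracle, info = paste("case", case))
  }
})

test_that("coverage conserves aligned bases and recovers simulated depth", {
  px <- generate_plastome(small_spec(54))
  g <- px$genome
  n <- nchar(residues(g))
  reads <- simulate_reads(g, read_sim_spec(depth = 30, read_length = 79L,
                                           substitution_rate = 0.005,
                                           seed = 55))
  hits <- map_reads(reads, g)
  prof <- compute_coverage(hits, g)
  acc <- hits[hits$accepted, ]
  expect_equal(sum(prof$depth), sum(acc$end - acc$start))
  # depth over the LSC interior (unaffected by IR double placement); the
  # number of reads touching the window is binomial in the read count
  w <- prof$depth[1000:11000]
  p <- (length(w) + 78) / n
  se <- (79 / length(w)) * sqrt(length(reads) * p * (1 - p))
  expect_lt(abs(mean(w) - 30), 3 * se)
  # zero accepted reads give an all-zero profile
  set.seed(56)
  empty <- compute_coverage(c(r1 = rand_dna(79)), g)
  expect_equal(empty$mean_depth, 0)
  expect_equal(empty$mapped_read_count, 0L)
})

test_that("multi-placement doubles IR depth; primary placement does not", {
  px <- generate_plastome(small_spec(57))
  g <- px$genome
  reads <- simulate_reads(g, read_sim_spec(depth = 20, substitution_rate = 0,
                                           seed = 58))
  hits <- map_reads(reads, g)
  both <- compute_coverage(hits, g, multi = "all")
  prim <- compute_coverage(hits, g, multi = "primary")
  r <- px$structure$regions
  ira <- (r$start[r$label == "IRa"] + 200):(r$end[r$label == "IRa"] - 200)
  irb <- (r$start[r$label == "IRb"] + 200):(r$end[r$label == "IRb"] - 200)
  lsc <- 1000:11000
  expect_gt(mean(both$depth[ira]) / mean(both$depth[lsc]), 1.6)
  expect_lt(mean(prim$depth[irb]) / mean(prim$depth[lsc]), 0.4)
  n <- length(both$depth)
  expect_true(all(both$depth[100:(n - 100)] > 0))   # interior fully covered
})

test_that("stringency filters are monotone and exact reads always pass", {
  px <- generate_plastome(small_spec(59))
  g <- px$genome
  reads <- simulate_reads(g, read_sim_spec(depth = 5, substitution_rate = 0.01,
                                           seed = 60))
  hits <- map_reads(reads, g)
  grid <- expand.grid(lf = c(0.6, 0.8, 0.99), sf = c(0.8, 0.9, 0.99))
  counts <- mapply(function(lf, sf) {
    sum(accept_alignment(hits, mapping_parameters(length_fraction = lf,
                                                  similarity_fraction = sf)) &
          hits$primary == 1L)
  }, grid$lf, grid$sf)
  m <- matrix(counts, 3, 3)
  expect_true(all(diff(m[, 1]) <= 0))      # raising length fraction
  expect_true(all(diff(m[1, ]) <= 0))      # raising similarity fraction
  clean <- simulate_reads(g, read_sim_spec(depth = 2, substitution_rate = 0,
                                           seed = 61))
  # reads wrapping the circular origin cannot fully align to the linear
  # reference; the 100%-acceptance invariant holds for the non-wrapping ones
  starts <- as.integer(sub("^read\\d+_(\\d+)_.*$", "\\1", names(clean)))
  clean <- clean[starts + 79L - 1L <= nchar(residues(g))]
  ch <- map_reads(clean, g, strict_mapping_parameters())
  accepted_reads <- unique(ch$read[ch$accepted])
  expect_equal(length(accepted_reads), length(clean))
})

test_that("dual-stringency report: error-free identical, errors reduce strict mean", {
  px <- generate_plastome(small_spec(62))
  g <- px$genome
  clean <- simulate_reads(g, read_sim_spec(depth = 5, substitution_rate = 0,
                                           seed = 63))
  starts <- as.integer(sub("^read\\d+_(\\d+)_.*$", "\\1", names(clean)))
  clean <- clean[starts + 79L - 1L <= nchar(residues(g))]  # drop origin wraps
  ds <- dual_stringency_report(clean, g)
  expect_equal(ds$default$depth, ds$strict$depth)
  expect_equal(ds$delta_mean, 0)
  noisy <- simulate_reads(g, read_sim_spec(depth = 5, substitution_rate = 0.01,
                                           seed = 64))
  ds2 <- dual_stringency_report(noisy, g)
  expect_lte(ds2$strict$mean_depth, ds2$default$mean_depth)
  expect_gt(ds2$delta_mean, 0)
})

test_that("low-coverage screening uses a strict threshold on maximal runs", {
  prof <- structure(list(depth = rep(100L, 500)), class = "coverage_profile")
  expect_equal(nrow(screen_low_coverage(prof)), 0L)
  prof$depth[201:250] <- 0L
  out <- screen_low_coverage(prof)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 200L)
  expect_equal(out$end, 250L)
  expect_equal(out$min_depth_in_interval, 0L)
  prof$depth <- rep(100L, 500)
  prof$depth[42] <- 39L
  out2 <- screen_low_coverage(prof)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$end - out2$start, 1L)
  prof$depth[42] <- 40L
  expect_equal(nrow(screen_low_coverage(prof)), 0L)
})

test_that("concatenated remapping rescues the circular junction", {
  px <- generate_plastome(small_spec(65))
  g <- px$genome
  reads <- simulate_reads(g, read_sim_spec(depth = 60, substitution_rate = 0,
                                           seed = 66))
  linear <- compute_coverage(reads, g)
  n <- length(linear$depth)
  expect_lt(min(linear$depth[c(1:3, (n - 2):n)]), 40)  # terminal artifact
  jp <- remap_circular_junction(reads, g, px$structure, window = 500L)
  mid <- (500 - 79):(500 + 79)                         # junction vicinity
  expect_true(all(jp$depth[mid] >= 40))
  expect_equal(length(jp$depth), 1000L)
  none <- remap_circular_junction(character(0), g, px$structure, window = 500L)
  expect_equal(sum(none$depth), 0L)
  expect_warning(remap_circular_junction(reads[1:5], g, px$structure,
                                         window = 10000L), "truncating")
})
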