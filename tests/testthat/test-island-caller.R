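test_that("island_config validates its invariants", {
  expect_error(island_config(gap_size = 500L), "multiple")
  expect_error(island_config(effective_genome_fraction = 1.2), "fraction")
  cfg <- island_config()
  expect_equal(cfg$window_size, 200L)
  expect_equal(cfg$gap_size, 600L)
  expect_equal(cfg$effective_genome_fraction, 0.854)
  expect_equal(cfg$evalue, 1000)
})

test_that("window scores follow the closed-form Poisson tail", {
  cfg <- island_config()
  wc <- wc_from_counts(list(chr1 = c(0L, 4L, 1L)), 200L,
                       library_size = 100L, chrom_sizes = c(chr1 = 600))
  sw <- score_windows(wc, cfg, lambda = 1)
  # count 0: upper tail at zero is 1, ineligible
  expect_equal(sw$p[1L], 1)
  expect_false(sw$eligible[1L])
  expect_equal(sw$score[1L], 0)
  # count 4 at lambda 1: p = 1 - e^-1 (1 + 1 + 1/2 + 1/6)
  p4 <- 1 - exp(-1) * (1 + 1 + 1/2 + 1/6)
  expect_equal(sw$p[2L], p4, tolerance = 1e-12)
  expect_true(sw$eligible[2L])
  expect_equal(sw$score[2L], -log(p4), tolerance = 1e-12)
  # counts at round(lambda) are never eligible at threshold 0.2 for lambda >= 1
  for (lam in c(1, 2.5, 7, 20)) {
    p <- ppois(round(lam) - 1L, lam, lower.tail = FALSE)
    expect_true(p >= 0.2)
  }
})

test_that("derived lambda matches the stated background-rate formula", {
  cfg <- island_config()
  tags <- tagset_from_midpoints(list(chr1 = sample(0:999999, 5000L)),
                                c(chr1 = 1e6))
  sw <- score_windows(count_window_tags(tags, 200L), cfg)
  expect_equal(attr(sw, "lambda"), 200 * 5000 / (0.854 * 1e6))
  empty <- tagset_from_midpoints(list(chr1 = integer(0)), c(chr1 = 1e6))
  expect_error(score_windows(count_window_tags(empty, 200L), cfg), "empty")
})

test_that("island linking respects the gap rule at the boundary", {
  cfg <- island_config()
  mk <- function(elig_starts, n = 10L) {
    cnt <- integer(n)
    cnt[elig_starts / 200L + 1L] <- 50L   # hugely significant windows
    wc_from_counts(list(chr1 = cnt), 200L, 1000L, c(chr1 = n * 200))
  }
  sw <- score_windows(mk(c(0L, 800L)), cfg, lambda = 1)
  isl <- link_islands(sw, cfg)    # gap = 600 exactly -> one island
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 1000L)
  sw2 <- score_windows(mk(c(0L, 1000L)), cfg, lambda = 1)
  isl2 <- link_islands(sw2, cfg)  # gap = 800 -> two islands
  expect_equal(nrow(isl2), 2L)
  # single eligible window: island score equals the window score
  sw3 <- score_windows(mk(600L), cfg, lambda = 1)
  isl3 <- link_islands(sw3, cfg)
  expect_equal(isl3$score, sw3[eligible == TRUE, score])
  expect_true(all(isl3$score >= max(sw3$score)))
})

test_that("score threshold is monotone in the E-value with limits", {
  cfg_hi <- island_config(evalue = 1e9)
  thr_hi <- island_score_threshold(0.5, cfg_hi, genome_length = 2e6)
  expect_equal(thr_hi, 0)
  cfg1 <- island_config(evalue = 20)
  cfg2 <- island_config(evalue = 10)
  thr1 <- island_score_threshold(0.5, cfg1, genome_length = 2e6)
  thr2 <- island_score_threshold(0.5, cfg2, genome_length = 2e6)
  expect_true(thr2 >= thr1)
  expect_error(island_score_threshold(0, cfg1, 2e6), "lambda")
})

test_that("score threshold agrees with a longer independent simulation", {
  # toy genome of 1e4 windows at lambda = 0.5, tight E-value
  cfg <- island_config(evalue = 5, effective_genome_fraction = 1,
                       threshold_reps = 25L)
  glen <- 1e4 * 200
  thr <- island_score_threshold(0.5, cfg, genome_length = glen)
  # oracle: 10x longer brute-force simulation, different seed and code path
  set.seed(4242)
  pool <- unlist(lapply(1:250, function(r) {
    cnt <- rpois(1e4, 0.5)
    brute_islands(cnt, 0.5, 200L, 600L)$score
  }))
  exceed <- sort(pool, decreasing = TRUE)
  oracle_thr <- exceed[floor(5 * 250) + 1L]
  # agreement within the score of one strong window
  one_window <- -log(ppois(2L, 0.5, lower.tail = FALSE))
  expect_lt(abs(thr - oracle_thr), one_window)
})

test_that("identical control zeroes out input-corrected island calls", {
  set.seed(9)
  cs <- c(chr1 = 1e6)
  mids <- sample(0:999999, 20000L, replace = TRUE)
  tags <- tagset_from_midpoints(list(chr1 = mids), cs)
  cfg <- island_config()
  isl_plain <- call_islands(tags, cfg)
  expect_gt(nrow(isl_plain), 0L)
  isl_ctrl <- call_islands(tags, cfg, control_tags = tags)
  expect_equal(nrow(isl_ctrl), 0L)
})

test_that("differential calling of a library against itself finds nothing", {
  set.seed(10)
  cs <- c(chr1 = 1e6)
  tags <- tagset_from_midpoints(list(chr1 = sample(0:999999, 30000L, TRUE)), cs)
  dr <- call_differential_regions(tags, tags)
  expect_true(all(dr$norm_fc == 1))
  expect_equal(sum(dr$significant), 0L)
  expect_true(all(dr$q_value >= dr$p_value))
  empty <- tagset_from_midpoints(list(chr1 = integer(0)), cs)
  expect_error(call_differential_regions(tags, empty), "empty")
})

test_that("differential counts give the exact binomial p and pseudocounted fold", {
  # construct two tag sets with a known count imbalance in one island
  set.seed(12)
  cs <- c(chr1 = 2e5)
  bg_a <- sample(0:199999, 3000L, TRUE)
  bg_b <- sample(0:199999, 3000L, TRUE)
  ta <- tagset_from_midpoints(list(chr1 = c(bg_a, sample(50000:51999, 160L, TRUE))), cs)
  tb <- tagset_from_midpoints(list(chr1 = c(bg_b, sample(50000:51999, 40L, TRUE))), cs)
  dr <- call_differential_regions(ta, tb)
  hit <- dr[start < 52000 & end > 50000]
  expect_equal(nrow(hit), 1L)
  na <- ta$library_size; nb <- tb$library_size
  expect_equal(hit$norm_fc,
               ((hit$count_a + 1) / na) / ((hit$count_b + 1) / nb))
  expect_equal(hit$p_value,
               binom.test(hit$count_a, hit$count_a + hit$count_b,
                          na / (na + nb))$p.value)
  expect_equal(hit$direction, "hyper")
  expect_true(hit$significant)
})

test_that("norm_fc is invariant under duplicating every tag in both libraries", {
  set.seed(13)
  cs <- c(chr1 = 2e5)
  ma <- c(sample(0:199999, 2000L, TRUE), sample(30000:31999, 150L, TRUE))
  mb <- sample(0:199999, 2000L, TRUE)
  ta <- tagset_from_midpoints(list(chr1 = ma), cs)
  tb <- tagset_from_midpoints(list(chr1 = mb), cs)
  ta2 <- tagset_from_midpoints(list(chr1 = rep(ma, 2L)), cs)
  tb2 <- tagset_from_midpoints(list(chr1 = rep(mb, 2L)), cs)
  dr1 <- call_differential_regions(ta, tb)
  dr2 <- call_differential_regions(ta2, tb2)
  m <- merge(dr1[, .(chrom, start, end, norm_fc)],
             dr2[, .(chrom, start, end, norm_fc)],
             by = c("chrom", "start", "end"))
  expect_gt(nrow(m), 0L)
  # pseudocount also doubles with counts, so equality is approximate;
  # compare the pseudocount-free ratio instead
  d1 <- dr1[, .(chrom, start, end, r = (count_a / ta$library_size) /
                  pmax(count_b / tb$library_size, 1e-12))]
  d2 <- dr2[, .(chrom, start, end, r = (count_a / ta2$library_size) /
                  pmax(count_b / tb2$library_size, 1e-12))]
  mm <- merge(d1, d2, by = c("chrom", "start", "end"))
  expect_equal(mm$r.x, mm$r.y)
})

test_that("island calling is independent across chromosomes", {
  set.seed(14)
  m1 <- sample(0:499999, 8000L, TRUE)
  m2 <- sample(0:299999, 6000L, TRUE)
  cfg <- island_config()
  t12 <- tagset_from_midpoints(list(chrA = m1, chrB = m2),
                               c(chrA = 5e5, chrB = 3e5))
  t21 <- tagset_from_midpoints(list(chrB = m2, chrA = m1),
                               c(chrB = 3e5, chrA = 5e5))
  i12 <- call_islands(t12, cfg)
  i21 <- call_islands(t21, cfg)
  setkey(i12, chrom, start); setkey(i21, chrom, start)
  expect_equal(as.data.frame(i12), as.data.frame(i21))
})
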