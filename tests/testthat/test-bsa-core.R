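# Per-site statistics, filtering rules, window machinery and thresholds.

test_that("snp_index and delta follow their definitions", {
  expect_identical(snp_index(5, 5), 0.5)
  expect_identical(snp_index(0, 37), 1)
  expect_identical(snp_index(30, 10), 0.25)
  expect_error(snp_index(0, 0), "zero total depth")
  expect_error(snp_index(-1, 5), "non-negative")

  expect_equal(delta_snp_index(27, 13, 0, 40), 1 - 0.325)
  expect_identical(delta_snp_index(10, 5, 10, 5), 0)
})

test_that("ed2 matches the four-base proportion formula", {
  # pools fixed for opposite bases
  expect_identical(ed2(c(A = 30, C = 0, G = 0, T = 0),
                       c(A = 0, C = 30, G = 0, T = 0)), 2)
  expect_identical(ed2(c(10, 20), c(10, 20)), 0)
  # fully linked causal expectation: green 1/3 vs yellow 1 alt fraction
  expect_equal(ed2(c(2000, 1000), c(0, 3000)), 8 / 9)
  expect_error(ed2(c(0, 0), c(1, 1)), "zero total depth")
})

test_that("biallelic identity: ed2 equals twice the squared alt-proportion difference", {
  set.seed(41)
  for (i in 1:200) {
    g <- c(sample(0:50, 1L), sample(1:50, 1L))
    y <- c(sample(1:50, 1L), sample(0:50, 1L))
    dlt <- delta_snp_index(g[1L], g[2L], y[1L], y[2L])
    expect_equal(ed2(g, y), 2 * dlt^2, tolerance = 1e-12)
    expect_true(abs(dlt) <= 1)
    expect_true(ed2(g, y) >= 0 && ed2(g, y) <= 2)
  }
})

test_that("filter rules attribute each site to its first failing rule", {
  vt <- make_vt(list(
    list(), # clean pass
    list(pool_green = list(gq = 20L)), # low_gq
    list(parent_green = list(gt = "0/1", ad = c(15L, 15L))), # parent_het
    list(parent_green = list(gt = "./.", ad = c(0L, 0L))), # parent_het (missing)
    list(parent_yellow = list(gt = "0/0", ad = c(30L, 0L))), # parent_monomorphic
    list(pool_yellow = list(ad = c(0L, 0L))), # pool_missing
    # fails GQ *and* parent het: attributed to low_gq (first rule)
    list(parent_green = list(gt = "0/1", gq = 10L))
  ))
  res <- filter_variants(vt)
  expect_identical(res$report$n_input, 7L)
  expect_identical(res$report$low_gq, 2L)
  expect_identical(res$report$parent_het, 2L)
  expect_identical(res$report$parent_monomorphic, 1L)
  expect_identical(res$report$pool_missing, 1L)
  expect_identical(res$report$n_pass, 1L)
  with(res$report, expect_identical(
    n_input, n_pass + low_gq + parent_het + parent_monomorphic + pool_missing
  ))
  expect_identical(res$variants$pos, 1000)

  # gq threshold is >= (a GQ of exactly 50 passes)
  vt50 <- make_vt(list(list(pool_green = list(gq = 50L))))
  expect_identical(filter_variants(vt50)$report$n_pass, 1L)

  expect_error(
    filter_variants(vt, roles = c(parent_green = "nope",
                                  parent_yellow = "parent_yellow",
                                  pool_green = "pool_green",
                                  pool_yellow = "pool_yellow")),
    "parent_green"
  )
})

test_that("window means match arithmetic and each site lands in two interior windows", {
  stats <- data.frame(
    chrom = "chr1", pos = c(50000, 150000, 150001),
    delta_snp_index = c(0.4, 0.6, 0.2), ed2 = c(0.32, 0.72, 0.08),
    depth_green = 50, depth_yellow = 50
  )
  w <- sliding_windows(stats, chrom_lengths = c(chr1 = 400000))
  first <- w[w$start == 1, ]
  expect_equal(first$mean_delta, mean(c(0.4, 0.6, 0.2)))
  expect_identical(first$n_sites, 3L)
  # a site at 150,001 appears in exactly the windows starting 1 and 100,001
  covering <- w[w$start <= 150001 & w$end >= 150001 & w$n_sites > 0, ]
  expect_identical(nrow(covering), 2L)
  expect_identical(covering$start, c(1, 100001))
  expect_error(sliding_windows(stats[c(2, 1, 3), ]), "sorted")
})

test_that("window means equal a naive per-window recomputation on fuzzed data", {
  vt <- random_vt(300, seed = 43L)
  stats <- site_stats(vt)
  lens <- c(chr1 = 3e6, chr2 = 3e6, chr3 = 1e6) # chr3 has no sites
  w <- sliding_windows(stats, chrom_lengths = lens)
  bf <- brute_force_windows(stats, lens, 200000, 100000)
  expect_equal(w$mean_delta, bf$mean_delta, tolerance = 1e-10)
  expect_equal(w$mean_ed2, bf$mean_ed2, tolerance = 1e-10)
  expect_identical(w$n_sites, bf$n_sites)
  expect_true(all(is.na(w$mean_delta[w$chrom == "chr3"])))
})

test_that("Monte-Carlo null thresholds are ordered, stable and below the peak scale", {
  d <- rep(50, 20)
  thr <- null_thresholds(d, d, pool_size = 30L, n_sims = 5000L, seed = 51L)
  expect_lt(thr$thr95, thr$thr99)
  # a fully linked causal window (delta = 2/3) is callable above this null
  expect_lt(thr$thr99, 2 / 3)
  # doubling the simulation count moves the estimate by < 0.02
  thr2 <- null_thresholds(d, d, pool_size = 30L, n_sims = 10000L, seed = 51L)
  expect_lt(abs(thr2$thr99 - thr$thr99), 0.02)
  # deterministic under a fixed seed
  expect_identical(thr, null_thresholds(d, d, pool_size = 30L,
                                        n_sims = 5000L, seed = 51L))
  expect_error(null_thresholds(c(0, 50), c(50, 50), n_sims = 1000L), "positive")
  expect_error(null_thresholds(d, d, n_sims = 500L), "at least 1000")
})

test_that("threshold modes: fixed is constant, quantile matches quantile()", {
  w <- data.frame(chrom = "chr1", k = 0:9, start = 1, end = 2,
                  n_sites = 1L, mean_delta = seq(0.05, 0.5, by = 0.05),
                  mean_ed2 = 0.1)
  thr_f <- bsa_thresholds(w, mode = "fixed")
  expect_true(all(thr_f$thr99 == 0.5))
  thr_q <- bsa_thresholds(w, mode = "quantile")
  expect_equal(thr_q$thr99[1L],
               quantile(abs(w$mean_delta), 0.99, names = FALSE))
  expect_error(bsa_thresholds(w, mode = "simulate"), "per-site")
})

test_that("peak calling merges overlapping or adjacent significant windows", {
  w <- data.frame(
    chrom = "chr1", k = 0:3,
    start = c(1, 100001, 200001, 300001),
    end = c(200000, 300000, 400000, 500000),
    n_sites = 2L,
    mean_delta = c(0.8, 0.7, 0.9, 0.1),
    mean_ed2 = c(1.0, 0.9, 1.1, 0.05)
  )
  thr <- data.frame(thr95 = 0.4, thr99 = 0.5)
  pk <- call_peaks(w, thr)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$start, 1)
  expect_identical(pk$end, 400000)
  expect_identical(pk$n_windows, 3L)
  expect_identical(pk$max_mean_delta, 0.9)
  flagged <- attr(pk, "windows")
  expect_identical(flagged$sig99, c(TRUE, TRUE, TRUE, FALSE))

  # nothing significant -> empty interval list
  thr_hi <- data.frame(thr95 = 1, thr99 = 1)
  expect_identical(nrow(call_peaks(w, thr_hi)), 0L)

  # a gap of two windows splits runs unless merge_gap_bp bridges it
  w2 <- w
  w2$mean_delta <- c(0.8, 0.1, 0.1, 0.9)
  expect_identical(nrow(call_peaks(w2, thr)), 2L)
  expect_identical(nrow(call_peaks(w2, thr, merge_gap_bp = 300000)), 1L)

  # ED^2 co-requirement drops windows weak on that track (the survivors
  # here are still adjacent, so they merge into one interval)
  w3 <- w
  w3$mean_ed2 <- c(1.0, 0.2, 1.1, 0.05)
  pk3 <- call_peaks(w3, thr, ed2_min = 0.5)
  expect_identical(attr(pk3, "windows")$sig99, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(pk3$n_windows, 2L)
})

test_that("interval width does not inflate as depth grows", {
  cfg <- sim_config(seed = 0L)
  widths <- vapply(c(10, 53.83, 500), function(dp) {
    cfg$mean_depth <- dp
    st <- bsa_power_study(cfg, n_reps = 8L, seed = 61L)
    median(st$interval_width_bp, na.rm = TRUE)
  }, numeric(1))
  expect_true(widths[2L] <= widths[1L])
  expect_true(widths[3L] <= widths[2L])
})
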