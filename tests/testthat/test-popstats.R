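test_that("single-site window diversity follows the unbiased formula", {
  # n = 4 called alleles, j = 2: pi_site = 2*2*(4-2)/(4*3) = 2/3
  # (alleles 0,1,0,1: 4 differing pairs of 6)
  g <- matrix(c(1L, 1L), nrow = 1, ncol = 2)
  gm <- make_gm(g, pops = "p", pos = 50)
  w <- window_pi(gm, "p", window_bp = 100, step_bp = 100)
  expect_equal(w$value[1], (2 / 3) / 100, tolerance = 1e-12)
  expect_equal(w$value[1], oracle_pi_site(c(1L, 1L)) / 100, tolerance = 1e-12)
  expect_equal(w$n_sites[1], 1)
  # a monomorphic window is 0 (usable sites present, no variation) but a
  # window with zero usable sites is NA
  g2 <- rbind(c(1L, 1L), c(0L, 0L), c(NA, NA))
  gm2 <- make_gm(g2, pops = "p", pos = c(50, 150, 250))
  w2 <- window_pi(gm2, "p", window_bp = 100, step_bp = 100)
  expect_equal(w2$value[2], 0)
  expect_true(is.na(w2$value[3]))
})

test_that("window pi equals explicit pairwise-difference counting", {
  withr::with_seed(41, {
    g <- matrix(sample(c(0:2, NA), 30 * 6, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 30, 6)
    gm <- make_gm(g, pops = "p", pos = sort(sample(1:1000, 30)))
    w <- window_pi(gm, "p", window_bp = 1000, step_bp = 1000)
    manual <- sum(vapply(seq_len(30), function(i) {
      x <- oracle_pi_site(g[i, ])
      if (is.na(x)) 0 else x
    }, 0)) / 1000
    expect_equal(w$value[1], manual, tolerance = 1e-12)
  })
})

test_that("pi is invariant to sample order and ref/alt label swap", {
  withr::with_seed(42, {
    g <- matrix(sample(0:2, 40 * 8, replace = TRUE), 40, 8)
    gm <- make_gm(g, pops = "p", pos = sort(sample(1:5000, 40)))
    w1 <- window_pi(gm, "p")
    gm_perm <- make_gm(g[, sample(8)], pops = "p", pos = gm$sites$pos)
    expect_equal(window_pi(gm_perm, "p")$value, w1$value)
    gm_swap <- make_gm(2L - g, pops = "p", pos = gm$sites$pos)
    expect_equal(window_pi(gm_swap, "p")$value, w1$value)
  })
})

test_that("per-site Weir-Cockerham components match the formula transcription", {
  withr::with_seed(43, {
    g <- matrix(sample(c(0:2, NA), 20 * 12, replace = TRUE,
                       prob = c(0.35, 0.3, 0.25, 0.1)), 20, 12)
    gm <- make_gm(g, pops = rep(c("x", "y"), each = 6))
    f <- site_fst(gm, "x", "y", method = "wc")
    for (i in seq_len(20)) {
      o <- oracle_wc_site(g[i, 1:6], g[i, 7:12])
      if (f$usable[i]) {
        expect_equal(f$num[i], o[1], tolerance = 1e-12)
        expect_equal(f$den[i], o[2], tolerance = 1e-12)
      }
    }
  })
})

test_that("F_ST limits: identical frequencies give ~0, fixed differences give ~1", {
  g_same <- rbind(rep(c(0L, 1L, 1L, 2L), 10))
  gm <- make_gm(g_same, pops = rep(c("x", "y"), each = 20))
  f <- site_fst(gm, "x", "y")
  expect_lt(abs(f$fst[1]), 0.05)
  g_fix <- rbind(c(rep(0L, 30), rep(2L, 30)))
  gmf <- make_gm(g_fix, pops = rep(c("x", "y"), each = 30))
  expect_gt(site_fst(gmf, "x", "y")$fst[1], 0.95)
  expect_gt(site_fst(gmf, "x", "y", method = "hudson")$fst[1], 0.95)
})

test_that("windowed F_ST is the ratio of summed components", {
  withr::with_seed(44, {
    g <- matrix(sample(0:2, 50 * 10, replace = TRUE), 50, 10)
    gm <- make_gm(g, pops = rep(c("x", "y"), each = 5),
                  pos = sort(sample(1:10000, 50)))
    f <- site_fst(gm, "x", "y")
    w <- window_fst(f, window_bp = 1e4, step_bp = 1e4, anchor = "origin")
    u <- f$usable
    expect_equal(w$value[1], sum(f$num[u]) / sum(f$den[u]), tolerance = 1e-12)
    # single-site windows equal the site estimator
    w1 <- window_fst(f, window_bp = 1, step_bp = 1, anchor = "origin")
    nz <- w1[w1$n_sites == 1 & !is.na(w1$value), ]
    i <- match(nz$start, f$pos)
    expect_equal(nz$value, f$fst[i], tolerance = 1e-12)
  })
})

test_that("PBS follows the printed three-branch combination", {
  # t_N_OT = 0.3, t_N_D = 0.2, t_OT_D = 0.1 -> PBS = 0.2
  f <- 1 - exp(-c(0.3, 0.2, 0.1))
  pb <- pbs_from_fst(f[1], f[2], f[3])
  expect_equal(pb$pbs, 0.2, tolerance = 1e-12)
  expect_equal(pb$t_n_ot, 0.3, tolerance = 1e-12)
})

test_that("PBS clamps pathological F_ST without NaN or infinities", {
  pb <- pbs_from_fst(c(-0.3, 0, 1, 2), c(0.5, -1, 0.2, 0.3), c(1.5, 0.1, -0.2, 0))
  expect_true(all(is.finite(pb$pbs)))
  expect_equal(pb$t_n_ot[1], 0)  # negative F_ST -> zero branch
  expect_equal(pb$t_n_ot[2], 0)
})

test_that("swapping target and control swaps the outgroup branches only", {
  st <- simulate_truth(demography_config(
    data.frame(label = c("n", "ot", "d"), n_dip = c(8, 8, 6), ne = 1000,
               split_gen = c(150, 150, 1500)),
    c(chr1 = 1e6), 1e-3, seed = 51
  ))
  a <- pbs_scan(st$gm, "n", "ot", "d", window_bp = 5e4, step_bp = 5e4)
  b <- pbs_scan(st$gm, "ot", "n", "d", window_bp = 5e4, step_bp = 5e4)
  expect_equal(a$t_n_ot, b$t_n_ot, tolerance = 1e-12)
  expect_equal(a$t_n_d, b$t_ot_d, tolerance = 1e-12)
  expect_equal(a$t_ot_d, b$t_n_d, tolerance = 1e-12)
  expect_error(pbs_scan(st$gm, "n", "n", "d"), "disjoint")
})

test_that("windowed F_ST recovers the drift-model expectation", {
  cfg <- two_pop_config(52, n_dip = 20, t = 150, len = 4e6, mu = 3e-3)
  st <- simulate_truth(cfg)
  f <- site_fst(st$gm, "a", "b")
  w <- window_fst(f, window_bp = 5e4, step_bp = 5e4)
  est <- mean(w$value, na.rm = TRUE)
  expect_lt(abs(est - (1 - exp(-150 / 2000))), 0.02)
})

test_that("empirical outliers slice the top quantile with ties included", {
  ws <- data.frame(chrom = "chr1", start = 1:1000, end = 1:1000,
                   n_sites = 1, value = sample(seq(0.001, 1, length.out = 1000)))
  out <- empirical_outliers(ws, 0.01)
  expect_equal(nrow(out), 10)
  expect_equal(sort(out$value), sort(ws$value, decreasing = TRUE)[10:1])
  # all-equal values are all returned
  ws2 <- ws; ws2$value <- 1
  expect_equal(nrow(empirical_outliers(ws2, 0.01)), 1000)
  # missing windows never rank
  ws3 <- ws; ws3$value[1:500] <- NA
  out3 <- empirical_outliers(ws3, 0.01)
  expect_equal(nrow(out3), 5)
  expect_true(all(!is.na(out3$value)))
})

test_that("a strong simulated sweep puts its window in the top 1% of PBS", {
  cfg <- demography_config(
    data.frame(label = c("n", "ot", "d"), n_dip = c(15, 15, 8), ne = 1000,
               split_gen = c(300, 300, 2500)),
    c(chr1 = 5e6), 6e-4, seed = 201
  )
  st <- simulate_truth(cfg, list(sweep_spec("chr1", 2.5e6, 4e5, 0.9)))
  pb <- pbs_scan(st$gm, "n", "ot", "d")
  out <- empirical_outliers(pb, 0.01)
  expect_true(any(out$start <= 2.5e6 & out$end >= 2.5e6))
})

test_that("window stats export in 1-based and BED coordinates", {
  ws <- data.frame(chrom = "chr1", start = c(1, 101), end = c(100, 200),
                   n_sites = c(2, 0), value = c(0.5, NA))
  class(ws) <- c("window_stat", "data.frame")
  p1 <- tempfile(); p2 <- tempfile()
  write_window_stats(ws, p1)
  write_window_stats(ws, p2, bed = TRUE)
  t1 <- read.delim(p1); t2 <- read.delim(p2)
  expect_equal(t1$start, c(1, 101))
  expect_equal(t2$start, c(0, 100))
  expect_equal(t2$end, c(100, 200))
})
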