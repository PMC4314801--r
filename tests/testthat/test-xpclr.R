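test_that("omega is the mean scaled squared frequency divergence", {
  expect_equal(estimate_omega(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(estimate_omega(0.7, 0.5), 0.16)
  # SNPs fixed in B are excluded
  expect_equal(estimate_omega(c(0.7, 0.2), c(0.5, 0)), 0.16)
  expect_error(estimate_omega(0.5, 1), "polymorphic")
})

test_that("omega grows with divergence time", {
  om <- vapply(c(30L, 150L), function(t) {
    sim <- simulate_two_pops(sim_params(seed = 21, t_split = t))
    estimate_omega(colMeans(sim$hapA$alleles), colMeans(sim$hapB$alleles))
  }, 0)
  expect_lt(om[1], om[2])
})

test_that("LD weights give 1/cluster-size under single linkage", {
  set.seed(31)
  ind <- rand_mat(40, 4)  # independent columns: all weights 1
  expect_equal(ld_weights(ind, 0.95), rep(1, 4))

  dup <- cbind(ind[, 1], ind[, 1], ind[, 1])  # perfect LD triple
  expect_equal(ld_weights(dup, 0.95), rep(1 / 3, 3))

  # single-linkage chain: a~b and b~c linked, a~c not. Build b as a noisy
  # copy shared by a and c so that r2(a,b), r2(b,c) > thr but r2(a,c) <= thr
  a <- rep(c(0L, 1L), each = 30)
  b <- a; b[c(1, 31)] <- 1L - b[c(1, 31)]
  cc <- b; cc[c(2, 32)] <- 1L - cc[c(2, 32)]
  w <- suppressWarnings(cor(cbind(a, b, cc)))^2
  thr <- (w["a", "b"] + w["a", "cc"]) / 2  # between the two r2 levels
  expect_true(w["a", "b"] > thr && w["b", "cc"] > thr && w["a", "cc"] < thr)
  expect_equal(ld_weights(cbind(a, b, cc), thr), rep(1 / 3, 3))

  # weights within each cluster always sum to 1
  set.seed(32)
  mat <- cbind(rand_mat(40, 3), dup)
  wts <- ld_weights(mat, 0.95)
  expect_true(all(wts > 0 & wts <= 1))
})

test_that("the sweep likelihood collapses to the neutral one as c -> 1", {
  cfg <- xpclr_config()
  ll_n <- snp_sweep_loglik(3, 16, 0.4, r = 1, s = 0.01, omega = 0.1,
                           cfg, neutral = TRUE)
  # r so large that c is numerically 1
  ll_s <- snp_sweep_loglik(3, 16, 0.4, r = 10, s = 0.01, omega = 0.1, cfg)
  expect_equal(ll_s, ll_n, tolerance = 1e-9)
})

test_that("with c = 1 and small omega the quadrature recovers the exact binomial", {
  # as omega -> 0 the frequency density collapses to a spike at pB and the
  # likelihood tends to Binom(kA | nA, pB); omega is kept large enough that
  # the spike stays resolvable on the quadrature grid (sd >= a few dx)
  cfg <- xpclr_config(quadrature_points = 32768)
  ll <- snp_sweep_loglik(5, 10, 0.5, r = 10, s = 0.01, omega = 1e-7, cfg)
  expect_equal(ll, dbinom(5, 10, 0.5, log = TRUE), tolerance = 1e-6)
})

test_that("a zero-distance sweep explains fixation better than drift", {
  cfg <- xpclr_config()
  ll_s <- snp_sweep_loglik(16, 16, 0.3, r = 0, s = 0.05, omega = 0.05, cfg)
  ll_n <- snp_sweep_loglik(16, 16, 0.3, r = 0, s = 0.05, omega = 0.05, cfg,
                           neutral = TRUE)
  expect_gt(ll_s, ll_n)
})

test_that("escape probability is 0 at the sweep site and rises with distance", {
  cc <- sweepscan:::sweep_escape_prob(c(0, 1e-5, 1e-4, 1e-2), 0.05, 20000)
  expect_equal(cc[1], 0)
  expect_true(all(diff(cc) >= 0))
  expect_true(all(cc >= 0 & cc <= 1))
})

test_that("window scores are non-negative, capped at 400 SNPs, and localize sweeps", {
  # dense window: more SNPs than the cap
  set.seed(41)
  nsnp <- 500
  mB <- rand_mat(24, nsnp, p = 0.5)
  mA <- rand_mat(16, nsnp, p = 0.5)
  pos <- sort(sample.int(50000, nsnp))
  hapA <- haplotype_matrix(mA, pos, "1", population = "A")
  hapB <- haplotype_matrix(mB, pos, "1", population = "B")
  res <- xpclr_scan(hapA, hapB, 50000, xpclr_config(site_grid_step = 25000))
  expect_equal(res$n_snps_used, 400L)
  expect_gte(res$score, 0)

  # simulated sweep: the best-scoring window is within 50 kb of the truth
  hits <- 0
  for (seed in 701:705) {
    sw <- simulate_two_pops(sim_params(seed = seed),
                            sweep_params(origin = "new",
                                         condition_freq = 0.9))
    xc <- xpclr_scan(sw$hapA, sw$hapB, 500000)
    expect_true(all(xc$score >= -1e-9, na.rm = TRUE))
    best <- xc[which.max(xc$score), ]
    d <- max(best$start - sw$truth$sweep_pos,
             sw$truth$sweep_pos - best$end, 0)
    if (d <= 50000) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("windows near a sweep outscore distant windows in most replicates", {
  wins_hit <- 0
  n_rep <- 10
  for (seed in 711:(710 + n_rep)) {
    sw <- simulate_two_pops(sim_params(seed = seed),
                            sweep_params(origin = "new",
                                         condition_freq = 0.9))
    xc <- xpclr_scan(sw$hapA, sw$hapB, 500000)
    mid <- (xc$start + xc$end) / 2
    d <- abs(mid - sw$truth$sweep_pos)
    near <- d <= 50000
    far <- d >= 200000
    if (any(near) && any(far) &&
        mean(xc$score[near], na.rm = TRUE) >
        mean(xc$score[far], na.rm = TRUE)) wins_hit <- wins_hit + 1
  }
  expect_gte(wins_hit, 0.8 * n_rep)
})

test_that("neutral no-differentiation data yields near-zero scores", {
  # hapA resampled from hapB's own frequencies: no systematic divergence
  set.seed(42)
  sim <- simulate_two_pops(sim_params(seed = 51, t_split = 10L))
  pB <- colMeans(sim$hapB$alleles)
  mA <- vapply(pB, function(p) rbinom(16, 1L, p), integer(16))
  hapA <- haplotype_matrix(mA, sim$hapB$positions, "1", population = "A")
  res <- xpclr_scan(hapA, sim$hapB, 500000)
  expect_true(all(res$score <= 0.5, na.rm = TRUE))
})

test_that("top_fraction designates scores strictly above the empirical quantile", {
  set.seed(43)
  x <- sample(seq_len(1000))  # 1000 distinct scores
  tf <- top_fraction(x, 0.01)
  expect_equal(tf$n_designated, 10L)
  expect_true(all(x[tf$regions] > tf$threshold))

  expect_equal(top_fraction(rep(3, 50))$n_designated, 0L)

  xr <- c(1, 1, 2, 5, 9)
  all_but_min <- top_fraction(xr, 1.0)
  expect_equal(sort(xr[all_but_min$regions]), c(2, 5, 9))

  df <- data.frame(start = 1:5, score = c(0.1, 5, 2, NA, 3))
  tf2 <- top_fraction(df, 0.2)
  expect_equal(tf2$regions$start, 2L)
})

test_that("SNP thinning inside windows is deterministic under the config seed", {
  sim <- simulate_two_pops(sim_params(seed = 61))
  cfg <- xpclr_config(max_snps = 20, seed = 9L)
  r1 <- xpclr_scan(sim$hapA, sim$hapB, 500000, cfg)
  r2 <- xpclr_scan(sim$hapA, sim$hapB, 500000, cfg)
  expect_identical(r1, r2)
})
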