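test_that("EHH matches direct pair counting on constructed cases", {
  # at the core itself the empty extension gives 1 by convention
  m <- rand_mat(6, 10)
  expect_equal(ehh_at(hm(m), 4, 4), 1)

  # all strings distinct over the span -> no identical pair
  m6 <- rbind(c(0,0,0), c(0,0,1), c(0,1,0), c(0,1,1), c(1,0,0), c(1,1,1))
  expect_equal(ehh_at(hm(m6), 1, 3), 0)

  # strings {AAB, AAB, AAB, ABB}: 3 identical pairs of 6
  m4 <- rbind(c(0,0,1), c(0,0,1), c(0,0,1), c(0,1,1))
  expect_equal(ehh_at(hm(m4), 1, 3), 0.5)
})

test_that("EHH equals the brute-force oracle for all core/target pairs", {
  set.seed(101)
  for (rep in 1:3) {
    m <- rand_mat(10, 20)
    hap <- hm(m)
    for (core in c(1, 5, 11, 20))
      for (target in seq(1, 20, by = 3)) {
        if (target == core) next
        expect_equal(ehh_at(hap, core, target), brute_ehh(m, core, target),
                     info = sprintf("core %d target %d", core, target))
      }
  }
})

test_that("EHH profiles are non-increasing and bounded in [0, 1]", {
  set.seed(102)
  for (rep in 1:5) {
    hap <- hm(rand_mat(12, 30, p = runif(1, 0.2, 0.8)))
    for (core in c(1, 15, 30)) {
      for (dir in c("downstream", "upstream")) {
        prof <- ehh_profile(hap, core, dir, max_dist = Inf)
        expect_true(all(diff(prof$ehh) <= 1e-12))
        expect_true(all(prof$ehh >= 0 & prof$ehh <= 1))
        expect_equal(prof$ehh[1], 1)
      }
    }
  }
})

test_that("boundary SNP is the pooled-EHH value closest to 0.04, ties to the farther SNP", {
  # construct pooled haplotypes whose EHH decays through 0.04:
  # 10+10 haplotypes; columns progressively split the groups
  set.seed(103)
  mA <- rand_mat(10, 40); mB <- rand_mat(10, 40)
  hapA <- hm(mA); hapB <- hm(mB, population = "B")
  pooled <- pool_haplotypes(hapA, hapB)
  for (core in c(1, 20)) {
    X <- find_boundary_snp(hapA, hapB, core, "downstream", max_dist = Inf)
    prof <- ehh_profile(pooled, core, "downstream", max_dist = Inf)
    cand <- prof[-1, ]
    d <- abs(cand$ehh - 0.04)
    best <- cand$index[which(d == min(d))]
    expect_equal(X, best[length(best)])
  }
  # saturated profile: all pooled EHH far above 0.04 -> farthest SNP wins
  mono <- matrix(0L, 8, 5)
  hA <- hm(mono); hB <- hm(mono, population = "B")
  expect_equal(find_boundary_snp(hA, hB, 1, "downstream", max_dist = Inf), 5L)
  # no SNP in the direction -> NA
  expect_true(is.na(find_boundary_snp(hA, hB, 1, "upstream")))
})

test_that("integrated EHH is a trapezoid sum against physical distance", {
  # identical haplotypes: EHH stays 1, area = span length
  hap <- haplotype_matrix(matrix(0L, 8, 11), positions = seq(0, 10000, 1000) + 1,
                          chrom = "1")
  expect_equal(integrated_ehh(hap, 1, 11), 10000)

  # two haplotypes diverging at the target: profile (1, 0) over 1000 bp
  m <- rbind(c(0L, 0L), c(0L, 1L))
  hap2 <- haplotype_matrix(m, positions = c(1, 1001), chrom = "1")
  expect_equal(integrated_ehh(hap2, 1, 2), 500)

  # 5-point profile equals an explicit trapezoid sum
  set.seed(104)
  m5 <- rand_mat(10, 5)
  hap5 <- hm(m5, spacing = 700L)
  prof <- vapply(2:5, function(t) brute_ehh(m5, 1, t), 0)
  xs <- 700 * (1:5)
  ys <- c(1, prof)
  manual <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  expect_equal(integrated_ehh(hap5, 1, 5), manual)
})

test_that("XP-EHH is zero for identical populations and ln(e) for a constructed ratio", {
  set.seed(105)
  m <- rand_mat(10, 30)
  hapA <- hm(m); hapB <- hm(m, population = "B")
  r <- xpehh_raw(hapA, hapB, 15)
  expect_equal(r$raw, 0)
  expect_equal(r$I_A, r$I_B)
})

test_that("swapping populations negates every raw XP-EHH score", {
  set.seed(106)
  hapA <- hm(rand_mat(10, 25)); hapB <- hm(rand_mat(8, 25), population = "B")
  fwd <- xpehh_scan(hapA, hapB)
  rev <- xpehh_scan(hapB, hapA)
  expect_equal(fwd$raw, -rev$raw, tolerance = 1e-12)
})

test_that("a simulated sweep in population A yields a positive raw score at the swept core", {
  sw <- simulate_two_pops(sim_params(seed = 3),
                          sweep_params(origin = "new", condition_freq = 0.9))
  core <- which.min(abs(sw$hapA$positions - sw$truth$sweep_pos))
  r <- xpehh_raw(sw$hapA, sw$hapB, core)
  expect_gt(r$raw, 0)
})

test_that("standardization yields exact mean 0 / variance 1 with population variance", {
  expect_equal(standardize_scores(c(1, 2, 3)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(107)
  x <- rnorm(500, mean = 3, sd = 7)
  z <- standardize_scores(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(mean(z^2) - 1), 1e-12)
  # NAs pass through in place
  x[c(5, 50)] <- NA
  z <- standardize_scores(x)
  expect_true(all(is.na(z[c(5, 50)])))
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-12)
  expect_error(standardize_scores(rep(2, 10)), "constant")
  expect_error(standardize_scores(c(1, NA)), "finite")
})

test_that("sweep cores are score outliers within their own genome", {
  # power property: the maximum standardized score within 50 kb of the
  # sweep sits in the top decile of the run's own score distribution.
  # (Cross-run score exceedance is not a usable criterion at this genome
  # size: standardization is genome-wide, and on a 500-kb chromosome the
  # sweep itself shifts the moments it is standardized by.)
  hits <- 0
  n_rep <- 20
  for (seed in 611:(610 + n_rep)) {
    sw <- simulate_two_pops(sim_params(seed = seed),
                            sweep_params(origin = "new",
                                         condition_freq = 0.9))
    sc <- xpehh_scan(sw$hapA, sw$hapB)
    near <- abs(sc$pos - sw$truth$sweep_pos) <= 50000
    q90 <- quantile(sc$std, 0.9, na.rm = TRUE)
    if (any(near) && max(sc$std[near], na.rm = TRUE) > q90) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_rep)
})
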