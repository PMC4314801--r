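#' Configuration for the XP-CLR-style composite likelihood scan
#'
#' Defaults follow the standard parameterization of cross-population
#' composite likelihood scans: non-overlapping 50-kb windows, at most 400
#' SNPs per window, and down-weighting of SNP pairs correlated above
#' r-squared 0.95. The sweep model is an explicit, documented approximation
#' of the classical hitchhiking escape process: a beneficial allele at a
#' candidate site lets linked neutral alleles "escape" the sweep by
#' recombination with probability `c = 1 - (2N s)^(-r/s)`; allele
#' frequencies in the test population are then modelled as a two-point
#' mixture of truncated normals around the escape-weighted means, with
#' drift variance `omega * pB (1 - pB)`.
#'
#' @param window_bp window size in bp.
#' @param max_snps maximum SNPs used per window (uniform random thinning).
#' @param ld_corr_threshold r-squared above which SNP pairs are clustered
#'   and down-weighted.
#' @param s_grid selection coefficients scanned (log-spaced by default).
#' @param site_grid_step spacing of candidate sweep positions within a
#'   window, bp.
#' @param recomb_rate genetic map rate in Morgans per bp (default 1 cM/Mb).
#' @param two_N effective number of chromosomes (enters only through 2Ns).
#' @param quadrature_points grid size for the frequency integral on (0, 1).
#' @param seed RNG seed for within-window SNP thinning.
#' @return A list of class `xpclr_config`.
#' @export
xpclr_config <- function(window_bp = 50000, max_snps = 400,
                         ld_corr_threshold = 0.95,
                         s_grid = exp(seq(log(1e-4), log(0.5), length.out = 12)),
                         site_grid_step = 10000, recomb_rate = 1e-8,
                         two_N = 20000, quadrature_points = 512, seed = 1L) {
  cfg <- list(window_bp = window_bp, max_snps = max_snps,
              ld_corr_threshold = ld_corr_threshold, s_grid = s_grid,
              site_grid_step = site_grid_step, recomb_rate = recomb_rate,
              two_N = two_N, quadrature_points = quadrature_points,
              seed = as.integer(seed))
  stopifnot(window_bp > 0, max_snps > 0, ld_corr_threshold > 0,
            ld_corr_threshold <= 1, all(s_grid > 0), site_grid_step > 0,
            recomb_rate > 0, two_N > 0, quadrature_points > 0)
  class(cfg) <- "xpclr_config"
  cfg
}

#' Estimate the drift scale omega between two populations
#'
#' `omega` is the variance-scaled allele-frequency divergence, averaged
#' over SNPs polymorphic in the reference population B:
#' `mean((pA - pB)^2 / (pB (1 - pB)))`. It grows with divergence time and
#' sets the drift variance of the neutral model.
#'
#' @param freqA,freqB per-SNP derived-allele frequencies in populations A
#'   and B.
#' @return The scalar omega estimate (>= 0).
#' @export
estimate_omega <- function(freqA, freqB) {
  stopifnot(length(freqA) == length(freqB))
  use <- freqB > 0 & freqB < 1
  if (!any(use)) stop("no SNP polymorphic in population B")
  mean((freqA[use] - freqB[use])^2 / (freqB[use] * (1 - freqB[use])))
}

#' LD down-weighting of SNPs within a window
#'
#' SNPs are clustered by single linkage over pairs whose r-squared in the
#' reference population exceeds `threshold`; each SNP contributes
#' `1 / cluster size` to the composite likelihood, so every cluster of
#' near-duplicate SNPs carries total weight 1.
#'
#' @param hapB_window reference-population haplotype 0/1 matrix restricted
#'   to the window's SNP columns (haplotypes x SNPs).
#' @param threshold r-squared linkage threshold (default 0.95).
#' @return Numeric vector of per-SNP weights in (0, 1\].
#' @export
ld_weights <- function(hapB_window, threshold = 0.95) {
  m <- ncol(hapB_window)
  if (m == 0L) return(numeric(0))
  if (m == 1L) return(1)
  r2 <- suppressWarnings(stats::cor(hapB_window))^2
  r2[!is.finite(r2)] <- 0  # monomorphic columns: never linked
  adj <- r2 > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  csize <- table(memb)
  as.numeric(1 / csize[as.character(memb)])
}

#' Log-likelihood of one SNP under the sweep (or neutral) model
#'
#' The escape probability at genetic distance `r` from a sweep of strength
#' `s` is `c = 1 - (2N s)^(-r/s)`, clipped to \[0, 1\]. The latent
#' test-population frequency is a two-point mixture: with weight `pB` a
#' truncated normal centred at `(1 - c) + c pB`, with weight `1 - pB` one
#' centred at `c pB`, both with variance `omega * pB (1 - pB)` and with the
#' mass falling outside (0, 1) collected into boundary point masses at 0
#' and 1. The sampling likelihood integrates the binomial over this
#' density by fixed-grid quadrature. `neutral = TRUE` (equivalently c = 1)
#' collapses the mixture to a single normal at mean `pB`.
#'
#' @param kA,nA derived-allele count and total chromosomes in population A.
#' @param pB derived-allele frequency in population B, in (0, 1).
#' @param r genetic distance (Morgans) from the SNP to the candidate site.
#' @param s selection coefficient (> 0).
#' @param omega drift scale from [estimate_omega()].
#' @param config an [xpclr_config()] (supplies `two_N` and the quadrature).
#' @param neutral evaluate the neutral model (c fixed at 1) instead.
#' @return The log-likelihood.
#' @export
snp_sweep_loglik <- function(kA, nA, pB, r, s, omega, config = xpclr_config(),
                             neutral = FALSE) {
  if (pB <= 0 || pB >= 1) stop("pB must lie strictly in (0, 1)")
  if (r < 0) stop("r must be >= 0")
  if (s <= 0) stop("s must be > 0")
  if (kA < 0 || kA > nA) stop("kA out of range")
  cc <- if (neutral) 1 else sweep_escape_prob(r, s, config$two_N)
  q <- quad_grid(config$quadrature_points)
  lik <- snp_lik_on_grid(kA, nA, pB, cc, omega, q$p, q$dx)
  log(max(lik, 1e-300))
}

sweep_escape_prob <- function(r, s, two_N) {
  cc <- 1 - (two_N * s)^(-r / s)
  pmin(pmax(cc, 0), 1)
}

quad_grid <- function(n) {
  dx <- 1 / n
  list(p = seq(dx / 2, 1 - dx / 2, by = dx), dx = dx)
}

# censored-normal mixture density evaluated on the quadrature grid, plus
# boundary masses, integrated against Binom(kA | nA, p); vectorized over a
# vector of (pB, c) pairs sharing omega.
snp_lik_on_grid <- function(kA, nA, pB, cc, omega, p, dx) {
  sd <- sqrt(omega * pB * (1 - pB))
  m1 <- (1 - cc) + cc * pB  # component tracking the swept (derived) class
  m2 <- cc * pB             # component tracking the escaped class
  dens <- pB * dnorm(p, m1, sd) + (1 - pB) * dnorm(p, m2, sd)
  mass0 <- pB * pnorm(0, m1, sd) + (1 - pB) * pnorm(0, m2, sd)
  mass1 <- pB * pnorm(1, m1, sd, lower.tail = FALSE) +
    (1 - pB) * pnorm(1, m2, sd, lower.tail = FALSE)
  sum(dbinom(kA, nA, p) * dens) * dx +
    mass0 * (kA == 0) + mass1 * (kA == nA)
}

#' Windowed XP-CLR-style composite likelihood ratio scan
#'
#' For each window, SNPs polymorphic in population B are thinned to at most
#' `max_snps` (seeded uniform random), LD-down-weighted, and scored under a
#' grid of candidate sweep sites (every `site_grid_step` bp within the
#' window) and selection strengths `s_grid`. The window score is
#' `2 * (best sweep composite log-likelihood - neutral composite
#' log-likelihood)`, floored at 0 because the neutral model is included in
#' the candidate set. Windows without usable SNPs are masked (`NA` score).
#'
#' @param hapA,hapB test and reference [haplotype_matrix()] objects on a
#'   shared grid.
#' @param chrom_length chromosome length in bp (defines the window tiling).
#' @param config an [xpclr_config()].
#' @return data.frame with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open), `score`, `arg_site`, `arg_s`, `n_snps_used`,
#'   `weights_sum`.
#' @export
xpclr_scan <- function(hapA, hapB, chrom_length, config = xpclr_config()) {
  check_shared_grid(hapA, hapB)
  pos <- hapA$positions
  freqA <- colMeans(hapA$alleles)
  freqB <- colMeans(hapB$alleles)
  omega <- estimate_omega(freqA, freqB)
  nA <- n_haplotypes(hapA)
  kA_all <- as.integer(round(freqA * nA))

  wins <- make_windows(stats::setNames(chrom_length, hapA$chrom),
                       size = config$window_bp)
  q <- quad_grid(config$quadrature_points)

  out <- wins
  out$score <- NA_real_
  out$arg_site <- NA_real_
  out$arg_s <- NA_real_
  out$n_snps_used <- 0L
  out$weights_sum <- NA_real_

  withr::with_seed(config$seed, {
    for (w in seq_len(nrow(wins))) {
      in_w <- which(pos - 1L >= wins$start[w] & pos - 1L < wins$end[w] &
                      freqB > 0 & freqB < 1)
      if (!length(in_w)) next
      if (length(in_w) > config$max_snps)
        in_w <- sort(sample(in_w, config$max_snps))
      wts <- ld_weights(hapB$alleles[, in_w, drop = FALSE],
                        config$ld_corr_threshold)

      pB <- freqB[in_w]
      kA <- kA_all[in_w]
      sdv <- sqrt(omega * pB * (1 - pB))
      # binomial kernel on the grid, one row per SNP
      B <- outer(seq_along(in_w), q$p,
                 function(i, p) dbinom(kA[i], nA, p))

      comp_loglik <- function(cc) {
        m1 <- (1 - cc) + cc * pB
        m2 <- cc * pB
        D <- pB * dnorm_rows(q$p, m1, sdv) +
          (1 - pB) * dnorm_rows(q$p, m2, sdv)
        mass0 <- pB * pnorm(0, m1, sdv) + (1 - pB) * pnorm(0, m2, sdv)
        mass1 <- pB * pnorm(1, m1, sdv, lower.tail = FALSE) +
          (1 - pB) * pnorm(1, m2, sdv, lower.tail = FALSE)
        lik <- rowSums(B * D) * q$dx +
          mass0 * (kA == 0L) + mass1 * (kA == nA)
        sum(wts * log(pmax(lik, 1e-300)))
      }

      ll_neutral <- comp_loglik(rep(1, length(in_w)))
      sites <- seq(wins$start[w] + config$site_grid_step / 2,
                   wins$end[w], by = config$site_grid_step)
      best <- ll_neutral; b_site <- NA_real_; b_s <- NA_real_
      for (site in sites) {
        rr <- abs(pos[in_w] - site) * config$recomb_rate
        for (s in config$s_grid) {
          ll <- comp_loglik(sweep_escape_prob(rr, s, config$two_N))
          if (ll > best) { best <- ll; b_site <- site; b_s <- s }
        }
      }
      out$score[w] <- 2 * (best - ll_neutral)
      out$arg_site[w] <- b_site
      out$arg_s[w] <- b_s
      out$n_snps_used[w] <- length(in_w)
      out$weights_sum[w] <- sum(wts)
    }
  })
  out
}

# dnorm of each grid value against per-row (mean, sd): returns SNP x grid
dnorm_rows <- function(p, mean, sd) {
  z <- (matrix(p, nrow = length(mean), ncol = length(p), byrow = TRUE) -
          mean) / sd
  exp(-0.5 * z * z) / (sd * sqrt(2 * pi))
}

#' Designate the top fraction of window scores as candidate sweeps
#'
#' Windows whose score lies strictly above the empirical
#' `(1 - fraction)` quantile (inverse-ECDF definition) are designated;
#' with all-equal scores nothing is designated.
#'
#' @param scores data.frame of window scores (from [xpclr_scan()]) with a
#'   `score` column, or a bare numeric vector.
#' @param fraction upper tail fraction (default 0.01, the top 1 percent).
#' @return A list with `regions` (the designated rows, or indices when a
#'   vector was given), `threshold` (the realized score cutoff) and
#'   `n_designated`.
#' @export
top_fraction <- function(scores, fraction = 0.01) {
  vec <- if (is.data.frame(scores)) scores$score else scores
  ok <- which(is.finite(vec))
  if (!length(ok)) stop("no defined scores")
  thr <- as.numeric(quantile(vec[ok], probs = 1 - fraction))
  sel <- ok[vec[ok] > thr]
  regions <- if (is.data.frame(scores)) {
    r <- scores[sel, , drop = FALSE]; rownames(r) <- NULL; r
  } else sel
  list(regions = regions, threshold = thr, n_designated = length(sel))
}
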