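#' Per-SNP minor allele frequencies
#'
#' The folded frequency `min(f, 1 - f)` of the alternate allele fraction
#' `f` at each SNP column.
#'
#' @param hap a [haplotype_matrix()].
#' @return Numeric vector of MAF values in \[0, 0.5\].
#' @export
minor_allele_freqs <- function(hap) {
  if (n_haplotypes(hap) < 2L) stop("need at least 2 haplotypes")
  f <- colMeans(hap$alleles)
  pmin(f, 1 - f)
}

#' Sliding-window proportion of low-frequency SNPs
#'
#' Within overlapping windows (100 kb advancing every 20 kb by default),
#' the fraction of SNPs with MAF below `threshold` summarizes the local
#' excess of rare alleles, a hallmark of a recent sweep. Windows with
#' fewer than `min_snps` SNPs are masked.
#'
#' @param positions 1-based sorted SNP positions.
#' @param maf per-SNP minor allele frequencies (from
#'   [minor_allele_freqs()]).
#' @param chrom_length chromosome length in bp; defaults to the last SNP
#'   position.
#' @param window,step window size and step in bp.
#' @param threshold MAF below which a SNP counts as low-frequency.
#' @param min_snps minimum SNPs for an unmasked window.
#' @param chrom chromosome label for the output.
#' @return data.frame per window: `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `prop_low`, `masked`.
#' @export
maf_window_scan <- function(positions, maf, chrom_length = NULL,
                            window = 100000, step = 20000, threshold = 0.10,
                            min_snps = 10L, chrom = "1") {
  stopifnot(length(positions) == length(maf))
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (is.null(chrom_length)) chrom_length <- max(positions)
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  p0 <- positions - 1L
  low <- maf < threshold
  n_snps <- integer(length(starts))
  prop_low <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    in_w <- p0 >= starts[i] & p0 < starts[i] + window
    n_snps[i] <- sum(in_w)
    if (n_snps[i] >= min_snps) prop_low[i] <- mean(low[in_w])
  }
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(pmin(starts + window, chrom_length)),
             n_snps = n_snps, prop_low = prop_low,
             masked = n_snps < min_snps, stringsAsFactors = FALSE)
}

# Tajima's D constants for sample size n (haplotypes)
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for one haplotype window
#'
#' The normalized difference between the mean pairwise diversity `pi` and
#' the Watterson estimate `S / a1`, using the standard variance constants
#' for sample size n. Monomorphic windows (S = 0) are masked.
#'
#' @param alleles 0/1 haplotype matrix restricted to the window's columns
#'   (haplotypes x SNPs), or a [haplotype_matrix()].
#' @return A list with `n`, `S`, `pi` and `D` (`NA` when S = 0).
#' @export
tajimas_d <- function(alleles) {
  if (inherits(alleles, "haplotype_matrix")) alleles <- alleles$alleles
  n <- nrow(alleles)
  if (n < 2L) stop("need at least 2 haplotypes")
  k <- colSums(alleles)
  seg <- k > 0L & k < n
  S <- sum(seg)
  if (S == 0L) return(list(n = n, S = 0L, pi = 0, D = NA_real_))
  pi <- sum(2 * k[seg] * (n - k[seg])) / (n * (n - 1))
  cst <- tajima_constants(n)
  D <- (pi - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  list(n = n, S = S, pi = pi, D = D)
}

#' Windowed Tajima's D scan with optional coalescent significance
#'
#' Computes Tajima's D in non-overlapping windows (50 kb by default) and,
#' when `null_reps > 0`, a per-window lower-tail P-value
#' `P(D_simul < D_obs)` against the fixed-S neutral coalescent null of
#' [coalescent_null()].
#'
#' @param hap a [haplotype_matrix()].
#' @param chrom_length chromosome length in bp.
#' @param window window size in bp.
#' @param null_reps coalescent replicates per window (0 = no P-values).
#' @param seed RNG seed for the null simulations.
#' @param alpha significance level on the lower-tail P-value.
#' @return data.frame per window: `chrom`, `start`, `end`, `n`, `S`, `pi`,
#'   `D`, and with P-values `p_value` and `significant`.
#' @export
tajima_scan <- function(hap, chrom_length, window = 50000, null_reps = 0L,
                        seed = 1L, alpha = 0.05) {
  wins <- make_windows(stats::setNames(chrom_length, hap$chrom), size = window)
  p0 <- hap$positions - 1L
  n <- n_haplotypes(hap)
  out <- wins
  out$n <- n
  out$S <- 0L
  out$pi <- 0
  out$D <- NA_real_
  for (w in seq_len(nrow(wins))) {
    cols <- which(p0 >= wins$start[w] & p0 < wins$end[w])
    if (!length(cols)) next
    td <- tajimas_d(hap$alleles[, cols, drop = FALSE])
    out$S[w] <- td$S
    out$pi[w] <- td$pi
    out$D[w] <- td$D
  }
  if (null_reps > 0L) {
    out$p_value <- NA_real_
    withr::with_seed(seed, {
      for (w in seq_len(nrow(out))) {
        if (is.na(out$D[w])) next
        null <- tajima_null_cpp(n, out$S[w], as.integer(null_reps))
        out$p_value[w] <- d_pvalue(out$D[w], null)
      }
    })
    out$significant <- out$p_value < alpha
  }
  out
}

#' Neutral coalescent null distribution of Tajima's D
#'
#' Simulates `reps` standard neutral Kingman genealogies for `n` samples
#' (coalescence at rate C(k, 2); the time scale cancels) and places exactly
#' `S` mutations on branches with probability proportional to branch
#' length (fixed-S conditioning), returning the simulated D values.
#'
#' @param n sample size (haplotypes).
#' @param S observed number of segregating sites (>= 1).
#' @param reps number of replicates (default 10000).
#' @param seed optional RNG seed.
#' @return Numeric vector of `reps` simulated D values.
#' @export
coalescent_null <- function(n, S, reps = 10000L, seed = NULL) {
  run <- function() tajima_null_cpp(as.integer(n), as.integer(S),
                                    as.integer(reps))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Lower-tail empirical P-value of an observed Tajima's D
#'
#' `p = #\{D_sim < D_obs\} / reps`; small values flag an excess of rare
#' variants relative to the neutral null.
#'
#' @param D_obs observed D.
#' @param null simulated null distribution from [coalescent_null()].
#' @return The empirical P-value in \[0, 1\].
#' @export
d_pvalue <- function(D_obs, null) {
  if (!length(null)) stop("null distribution is empty")
  mean(null < D_obs)
}
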