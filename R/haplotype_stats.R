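#' Extended haplotype homozygosity between a core SNP and a target SNP
#'
#' EHH over the inclusive column span from `core` to `target` is the
#' probability that two haplotypes drawn without replacement are identical
#' over that span: `sum_g C(n_g, 2) / C(n, 2)` for haplotype-identity
#' groups g. The statistic is allele-agnostic (all chromosomes, no
#' partitioning on the core allele); at `target == core` the span is the
#' empty extension and EHH is 1 by convention.
#'
#' @param hap a [haplotype_matrix()].
#' @param core,target SNP column indices (1-based).
#' @return EHH value in \[0, 1\].
#' @export
ehh_at <- function(hap, core, target) {
  m <- ncol(hap$alleles)
  if (core < 1L || core > m || target < 1L || target > m)
    stop("core/target out of range")
  if (n_haplotypes(hap) < 2L) stop("EHH needs at least 2 haplotypes")
  if (target == core) return(1)
  targets <- if (target > core) (core + 1L):target else (core - 1L):target
  prof <- ehh_profile_cpp(hap$alleles, core - 1L, targets - 1L)
  prof[length(prof)]
}

#' EHH profile outward from a core SNP
#'
#' @param hap a [haplotype_matrix()] (or a pooled matrix from
#'   [pool_haplotypes()]).
#' @param core core SNP column (1-based).
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param max_dist maximum distance from the core in bp (default 1 Mb).
#' @return data.frame with columns `index` (SNP column), `pos` and `ehh`,
#'   starting at the core (ehh = 1) and extending outward. Zero further
#'   rows when no SNP lies within `max_dist` in that direction.
#' @export
ehh_profile <- function(hap, core, direction = c("downstream", "upstream"),
                        max_dist = 1e6) {
  direction <- match.arg(direction)
  pos <- hap$positions
  m <- length(pos)
  if (core < 1L || core > m) stop("core out of range")
  idx <- if (direction == "downstream") {
    which(seq_len(m) > core & pos - pos[core] <= max_dist)
  } else {
    rev(which(seq_len(m) < core & pos[core] - pos <= max_dist))
  }
  if (!length(idx))
    return(data.frame(index = core, pos = pos[core], ehh = 1))
  prof <- ehh_profile_cpp(hap$alleles, core - 1L, idx - 1L)
  data.frame(index = c(core, idx), pos = pos[c(core, idx)],
             ehh = c(1, prof))
}

#' Pool the haplotypes of two populations on a shared variant grid
#'
#' @param hapA,hapB [haplotype_matrix()] objects with identical positions.
#' @return A [haplotype_matrix()] holding all chromosomes of both
#'   populations, labelled `"pooled"`.
#' @export
pool_haplotypes <- function(hapA, hapB) {
  check_shared_grid(hapA, hapB)
  haplotype_matrix(rbind(hapA$alleles, hapB$alleles), hapA$positions,
                   chrom = hapA$chrom,
                   sample_ids = c(hapA$sample_ids, hapB$sample_ids),
                   population = "pooled")
}

#' Boundary SNP for XP-EHH integration
#'
#' Finds the SNP X, within `max_dist` of the core in the given direction,
#' whose EHH computed on the pooled chromosomes of both populations is
#' closest to `ehh_target` (default 0.04). Ties are broken toward the
#' farther SNP, which gives the longer integration support.
#'
#' @param hapA,hapB [haplotype_matrix()] objects on a shared grid.
#' @param core core SNP column (1-based).
#' @param direction `"downstream"` or `"upstream"`.
#' @param max_dist search radius in bp (default 1 Mb).
#' @param ehh_target pooled EHH level defining the boundary.
#' @return The boundary SNP column index, or `NA_integer_` when no SNP lies
#'   within `max_dist` in that direction.
#' @export
find_boundary_snp <- function(hapA, hapB, core,
                              direction = c("downstream", "upstream"),
                              max_dist = 1e6, ehh_target = 0.04) {
  direction <- match.arg(direction)
  pooled <- pool_haplotypes(hapA, hapB)
  prof <- ehh_profile(pooled, core, direction, max_dist)
  if (nrow(prof) < 2L) return(NA_integer_)
  prof <- prof[-1L, , drop = FALSE]  # candidates exclude the core itself
  d <- abs(prof$ehh - ehh_target)
  best <- which(d == min(d))
  prof$index[best[length(best)]]  # rows are ordered outward; last = farthest
}

#' Integrated EHH from a core SNP to a boundary SNP
#'
#' Trapezoidal integral of the population's EHH profile against physical
#' position (bp) over the span from the core (where EHH is 1) to the
#' boundary SNP X.
#'
#' @param hap a [haplotype_matrix()].
#' @param core core SNP column.
#' @param X boundary SNP column (from [find_boundary_snp()]).
#' @return Integrated EHH area in bp units; strictly positive.
#' @export
integrated_ehh <- function(hap, core, X) {
  if (is.na(X) || X == core) stop("boundary SNP must differ from the core")
  targets <- if (X > core) (core + 1L):X else (core - 1L):X
  prof <- ehh_profile_cpp(hap$alleles, core - 1L, targets - 1L)
  x <- hap$positions[c(core, targets)]
  abs(pracma::trapz(as.numeric(x), c(1, prof)))
}

#' Raw XP-EHH score at a core SNP
#'
#' Determines the boundary SNP in each direction on the pooled haplotypes,
#' integrates EHH over the identical intervals in each population, sums the
#' two directions, and returns `ln(I_A / I_B)`. A positive score means
#' longer haplotypes (slower EHH decay) in population A, the test
#' population. If only one direction has a boundary the score uses that
#' direction alone and is flagged `one_sided`.
#'
#' @param hapA test-population [haplotype_matrix()].
#' @param hapB reference-population [haplotype_matrix()] on the same grid.
#' @param core core SNP column.
#' @param max_dist boundary search radius in bp.
#' @param ehh_target pooled EHH level defining the boundary.
#' @return A list with `raw` (the log-ratio, `NA` when no direction has a
#'   boundary), `I_A`, `I_B`, `boundary_down`, `boundary_up` (SNP columns,
#'   `NA` when undefined) and `one_sided`.
#' @export
xpehh_raw <- function(hapA, hapB, core, max_dist = 1e6, ehh_target = 0.04) {
  check_shared_grid(hapA, hapB)
  pooled <- rbind(hapA$alleles, hapB$alleles)
  xpehh_core_stat(hapA$alleles, hapB$alleles, pooled, hapA$positions,
                  core, max_dist, ehh_target)
}

# internal workhorse shared by xpehh_raw and xpehh_scan: boundary search on
# the pooled chromosomes, then trapezoidal integration of each population's
# EHH profile over the identical intervals.
xpehh_core_stat <- function(A, B, pooled, pos, core, max_dist, ehh_target) {
  m <- length(pos)
  bnd <- c(downstream = NA_integer_, upstream = NA_integer_)
  spans <- list(downstream = NULL, upstream = NULL)
  for (dir in c("downstream", "upstream")) {
    idx <- if (dir == "downstream") {
      which(seq_len(m) > core & pos - pos[core] <= max_dist)
    } else {
      rev(which(seq_len(m) < core & pos[core] - pos <= max_dist))
    }
    if (!length(idx)) next
    prof <- ehh_profile_cpp(pooled, core - 1L, idx - 1L)
    d <- abs(prof - ehh_target)
    best <- which(d == min(d))
    k <- best[length(best)]  # tie -> farther SNP
    bnd[[dir]] <- idx[k]
    spans[[dir]] <- idx[seq_len(k)]
  }
  I_A <- 0; I_B <- 0
  for (dir in c("downstream", "upstream")) {
    sp <- spans[[dir]]
    if (is.null(sp)) next
    x <- as.numeric(pos[c(core, sp)])
    I_A <- I_A + abs(pracma::trapz(x, c(1, ehh_profile_cpp(A, core - 1L, sp - 1L))))
    I_B <- I_B + abs(pracma::trapz(x, c(1, ehh_profile_cpp(B, core - 1L, sp - 1L))))
  }
  n_dir <- sum(!is.na(bnd))
  raw <- if (n_dir == 0L) NA_real_ else {
    if (I_B <= 0) stop("integrated EHH in population B is zero")
    log(I_A / I_B)
  }
  list(raw = raw, I_A = I_A, I_B = I_B,
       boundary_down = bnd[["downstream"]], boundary_up = bnd[["upstream"]],
       one_sided = n_dir == 1L)
}

#' Standardize genome-wide scores to mean 0, variance 1
#'
#' Uses the population variance (divisor n) over all finite values; `NA`
#' entries are preserved in place.
#'
#' @param raw numeric vector of raw scores.
#' @return Standardized vector with mean 0 and variance 1 over its finite
#'   entries.
#' @export
standardize_scores <- function(raw) {
  ok <- is.finite(raw)
  if (sum(ok) < 2L) stop("need at least 2 finite scores")
  x <- raw[ok]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("scores are constant; cannot standardize")
  out <- rep(NA_real_, length(raw))
  out[ok] <- (x - m) / s
  out
}

#' Genome-wide XP-EHH scan
#'
#' Computes the raw XP-EHH log-ratio at every core SNP (or a subset) and
#' standardizes the scores to mean 0, variance 1. Cores whose boundary is
#' defined in only one direction are retained and flagged by default.
#'
#' @param hapA,hapB test and reference [haplotype_matrix()] objects.
#' @param cores SNP columns to use as cores (default: all).
#' @param max_dist boundary search radius in bp (default 1 Mb).
#' @param ehh_target pooled EHH boundary level (default 0.04).
#' @param drop_one_sided drop cores with a single-direction boundary
#'   instead of retaining them flagged.
#' @return data.frame with columns `chrom`, `pos`, `raw`, `std`,
#'   `one_sided`.
#' @export
xpehh_scan <- function(hapA, hapB, cores = NULL, max_dist = 1e6,
                       ehh_target = 0.04, drop_one_sided = FALSE) {
  check_shared_grid(hapA, hapB)
  if (is.null(cores)) cores <- seq_along(hapA$positions)
  pooled <- rbind(hapA$alleles, hapB$alleles)
  raw <- numeric(length(cores))
  one_sided <- logical(length(cores))
  for (i in seq_along(cores)) {
    r <- xpehh_core_stat(hapA$alleles, hapB$alleles, pooled, hapA$positions,
                         cores[i], max_dist, ehh_target)
    raw[i] <- r$raw
    one_sided[i] <- r$one_sided
  }
  out <- data.frame(chrom = hapA$chrom, pos = hapA$positions[cores],
                    raw = raw, one_sided = one_sided)
  if (drop_one_sided) out <- out[!out$one_sided, , drop = FALSE]
  out$std <- standardize_scores(out$raw)
  rownames(out) <- NULL
  out
}
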