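#' Pairwise linkage disequilibrium r-squared between two SNPs
#'
#' Computed from phased haplotype counts: `r2 = D^2 / (p(1-p) q(1-q))`
#' with `D = f11 - p q`, which equals the squared Pearson correlation of
#' the two 0/1 allele columns.
#'
#' @param hap a [haplotype_matrix()].
#' @param i,j SNP column indices.
#' @return r-squared in \[0, 1\], or `NA` when either column is
#'   monomorphic.
#' @export
pair_r2 <- function(hap, i, j) {
  x <- hap$alleles[, i]
  y <- hap$alleles[, j]
  p <- mean(x); q <- mean(y)
  if (p == 0 || p == 1 || q == 0 || q == 1) return(NA_real_)
  D <- mean(x * y) - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}

#' Distance-binned LD decay curve
#'
#' Computes r-squared for every pair of polymorphic SNPs separated by less
#' than `max_dist` bp and averages within left-closed right-open distance
#' bins of width `bin`.
#'
#' @param hap a [haplotype_matrix()].
#' @param max_dist maximum inter-SNP distance considered, exclusive
#'   (default 10 Mb).
#' @param bin distance bin width in bp (default 50 kb).
#' @param population label for the output (defaults to the matrix's own).
#' @return data.frame per occupied bin: `population`, `bin` (0-based
#'   index), `bin_start`, `bin_end`, `mean_r2`, `n_pairs`, ordered by
#'   distance.
#' @export
ld_decay <- function(hap, max_dist = 1e7, bin = 50000, population = NULL) {
  if (is.null(population)) population <- hap$population
  pos <- hap$positions
  poly <- which(apply(hap$alleles, 2L, function(x) {
    f <- mean(x); f > 0 && f < 1
  }))
  if (length(poly) < 2L) stop("need at least 2 polymorphic SNPs")
  a <- hap$alleles[, poly, drop = FALSE]
  p <- pos[poly]
  r2 <- suppressWarnings(stats::cor(a))^2
  m <- length(p)
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  dist <- p[ut[, 2L]] - p[ut[, 1L]]
  keep <- dist < max_dist
  dist <- dist[keep]
  vals <- r2[ut[keep, , drop = FALSE]]
  bins <- floor(dist / bin)
  agg_mean <- tapply(vals, bins, mean)
  agg_n <- tapply(vals, bins, length)
  b <- as.integer(names(agg_mean))
  out <- data.frame(population = population, bin = b,
                    bin_start = b * as.integer(bin),
                    bin_end = (b + 1L) * as.integer(bin),
                    mean_r2 = as.numeric(agg_mean),
                    n_pairs = as.integer(agg_n), stringsAsFactors = FALSE)
  out[order(out$bin), , drop = FALSE]
}
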