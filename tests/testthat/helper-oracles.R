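# Independent oracles used by the unit tests. These deliberately re-derive
# each quantity by a different route than the package implementation.

# EHH by exhaustive pairwise string comparison over the inclusive span
brute_ehh <- function(mat, core, target) {
  span <- min(core, target):max(core, target)
  strs <- apply(mat[, span, drop = FALSE], 1L, paste, collapse = "")
  n <- nrow(mat)
  npairs <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (strs[i] == strs[j]) npairs <- npairs + 1L
  npairs / choose(n, 2)
}

# Tajima's D re-derived from scratch: pi by explicit pair loop, constants
# written out independently
tajima_oracle <- function(mat) {
  n <- nrow(mat)
  k <- colSums(mat)
  seg <- which(k > 0L & k < n)
  S <- length(seg)
  if (S == 0L) return(NA_real_)
  diffs <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      diffs <- diffs + sum(mat[i, seg] != mat[j, seg])
  pi <- diffs / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# quick haplotype_matrix builder with evenly spaced positions
hm <- function(mat, spacing = 1000L, chrom = "1", population = "A") {
  haplotype_matrix(mat, positions = spacing * seq_len(ncol(mat)),
                   chrom = chrom, population = population)
}

# small deterministic random 0/1 matrix
rand_mat <- function(nrow, ncol, p = 0.5) {
  matrix(rbinom(nrow * ncol, 1L, p), nrow, ncol)
}
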