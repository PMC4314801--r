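#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param size window size in bp (default 50 kb).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `partial` (flagging a shorter terminal tile).
#' @export
make_windows <- function(chrom_lengths, size = 50000) {
  stopifnot(all(chrom_lengths > 0), size > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  res <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
               partial = ends - starts < size, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-window maximum of a per-SNP statistic
#'
#' Assigns each scored SNP to its window by the half-open convention
#' (1-based SNP position p lies in the window with `start <= p - 1 < end`)
#' and records the per-window SNP count and maximum statistic. Windows
#' without SNPs are masked (`NA` max, excluded from later binning).
#'
#' @param scores data.frame with columns `chrom`, `pos` (1-based) and the
#'   statistic named by `stat_col` (default `"std"`).
#' @param windows window tiling from [make_windows()].
#' @param stat_col name of the statistic column in `scores`.
#' @param drop_partial drop flagged partial terminal windows.
#' @return The windows data.frame extended with `n_snps` and `max_stat`.
#' @export
window_max_stat <- function(scores, windows, stat_col = "std",
                            drop_partial = FALSE) {
  stopifnot(all(c("chrom", "pos", stat_col) %in% names(scores)))
  out <- windows
  if (drop_partial) out <- out[!out$partial, , drop = FALSE]
  out$n_snps <- 0L
  out$max_stat <- NA_real_
  for (ch in unique(out$chrom)) {
    sc <- scores[scores$chrom == ch & is.finite(scores[[stat_col]]), ,
                 drop = FALSE]
    wi <- which(out$chrom == ch)
    if (!nrow(sc)) next
    p0 <- sc$pos - 1L
    for (w in wi) {
      in_w <- p0 >= out$start[w] & p0 < out$end[w]
      n <- sum(in_w)
      out$n_snps[w] <- n
      if (n > 0L) out$max_stat[w] <- max(sc[[stat_col]][in_w])
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign SNP-count bins to scored windows
#'
#' Windows are binned by their SNP counts in increments of `increment`
#' SNPs, with all windows holding more than `cap` SNPs combined into one
#' top bin (defaults: bins 1-200, 201-400, 401-600, >600). Masked windows
#' (no SNPs) receive `NA`.
#'
#' @param table window table from [window_max_stat()].
#' @param increment bin width in SNPs.
#' @param cap SNP count above which windows share the top bin.
#' @return The table with a `bin_id` column.
#' @export
assign_bins <- function(table, increment = 200, cap = 600) {
  stopifnot(cap %% increment == 0)
  bin <- ceiling(table$n_snps / increment)
  bin <- pmin(bin, cap / increment + 1)
  bin[table$n_snps < 1L | !is.finite(table$max_stat)] <- NA_integer_
  table$bin_id <- as.integer(bin)
  table
}

#' Within-bin empirical P-values and significance calls
#'
#' Within each SNP-count bin, a window's empirical P-value is the fraction
#' of windows in that bin with a strictly greater statistic; windows with
#' `empirical_p < pcut` are flagged significant. Equal-maximum windows
#' share the same P-value.
#'
#' @param table binned window table from [assign_bins()].
#' @param pcut significance cutoff on the empirical P-value (default 0.01).
#' @param min_bin_size warn when an occupied bin holds fewer windows than
#'   this.
#' @return The table with `empirical_p` and `significant` columns (both
#'   `NA` for masked windows).
#' @export
empirical_pvalues <- function(table, pcut = 0.01, min_bin_size = 1L) {
  table$empirical_p <- NA_real_
  table$significant <- NA
  for (b in unique(table$bin_id[!is.na(table$bin_id)])) {
    idx <- which(table$bin_id == b)
    M <- length(idx)
    if (M < min_bin_size)
      warning("bin ", b, " holds only ", M, " window(s)")
    x <- table$max_stat[idx]
    # fraction strictly greater = (M - max-tie rank) / M
    table$empirical_p[idx] <- (M - rank(x, ties.method = "max")) / M
  }
  table$significant <- table$empirical_p < pcut
  table
}

#' Annotate significant windows with overlapping genes
#'
#' A gene is a candidate when its interval overlaps any significant window
#' by at least 1 bp (half-open overlap), i.e. genes spanning a window
#' partially or completely are both included.
#'
#' @param regions data.frame of significant windows with columns `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param genes a `gene_set` from [read_genes()].
#' @param method label for the resulting candidate set.
#' @return A `candidate_gene_set`: list with `method`, `gene_ids` and
#'   `support` (one row per gene-window overlap).
#' @export
annotate_genes <- function(regions, genes, method = "scan") {
  if (nrow(regions) == 0L) {
    return(structure(list(method = method, gene_ids = character(0),
                          support = data.frame()),
                     class = "candidate_gene_set"))
  }
  gr_w <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(start = regions$start + 1L,
                                    end = regions$end))
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  ov <- GenomicRanges::findOverlaps(gr_g, gr_w)
  gi <- S4Vectors::queryHits(ov)
  wi <- S4Vectors::subjectHits(ov)
  support <- data.frame(gene_id = genes$gene_id[gi],
                        chrom = genes$chrom[gi],
                        gene_start = genes$start[gi],
                        gene_end = genes$end[gi],
                        window_start = regions$start[wi],
                        window_end = regions$end[wi],
                        stringsAsFactors = FALSE)
  if ("max_stat" %in% names(regions)) support$max_stat <- regions$max_stat[wi]
  if ("score" %in% names(regions)) support$score <- regions$score[wi]
  structure(list(method = method, gene_ids = unique(support$gene_id),
                 support = support),
            class = "candidate_gene_set")
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat("candidate_gene_set [", x$method, "]: ", length(x$gene_ids),
      " gene(s)\n", sep = "")
  invisible(x)
}

#' Combine candidate gene sets from two scan methods
#'
#' @param setA,setB `candidate_gene_set` objects (or bare character
#'   vectors of gene ids).
#' @return A list reporting `n_A`, `n_B`, `n_intersection`, `n_union` and
#'   the corresponding member vectors.
#' @export
combine_candidates <- function(setA, setB) {
  ids <- function(s) if (inherits(s, "candidate_gene_set")) s$gene_ids else
    unique(as.character(s))
  a <- ids(setA); b <- ids(setB)
  list(n_A = length(a), n_B = length(b),
       n_intersection = length(intersect(a, b)),
       n_union = length(union(a, b)),
       intersection = intersect(a, b), union = union(a, b),
       only_A = setdiff(a, b), only_B = setdiff(b, a))
}
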