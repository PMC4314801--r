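#' Phased haplotype matrix for one population on one chromosome
#'
#' The substrate of every haplotype statistic in the package: a matrix of
#' 0/1 alleles with haplotypes in rows (two consecutive rows per diploid
#' sample) and SNPs in columns, ordered by strictly increasing 1-based
#' physical position.
#'
#' @param alleles integer matrix of 0/1 values, haplotypes x SNPs.
#' @param positions integer vector of 1-based bp positions, strictly
#'   increasing, one per column.
#' @param chrom single chromosome identifier.
#' @param sample_ids character vector of diploid sample names, one per pair
#'   of rows (recycled to two rows each), or `NULL` for anonymous samples.
#' @param population population label.
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `alleles`, `positions`, `chrom`, `sample_ids` (per haplotype row) and
#'   `population`.
#' @export
haplotype_matrix <- function(alleles, positions, chrom,
                             sample_ids = NULL, population = NA_character_) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 2L || nrow(alleles) %% 2L != 0L)
    stop("haplotype row count must be even and >= 2 (two rows per diploid)")
  if (ncol(alleles) != length(positions))
    stop("column count (", ncol(alleles), ") must equal number of positions (",
         length(positions), ")")
  if (length(positions) > 0L) {
    positions <- as.integer(positions)
    if (anyNA(positions) || any(diff(positions) <= 0L))
      stop("positions must be strictly increasing without NA")
    bad <- !(alleles %in% c(0L, 1L))
    if (any(bad)) stop("alleles must be 0/1; found other values")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(alleles) / 2L))
  }
  if (length(sample_ids) == nrow(alleles) / 2L)
    sample_ids <- rep(sample_ids, each = 2L)
  if (length(sample_ids) != nrow(alleles))
    stop("sample_ids must name each diploid (n/2) or each haplotype row (n)")
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom)[1L],
                 sample_ids = as.character(sample_ids),
                 population = as.character(population)[1L]),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix: ", nrow(x$alleles), " haplotypes (",
      nrow(x$alleles) / 2L, " diploids) x ", ncol(x$alleles),
      " SNPs on chrom ", x$chrom, "\n", sep = "")
  cat("  population: ", x$population, "\n", sep = "")
  if (length(x$positions))
    cat("  positions: ", x$positions[1L], " .. ",
        x$positions[length(x$positions)], " bp\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Number of haplotypes
#' @param hap a [haplotype_matrix()].
#' @return Integer row count.
#' @export
n_haplotypes <- function(hap) nrow(hap$alleles)

#' Per-site variant annotation table
#'
#' Site-level records carrying the fields consumed by the hard-filtering
#' rules: phred-scaled site quality (`qual`), the count of mapping-quality
#' zero reads (`mq0`), quality by depth (`qd`) and the phred-scaled strand
#' bias score (`fs`). Annotation fields may be `NA` when absent from the
#' source VCF.
#'
#' @param chrom,pos,ref,alt,qual,mq0,qd,fs per-record vectors; `pos` is
#'   1-based and must be strictly increasing within each chromosome, `ref`
#'   and `alt` single alleles, `qual >= 0` where non-missing.
#' @return A `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, qual = NA_real_,
                          mq0 = NA_real_, qd = NA_real_, fs = NA_real_) {
  vt <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   qual = as.numeric(qual), mq0 = as.numeric(mq0),
                   qd = as.numeric(qd), fs = as.numeric(fs),
                   stringsAsFactors = FALSE)
  if (any(grepl(",", vt$alt, fixed = TRUE)))
    stop("exactly one alt allele per record")
  if (any(!is.na(vt$qual) & vt$qual < 0)) stop("qual must be >= 0")
  for (ch in unique(vt$chrom)) {
    p <- vt$pos[vt$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("pos must be strictly increasing within chrom ", ch)
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

# internal: validate two haplotype matrices share one variant grid
check_shared_grid <- function(hapA, hapB) {
  if (!identical(hapA$positions, hapB$positions) ||
      !identical(hapA$chrom, hapB$chrom))
    stop("haplotype matrices must share chromosome and SNP positions")
  invisible(TRUE)
}
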