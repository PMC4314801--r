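#' Read a phased two-population VCF into haplotype matrices
#'
#' Parses a phased, biallelic-SNP VCF (via \pkg{vcfR}) and splits the
#' genotype columns into one [haplotype_matrix()] per population according
#' to a sample-to-population map. Records that are not biallelic SNPs are
#' skipped with a reported count. Genotypes must be phased (`|` separator)
#' and complete: the pipeline contract is a post-imputation, post-phasing
#' call set, so unphased or missing genotypes are errors, not data.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample_map data.frame with columns `sample` and `population`, or
#'   the path of a two-column whitespace-separated text file.
#' @param region optional `"chrom:start-end"` string (1-based inclusive)
#'   restricting the records read.
#' @return A list with elements `variants` (a [variant_table()]),
#'   `haplotypes` (named list of [haplotype_matrix()], one per population)
#'   and `n_skipped` (non-biallelic-SNP records dropped).
#' @export
read_vcf <- function(path, sample_map, region = NULL) {
  sample_map <- read_sample_map(sample_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records")

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")

  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- keep & chrom == rg$chrom & pos >= rg$start & pos <= rg$end
  }
  if (!any(keep)) stop("no biallelic SNP records retained")

  chroms <- unique(chrom[keep])
  if (length(chroms) > 1L)
    stop("VCF spans multiple chromosomes (", paste(chroms, collapse = ", "),
         "); read one chromosome at a time with region=")

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info_num <- function(tag) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = tag,
                                             as.numeric = TRUE))
    if (is.null(v)) rep(NA_real_, nrow(fix)) else as.numeric(v)
  }
  vt <- variant_table(chrom = chrom[keep], pos = pos[keep],
                      ref = ref[keep], alt = alt[keep],
                      qual = qual[keep], mq0 = info_num("MQ0")[keep],
                      qd = info_num("QD")[keep], fs = info_num("FS")[keep])

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  vcf_samples <- colnames(gt)
  missing_in_map <- setdiff(vcf_samples, sample_map$sample)
  if (length(missing_in_map))
    stop("VCF sample(s) missing from the sample map: ",
         paste(missing_in_map, collapse = ", "))
  missing_in_vcf <- setdiff(sample_map$sample, vcf_samples)
  if (length(missing_in_vcf))
    stop("sample map sample(s) missing from the VCF: ",
         paste(missing_in_vcf, collapse = ", "))

  bad <- which(matrix(is.na(gt) | gt %in% c(".", "./.", ".|."), nrow(gt)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing genotype at ", vt$chrom[bad[1L, 1L]], ":",
         vt$pos[bad[1L, 1L]], " sample ", vcf_samples[bad[1L, 2L]],
         "; input must be fully imputed and phased")
  unph <- which(matrix(grepl("/", gt, fixed = TRUE), nrow(gt)),
                arr.ind = TRUE)
  if (nrow(unph) > 0L)
    stop("unphased genotype at ", vt$chrom[unph[1L, 1L]], ":",
         vt$pos[unph[1L, 1L]], " sample ", vcf_samples[unph[1L, 2L]],
         "; phase the VCF before scanning")

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (any(!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))))
    stop("genotype alleles must be 0 or 1 for biallelic records")

  haps <- vector("list", 0L)
  for (p in unique(sample_map$population)) {
    sm <- sample_map$sample[sample_map$population == p]
    n_hap <- 2L * length(sm)
    mat <- matrix(0L, nrow = n_hap, ncol = nrow(vt))
    for (i in seq_along(sm)) {
      mat[2L * i - 1L, ] <- as.integer(a1[, sm[i]])
      mat[2L * i, ] <- as.integer(a2[, sm[i]])
    }
    haps[[p]] <- haplotype_matrix(mat, vt$pos, chrom = vt$chrom[1L],
                                  sample_ids = sm, population = p)
  }
  list(variants = vt, haplotypes = haps, n_skipped = n_skipped)
}

read_sample_map <- function(sample_map) {
  if (is.character(sample_map) && length(sample_map) == 1L) {
    sample_map <- read.table(sample_map, header = FALSE,
                             col.names = c("sample", "population"),
                             stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sample_map) ||
      !all(c("sample", "population") %in% names(sample_map)))
    stop("sample_map must have columns 'sample' and 'population'")
  if (anyDuplicated(sample_map$sample))
    stop("duplicated sample in sample map")
  sample_map
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end'")
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

#' Apply GATK-style hard filters to a variant table
#'
#' A record fails when `qual < qual_min`, when `mq0 > mq0_max` **and**
#' `qd < qd_min` jointly (the conjunctive mapping-quality-zero rule), or
#' when `fs > fs_max`. Comparisons are strict, so records sitting exactly
#' on a threshold pass. A missing annotation never triggers its rule
#' (conservative retention, matching the conjunctive semantics of the
#' upstream caller); one warning is emitted if any required field is
#' missing anywhere.
#'
#' @param vt a [variant_table()].
#' @param qual_min,mq0_max,qd_min,fs_max filter thresholds; the defaults are
#'   the standard hard-filter set (QUAL 30, MQ0 4 with QD 5, FS 200).
#' @return A list with `pass` (the retained [variant_table()]), `report`
#'   (named counts of records failing each rule independently, plus totals)
#'   and `status` (per input record: `"PASS"` or semicolon-joined reasons).
#' @export
apply_hard_filters <- function(vt, qual_min = 30, mq0_max = 4,
                               qd_min = 5, fs_max = 200) {
  stopifnot(is.data.frame(vt))
  cmp <- function(x, test) ifelse(is.na(x), FALSE, test(x))
  if (anyNA(vt$qual) || anyNA(vt$mq0) || anyNA(vt$qd) || anyNA(vt$fs))
    warning("missing filter annotation(s); affected rules treated as not triggered")
  r_qual <- cmp(vt$qual, function(x) x < qual_min)
  r_mq0qd <- cmp(vt$mq0, function(x) x > mq0_max) &
    cmp(vt$qd, function(x) x < qd_min)
  r_fs <- cmp(vt$fs, function(x) x > fs_max)
  fail <- r_qual | r_mq0qd | r_fs

  status <- rep("PASS", nrow(vt))
  reason <- function(flag, tag) ifelse(flag, tag, NA_character_)
  rs <- cbind(reason(r_qual, "LowQual"), reason(r_mq0qd, "MQ0QD"),
              reason(r_fs, "StrandBias"))
  status[fail] <- apply(rs[fail, , drop = FALSE], 1L,
                        function(x) paste(x[!is.na(x)], collapse = ";"))
  pass <- vt[!fail, , drop = FALSE]
  rownames(pass) <- NULL
  class(pass) <- class(vt)
  list(pass = pass,
       report = c(qual = sum(r_qual), mq0_qd = sum(r_mq0qd), fs = sum(r_fs),
                  removed = sum(fail), retained = sum(!fail)),
       status = status)
}

#' Thin a variant table to a random subset
#'
#' Draws a uniform random subset of records without replacement (the usual
#' pre-processing step before LD or population-structure analyses on dense
#' call sets) and returns it position-sorted. Deterministic under `seed`.
#'
#' @param vt a [variant_table()].
#' @param target subset size: a fraction in (0, 1] or an absolute count
#'   (> 1). A value of exactly 1 is read as the fraction 1.0 (identity).
#' @param seed integer RNG seed.
#' @return The thinned [variant_table()], sorted by (chrom, pos).
#' @export
thin_variants <- function(vt, target, seed) {
  n <- nrow(vt)
  k <- if (target <= 1) as.integer(round(target * n)) else as.integer(target)
  if (k > n) stop("target (", k, ") exceeds number of records (", n, ")")
  if (k < 1L) stop("target selects no records")
  idx <- withr::with_seed(seed, sort(sample.int(n, k)))
  out <- vt[idx, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(vt)
  out
}

#' Read gene intervals from a BED4 file
#'
#' BED input is 0-based half-open, which is also the package's internal
#' interval convention, so coordinates pass through unchanged.
#'
#' @param path path to a 4-column BED file (chrom, start, end, name).
#' @return A `gene_set` data.frame with columns `chrom`, `start`, `end`,
#'   `gene_id`, `strand`.
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) stop("BED file has no interval lines")
  fields <- strsplit(lines, "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop("malformed BED line ", i, ": expected >= 4 fields")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (s >= e)
      stop("malformed BED line ", i, ": start >= end")
  }
  gs <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    gene_id = vapply(fields, `[`, "", 4L),
    strand = vapply(fields, function(f)
      if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*", ""),
    stringsAsFactors = FALSE)
  if (anyDuplicated(gs$gene_id)) stop("gene_id values must be unique")
  class(gs) <- c("gene_set", "data.frame")
  gs
}

#' Write a phased VCF from a variant table and haplotype matrices
#'
#' Emits a minimal VCFv4.2 file whose genotype columns are the phased
#' diploids of the supplied haplotype matrices (populations concatenated in
#' list order). Round-trips through [read_vcf()] with identical positions,
#' alleles and population assignment.
#'
#' @param vt a [variant_table()] describing the sites.
#' @param haplotypes named list of [haplotype_matrix()] objects sharing the
#'   variant grid of `vt`.
#' @param path output file path.
#' @param chrom_length optional chromosome length for the contig header.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, haplotypes, path, chrom_length = NULL) {
  stopifnot(is.list(haplotypes), length(haplotypes) >= 1L)
  for (h in haplotypes) {
    if (!identical(as.integer(h$positions), as.integer(vt$pos)))
      stop("haplotype positions must match the variant table")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan",
           if (!is.null(chrom_length))
             sprintf("##contig=<ID=%s,length=%d>", vt$chrom[1L],
                     as.integer(chrom_length)),
           '##INFO=<ID=MQ0,Number=1,Type=Integer,Description="Count of mapping quality zero reads">',
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias P-value">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">')

  sample_names <- unlist(lapply(haplotypes, function(h)
    h$sample_ids[seq(1L, length(h$sample_ids), by = 2L)]), use.names = FALSE)

  gt_cols <- lapply(haplotypes, function(h) {
    a <- h$alleles
    n_dip <- nrow(a) / 2L
    sapply(seq_len(n_dip), function(i)
      paste(a[2L * i - 1L, ], a[2L * i, ], sep = "|"))
  })
  gt <- do.call(cbind, gt_cols)
  if (nrow(vt) == 1L) gt <- matrix(gt, nrow = 1L)

  num_or_dot <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                         scientific = FALSE))
  info <- paste0("MQ0=", num_or_dot(vt$mq0), ";QD=", num_or_dot(vt$qd),
                 ";FS=", num_or_dot(vt$fs))
  info[is.na(vt$mq0) & is.na(vt$qd) & is.na(vt$fs)] <- "."
  body <- cbind(vt$chrom, vt$pos, ".", vt$ref, vt$alt, num_or_dot(vt$qual),
                "PASS", info, "GT", gt)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_names), collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
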