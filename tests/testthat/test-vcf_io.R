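toy_vcf <- function(path, records, samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=1000000>",
           '##INFO=<ID=MQ0,Number=1,Type=Integer,Description="x">',
           '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
toy_map <- data.frame(sample = c("s1", "s2"), population = c("A", "B"))

test_that("phased biallelic VCF is transcribed into per-population haplotype matrices", {
  f <- toy_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tC\t50\tPASS\tMQ0=0;QD=20;FS=1\tGT\t0|1\t1|1",
    "1\t200\t.\tG\tT\t60\tPASS\tMQ0=1;QD=15;FS=2\tGT\t1|0\t0|0",
    "1\t300\t.\tT\tA\t70\tPASS\tMQ0=0;QD=30;FS=0.5\tGT\t0|0\t0|1"))
  res <- read_vcf(f, toy_map)
  expect_equal(res$n_skipped, 0L)
  expect_equal(dim(res$haplotypes$A$alleles), c(2L, 3L))
  expect_equal(dim(res$haplotypes$B$alleles), c(2L, 3L))
  # s1 = population A: haplotype rows transcribe GT fields in order
  expect_equal(res$haplotypes$A$alleles[, 1], c(0L, 1L))
  expect_equal(res$haplotypes$B$alleles[, 1], c(1L, 1L))
  expect_equal(res$variants$pos, c(100L, 200L, 300L))
  expect_equal(res$variants$qd, c(20, 15, 30))
})

test_that("unphased and missing genotypes are rejected with the offending record named", {
  f <- toy_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tG\tT\t60\tPASS\t.\tGT\t0/1\t0|0"))
  expect_error(read_vcf(f, toy_map), "unphased.*1:200")
  f2 <- toy_vcf(tempfile(fileext = ".vcf"),
                "1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t.|.\t1|1")
  expect_error(read_vcf(f2, toy_map), "missing genotype")
})

test_that("non-biallelic-SNP records are skipped with a count", {
  f <- toy_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tG\tT,A\t60\tPASS\t.\tGT\t0|1\t0|0",
    "1\t300\t.\tT\tA\t70\tPASS\t.\tGT\t0|0\t0|1"))
  res <- suppressMessages(read_vcf(f, toy_map))
  expect_equal(res$n_skipped, 1L)
  expect_equal(res$variants$pos, c(100L, 300L))
})

test_that("samples missing from the map or the VCF are errors", {
  f <- toy_vcf(tempfile(fileext = ".vcf"),
               "1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0|1\t1|1")
  expect_error(read_vcf(f, toy_map[1, ]), "missing from the sample map")
  map3 <- rbind(toy_map, data.frame(sample = "s3", population = "B"))
  expect_error(read_vcf(f, map3), "missing from the VCF")
})

test_that("hard filters implement the three rules with strict comparisons", {
  vt <- variant_table(chrom = "1", pos = c(100, 200, 300, 400, 500),
                      ref = "A", alt = "C",
                      qual = c(29.9, 50, 50, 50, 30),
                      mq0 = c(0, 5, 5, 0, 4),
                      qd = c(20, 4.9, 10, 20, 5),
                      fs = c(10, 10, 100, 200.5, 200))
  res <- apply_hard_filters(vt)
  # rule 1: qual < 30; rule 2: mq0 > 4 AND qd < 5; rule 3: fs > 200;
  # boundary values (qual 30, mq0 4, qd 5, fs 200) all pass
  expect_equal(res$status,
               c("LowQual", "MQ0QD", "PASS", "StrandBias", "PASS"))
  expect_equal(unname(res$report[c("qual", "mq0_qd", "fs", "removed")]),
               c(1, 1, 1, 3))
  expect_equal(res$pass$pos, c(300L, 500L))
})

test_that("filtering is idempotent and missing annotations never trigger a rule", {
  set.seed(11)
  vt <- variant_table(chrom = "1", pos = seq(100, 2100, by = 100),
                      ref = "A", alt = "C",
                      qual = runif(21, 10, 60), mq0 = rpois(21, 3),
                      qd = runif(21, 2, 20), fs = runif(21, 0, 300))
  pass1 <- apply_hard_filters(vt)$pass
  res2 <- apply_hard_filters(pass1)
  expect_equal(unname(res2$report["removed"]), 0)
  expect_equal(res2$pass, pass1)

  vt$fs <- NA_real_
  vt$qual <- 50
  vt$mq0 <- NA_real_
  expect_warning(res <- apply_hard_filters(vt), "missing")
  expect_equal(unname(res$report["removed"]), 0)
})

test_that("thinning is seeded, sorted, uniform, and supports fractions and counts", {
  vt <- variant_table(chrom = "1", pos = seq(10, 10000, by = 10),
                      ref = "A", alt = "C", qual = 50, mq0 = 0, qd = 10,
                      fs = 1)
  th <- thin_variants(vt, 0.01, seed = 5)
  expect_equal(nrow(th), 10L)
  expect_false(is.unsorted(th$pos, strictly = TRUE))
  expect_identical(th, thin_variants(vt, 0.01, seed = 5))
  expect_equal(thin_variants(vt, 1.0, seed = 5)$pos, vt$pos)
  expect_equal(nrow(thin_variants(vt, 25, seed = 1)), 25L)
  expect_error(thin_variants(vt, 2000, seed = 1), "exceeds")

  # uniform inclusion over many seeds on a 20-record table
  small <- vt[1:20, ]
  counts <- integer(20)
  for (s in 1:400) {
    idx <- match(thin_variants(small, 5, seed = s)$pos, small$pos)
    counts[idx] <- counts[idx] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("BED genes read 0-based half-open with line-numbered errors", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tgeneA", "1\t150\t400\tgeneB\t0\t-"), f)
  gs <- read_genes(f)
  expect_equal(gs$start, c(100L, 150L))
  expect_equal(gs$end, c(200L, 400L))
  expect_equal(gs$gene_id, c("geneA", "geneB"))
  expect_equal(gs$strand, c("*", "-"))

  writeLines(c("1\t100\t200\tgeneA", "1\t300\t250\tgeneB"), f)
  expect_error(read_genes(f), "line 2.*start >= end")
  writeLines("1\t100\tgeneA", f)
  expect_error(read_genes(f), "line 1")
})

test_that("VCF writing round-trips positions, alleles and population assignment", {
  sim <- simulate_two_pops(sim_params(seed = 77, L = 100000L,
                                      burn_in = 100L, t_split = 50L))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$variants, list(A = sim$hapA, B = sim$hapB), f,
            chrom_length = 100000)
  map <- data.frame(
    sample = c(paste0("A", 1:8), paste0("B", 1:6)),
    population = rep(c("A", "B"), c(8, 6)))
  back <- read_vcf(f, map)
  expect_identical(back$haplotypes$A$alleles, sim$hapA$alleles)
  expect_identical(back$haplotypes$B$alleles, sim$hapB$alleles)
  expect_identical(back$haplotypes$A$positions, sim$hapA$positions)
  expect_equal(back$variants$ref, sim$variants$ref)
  expect_equal(back$variants$alt, sim$variants$alt)
})
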