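test_that("dosage-matrix files parse and round-trip bit-exactly", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2,m3,m4",
               "s1,0,1,2,NA",
               "s2,2,2,0,0",
               "s3,0,0,1,2"), csv)
  gm <- read_genotypes(csv)
  expect_equal(dim(gm$dosages), c(3L, 4L))
  expect_identical(gm$dosages["s1", "m4"], NA_integer_)
  expect_identical(gm$dosages["s2", "m1"], 2L)

  set.seed(11)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 50, TRUE), 20, 50,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("m%02d", 1:50)))
  gm0 <- genotype_matrix(d)
  f <- tempfile(fileext = ".csv")
  write_dosage_matrix(gm0, f)
  gm1 <- read_genotypes(f)
  expect_identical(gm1$dosages, gm0$dosages)
  expect_identical(gm1$map$marker_id, gm0$map$marker_id)
})

test_that("duplicate sample or marker ids are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "s1,0,1", "s1,2,0"), f)
  expect_error(read_genotypes(f), "duplicate sample id")
  writeLines(c("sample_id,m1,m1", "s1,0,1", "s2,2,0"), f)
  expect_error(read_genotypes(f), "duplicate marker id")
  writeLines(c("sample_id,m1,m2", "s1,0,x", "s2,2,0"), f)
  expect_error(read_genotypes(f), "unparseable")
})

test_that("VCF input keeps biallelic SNPs only and round-trips dosages", {
  set.seed(4)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 6 * 9, TRUE), 6, 9,
              dimnames = list(sprintf("s%d", 1:6), sprintf("mk%d", 1:9)))
  map <- data.frame(marker_id = sprintf("mk%d", 1:9), chrom = "1",
                    pos = seq(100, 900, by = 100),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm0 <- genotype_matrix(d, map = map)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_genotypes(gm0, vcf)
  # splice in one multi-allelic record among the 10
  lines <- readLines(vcf)
  multi <- paste(c("1", "950", "mk_multi", "A", "G,T", ".", "PASS", ".", "GT",
                   rep("0/0", 6)), collapse = "\t")
  writeLines(c(lines, multi), vcf)
  expect_message(gm1 <- read_genotypes(vcf, format = "vcf"), "skipped 1 multi-allelic")
  expect_equal(n_markers(gm1), 9L)
  expect_equal(unname(gm1$dosages), unname(d))
})

test_that("qc_filter applies thresholds in the documented order", {
  # sample s_bad has 8/10 calls (0.80 < 0.90) -> removed for call rate even
  # though its heterozygosity is also extreme
  d <- matrix(0L, 5, 10, dimnames = list(c("s_bad", "s_het", "ok1", "ok2", "ok3"),
                                         sprintf("m%02d", 1:10)))
  d["s_bad", 1:2] <- NA
  d["s_bad", 3:10] <- 1L
  d["s_het", 1:2] <- 1L   # 20% heterozygous > 15%
  res <- qc_filter(genotype_matrix(d))
  expect_setequal(res$report$samples_removed$sample_id, c("s_bad", "s_het"))
  expect_identical(
    res$report$samples_removed$reason[res$report$samples_removed$sample_id == "s_bad"],
    "call_rate")
  expect_identical(
    res$report$samples_removed$reason[res$report$samples_removed$sample_id == "s_het"],
    "heterozygosity")
  expect_equal(n_samples(res$genotypes), 3L)
})

test_that("DH heterozygote calls are set missing but the sample is kept", {
  d <- matrix(0L, 10, 20, dimnames = list(sprintf("s%02d", 1:10), sprintf("m%02d", 1:20)))
  d[1, 1:3] <- 1L
  st <- data.frame(sample_id = rownames(d), is_dh = c(TRUE, rep(FALSE, 9)))
  res <- qc_filter(genotype_matrix(d, samples = st))
  expect_equal(res$report$het_calls_set_missing, 3L)
  expect_true("s01" %in% rownames(res$genotypes$dosages))
  expect_true(all(is.na(res$genotypes$dosages["s01", 1:3])))
  expect_false(any(res$genotypes$dosages == 1L, na.rm = TRUE))
})

test_that("qc_filter is the identity on clean data and is idempotent", {
  set.seed(2)
  d <- matrix(sample(c(0L, 2L), 8 * 30, TRUE), 8, 30)
  gm <- genotype_matrix(d)
  res <- qc_filter(gm)
  expect_identical(res$genotypes$dosages, gm$dosages)
  expect_equal(res$report$n_samples_removed, 0L)
  expect_equal(res$report$n_markers_removed, 0L)

  d2 <- d
  d2[1, 1:25] <- NA   # low call-rate sample
  d2[, 1] <- NA; d2[2:8, 2] <- NA
  once <- qc_filter(genotype_matrix(d2))
  twice <- qc_filter(once$genotypes)
  expect_identical(twice$genotypes$dosages, once$genotypes$dosages)
  expect_equal(twice$report$n_samples_removed, 0L)
})

test_that("marker call rate is computed after sample removal by default", {
  # marker m01 is missing only in the to-be-removed sample: kept with
  # samples_first (call rate 4/4), removed when rates are computed on the raw
  # matrix (4/5 = 0.8 < 0.9)
  d <- matrix(0L, 5, 10, dimnames = list(sprintf("s%02d", 1:5), sprintf("m%02d", 1:10)))
  d[1, 1:9] <- NA           # sample s01 fails call rate (1/10)
  expect_false("m01" %in% qc_filter(genotype_matrix(d))$report$markers_removed)
  expect_true("m01" %in%
    qc_filter(genotype_matrix(d), samples_first = FALSE)$report$markers_removed)
})

test_that("qc_filter errors when everything is removed", {
  d <- matrix(NA_integer_, 3, 5)
  d[, 1] <- 0L  # 20% call rate everywhere
  expect_error(qc_filter(genotype_matrix(d)), "empty after QC")
})

test_that("eras map registration years to ten-year intervals", {
  expect_identical(assign_eras(c(1989, 1990, 1999, 2000, 2019, 2020, 2034)),
                   c(0L, 1L, 1L, 2L, 3L, 4L, 4L))
  expect_identical(assign_eras(NA_integer_), NA_integer_)
  expect_identical(assign_eras(integer(0)), integer(0))
  expect_error(assign_eras(2000, boundaries = c(2000, 1990)), "strictly increasing")
})

test_that("subsetting slices metadata consistently", {
  set.seed(5)
  d <- matrix(sample(c(0L, 2L), 12 * 20, TRUE), 12, 20)
  map <- data.frame(marker_id = sprintf("marker_%d", 1:20),
                    chrom = rep(c("chr1", "chr2"), each = 10), pos = rep(1:10, 2))
  st <- data.frame(sample_id = sprintf("sample_%d", 1:12),
                   era = rep(0:2, each = 4), group = rep(c("SS", "NSS"), 6))
  gm <- genotype_matrix(d, map = map, samples = st)

  sub <- subset_genotypes(gm, samples = st$era == 0 & st$group == "SS")
  expect_true(all(sub$samples$era == 0 & sub$samples$group == "SS"))
  expect_equal(n_samples(sub), 2L)

  same <- subset_genotypes(gm, samples = rep(TRUE, 12), markers = rep(TRUE, 20))
  expect_identical(same$dosages, gm$dosages)

  chr2 <- subset_genotypes(gm, markers = gm$map$chrom == "chr2")
  expect_true(all(chr2$map$chrom == "chr2"))

  expect_error(subset_genotypes(gm, samples = rep(FALSE, 12)), "empty sample selection")
})
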