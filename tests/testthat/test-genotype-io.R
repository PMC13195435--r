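vcf_lines <- function(records, samples = c("a", "b"), format = "GT") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

write_popmap <- function(samples, pops, dir) {
  f <- file.path(dir, "popmap.tsv")
  writeLines(paste(samples, pops, sep = "\t"), f)
  f
}

test_that("read_vcf converts GT calls to dosages and flags multiallelics", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.vcf")
  writeLines(vcf_lines(c(
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tA\tT\t50\tPASS\t.\tGT\t./.\t0|1",
    "chr1\t300\t.\tC\tA,T\t50\tPASS\t.\tGT\t1/2\t0/1")), f)
  pm <- write_popmap(c("a", "b"), c("X", "Y"), dir)
  gm <- read_vcf(f, pm)
  expect_equal(unname(gm$dosage[1, ]), c(1L, 2L))
  expect_equal(unname(gm$dosage[2, ]), c(NA_integer_, 1L))
  # multiallelic: dosage counts first-ALT copies only, removal deferred
  expect_true(gm$sites$multiallelic[3])
  expect_equal(unname(gm$dosage[3, ]), c(1L, 1L))
  expect_equal(unname(gm$pop), c("X", "Y"))
})

test_that("read_vcf rejects samples missing from the popmap", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.vcf")
  writeLines(vcf_lines("chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0/1\t1/1"), f)
  pm <- write_popmap("a", "X", dir)
  expect_error(read_vcf(f, pm), "absent from popmap")
})

test_that("write_vcf -> read_vcf round-trips dosages exactly", {
  gm <- random_panel(31, n_samples = 12, n_snps = 80, miss_rate = 0.1)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rt.vcf")
  write_vcf(gm, f)
  pm <- write_popmap(gm$samples, unname(gm$pop), dir)
  back <- read_vcf(f, pm)
  expect_identical(back$dosage, gm$dosage)
  expect_equal(back$sites$pos, gm$sites$pos)
})

test_that("site filters apply each rule and the log conserves totals", {
  # toy panel of 6 records: indel, multiallelic, low call rate, low MAF,
  # and 2 clean survivors
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.vcf")
  samples <- paste0("s", 1:10)
  gt <- function(x) paste(x, collapse = "\t")
  clean <- gt(c("0/0", "0/1", "1/1", "0/0", "0/1", "0/0", "1/1", "0/1",
                "0/0", "0/1"))
  writeLines(vcf_lines(c(
    paste0("chr1\t100\t.\tA\tAT\t90\tPASS\t.\tGT\t", clean),     # indel
    paste0("chr1\t200\t.\tA\tT,G\t90\tPASS\t.\tGT\t", clean),    # multiallelic
    paste0("chr1\t300\t.\tA\tT\t90\tPASS\t.\tGT\t",
           gt(c("./.", "./.", "./.", "0/1", "0/1", "0/1", "0/0", "0/0",
                "1/1", "0/1"))),                                  # call rate 0.7
    paste0("chr1\t400\t.\tA\tT\t90\tPASS\t.\tGT\t",
           gt(c("0/1", rep("0/0", 9)))),                          # MAF 1/20 = 0.05 < 0.06
    paste0("chr1\t500\t.\tG\tC\t90\tPASS\t.\tGT\t", clean),
    paste0("chr1\t600\t.\tG\tA\t90\tPASS\t.\tGT\t", clean)),
    samples = samples), f)
  pm <- write_popmap(samples, rep("X", 10), dir)
  gm <- read_vcf(f, pm)
  spec <- site_filter_spec(min_mean_dp = 0, min_gq = 0, min_maf = 0.06)
  out <- apply_site_filters(gm, spec)
  log <- attr(out, "filter_log")
  expect_equal(nrow(out$sites), 2)
  expect_equal(out$sites$pos, c(500L, 600L))
  expect_equal(sum(log$removed), log$n_in - log$n_out)
  expect_equal(unname(log$removed[c("indel", "multiallelic", "call_rate",
                                    "maf")]), c(1L, 1L, 1L, 1L))
})

test_that("MAF below the threshold removes a site (0.04 < 0.05)", {
  # 25 diploids, 2 alt alleles -> MAF = 0.04
  d <- matrix(0L, 1, 25); d[1, 1] <- 1L; d[1, 2] <- 1L
  gm <- tiny_gm(d)
  spec <- site_filter_spec(min_mean_dp = 0, min_gq = 0, max_missing = 0)
  expect_equal(nrow(apply_site_filters(gm, spec)$sites), 0)
  # MAF exactly 0.05 survives: 50 allele copies were needed; use 20 samples
  d2 <- matrix(0L, 1, 20); d2[1, 1] <- 2L
  out2 <- apply_site_filters(tiny_gm(d2), spec)
  expect_equal(nrow(out2$sites), 1)
})

test_that("GQ masking happens before call-rate and MAF rules", {
  d <- matrix(c(0L, 1L, 1L, 0L, 0L), 1, 5)
  gm <- tiny_gm(d)
  gm$gq <- matrix(c(99, 5, 5, 99, 99), 1, 5)
  # masking the two hets leaves the site monomorphic -> MAF rule removes it
  spec <- site_filter_spec(min_mean_dp = 0, max_missing = 0.5)
  out <- apply_site_filters(gm, spec)
  log <- attr(out, "filter_log")
  expect_equal(log$n_gq_masked_genotypes, 2L)
  expect_equal(unname(log$removed["maf"]), 1L)
})

test_that("missing FORMAT fields: permissive warns, strict errors", {
  gm <- tiny_gm(matrix(c(0L, 1L, 2L, 1L), 1, 4))
  spec_gq_only <- site_filter_spec(min_mean_dp = 0, min_maf = 0,
                                   max_missing = 0)
  expect_warning(apply_site_filters(gm, spec_gq_only), "GQ")
  expect_warning(
    apply_site_filters(gm, site_filter_spec(min_gq = 0, min_maf = 0,
                                            max_missing = 0)), "DP")
  expect_error(
    apply_site_filters(gm, site_filter_spec(permissive = FALSE)),
    "FORMAT")
})

test_that("filtering is idempotent", {
  gm <- random_panel(7, n_samples = 16, n_snps = 150, miss_rate = 0.15)
  spec <- site_filter_spec(min_mean_dp = 0, min_gq = 0)
  once <- apply_site_filters(gm, spec)
  twice <- apply_site_filters(once, spec)
  expect_identical(once$dosage, twice$dosage)
  expect_identical(once$sites, twice$sites)
})

test_that("genotype_r2 matches the direct Pearson formula", {
  expect_equal(genotype_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(genotype_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(genotype_r2(c(0, 1, 2, 1), c(2, 0, 1, 1)), 0.25)
  expect_true(is.na(genotype_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
  expect_error(genotype_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("ld_prune keeps the earlier SNP of an offending pair", {
  set.seed(2)
  s1 <- rbinom(40, 2, 0.5)
  s2 <- s1; s2[1:3] <- 2 - s2[1:3]           # highly correlated with s1
  s3 <- rbinom(40, 2, 0.5)                   # independent
  stopifnot(genotype_r2(s1, s2) > 0.5, genotype_r2(s1, s3) < 0.5,
            genotype_r2(s2, s3) < 0.5)
  gm <- tiny_gm(rbind(s1, s2, s3), pos = c(100, 200, 300))
  out <- ld_prune(gm, window_snps = 10, r2_threshold = 0.5)
  expect_equal(out$sites$pos, c(100, 300))
  expect_equal(attr(out, "pruned_out")$pos, 200)
})

test_that("ld_prune removes duplicated columns and keeps uncorrelated ones", {
  set.seed(3)
  s <- rbinom(30, 2, 0.5)
  gm <- tiny_gm(rbind(s, s), pos = c(10, 5000))
  expect_equal(nrow(ld_prune(gm)$sites), 1)
  gm2 <- random_panel(5, n_samples = 40, n_snps = 20, miss_rate = 0)
  r2all <- apply(utils::combn(20, 2), 2, function(ij)
    genotype_r2(gm2$dosage[ij[1], ], gm2$dosage[ij[2], ]))
  if (max(r2all, na.rm = TRUE) < 0.5)
    expect_equal(nrow(ld_prune(gm2)$sites), 20)
})

test_that("ld_prune postcondition holds under brute-force window checks", {
  for (seed in 1:5) {
    gm <- random_panel(seed + 100, n_samples = 10, n_snps = 60,
                       miss_rate = 0.05)
    w <- 8
    out <- ld_prune(gm, window_snps = w, r2_threshold = 0.5)
    d <- out$dosage
    n <- nrow(d)
    for (i in seq_len(max(0, n - 1)))
      for (j in (i + 1):min(n, i + w - 1)) {
        r2 <- suppressWarnings(genotype_r2(d[i, ], d[j, ]))
        if (!is.na(r2)) expect_lte(r2, 0.5)
      }
  }
})
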