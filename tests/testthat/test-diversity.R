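test_that("windowed pi matches pairwise-mismatch enumeration", {
  # one site, 2 diploids with dosages {0, 2}: 4 of the C(4,2)=6 haplotype
  # pairs differ -> per-site pi = 2/3, over a 10-kb window 6.67e-5
  gm <- tiny_gm(matrix(c(0L, 2L), 1, 2), pos = 5000)
  w <- data.frame(chrom = "chr1", start = 1, end = 10000)
  out <- windowed_pi(gm, "P1", w)
  expect_equal(out$value, (2 / 3) / 10000, tolerance = 1e-12)
  expect_equal(out$n_variants, 1)
})

test_that("windows without variants or data give pi 0", {
  gm <- tiny_gm(matrix(c(0L, 0L, NA, NA), 2, 2, byrow = TRUE),
                pos = c(500, 800))
  w <- data.frame(chrom = "chr1", start = 1, end = 1000)
  out <- windowed_pi(gm, "P1", w)
  expect_equal(out$value, 0)
  expect_equal(out$n_variants, 0)  # fully-missing site excluded
})

test_that("Tajima's D reproduces the n=4, S=1 textbook values", {
  w <- data.frame(chrom = "chr1", start = 1, end = 1000)
  # p = 0.5: dosages {0, 2}; theta_pi = 2/3
  gm <- tiny_gm(matrix(c(0L, 2L), 1, 2), pos = 500)
  expect_equal(windowed_tajimas_d(gm, "P1", w)$value, 1.63299316186,
               tolerance = 1e-9)
  # singleton (p = 0.25): dosages {1, 0}; theta_pi = 1/2
  gm2 <- tiny_gm(matrix(c(1L, 0L), 1, 2), pos = 500)
  expect_equal(windowed_tajimas_d(gm2, "P1", w)$value, -0.612372435696,
               tolerance = 1e-9)
  # S = 0 -> undefined, not zero
  gm3 <- tiny_gm(matrix(c(2L, 2L), 1, 2), pos = 500)
  expect_true(is.na(windowed_tajimas_d(gm3, "P1", w)$value))
})

test_that("Weir-Cockerham Fst handles fixed and identical populations", {
  pops <- rep(c("A", "B"), each = 4)
  d <- matrix(rep(c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L), 3), 3, 8,
              byrow = TRUE)
  gm <- tiny_gm(d, pos = c(100, 200, 300), pops = pops)
  w <- data.frame(chrom = "chr1", start = 1, end = 1000)
  expect_equal(windowed_fst(gm, "A", "B", w)$value, 1)
  # identical allele frequencies and genotype counts -> Fst <= 0
  d2 <- matrix(rep(c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L), 3), 3, 8,
               byrow = TRUE)
  gm2 <- tiny_gm(d2, pos = c(100, 200, 300), pops = pops)
  expect_lte(windowed_fst(gm2, "A", "B", w)$value, 0)
})

test_that("Weir-Cockerham Fst equals the hand-computed component example", {
  # popA genotype counts 6/3/1 and popB 1/3/6 for dosages 0/1/2:
  # a = 0.1125, b = 0.05, c = 0.15 -> theta = 0.36
  dA <- rep(0:2, c(6, 3, 1)); dB <- rep(0:2, c(1, 3, 6))
  gm <- tiny_gm(matrix(c(dA, dB), 1, 20),
                pops = rep(c("A", "B"), each = 10))
  w <- data.frame(chrom = "chr1", start = 1, end = 200)
  expect_equal(windowed_fst(gm, "A", "B", w)$value, 0.36, tolerance = 1e-12)
  expect_equal(global_fst(gm, "A", "B")$ratio_of_sums, 0.36,
               tolerance = 1e-12)
})

test_that("pi, D and Fst agree with site-by-site oracles on random panels", {
  for (seed in 1:8) {
    gm <- random_panel(seed, n_samples = 20, n_snps = 200, miss_rate = 0.1)
    w <- data.frame(chrom = "chr1", start = 1, end = 1e6)
    expect_equal(windowed_pi(gm, "P1", w)$value,
                 oracle_window_pi(gm, "P1", w[1, ]), tolerance = 1e-10)
    expect_equal(windowed_tajimas_d(gm, "P1", w)$value,
                 oracle_tajimas_d(gm, "P1", w[1, ]), tolerance = 1e-10)
    expect_equal(windowed_fst(gm, "P1", "P2", w)$value,
                 oracle_wc_fst(gm, "P1", "P2"), tolerance = 1e-10)
  }
})

test_that("Fst is symmetric and window stats ignore site order", {
  gm <- random_panel(42, n_samples = 16, n_snps = 100, miss_rate = 0.05)
  w <- data.frame(chrom = "chr1", start = 1, end = 1e6)
  expect_equal(windowed_fst(gm, "P1", "P2", w)$value,
               windowed_fst(gm, "P2", "P1", w)$value)
  perm <- sample(nrow(gm$sites))
  gm2 <- geno_matrix(gm$sites[perm, ], gm$dosage[perm, ], gm$samples,
                     gm$pop)
  expect_equal(windowed_pi(gm2, "P1", w)$value,
               windowed_pi(gm, "P1", w)$value)
  expect_equal(windowed_fst(gm2, "P1", "P2", w)$value,
               windowed_fst(gm, "P1", "P2", w)$value)
})

test_that("windows tile chromosomes with truncated terminal spans", {
  w <- make_windows(c(chr1 = 250001), size = 1e5, step = 1e4)
  expect_true(all(w$end - w$start + 1 <= 1e5))
  expect_equal(w$start, seq(1, 250001, by = 1e4))
  expect_equal(max(w$end), 250001)
})

test_that("private alleles follow the observed-in-one-population rule", {
  pops <- rep(c("A", "B", "C"), each = 2)
  d <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),   # alt private to A
             c(1L, 0L, 1L, 0L, 0L, 0L),   # alt shared A,B
             c(2L, 2L, 2L, 2L, 1L, 2L))   # ref observed only in C
  gm <- tiny_gm(d, pos = c(10, 20, 30), pops = pops)
  out <- private_allele_counts(gm)
  expect_equal(out[["A"]], 1L)
  expect_equal(out[["B"]], 0L)
  expect_equal(out[["C"]], 1L)
})

test_that("LD decay bins average pair r2 and respect the distance cap", {
  set.seed(9)
  s <- rbinom(30, 2, 0.5)
  s2 <- rbinom(30, 2, 0.5)
  gm <- tiny_gm(rbind(s, s, s2), pos = c(1000, 6000, 360000))
  cur <- ld_decay_curve(gm, max_dist = 3e5, bin_width = 1e3)
  # identical SNPs 5 kb apart -> their bin mean is 1
  expect_equal(cur$mean_r2[cur$bin_start == 5000], 1)
  # pair at 354 kb separation excluded entirely
  expect_equal(sum(cur$n_pairs), 1)
})

test_that("LD decay bin means equal arithmetic means of member pairs", {
  gm <- random_panel(11, n_samples = 30, n_snps = 10, miss_rate = 0)
  gm$sites$pos <- seq(1000, by = 700, length.out = 10)
  cur <- ld_decay_curve(gm, max_dist = 1e4, bin_width = 2e3)
  # recompute by enumeration
  ref <- list()
  for (i in 1:9) for (j in (i + 1):10) {
    dist <- gm$sites$pos[j] - gm$sites$pos[i]
    if (dist > 1e4) next
    bin <- floor(dist / 2e3) + 1
    ref[[length(ref) + 1]] <- c(bin = bin,
                                r2 = genotype_r2(gm$dosage[i, ],
                                                 gm$dosage[j, ]))
  }
  ref <- do.call(rbind, ref)
  for (b in unique(ref[, "bin"])) {
    expect_equal(cur$mean_r2[b], mean(ref[ref[, "bin"] == b, "r2"]),
                 tolerance = 1e-12)
  }
})

test_that("mantel test: perfect linear relation gives r = 1, small p", {
  set.seed(1)
  m <- matrix(runif(25), 5)
  d1 <- as.matrix(dist(m))
  d2 <- 2 * d1 + 1
  out <- mantel_test(d1, d2, n_perm = 999, seed = 4)
  expect_equal(out$r, 1)
  # exhaustive enumeration: among all 120 label permutations only the
  # identity attains r >= 1, so p is near (1 + 999/120) / 1000
  expect_lt(out$p, 0.03)
  # constant off-diagonal -> undefined
  d3 <- matrix(1, 5, 5); diag(d3) <- 0
  expect_true(is.na(mantel_test(d1, d3, n_perm = 99, seed = 1)$r))
  expect_error(mantel_test(d1[1:4, 1:5], d2, n_perm = 9),
               "size|symmetric")
})

test_that("mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  d1 <- as.matrix(dist(matrix(runif(14), 7)))
  d2 <- as.matrix(dist(matrix(runif(14), 7)))
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel p is approximately uniform under the null", {
  set.seed(13)
  n <- 6
  ps <- replicate(400, {
    d1 <- as.matrix(dist(matrix(runif(2 * n), n)))
    d2 <- as.matrix(dist(matrix(runif(2 * n), n)))
    mantel_test(d1, d2, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  # discrete grid of (k+1)/100; KS against uniform with generous alpha
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("distance helpers produce symmetric zero-diagonal matrices", {
  coords <- data.frame(unit = c("a", "b", "c"), lon = c(112, 114, 116),
                       lat = c(36, 38, 40))
  g <- geo_distance_matrix(coords)
  expect_true(isSymmetric(unname(g)))
  expect_equal(diag(g), c(a = 0, b = 0, c = 0))
  expect_gt(g["a", "c"], g["a", "b"])
  f <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_equal(linearized_fst(f)[1, 2], 0.25)
  env <- data.frame(unit = c("a", "b"), bio1 = c(1, 2), bio2 = c(5, 3))
  e <- env_distance_matrix(env)
  expect_equal(e["a", "b"], 2, tolerance = 1e-9)  # both vars z-scored to +/- 1/sqrt(2)... distance sqrt(2+2)
})
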