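## ---- shared GEA plumbing ------------------------------------------------

## Environmental tables are measured per sampling location, so samples of
## one population share values. Accepts a per-sample table (a `sample`
## column) or a per-population table (a `unit` column matched against the
## population labels) and returns a numeric matrix aligned to gm$samples.
align_env <- function(env, gm) {
  env <- as.data.frame(env)
  vars <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                  c("lon", "lat"))
  if ("sample" %in% names(env)) {
    i <- match(gm$samples, env$sample)
    assert_that(!anyNA(i), "env table lacks rows for some samples")
  } else {
    unit_col <- intersect(c("unit", "pop", "population"), names(env))[1]
    assert_that(!is.na(unit_col),
                "env table needs a 'sample' or 'unit' column")
    i <- match(unname(gm$pop[gm$samples]), env[[unit_col]])
    assert_that(!anyNA(i), "env table lacks rows for some populations")
  }
  m <- as.matrix(env[i, vars, drop = FALSE])
  rownames(m) <- gm$samples
  assert_that(!anyNA(m), "env table contains missing values")
  m
}

## Samples x SNPs dosage matrix with per-SNP mean imputation of missing
## calls; columns named chrom:pos.
dosage_matrix_imputed <- function(gm) {
  Y <- t(gm$dosage)
  colnames(Y) <- paste(gm$sites$chrom, gm$sites$pos, sep = ":")
  mu <- colMeans(Y, na.rm = TRUE)
  na <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(na) > 0) Y[na] <- mu[na[, 2]]
  Y
}

#' Subset sites by call rate
#'
#' The GEA scans run on a near-complete SNP subset (default call rate
#' >= 0.99).
#'
#' @param gm a [geno_matrix()].
#' @param min_call_rate minimum fraction of samples with a call.
#' @export
subset_by_call_rate <- function(gm, min_call_rate = 0.99) {
  cr <- rowMeans(!is.na(gm$dosage))
  gm[cr >= min_call_rate, ]
}

#' Greedy correlation-filtered environmental variable selection
#'
#' Variables are considered in decreasing importance; one is retained iff
#' its absolute Pearson correlation with every already-retained variable
#' is below `r_max`. Constant variables are excluded with a warning.
#'
#' @param env data.frame with the candidate variables (lon/lat ignored).
#' @param importance named numeric vector of importance scores (e.g.
#'   gradient-forest predictor importance).
#' @param r_max correlation bound (default 0.8, i.e. keep |r| < 0.8).
#' @return character vector of retained variable names.
#' @export
select_env_variables <- function(env, importance, r_max = 0.8) {
  env <- as.data.frame(env)
  vars <- names(sort(importance, decreasing = TRUE))
  vars <- vars[vars %in% names(env)]
  const <- vars[vapply(vars, function(v) stats::sd(env[[v]]) == 0, logical(1))]
  if (length(const) > 0) {
    warning(paste("constant variables excluded:",
                  paste(const, collapse = ", ")), call. = FALSE)
    vars <- setdiff(vars, const)
  }
  kept <- character(0)
  for (v in vars) {
    r <- vapply(kept, function(k) abs(stats::cor(env[[v]], env[[k]])),
                numeric(1))
    if (all(r < r_max)) kept <- c(kept, v)
  }
  kept
}

#' Latent-factor association scan (ridge/least-squares LFMM)
#'
#' Deterministic latent-factor linear model scan, one environmental
#' variable at a time: (1) the variable's projection is removed from the
#' centered genotype matrix and the top-K left singular vectors of the
#' residual become latent factors (so they absorb population structure
#' orthogonal to the tested variable); (2) each SNP's dosage is regressed
#' on the variable plus factors; (3) t-statistics are converted to
#' p-values; (4) a genomic inflation factor lambda = median(t^2) /
#' qchisq(0.5, 1) recalibrates them. A SNP is significant when its
#' calibrated p <= `p_threshold` for at least one variable.
#'
#' @param gm a [geno_matrix()] (typically the call-rate >= 0.99 subset).
#' @param env per-sample or per-population environment table.
#' @param K number of latent factors (>= 0; default 7, the number of
#'   ancestral populations in the sky-island design).
#' @param p_threshold significance threshold (default 1e-5).
#' @param calibrate apply GIF calibration (default TRUE).
#' @return list with `tests` (long data.frame snp, variable, beta, t,
#'   p_raw, p_cal), `lambda` (per variable), `significant` (per-SNP
#'   provenance of significant variables) and `snps` (SNP universe).
#' @export
lfmm_scan <- function(gm, env, K = 7, p_threshold = 1e-5, calibrate = TRUE) {
  E <- align_env(env, gm)
  Y <- dosage_matrix_imputed(gm)
  n <- nrow(Y); m <- ncol(Y)
  assert_that(K >= 0, "K must be >= 0")
  assert_that(K < min(n, m), "K must be < min(samples, SNPs)")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  tests <- vector("list", ncol(E))
  lambda <- stats::setNames(numeric(ncol(E)), colnames(E))
  for (v in seq_len(ncol(E))) {
    x <- as.numeric(scale(E[, v]))
    X <- cbind(1, x)
    U <- NULL
    if (K > 0) {
      R <- Yc - X %*% solve(crossprod(X), crossprod(X, Yc))
      ## left singular vectors of R via the n x n outer cross-product
      ## (n << number of SNPs)
      U <- eigen(tcrossprod(R), symmetric = TRUE)$vectors[, seq_len(K),
                                                          drop = FALSE]
    }
    D <- cbind(X, U)
    qrD <- qr(D)
    B <- qr.coef(qrD, Yc)
    res <- Yc - D %*% B
    df <- n - ncol(D)
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qrD))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    tstat <- B[2, ] / se
    p_raw <- 2 * stats::pt(-abs(tstat), df)
    lam <- stats::median(tstat^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    lambda[v] <- lam
    p_cal <- stats::pchisq(tstat^2 / max(lam, 1e-12), 1, lower.tail = FALSE)
    tests[[v]] <- data.frame(snp = colnames(Y), variable = colnames(E)[v],
                             beta = B[2, ], t = tstat, p_raw = p_raw,
                             p_cal = p_cal, row.names = NULL)
  }
  tests <- do.call(rbind, tests)
  pcol <- if (calibrate) tests$p_cal else tests$p_raw
  sig <- tests[!is.na(pcol) & pcol <= p_threshold, c("snp", "variable")]
  prov <- if (nrow(sig) > 0)
    stats::aggregate(variable ~ snp, data = sig,
                     FUN = function(z) paste(sort(unique(z)), collapse = ","))
  else data.frame(snp = character(), variable = character())
  list(tests = tests, lambda = lambda, significant = prov,
       snps = colnames(Y), K = K, p_threshold = p_threshold)
}

#' Redundancy-analysis outlier scan
#'
#' Constrained ordination of the mean-imputed, centered genotype matrix
#' on the standardized environmental variables: the SVD of the fitted
#' values yields constrained axes; a SNP is an outlier when its loading
#' on any of the first `n_axes` axes deviates from that axis's mean
#' loading by more than `sd_cutoff` standard deviations.
#'
#' @param gm a [geno_matrix()].
#' @param env per-sample or per-population environment table.
#' @param n_axes number of constrained axes to screen (default: number of
#'   env variables).
#' @param sd_cutoff loading z-score cutoff (default 3.5).
#' @return list with `loadings` (SNPs x axes), `var_fraction` (per axis,
#'   fraction of total genotype variance), `outliers` (per-SNP axis
#'   provenance) and `snps`.
#' @export
rda_scan <- function(gm, env, n_axes = NULL, sd_cutoff = 3.5) {
  E <- align_env(env, gm)
  n_axes <- n_axes %||% ncol(E)
  assert_that(n_axes >= 1 && n_axes <= ncol(E),
              "n_axes must be in 1..ncol(env)")
  Y <- dosage_matrix_imputed(gm)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  X <- zscore(E)
  qrX <- qr(cbind(1, X))
  Fit <- qr.fitted(qrX, Yc)
  sv <- svd(Fit)
  k <- min(n_axes, sum(sv$d > 1e-8))
  load <- sv$v[, seq_len(k), drop = FALSE]
  rownames(load) <- colnames(Y)
  colnames(load) <- paste0("RDA", seq_len(k))
  var_frac <- sv$d[seq_len(k)]^2 / sum(Yc^2)
  z <- scale(load)
  out_mat <- abs(z) > sd_cutoff
  hit <- which(rowSums(out_mat) > 0)
  outliers <- data.frame(
    snp = rownames(load)[hit],
    axes = vapply(hit, function(i)
      paste(colnames(load)[out_mat[i, ]], collapse = ","), character(1)),
    row.names = NULL)
  list(loadings = load, var_fraction = var_frac, outliers = outliers,
       snps = colnames(Y), sd_cutoff = sd_cutoff)
}

#' Core environment-associated SNPs: LFMM intersect RDA
#'
#' @param lfmm output of [lfmm_scan()].
#' @param rda output of [rda_scan()].
#' @return data.frame(snp, variables, axes) for SNPs detected by both
#'   methods.
#' @export
intersect_core_snps <- function(lfmm, rda) {
  assert_that(length(intersect(lfmm$snps, rda$snps)) > 0,
              "LFMM and RDA were run on disjoint SNP universes")
  core <- intersect(lfmm$significant$snp, rda$outliers$snp)
  data.frame(snp = core,
             variables = lfmm$significant$variable[
               match(core, lfmm$significant$snp)],
             axes = rda$outliers$axes[match(core, rda$outliers$snp)],
             row.names = NULL)
}
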