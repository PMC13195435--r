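#' Genotype matrix container
#'
#' The pipeline's central data structure: an ordered table of variant sites
#' together with a sites x samples matrix of alternate-allele dosages
#' (0/1/2, `NA` = missing call) and a sample -> population map. Optional
#' per-genotype depth (`dp`) and genotype-quality (`gq`) matrices carry the
#' VCF FORMAT fields needed by the depth/quality filters.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`, `multiallelic` (logical; dosages at flagged records are
#'   computed against the first ALT allele only, removal is deferred to
#'   [apply_site_filters()]).
#' @param dosage integer matrix, `nrow(sites)` x `length(samples)`.
#' @param samples character vector of sample ids (column order of `dosage`).
#' @param pop named character vector mapping every sample to a population.
#' @param dp,gq optional numeric matrices with the same shape as `dosage`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, dosage, samples, pop, dp = NULL, gq = NULL) {
  sites <- as.data.frame(sites)
  needed <- c("chrom", "pos", "ref", "alt", "qual", "multiallelic")
  missing_cols <- setdiff(needed, names(sites))
  if ("qual" %in% missing_cols) sites$qual <- NA_real_
  if ("multiallelic" %in% missing_cols)
    sites$multiallelic <- grepl(",", sites$alt, fixed = TRUE)
  missing_cols <- setdiff(needed, names(sites))
  assert_that(length(missing_cols) == 0,
              paste("sites lacks columns:", paste(missing_cols, collapse = ", ")))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  assert_that(nrow(dosage) == nrow(sites) && ncol(dosage) == length(samples),
              "dosage dimensions must be nrow(sites) x length(samples)")
  assert_that(all(samples %in% names(pop)),
              "every sample needs a population label in `pop`")
  assert_that(all(sites$pos >= 1), "positions must be >= 1")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL
  dimnames(dosage) <- list(NULL, samples)
  structure(list(sites = sites, dosage = dosage, samples = samples,
                 pop = pop[samples], dp = dp, gq = gq),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples, %d populations\n",
              nrow(x$sites), length(x$samples), length(unique(x$pop))))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.3f; DP: %s; GQ: %s\n", miss,
              if (is.null(x$dp)) "absent" else "present",
              if (is.null(x$gq)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$sites), length(x$samples))

## Subset sites (i) and/or samples (j); keeps all aligned slots in step.
#' @export
`[.geno_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  geno_matrix(x$sites[i, , drop = FALSE],
              x$dosage[i, j, drop = FALSE],
              x$samples[j], x$pop,
              dp = if (!is.null(x$dp)) x$dp[i, j, drop = FALSE],
              gq = if (!is.null(x$gq)) x$gq[i, j, drop = FALSE])
}

## Column indices of samples belonging to population `pop_label`.
pop_cols <- function(gm, pop_label) {
  idx <- which(gm$pop == pop_label)
  assert_that(length(idx) > 0,
              sprintf("unknown population label '%s'", pop_label))
  idx
}

#' Per-site alternate-allele frequency within a set of samples
#'
#' @param gm a [geno_matrix()].
#' @param cols column indices (default: all samples).
#' @return list with `p` (alt frequency over called alleles, `NaN` where no
#'   calls), `n` (called allele count) and `nhet` (het genotype count).
#' @export
site_allele_stats <- function(gm, cols = seq_along(gm$samples)) {
  d <- gm$dosage[, cols, drop = FALSE]
  called <- !is.na(d)
  n <- 2L * rowSums(called)
  ac <- rowSums(d, na.rm = TRUE)
  list(p = ac / n, n = n, nhet = rowSums(d == 1L, na.rm = TRUE))
}
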