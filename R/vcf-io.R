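#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or bgzipped) with `vcfR` and converts GT
#' calls to alternate-allele dosages. Multiallelic records are retained and
#' flagged; their dosages count copies of the *first* ALT allele only, and
#' their removal is deferred to [apply_site_filters()]. Any genotype with a
#' missing or partial call (`./.`, `.|1`, ...) becomes `NA`.
#'
#' @param path VCF file.
#' @param popmap either a two-column data.frame (`sample`, `population`) or
#'   the path of a tab-separated file with those two columns (no header
#'   required).
#' @return A [geno_matrix()] with DP/GQ matrices when the VCF carries those
#'   FORMAT fields.
#' @export
read_vcf <- function(path, popmap) {
  popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  assert_that(nrow(fix) > 0, "VCF contains no variant records")
  samples <- colnames(v@gt)[-1]
  absent <- setdiff(samples, popmap$sample)
  assert_that(length(absent) == 0,
              paste("samples absent from popmap:", paste(absent, collapse = ", ")))
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- gt_to_dosage(gt)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  num_fmt <- function(el) {
    if (!el %in% fmt) return(NULL)
    m <- suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    dimnames(m) <- list(NULL, samples)
    m
  }
  pop <- stats::setNames(popmap$population, popmap$sample)
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF,
                      alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      multiallelic = grepl(",", fix$ALT, fixed = TRUE),
                      stringsAsFactors = FALSE)
  geno_matrix(sites, dosage, samples, pop,
              dp = num_fmt("DP"), gq = num_fmt("GQ"))
}

read_popmap <- function(popmap) {
  if (is.character(popmap) && length(popmap) == 1) {
    popmap <- utils::read.table(popmap, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE,
                                col.names = c("sample", "population"))
  }
  popmap <- as.data.frame(popmap)
  names(popmap)[1:2] <- c("sample", "population")
  popmap
}

## "0/1", "1|1", "1/2" ... -> count of allele index 1; any "." -> NA.
gt_to_dosage <- function(gt) {
  n <- nrow(gt); m <- ncol(gt)
  flat <- as.vector(gt)
  out <- rep(NA_integer_, length(flat))
  ok <- !is.na(flat) & !grepl(".", flat, fixed = TRUE)
  if (any(ok)) {
    parts <- strsplit(flat[ok], "[/|]")
    out[ok] <- vapply(parts, function(a) sum(a == "1"), integer(1))
  }
  matrix(out, n, m, dimnames = list(NULL, colnames(gt)))
}

#' Write a genotype matrix back to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT (plus DP/GQ when present). Dosages map
#' to `0/0`, `0/1`, `1/1`; missing to `./.`. Round-trips dosages exactly
#' through [read_vcf()].
#'
#' @param gm a [geno_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- nrow(gm$sites)
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", n, length(gm$samples))
  called <- !is.na(gm$dosage)
  gt[called] <- gtcode[as.character(gm$dosage[called])]
  fmt <- "GT"
  if (!is.null(gm$dp)) {
    fmt <- paste0(fmt, ":DP")
    gt <- matrix(paste(gt, ifelse(is.na(gm$dp), ".", gm$dp), sep = ":"),
                 n, length(gm$samples))
  }
  if (!is.null(gm$gq)) {
    fmt <- paste0(fmt, ":GQ")
    gt <- matrix(paste(gt, ifelse(is.na(gm$gq), ".", gm$gq), sep = ":"),
                 n, length(gm$samples))
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              if (!is.null(gm$dp))
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              if (!is.null(gm$gq))
                "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  qual <- ifelse(is.na(gm$sites$qual), ".", format(gm$sites$qual, trim = TRUE))
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                qual, "PASS", ".", fmt,
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Site filter specification
#'
#' Defaults mirror a standard VCFtools-style refinement of a raw SNP call
#' set: `--min-meanDP 3 --minGQ 10 --minQ 30 --maf 0.05 --remove-indels
#' --max-missing 0.8 --min-alleles 2 --max-alleles 2`.
#'
#' @param min_mean_dp minimum mean depth over called genotypes.
#' @param min_gq genotypes below this GQ are set missing before site rules.
#' @param min_qual minimum variant QUAL.
#' @param min_maf minimum minor-allele frequency over called alleles.
#' @param remove_indels drop records whose REF or ALT is not 1 bp.
#' @param max_missing minimum fraction of samples with a call (VCFtools
#'   `--max-missing` semantics: keep sites with call rate >= this value).
#' @param biallelic_only drop multiallelic records.
#' @param permissive if TRUE, DP/GQ rules are skipped with a warning when
#'   the VCF lacks those FORMAT fields; if FALSE that is an error.
#' @export
site_filter_spec <- function(min_mean_dp = 3, min_gq = 10, min_qual = 30,
                             min_maf = 0.05, remove_indels = TRUE,
                             max_missing = 0.8, biallelic_only = TRUE,
                             permissive = TRUE) {
  assert_that(min_maf >= 0 && min_maf <= 0.5, "min_maf must be in [0, 0.5]")
  assert_that(max_missing >= 0 && max_missing <= 1,
              "max_missing must be in [0, 1]")
  structure(list(min_mean_dp = min_mean_dp, min_gq = min_gq,
                 min_qual = min_qual, min_maf = min_maf,
                 remove_indels = remove_indels, max_missing = max_missing,
                 biallelic_only = biallelic_only, permissive = permissive),
            class = "site_filter_spec")
}

#' Apply site-level filters to a genotype matrix
#'
#' Rule order: genotype-level GQ masking first, then per-site rules
#' (multiallelic, indel, QUAL, mean depth, call rate, MAF), each site being
#' attributed to the first rule it fails. MAF is computed on called alleles
#' only, so sites left monomorphic by GQ masking fall to the MAF rule.
#'
#' @param gm a [geno_matrix()].
#' @param spec a [site_filter_spec()].
#' @return The filtered `geno_matrix`, with a `filter_log` attribute:
#'   `n_in`, `n_out`, `n_gq_masked_genotypes` and per-rule removal counts
#'   (which sum to `n_in - n_out`).
#' @export
apply_site_filters <- function(gm, spec = site_filter_spec()) {
  stopifnot(inherits(spec, "site_filter_spec"))
  n_in <- nrow(gm$sites)
  n_masked <- 0L
  if (!is.null(spec$min_gq) && spec$min_gq > 0) {
    if (is.null(gm$gq)) {
      if (!spec$permissive)
        stop2("GQ filtering requested but the VCF has no GQ FORMAT field")
      warning("no GQ FORMAT field; GQ masking skipped", call. = FALSE)
    } else {
      mask <- !is.na(gm$gq) & gm$gq < spec$min_gq & !is.na(gm$dosage)
      n_masked <- sum(mask)
      gm$dosage[mask] <- NA_integer_
    }
  }
  st <- site_allele_stats(gm)
  n_samp <- length(gm$samples)
  fail <- rep(NA_character_, n_in)
  mark <- function(bad, rule) {
    bad[is.na(bad)] <- FALSE
    fail[is.na(fail) & bad] <<- rule
  }
  if (spec$biallelic_only) mark(gm$sites$multiallelic, "multiallelic")
  if (spec$remove_indels)
    mark(nchar(gm$sites$ref) != 1 | nchar(gm$sites$alt) != 1, "indel")
  if (!is.null(spec$min_qual))
    mark(!is.na(gm$sites$qual) & gm$sites$qual < spec$min_qual, "low_qual")
  if (!is.null(spec$min_mean_dp) && spec$min_mean_dp > 0) {
    if (is.null(gm$dp)) {
      if (!spec$permissive)
        stop2("mean-depth filtering requested but the VCF has no DP FORMAT field")
      warning("no DP FORMAT field; mean-depth rule skipped", call. = FALSE)
    } else {
      dpm <- gm$dp
      dpm[is.na(gm$dosage)] <- NA
      mean_dp <- rowMeans(dpm, na.rm = TRUE)
      mark(is.nan(mean_dp) | mean_dp < spec$min_mean_dp, "low_mean_dp")
    }
  }
  call_rate <- (st$n / 2) / n_samp
  mark(call_rate < spec$max_missing, "call_rate")
  maf <- pmin(st$p, 1 - st$p)
  mark(is.nan(st$p) | maf < spec$min_maf, "maf")
  keep <- is.na(fail)
  removed <- table(factor(fail[!keep],
                          levels = c("multiallelic", "indel", "low_qual",
                                     "low_mean_dp", "call_rate", "maf")))
  out <- gm[keep, ]
  attr(out, "filter_log") <- list(
    n_in = n_in, n_out = sum(keep),
    n_gq_masked_genotypes = n_masked,
    removed = stats::setNames(as.integer(removed), names(removed)))
  out
}

#' Squared genotype correlation (composite LD)
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' samples — the unphased (composite) r^2 used for LD pruning and decay.
#'
#' @param a,b integer dosage vectors of equal length.
#' @return r^2, or `NA` if either vector is constant over the complete
#'   pairs.
#' @export
genotype_r2 <- function(a, b) {
  assert_that(length(a) == length(b), "dosage vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  assert_that(sum(ok) >= 2, "need >= 2 pairwise-complete samples")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Window-based LD pruning of a genotype matrix
#'
#' Sliding windows of `window_snps` SNPs advanced by `step_snps`; within a
#' window, for any retained pair with r^2 above the threshold the
#' later-positioned SNP is dropped (deterministic keep-earlier rule).
#' After pruning, no retained pair inside any window of `window_snps`
#' consecutive retained SNPs exceeds the threshold.
#'
#' @param gm a filtered, position-sorted [geno_matrix()].
#' @param window_snps,step_snps,r2_threshold pruning parameters
#'   (PLINK-style `--indep-pairwise 100 1 0.5` defaults).
#' @return The pruned `geno_matrix`; attribute `pruned_out` holds the
#'   dropped (chrom, pos) table.
#' @export
ld_prune <- function(gm, window_snps = 100, step_snps = 1,
                     r2_threshold = 0.5) {
  assert_that(window_snps >= 2, "window_snps must be >= 2")
  assert_that(r2_threshold > 0 && r2_threshold <= 1,
              "r2_threshold must be in (0, 1]")
  keep <- rep(TRUE, nrow(gm$sites))
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    kept <- integer(0)  # indices (into idx) of retained SNPs, in order
    for (k in seq_along(idx)) {
      prev <- utils::tail(kept, window_snps - 1L)
      drop <- FALSE
      if (length(prev) > 0) {
        r <- suppressWarnings(
          stats::cor(gm$dosage[idx[k], ],
                     t(gm$dosage[idx[prev], , drop = FALSE]),
                     use = "pairwise.complete.obs"))
        drop <- any(r^2 > r2_threshold, na.rm = TRUE)
      }
      if (drop) keep[idx[k]] <- FALSE else kept <- c(kept, k)
    }
  }
  out <- gm[keep, ]
  attr(out, "pruned_out") <- gm$sites[!keep, c("chrom", "pos")]
  out
}
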