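#' ln(pi ratio) between two window tables
#'
#' Per window, ln(pi_contrast / pi_focal); the upper tail then marks
#' diversity loss in the focal population. Windows where either pi is
#' zero or missing are dropped (count reported in the `n_dropped`
#' attribute).
#'
#' @param pi_contrast,pi_focal window tables from [windowed_pi()] on the
#'   same window frame.
#' @return data.frame(chrom, start, end, stat, pop, value, n_variants).
#' @export
ln_pi_ratio <- function(pi_contrast, pi_focal) {
  same <- identical(pi_contrast[c("chrom", "start", "end")],
                    pi_focal[c("chrom", "start", "end")])
  assert_that(same, "window frames differ between the two pi tables")
  ok <- !is.na(pi_contrast$value) & !is.na(pi_focal$value) &
    pi_contrast$value > 0 & pi_focal$value > 0
  out <- data.frame(pi_contrast[c("chrom", "start", "end")],
                    stat = "ln_pi_ratio",
                    pop = paste(pi_contrast$pop[1], pi_focal$pop[1], sep = "|"),
                    value = ifelse(ok, log(pi_contrast$value / pi_focal$value),
                                   NA_real_),
                    n_variants = pi_contrast$n_variants + pi_focal$n_variants)
  out <- out[ok, ]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

## Upper empirical quantile threshold: value of the ceiling((1-q)*n)-th
## largest defined observation; ties are included by the >= rule.
upper_tail_threshold <- function(x, q) {
  x <- x[!is.na(x)]
  ## epsilon guards the ceiling against floating-point excess,
  ## e.g. 0.05 * 100 = 5.000000000000004
  k <- max(1L, ceiling((1 - q) * length(x) - 1e-9))
  sort(x, decreasing = TRUE)[k]
}

#' Joint Fst x ln(pi ratio) sweep outlier windows
#'
#' Candidate windows fall in the upper (1 - q) empirical tail of both the
#' Fst and the ln(pi ratio) distributions (inclusive thresholds, ties
#' kept). Quantiles are computed over windows where both statistics are
#' defined. Overlapping or bookended candidate windows are merged into
#' regions.
#'
#' @param fst window table from [windowed_fst()].
#' @param ratio window table from [ln_pi_ratio()].
#' @param q quantile (default 0.95, i.e. top 5%).
#' @return list with `windows` (per-window flags in_top_fst,
#'   in_top_ratio, candidate), `regions` (merged candidate intervals) and
#'   `thresholds`.
#' @export
joint_outlier_windows <- function(fst, ratio, q = 0.95) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  i <- match(key(ratio), key(fst))
  assert_that(!anyNA(i), "ratio windows missing from the fst table")
  tab <- data.frame(ratio[c("chrom", "start", "end")],
                    fst = fst$value[i], ln_pi_ratio = ratio$value)
  tab <- tab[!is.na(tab$fst) & !is.na(tab$ln_pi_ratio), ]
  if (nrow(tab) < 20)
    warning("fewer than 20 jointly-defined windows; quantiles unstable",
            call. = FALSE)
  thr_fst <- upper_tail_threshold(tab$fst, q)
  thr_ratio <- upper_tail_threshold(tab$ln_pi_ratio, q)
  tab$in_top_fst <- tab$fst >= thr_fst
  tab$in_top_ratio <- tab$ln_pi_ratio >= thr_ratio
  tab$candidate <- tab$in_top_fst & tab$in_top_ratio
  regions <- merge_intervals(tab[tab$candidate, c("chrom", "start", "end")])
  list(windows = tab, regions = regions,
       thresholds = c(fst = thr_fst, ln_pi_ratio = thr_ratio, q = q))
}

## Union of 1-based inclusive intervals; bookended ([a,b],[b+1,c]) merge.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  out <- list()
  for (chr in unique(iv$chrom)) {
    x <- iv[iv$chrom == chr, ]
    x <- x[order(x$start), ]
    s <- x$start[1]; e <- x$end[1]
    for (k in seq_len(nrow(x))[-1]) {
      if (x$start[k] <= e + 1) e <- max(e, x$end[k])
      else { out[[length(out) + 1]] <- data.frame(chrom = chr, start = s, end = e)
             s <- x$start[k]; e <- x$end[k] }
    }
    out[[length(out) + 1]] <- data.frame(chrom = chr, start = s, end = e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes overlapping candidate sweep regions
#'
#' A gene is reported (once) when its span intersects any merged candidate
#' region by at least 1 bp; all overlapping regions are listed.
#'
#' @param regions merged regions from [joint_outlier_windows()].
#' @param gff_path GFF3 with gene features.
#' @return data.frame(gene, chrom, start, end, regions) where `regions`
#'   is a comma-separated list of overlapped intervals.
#' @export
annotate_candidate_genes <- function(regions, gff_path) {
  genes <- read_gene_models(gff_path)$genes
  if (nrow(regions) == 0 || nrow(genes) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      regions = character()))
  hits <- lapply(seq_len(nrow(genes)), function(g) {
    sel <- regions$chrom == genes$chrom[g] &
      regions$start <= genes$end[g] & regions$end >= genes$start[g]
    which(sel)
  })
  keep <- lengths(hits) > 0
  data.frame(genes[keep, c("gene", "chrom", "start", "end")],
             regions = vapply(hits[keep], function(h)
               paste(sprintf("%s:%d-%d", regions$chrom[h], regions$start[h],
                             regions$end[h]), collapse = ","),
               character(1)),
             row.names = NULL)
}
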