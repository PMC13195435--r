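#' Per-individual heterozygosity and method-of-moments F_IS
#'
#' Expected homozygosity per site is 1 - 2p(1-p), with p the sample-wide
#' alternate-allele frequency over called genotypes (no small-sample
#' correction; the difference to the VCFtools `--het` estimator is
#' O(1/2n)). Per individual, sums run over that individual's called sites
#' and F = (O(hom) - E(hom)) / (N - E(hom)).
#'
#' @param gm a [geno_matrix()] (>= 2 samples).
#' @return data.frame(sample, pop, n_sites, o_hom, e_hom, het_rate, f_is);
#'   individuals with no called site get an `NA` row.
#' @export
per_individual_het_fis <- function(gm) {
  assert_that(length(gm$samples) >= 2, "need >= 2 samples")
  st <- site_allele_stats(gm)
  e_hom_site <- 1 - 2 * st$p * (1 - st$p)
  e_hom_site[is.nan(e_hom_site)] <- 0
  d <- gm$dosage
  called <- !is.na(d)
  n_sites <- colSums(called)
  o_hom <- colSums(d == 0L | d == 2L, na.rm = TRUE)
  e_hom <- colSums(called * e_hom_site)
  het_rate <- ifelse(n_sites > 0, (n_sites - o_hom) / n_sites, NA_real_)
  f_is <- ifelse(n_sites > 0 & (n_sites - e_hom) != 0,
                 (o_hom - e_hom) / (n_sites - e_hom), NA_real_)
  data.frame(sample = gm$samples, pop = unname(gm$pop[gm$samples]),
             n_sites = n_sites, o_hom = o_hom, e_hom = e_hom,
             het_rate = het_rate, f_is = f_is, row.names = NULL)
}

#' Runs of homozygosity
#'
#' Maximal runs of consecutive homozygous calls per chromosome, truncated
#' at every heterozygous call. Missing calls neither break a run nor count
#' toward its SNP tally. A run is kept when its span (first to last
#' homozygous SNP, inclusive) strictly exceeds `min_len` bp and it
#' contains at least `min_snps` homozygous SNPs.
#'
#' @param gm a position-sorted [geno_matrix()].
#' @param samples samples to scan (default all).
#' @param min_len minimum span in bp, exclusive (default 1 kb).
#' @param min_snps minimum homozygous SNP count, inclusive (default 50).
#' @return data.frame(sample, chrom, start, end, length, n_snps).
#' @export
detect_roh <- function(gm, samples = gm$samples, min_len = 1000,
                       min_snps = 50) {
  out <- vector("list", 0)
  chr_idx <- split(seq_len(nrow(gm$sites)), gm$sites$chrom)
  for (smp in samples) {
    d_all <- gm$dosage[, smp]
    for (chr in names(chr_idx)) {
      idx <- chr_idx[[chr]]
      d <- d_all[idx]
      pos <- gm$sites$pos[idx]
      ## run id increments at each het; missing keeps the current run open
      het <- !is.na(d) & d == 1L
      run_id <- cumsum(het)
      hom <- !is.na(d) & (d == 0L | d == 2L)
      if (!any(hom)) next
      hom_idx <- which(hom)
      r <- rle(run_id[hom_idx])
      n <- r$lengths
      last <- cumsum(n); first <- last - n + 1
      p1 <- pos[hom_idx[first]]; p2 <- pos[hom_idx[last]]
      span <- p2 - p1 + 1
      keep <- n >= min_snps & span > min_len
      if (any(keep))
        out[[length(out) + 1]] <- data.frame(
          sample = smp, chrom = chr, start = p1[keep], end = p2[keep],
          length = span[keep], n_snps = n[keep])
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      length = integer(), n_snps = integer()))
  do.call(rbind, out)
}

#' Classify ROH by length and compute F_ROH
#'
#' Segments of 1-100 kb are "short", segments over 100 kb "long"
#' (boundary inclusive to short). F_ROH is the summed segment length
#' divided by the genome length.
#'
#' @param segments output of [detect_roh()].
#' @param genome_length_bp assembly length used as the F_ROH denominator
#'   (default 786,920,000 bp, a 786.92 Mb shrub genome).
#' @param samples sample ids that were scanned; guarantees a (possibly
#'   zero) F_ROH row for ROH-free individuals.
#' @return list with `segments` (plus `length_class` column), `class_totals`
#'   (per sample x class bp) and `froh` (data.frame sample, total_roh_bp,
#'   f_roh).
#' @export
classify_and_froh <- function(segments, genome_length_bp = 786920000,
                              samples = unique(segments$sample)) {
  assert_that(genome_length_bp > 0, "genome_length_bp must be positive")
  segments$length_class <- ifelse(segments$length > 1e5, "long", "short")
  tot <- function(cls) {
    v <- stats::setNames(rep(0, length(samples)), samples)
    sel <- segments$length_class == cls
    if (any(sel)) {
      s <- tapply(segments$length[sel], segments$sample[sel], sum)
      v[names(s)] <- s
    }
    v
  }
  short_bp <- tot("short"); long_bp <- tot("long")
  total <- short_bp + long_bp
  list(segments = segments,
       class_totals = data.frame(sample = samples, short_bp = short_bp,
                                 long_bp = long_bp, row.names = NULL),
       froh = data.frame(sample = samples, total_roh_bp = total,
                         f_roh = total / genome_length_bp,
                         row.names = NULL))
}
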