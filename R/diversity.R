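#' Sliding-window frame
#'
#' Windows anchored at position 1 of each chromosome, advanced by `step`;
#' the terminal window is truncated at the chromosome end and keeps its
#' true bp span as denominator for per-bp statistics.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp (default 100 kb).
#' @param step step in bp (default 10 kb).
#' @return data.frame(chrom, start, end), 1-based inclusive.
#' @export
make_windows <- function(chrom_lengths, size = 1e5, step = 1e4) {
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(1, len, by = step)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + size - 1, len))
  })
  do.call(rbind, out)
}

## Sum `values` (and count `hits`) of sites falling in each window.
## Sites and windows must refer to the same chromosome naming.
window_sums <- function(chrom, pos, windows, values, hits = NULL) {
  if (is.null(hits)) hits <- rep(1L, length(pos))
  vs <- numeric(nrow(windows)); nv <- numeric(nrow(windows))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(chrom == chr)
    p <- pos[si]
    o <- order(p); p <- p[o]; si <- si[o]
    cv <- cumsum(values[si]); ch <- cumsum(hits[si])
    lo <- findInterval(windows$start[wi] - 1L, p)
    hi <- findInterval(windows$end[wi], p)
    vs[wi] <- ifelse(hi > 0, cv[pmax(hi, 1)], 0) - ifelse(lo > 0, cv[pmax(lo, 1)], 0)
    nv[wi] <- ifelse(hi > 0, ch[pmax(hi, 1)], 0) - ifelse(lo > 0, ch[pmax(lo, 1)], 0)
  }
  list(sum = vs, n = nv)
}

## Per-site unbiased pi within one population: (n/(n-1)) * 2p(1-p).
## Sites with < 2 called alleles get 0 and are not counted as variants.
site_pi <- function(gm, cols) {
  st <- site_allele_stats(gm, cols)
  pi <- ifelse(st$n >= 2, st$n / (st$n - 1) * 2 * st$p * (1 - st$p), 0)
  pi[is.na(pi)] <- 0
  list(pi = pi, seg = pi > 0, n_alleles = st$n, p = st$p)
}

#' Windowed nucleotide diversity
#'
#' Per-site pi = (n/(n-1)) 2p(1-p) with n the called allele count, summed
#' over variant sites in each window and divided by the window's bp span.
#'
#' @param gm a [geno_matrix()].
#' @param pop population label.
#' @param windows frame from [make_windows()].
#' @return data.frame(chrom, start, end, stat, pop, value, n_variants).
#' @export
windowed_pi <- function(gm, pop, windows) {
  cols <- pop_cols(gm, pop)
  sp <- site_pi(gm, cols)
  ws <- window_sums(gm$sites$chrom, gm$sites$pos, windows, sp$pi,
                    hits = as.integer(sp$seg))
  data.frame(windows, stat = "pi", pop = pop,
             value = ws$sum / (windows$end - windows$start + 1),
             n_variants = ws$n)
}

## Tajima (1989) constants for (possibly fractional) sample size n.
tajima_constants <- function(n) {
  ## For fractional n (harmonic-mean allele counts) interpolate the sums.
  hsum <- function(f, n) {
    k <- floor(n - 1)
    s <- if (k >= 1) sum(f(seq_len(k))) else 0
    frac <- (n - 1) - k
    if (frac > 0) s <- s + frac * f(k + 1)
    s
  }
  a1 <- hsum(function(i) 1 / i, n)
  a2 <- hsum(function(i) 1 / i^2, n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S-1)) with the standard
#' constants evaluated at the harmonic mean of per-site called allele
#' counts over the window's segregating sites. Windows with S = 0 (or
#' fewer than 3 called alleles) are `NA`.
#'
#' @inheritParams windowed_pi
#' @export
windowed_tajimas_d <- function(gm, pop, windows) {
  cols <- pop_cols(gm, pop)
  sp <- site_pi(gm, cols)
  seg <- sp$seg
  ws_pi <- window_sums(gm$sites$chrom, gm$sites$pos, windows, sp$pi,
                       hits = as.integer(seg))
  inv_n <- ifelse(seg, 1 / sp$n_alleles, 0)
  ws_n <- window_sums(gm$sites$chrom, gm$sites$pos, windows, inv_n)
  value <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    S <- ws_pi$n[w]
    if (S < 1) next
    n_harm <- S / ws_n$sum[w]
    if (n_harm < 3) next
    k <- tajima_constants(n_harm)
    theta_pi <- ws_pi$sum[w]
    theta_w <- S / k$a1
    vr <- k$e1 * S + k$e2 * S * (S - 1)
    if (vr <= 0) next
    value[w] <- (theta_pi - theta_w) / sqrt(vr)
  }
  data.frame(windows, stat = "tajimas_d", pop = pop, value = value,
             n_variants = ws_pi$n)
}

## Per-site Weir-Cockerham (1984) variance components for two populations.
## Returns a, b, c vectors (NA where undefined).
wc_components <- function(gm, colsA, colsB) {
  stat <- function(cols) {
    d <- gm$dosage[, cols, drop = FALSE]
    ni <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * ni)
    h <- rowSums(d == 1L, na.rm = TRUE) / ni
    list(n = ni, p = p, h = h)
  }
  A <- stat(colsA); B <- stat(colsB)
  ok <- A$n >= 1 & B$n >= 1 & (A$n + B$n) >= 3
  n1 <- A$n; n2 <- B$n
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * A$p + n2 * B$p) / (2 * nbar)
  s2 <- (n1 * (A$p - pbar)^2 + n2 * (B$p - pbar)^2) / nbar
  hbar <- (n1 * A$h + n2 * B$h) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst between two populations
#'
#' Window value is the ratio of summed variance components
#' sum(a) / sum(a + b + c) over the window's sites (may be slightly
#' negative; windows with no usable site are `NA`).
#'
#' @inheritParams windowed_pi
#' @param popA,popB population labels.
#' @export
windowed_fst <- function(gm, popA, popB, windows) {
  comp <- wc_components(gm, pop_cols(gm, popA), pop_cols(gm, popB))
  ok <- !is.na(comp$a)
  num <- ifelse(ok, comp$a, 0)
  den <- ifelse(ok, comp$a + comp$b + comp$c, 0)
  ws_num <- window_sums(gm$sites$chrom, gm$sites$pos, windows, num,
                        hits = as.integer(ok))
  ws_den <- window_sums(gm$sites$chrom, gm$sites$pos, windows, den)
  value <- ifelse(ws_den$sum != 0, ws_num$sum / ws_den$sum, NA_real_)
  data.frame(windows, stat = "fst", pop = paste(popA, popB, sep = "|"),
             value = value, n_variants = ws_num$n)
}

#' Genome-wide Weir-Cockerham Fst
#'
#' @inheritParams windowed_fst
#' @return list with `ratio_of_sums` (primary: summed components over all
#'   sites) and `mean_per_site` (mean of per-site theta, secondary).
#' @export
global_fst <- function(gm, popA, popB) {
  comp <- wc_components(gm, pop_cols(gm, popA), pop_cols(gm, popB))
  ok <- !is.na(comp$a)
  den <- comp$a + comp$b + comp$c
  list(ratio_of_sums = sum(comp$a[ok]) / sum(den[ok]),
       mean_per_site = mean((comp$a / den)[ok & den != 0], na.rm = TRUE))
}

#' Pairwise Fst matrix over all populations
#'
#' Ratio-of-sums Weir-Cockerham Fst for every population pair.
#'
#' @param gm a [geno_matrix()].
#' @export
fst_matrix <- function(gm) {
  pops <- unique(gm$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) >= 2) {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      f <- global_fst(gm, pops[i], pops[j])$ratio_of_sums
      m[i, j] <- m[j, i] <- f
    }
  }
  m
}

#' Private-allele counts per population
#'
#' An allele (REF or ALT) is private to a population when it is observed
#' there and unobserved in every other population.
#'
#' @param gm a [geno_matrix()].
#' @return named integer vector, one count per population.
#' @export
private_allele_counts <- function(gm) {
  pops <- unique(gm$pop)
  assert_that(length(pops) >= 2, "need >= 2 populations")
  alt_obs <- sapply(pops, function(pp) {
    d <- gm$dosage[, pop_cols(gm, pp), drop = FALSE]
    rowSums(d >= 1L, na.rm = TRUE) > 0
  })
  ref_obs <- sapply(pops, function(pp) {
    d <- gm$dosage[, pop_cols(gm, pp), drop = FALSE]
    rowSums(d <= 1L & !is.na(d), na.rm = TRUE) > 0
  })
  count_private <- function(obs) {
    one <- rowSums(obs) == 1
    if (!any(one)) return(stats::setNames(integer(length(pops)), pops))
    tab <- table(factor(colnames(obs)[apply(obs[one, , drop = FALSE], 1,
                                            which)], levels = pops))
    stats::setNames(as.integer(tab), pops)
  }
  count_private(alt_obs) + count_private(ref_obs)
}

#' LD decay curve
#'
#' Mean composite r^2 of all intra-chromosome SNP pairs separated by at
#' most `max_dist` bp, binned by distance.
#'
#' @param gm a position-sorted [geno_matrix()].
#' @param max_dist maximum pair separation (default 300 kb).
#' @param bin_width distance-bin width in bp.
#' @return data.frame(bin_start, bin_mid, mean_r2, n_pairs).
#' @export
ld_decay_curve <- function(gm, max_dist = 3e5, bin_width = 1e3) {
  breaks <- seq(0, max_dist, by = bin_width)
  sums <- numeric(length(breaks)); cnts <- integer(length(breaks))
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    p <- gm$sites$pos[idx]
    for (k in seq_along(idx)) {
      jmax <- findInterval(p[k] + max_dist, p)
      if (jmax <= k) next
      js <- (k + 1):jmax
      r <- suppressWarnings(
        stats::cor(gm$dosage[idx[k], ],
                   t(gm$dosage[idx[js], , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      bin <- findInterval(p[js] - p[k], breaks)
      ok <- !is.na(r2)
      if (any(ok)) {
        agg_s <- tapply(r2[ok], bin[ok], sum)
        agg_n <- tapply(rep(1L, sum(ok)), bin[ok], sum)
        bi <- as.integer(names(agg_s))
        sums[bi] <- sums[bi] + agg_s
        cnts[bi] <- cnts[bi] + agg_n
      }
    }
  }
  data.frame(bin_start = breaks,
             bin_mid = breaks + bin_width / 2,
             mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_),
             n_pairs = cnts)
}

#' Distance at which LD decays below a level
#'
#' First bin midpoint at which the (3-bin running mean) smoothed r^2 drops
#' below `level`.
#'
#' @param curve output of [ld_decay_curve()].
#' @param level r^2 query level (default 0.2).
#' @export
ld_decay_distance <- function(curve, level = 0.2) {
  ok <- !is.na(curve$mean_r2)
  x <- curve$bin_mid[ok]; y <- curve$mean_r2[ok]
  if (length(y) >= 3)
    y <- stats::filter(y, rep(1 / 3, 3), sides = 2) |> as.numeric() |>
      (\(v) ifelse(is.na(v), y, v))()
  hit <- which(y < level)
  if (length(hit) == 0) return(NA_real_)
  x[hit[1]]
}

#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the upper-triangle entries; the p-value
#' is the one-sided permutation probability (1 + #{r_perm >= r_obs}) /
#' (n_perm + 1), jointly permuting rows and columns of `d2`.
#'
#' @param d1,d2 symmetric matrices with identical labels and order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation stream.
#' @return list(r, p, n_perm).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  assert_that(all(dim(d1) == dim(d2)), "distance matrices differ in size")
  assert_that(isSymmetric(unname(d1)) && isSymmetric(unname(d2)),
              "distance matrices must be symmetric")
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  ut <- upper.tri(d1)
  x <- d1[ut]; y <- d2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm))
  r_obs <- stats::cor(x, y)
  n <- nrow(d1)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      o <- sample.int(n)
      stats::cor(x, d2[o, o][ut]) >= r_obs
    }, logical(1)))
  })
  list(r = r_obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

#' Great-circle distance matrix between sampling sites
#'
#' @param coords data.frame with columns `unit`, `lon`, `lat`.
#' @return symmetric matrix of distances in km.
#' @export
geo_distance_matrix <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(coords$unit, coords$unit))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d <- geosphere::distGeo(c(coords$lon[i], coords$lat[i]),
                            c(coords$lon[j], coords$lat[j])) / 1000
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Linearized Fst distance, Fst / (1 - Fst)
#'
#' @param fst symmetric Fst matrix (e.g. from [fst_matrix()]).
#' @export
linearized_fst <- function(fst) {
  out <- fst / (1 - fst)
  diag(out) <- 0
  out
}

#' Euclidean environmental distance on z-scored variables
#'
#' @param env data.frame of environmental variables, one row per unit;
#'   row identity taken from a `unit` column if present.
#' @export
env_distance_matrix <- function(env) {
  labels <- if ("unit" %in% names(env)) env$unit else rownames(env)
  num <- env[vapply(env, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("lon", "lat"))]
  z <- zscore(num)
  m <- as.matrix(stats::dist(z))
  dimnames(m) <- list(labels, labels)
  m
}
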