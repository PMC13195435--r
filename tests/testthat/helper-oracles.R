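# Independent textbook oracles, written as plain per-site loops so they
# share no code path with the package's vectorized implementations.

# Per-site pi by direct pairwise-mismatch counting over called alleles.
oracle_site_pi <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- 2 * length(d)
  if (n < 2) return(0)
  ones <- sum(d)
  ones * (n - ones) / choose(n, 2)
}

oracle_window_pi <- function(gm, pop, win) {
  cols <- which(gm$pop == pop)
  rows <- which(gm$sites$chrom == win$chrom & gm$sites$pos >= win$start &
                  gm$sites$pos <= win$end)
  tot <- 0
  for (r in rows) tot <- tot + oracle_site_pi(gm$dosage[r, cols])
  tot / (win$end - win$start + 1)
}

oracle_tajimas_d <- function(gm, pop, win) {
  cols <- which(gm$pop == pop)
  rows <- which(gm$sites$chrom == win$chrom & gm$sites$pos >= win$start &
                  gm$sites$pos <= win$end)
  seg <- c(); ns <- c(); theta_pi <- 0
  for (r in rows) {
    d <- gm$dosage[r, cols]; d <- d[!is.na(d)]
    n <- 2 * length(d)
    if (n < 2) next
    p <- sum(d) / n
    if (p > 0 && p < 1) {
      seg <- c(seg, r); ns <- c(ns, n)
      theta_pi <- theta_pi + oracle_site_pi(gm$dosage[r, cols])
    }
  }
  S <- length(seg)
  if (S < 1) return(NA_real_)
  n <- S / sum(1 / ns)  # harmonic mean of called allele counts
  if (n < 3) return(NA_real_)
  # interpolated harmonic-number sums for fractional n
  hs <- function(f) {
    k <- floor(n - 1)
    s <- if (k >= 1) sum(f(1:k)) else 0
    s + ((n - 1) - k) * f(k + 1)
  }
  a1 <- hs(function(i) 1 / i); a2 <- hs(function(i) 1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (theta_pi - S / a1) / sqrt(v)
}

# Weir & Cockerham (1984) theta by explicit per-site a/b/c loops.
oracle_wc_fst <- function(gm, popA, popB, win = NULL) {
  rows <- if (is.null(win)) seq_len(nrow(gm$sites)) else
    which(gm$sites$chrom == win$chrom & gm$sites$pos >= win$start &
            gm$sites$pos <= win$end)
  ca <- which(gm$pop == popA); cb <- which(gm$pop == popB)
  num <- den <- 0
  for (r in rows) {
    da <- gm$dosage[r, ca]; da <- da[!is.na(da)]
    db <- gm$dosage[r, cb]; db <- db[!is.na(db)]
    n1 <- length(da); n2 <- length(db)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    p1 <- sum(da) / (2 * n1); p2 <- sum(db) / (2 * n2)
    h1 <- sum(da == 1) / n1; h2 <- sum(db == 1) / n2
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Brute-force ROH: every maximal interval of SNP indices that contains no
# heterozygous call, >= min_snps homozygous calls and spans > min_len bp.
oracle_roh <- function(dosage, pos, min_len = 1000, min_snps = 50) {
  n <- length(dosage)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    seg <- dosage[i:j]
    if (any(!is.na(seg) & seg == 1)) next
    hom <- which(!is.na(seg) & (seg == 0 | seg == 2))
    if (length(hom) < min_snps) next
    # maximality: cannot extend left or right without hitting a het or end
    extL <- i > 1 && !(!is.na(dosage[i - 1]) && dosage[i - 1] == 1)
    extR <- j < n && !(!is.na(dosage[j + 1]) && dosage[j + 1] == 1)
    if (extL || extR) next
    p <- pos[i:j][hom]
    span <- p[length(p)] - p[1] + 1
    if (span <= min_len) next
    out[[length(out) + 1]] <- c(start = p[1], end = p[length(p)],
                                n_snps = length(hom))
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer()))
  m <- unique(do.call(rbind, out))
  data.frame(start = m[, "start"], end = m[, "end"], n_snps = m[, "n_snps"])
}

# Exact Hardy-Weinberg test (two-sided, conditional on allele counts).
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- n1 + 2 * n2
  probs <- vapply(seq(na %% 2, min(na, 2 * n - na), by = 2), function(h) {
    hom2 <- (na - h) / 2
    hom0 <- n - h - hom2
    exp(lchoose(n, hom0) + lchoose(n - hom0, h) - lchoose(2 * n, na) +
          h * log(2))
  }, numeric(1))
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n1]
  sum(probs[probs <= p_obs + 1e-12])
}
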