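#' Synthetic sky-island cohort configuration
#'
#' Defaults emulate a 7-population, 3-lineage design of ~20 diploids per
#' population: hierarchical Balding-Nichols divergence, an inbreeding
#' gradient peaking in the most recently diverged population (JK), four
#' variant effect classes with frequency suppression of deleterious and
#' loss-of-function alleles, a purging deficit of homozygous deleterious
#' genotypes in the inbred population, adaptive loci tracking a
#' precipitation-like gradient (bio18), and paired current/future climate
#' grids for three climate models under four emission scenarios.
#'
#' @param pops population labels, ordered south to north.
#' @param lineage_of named lineage assignment.
#' @param n_per_pop diploid individuals per population.
#' @param n_snps number of core SNPs (excluding filter-fodder records).
#' @param chrom_lengths named chromosome lengths (bp).
#' @param f_lineage,f_pop Balding-Nichols divergence of lineages from the
#'   ancestral pool and of populations from their lineage.
#' @param autozygosity named per-population target genome fraction in
#'   forced-homozygous tracts.
#' @param roh_scale mean tract length (bp) of the exponential tract-length
#'   distribution.
#' @param class_mix fractions of SNPs in classes SYN/TOL/DEL/LoF
#'   (remainder noncoding).
#' @param suppression multiplicative downweighting of ancestral derived
#'   frequency per class (purifying-selection surrogate).
#' @param purging_delta named per-population probability that a
#'   homozygous-DEL genotype is converted to a heterozygote.
#' @param n_adaptive number of environment-associated loci.
#' @param adaptive_slope logit shift of population derived frequency per
#'   standard deviation of the driving variable.
#' @param adaptive_var driving bioclim variable (default "bio18").
#' @param n_env number of bioclim-style variables (bio1..bioN).
#' @param miss_rate random genotype missingness.
#' @param gq_low_frac fraction of genotypes with GQ below 10.
#' @param n_fodder counts of deliberately filter-failing records
#'   (indel, multiallelic, low_qual, high_missing).
#' @param grid_dim current/future climate raster dimensions (cells).
#' @param scenario_shift named displacement magnitude per scenario (in
#'   units of each variable's spatial SD).
#' @param models climate-model labels.
#' @param annotate build the toy genome FASTA + GFF3 so that true effect
#'   classes are recoverable from sequence (set FALSE for speed when only
#'   truth classes are needed).
#' @param seed mandatory RNG seed; all randomness flows from it.
#' @export
synth_config <- function(
    pops = c("HDL", "WTS", "BJS", "JMS", "BHS", "SS", "JK"),
    lineage_of = c(HDL = "south", WTS = "central", BJS = "central",
                   JMS = "north", BHS = "north", SS = "north", JK = "north"),
    n_per_pop = 20,
    n_snps = 20000,
    chrom_lengths = c(chr1 = 6e6, chr2 = 6e6),
    f_lineage = 0.08,
    f_pop = 0.08,
    autozygosity = c(HDL = 0.15, WTS = 0.08, BJS = 0.12, JMS = 0.12,
                     BHS = 0.12, SS = 0.12, JK = 0.24),
    roh_scale = 5e5,
    class_mix = c(SYN = 0.20, TOL = 0.04, DEL = 0.10, LoF = 0.03),
    suppression = c(SYN = 1, TOL = 0.9, DEL = 0.5, LoF = 0.3),
    purging_delta = c(JK = 0.3),
    n_adaptive = 50,
    adaptive_slope = 5,
    adaptive_var = "bio18",
    n_env = 19,
    miss_rate = 0.005,
    gq_low_frac = 0.01,
    n_fodder = c(indel = 10, multiallelic = 10, low_qual = 10,
                 high_missing = 10),
    grid_dim = c(8, 8),
    scenario_shift = c(ssp126 = 0.5, ssp245 = 1, ssp370 = 1.5, ssp585 = 2),
    models = c("gcmA", "gcmB", "gcmC"),
    annotate = TRUE,
    seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(sum(class_mix) <= 1, "class fractions must sum to <= 1")
  assert_that(all(class_mix >= 0) && all(suppression >= 0 & suppression <= 1),
              "rates must lie in [0, 1]")
  if (length(f_pop) == 1) f_pop <- stats::setNames(rep(f_pop, length(pops)), pops)
  az <- stats::setNames(rep(0, length(pops)), pops)
  az[names(autozygosity)] <- autozygosity
  assert_that(all(az >= 0 & az < 0.9), "autozygosity targets must be in [0, 0.9)")
  delta <- stats::setNames(rep(0, length(pops)), pops)
  delta[names(purging_delta)] <- purging_delta
  assert_that(all(delta >= 0 & delta <= 1), "purging deltas must be in [0, 1]")
  structure(list(pops = pops, lineage_of = lineage_of[pops],
                 n_per_pop = n_per_pop, n_snps = n_snps,
                 chrom_lengths = chrom_lengths, f_lineage = f_lineage,
                 f_pop = f_pop, autozygosity = az, roh_scale = roh_scale,
                 class_mix = class_mix, suppression = suppression,
                 purging_delta = delta, n_adaptive = n_adaptive,
                 adaptive_slope = adaptive_slope, adaptive_var = adaptive_var,
                 n_env = n_env, miss_rate = miss_rate,
                 gq_low_frac = gq_low_frac, n_fodder = n_fodder,
                 grid_dim = grid_dim, scenario_shift = scenario_shift,
                 models = models, annotate = annotate, seed = seed),
            class = "synth_config")
}

## Coding-template codons: ref base and admissible alt bases at the SNP
## offset within the codon, chosen so every substitution realizes the
## intended class (GGA third base: 4-fold synonymous; GCA second base:
## 0-fold missense; TGG second base G>A: stop gain).
CLASS_TEMPLATE <- list(
  SYN = list(codon = "GGA", offset = 3L, ref = "A", alts = c("C", "G", "T")),
  TOL = list(codon = "GCA", offset = 2L, ref = "C", alts = c("A", "G", "T")),
  DEL = list(codon = "GCA", offset = 2L, ref = "C", alts = c("A", "G", "T")),
  LoF = list(codon = "TGG", offset = 2L, ref = "G", alts = "A"))

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Simulate a synthetic cohort with truth tables
#'
#' Generates genotypes under a hierarchical Balding-Nichols model
#' (ancestral derived-allele frequencies Uniform(0.05, 0.95), lineage and
#' population frequencies Beta-distributed around them), Hardy-Weinberg
#' within populations, then layers autozygosity tracts (forced
#' homozygosity along exponentially-sized segments), class-specific
#' frequency suppression, a homozygous-DEL purging deficit, and
#' environment-driven logit shifts at adaptive loci. Optionally builds a
#' toy genome (FASTA) and single-exon gene models (GFF3) in which every
#' coding SNP's true class is recoverable by translation, plus a
#' fabricated deleteriousness-score table (DEL < 0.5 <= TOL, some NA).
#'
#' @param cfg a [synth_config()].
#' @return list with `gm` ([geno_matrix()]), `env` (per-population
#'   bioclim table), `grids` (current grid + per model/scenario future
#'   grids), `truth` (snp / individual / tract / population tables and
#'   grid displacements), `scores` (deleteriousness table), and — when
#'   `cfg$annotate` — `fasta` / `gff` (file-writable strings via
#'   [write_fixture_bundle()]) as in-memory objects.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  pops <- cfg$pops
  n_pop <- length(pops)
  n_ind <- cfg$n_per_pop * n_pop
  samples <- paste0(rep(pops, each = cfg$n_per_pop), "_",
                    sprintf("%02d", sequence(rep(cfg$n_per_pop, n_pop))))
  pop_of <- stats::setNames(rep(pops, each = cfg$n_per_pop), samples)

  ## --- geography and environment -----------------------------------------
  lon <- seq(112.5, 116.5, length.out = n_pop) +
    stats::rnorm(n_pop, 0, 0.15)
  lat <- seq(36.5, 40.8, length.out = n_pop) + stats::rnorm(n_pop, 0, 0.1)
  env_coef <- make_env_coef(cfg$n_env)
  env_vals <- eval_env(env_coef, lon, lat)
  env <- data.frame(unit = pops, lon = lon, lat = lat, env_vals)

  ## --- SNP positions, classes, alleles -----------------------------------
  chrom_names <- names(cfg$chrom_lengths)
  n_per_chrom <- round(cfg$n_snps * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  n_per_chrom[length(n_per_chrom)] <-
    cfg$n_snps - sum(n_per_chrom[-length(n_per_chrom)])
  chrom <- rep(chrom_names, n_per_chrom)
  pos <- unlist(lapply(seq_along(chrom_names), function(k)
    sort(sample.int(cfg$chrom_lengths[k] - 400L, n_per_chrom[k])) + 200L))
  classes <- sample(c(names(cfg$class_mix), "noncoding"), cfg$n_snps,
                    replace = TRUE,
                    prob = c(cfg$class_mix, 1 - sum(cfg$class_mix)))
  ## coding SNPs need an isolated 90-bp gene footprint
  coding <- classes != "noncoding"
  if (any(coding)) {
    ## 90-bp genes sit within +/-61 bp of their SNP, so >130 bp clearance
    ## on both sides keeps gene footprints disjoint and SNP-free
    d_prev <- c(Inf, diff(pos))
    d_prev[c(1, cumsum(n_per_chrom)[-length(n_per_chrom)] + 1)] <- Inf
    d_next <- c(d_prev[-1], Inf)
    iso <- d_prev > 130 & d_next > 130
    classes[coding & !iso] <- "noncoding"
    coding <- classes != "noncoding"
  }
  strand <- rep(c("+", "-"), length.out = sum(coding))

  ## allele pair per SNP (ref = ancestral by construction)
  ref <- alt <- character(cfg$n_snps)
  tpl_off <- integer(cfg$n_snps)
  ncd <- which(!coding)
  ref[ncd] <- sample(c("A", "C", "G", "T"), length(ncd), replace = TRUE)
  alt[ncd] <- vapply(ref[ncd], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  ki <- 0
  for (i in which(coding)) {
    ki <- ki + 1
    tpl <- CLASS_TEMPLATE[[classes[i]]]
    ref_cod <- tpl$ref
    alt_cod <- if (length(tpl$alts) == 1) tpl$alts else sample(tpl$alts, 1)
    if (strand[ki] == "-") {
      ref[i] <- COMPLEMENT[[ref_cod]]; alt[i] <- COMPLEMENT[[alt_cod]]
    } else {
      ref[i] <- ref_cod; alt[i] <- alt_cod
    }
    tpl_off[i] <- tpl$offset
  }

  ## --- population allele frequencies -------------------------------------
  p_anc <- stats::runif(cfg$n_snps, 0.05, 0.95)
  supp <- rep(1, cfg$n_snps)
  for (k in names(cfg$suppression))
    supp[classes == k] <- cfg$suppression[[k]]
  p_eff <- pmax(p_anc * supp, 0.01)
  bn <- function(p, f) {
    if (f <= 0) return(p)
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  lineages <- unique(unname(cfg$lineage_of))
  p_lin <- sapply(lineages, function(l)
    pmin(pmax(bn(p_eff, cfg$f_lineage), 1e-4), 1 - 1e-4))
  p_pop <- sapply(pops, function(pp)
    pmin(pmax(bn(p_lin[, cfg$lineage_of[[pp]]], cfg$f_pop[[pp]]),
              1e-4), 1 - 1e-4))

  ## adaptive loci: logit-shift population frequency along the driver
  adaptive <- rep(FALSE, cfg$n_snps)
  slope <- rep(0, cfg$n_snps)
  if (cfg$n_adaptive > 0) {
    pool <- which(!coding)
    ad <- sample(pool, min(cfg$n_adaptive, length(pool)))
    adaptive[ad] <- TRUE
    ## clines need room to move: anchor adaptive loci at intermediate
    ## ancestral frequencies, then redraw their population frequencies
    p_anc[ad] <- stats::runif(length(ad), 0.35, 0.65)
    for (l in lineages)
      p_lin[ad, l] <- pmin(pmax(bn(p_anc[ad], cfg$f_lineage), 1e-4), 1 - 1e-4)
    for (pp in pops)
      p_pop[ad, pp] <- pmin(pmax(bn(p_lin[ad, cfg$lineage_of[[pp]]],
                                    cfg$f_pop[[pp]]), 1e-4), 1 - 1e-4)
    slope[ad] <- cfg$adaptive_slope * sample(c(-1, 1), length(ad),
                                             replace = TRUE)
    zdrv <- as.numeric(scale(env[[cfg$adaptive_var]]))
    for (j in seq_len(n_pop))
      p_pop[ad, j] <- stats::plogis(stats::qlogis(p_pop[ad, j]) +
                                      slope[ad] * zdrv[j])
  }

  ## --- genotypes ----------------------------------------------------------
  dosage <- matrix(0L, cfg$n_snps, n_ind)
  for (j in seq_len(n_pop)) {
    colsj <- which(pop_of == pops[j])
    dosage[, colsj] <- stats::rbinom(cfg$n_snps * length(colsj), 2,
                                     rep(p_pop[, j], length(colsj)))
  }

  ## --- autozygosity tracts ------------------------------------------------
  genome_bp <- sum(cfg$chrom_lengths)
  chrom_offset <- cumsum(c(0, n_per_chrom[-length(n_per_chrom)]))
  names(chrom_offset) <- chrom_names
  pos_by_chrom <- split(pos, chrom)[chrom_names]
  tracts <- list()
  realized_az <- stats::setNames(numeric(n_ind), samples)
  for (j in seq_len(n_ind)) {
    target <- cfg$autozygosity[[pop_of[j]]]
    if (target <= 0) next
    tr <- place_tracts(target * genome_bp, cfg$chrom_lengths, cfg$roh_scale)
    realized_az[j] <- sum(tr$end - tr$start + 1) / genome_bp
    if (nrow(tr) > 0) {
      tracts[[length(tracts) + 1]] <- data.frame(sample = samples[j], tr)
      for (k in seq_len(nrow(tr))) {
        pc <- pos_by_chrom[[tr$chrom[k]]]
        lo <- findInterval(tr$start[k] - 1L, pc) + 1L
        hi <- findInterval(tr$end[k], pc)
        if (hi < lo) next
        rows <- chrom_offset[[tr$chrom[k]]] + lo:hi
        het <- rows[dosage[rows, j] == 1L]
        if (length(het) > 0)
          dosage[het, j] <- 2L * stats::rbinom(length(het), 1, 0.5)
      }
    }
  }
  tracts <- if (length(tracts) > 0) do.call(rbind, tracts) else
    data.frame(sample = character(), chrom = character(),
               start = integer(), end = integer())

  ## --- purging: deficit of homozygous-DEL genotypes ----------------------
  del_rows <- which(classes == "DEL")
  for (pp in pops) {
    dd <- cfg$purging_delta[[pp]]
    if (dd <= 0 || length(del_rows) == 0) next
    colsj <- which(pop_of == pp)
    sub <- dosage[del_rows, colsj, drop = FALSE]
    hom <- which(sub == 2L)
    flip <- hom[stats::runif(length(hom)) < dd]
    sub[flip] <- 1L
    dosage[del_rows, colsj] <- sub
  }

  ## --- missingness, QUAL, DP/GQ ------------------------------------------
  if (cfg$miss_rate > 0) {
    na_idx <- which(stats::runif(length(dosage)) < cfg$miss_rate)
    dosage[na_idx] <- NA_integer_
  }
  qual <- round(stats::runif(cfg$n_snps, 60, 1500), 1)
  dp <- matrix(stats::rpois(cfg$n_snps * n_ind, 13) + 1L, cfg$n_snps, n_ind)
  gq <- matrix(99L, cfg$n_snps, n_ind)
  if (cfg$gq_low_frac > 0) {
    low <- which(stats::runif(length(gq)) < cfg$gq_low_frac)
    gq[low] <- sample(0:9, length(low), replace = TRUE)
  }

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      qual = qual, multiallelic = FALSE)
  truth_snp <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          class = classes, ancestral = ref,
                          adaptive = adaptive, slope = slope,
                          p_anc = p_anc, fodder = FALSE)

  ## --- filter-fodder records ----------------------------------------------
  fodder <- make_fodder(cfg, n_ind, taken = pos[chrom == chrom_names[1]])
  if (!is.null(fodder)) {
    sites <- rbind(sites, fodder$sites)
    dosage <- rbind(dosage, fodder$dosage)
    dp <- rbind(dp, matrix(13L, nrow(fodder$sites), n_ind))
    gq <- rbind(gq, matrix(99L, nrow(fodder$sites), n_ind))
    truth_snp <- rbind(truth_snp, fodder$truth)
  }
  o <- order(sites$chrom, sites$pos)
  truth_snp <- truth_snp[o, ]
  rownames(truth_snp) <- NULL
  gm <- geno_matrix(sites, dosage, samples, pop_of,
                    dp = dp, gq = gq)  # geno_matrix() re-sorts all slots

  ## --- deleteriousness scores ---------------------------------------------
  mis <- truth_snp$class %in% c("DEL", "TOL")
  score <- rep(NA_real_, nrow(truth_snp))
  score[truth_snp$class == "DEL"] <- stats::runif(sum(truth_snp$class == "DEL"), 0, 0.499)
  score[truth_snp$class == "TOL"] <- stats::runif(sum(truth_snp$class == "TOL"), 0.5, 1)
  na_mis <- which(mis)[stats::runif(sum(mis)) < 0.08]
  score[na_mis] <- NA_real_
  scores <- data.frame(chrom = truth_snp$chrom, pos = truth_snp$pos,
                       alt = truth_snp$alt, score = score,
                       confidence = ifelse(is.na(score) & mis, "low", "high"))

  ## --- toy annotation ------------------------------------------------------
  annotation <- NULL
  if (cfg$annotate)
    annotation <- build_toy_annotation(cfg, truth_snp, strand)

  ## --- climate grids -------------------------------------------------------
  grids <- make_climate_grids(cfg, env_coef, lon, lat)

  truth <- list(
    snp = truth_snp,
    individual = data.frame(sample = samples, pop = unname(pop_of),
                            target_autozygosity =
                              unname(cfg$autozygosity[pop_of]),
                            realized_autozygosity = unname(realized_az)),
    tracts = tracts,
    population = data.frame(pop = pops,
                            lineage = unname(cfg$lineage_of[pops]),
                            f_pop = unname(cfg$f_pop[pops]),
                            autozygosity = unname(cfg$autozygosity[pops]),
                            delta = unname(cfg$purging_delta[pops]),
                            lon = lon, lat = lat),
    grid_displacement = grids$displacement)

  list(gm = gm, env = env, grids = grids$grids, truth = truth,
       scores = scores, fasta = annotation$fasta, gff = annotation$gff,
       config = cfg)
}

## Smooth deterministic spatial fields: each variable is a random linear
## mix of a longitude ramp, a latitude ramp and a diagonal sine; the
## adaptive driver (bio18 by default) is a pure latitudinal
## precipitation-like gradient, and bio19 is made nearly collinear with
## bio18 to exercise the |r| < 0.8 selection rule.
make_env_coef <- function(n_env) {
  co <- matrix(stats::rnorm(3 * n_env), n_env, 3)
  rownames(co) <- paste0("bio", seq_len(n_env))
  if (n_env >= 18) co["bio18", ] <- c(0, 1, 0)
  if (n_env >= 19) co["bio19", ] <- c(0.05, 0.98, 0.05)
  co
}

eval_env <- function(coef, lon, lat) {
  g1 <- (lon - 114.5) / 2
  g2 <- (lat - 38.5) / 2
  g3 <- sin((lon + lat) / 2)
  vals <- sapply(rownames(coef), function(v)
    coef[v, 1] * g1 + coef[v, 2] * g2 + coef[v, 3] * g3)
  vals <- matrix(vals, nrow = length(lon),
                 dimnames = list(NULL, rownames(coef)))
  as.data.frame(vals)
}

## Non-overlapping exponential-length tracts totalling `target_bp`.
place_tracts <- function(target_bp, chrom_lengths, scale) {
  out <- list(); covered <- 0; tries <- 0
  while (covered < target_bp && tries < 500) {
    tries <- tries + 1
    chr <- sample(names(chrom_lengths), 1, prob = chrom_lengths)
    len <- min(ceiling(stats::rexp(1, 1 / scale)) + 1,
               ceiling(target_bp - covered))
    len <- min(len, chrom_lengths[[chr]])
    start <- sample.int(chrom_lengths[[chr]] - len + 1L, 1)
    end <- start + len - 1L
    clash <- any(vapply(out, function(t)
      t$chrom == chr && t$start <= end && t$end >= start, logical(1)))
    if (clash) next
    out[[length(out) + 1]] <- data.frame(chrom = chr, start = start,
                                         end = end)
    covered <- covered + len
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

make_fodder <- function(cfg, n_ind, taken = integer(0)) {
  nf <- cfg$n_fodder
  total <- sum(nf)
  if (is.null(nf) || total == 0) return(NULL)
  chr <- names(cfg$chrom_lengths)[1]
  cand <- setdiff(seq(50L, cfg$chrom_lengths[[1]] - 50L, by = 37L), taken)
  pos <- sort(sample(cand, total))
  kind <- rep(names(nf), nf)
  ref <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  alt[kind == "indel"] <- paste0(ref[kind == "indel"], "T")
  alt[kind == "multiallelic"] <- paste0(alt[kind == "multiallelic"], ",",
                                        ref[kind == "multiallelic"])
  qual <- round(stats::runif(total, 60, 1500), 1)
  qual[kind == "low_qual"] <- round(stats::runif(sum(kind == "low_qual"),
                                                 1, 29), 1)
  p <- stats::runif(total, 0.3, 0.7)
  dosage <- matrix(stats::rbinom(total * n_ind, 2, rep(p, n_ind)),
                   total, n_ind)
  hm <- kind == "high_missing"
  if (any(hm)) {
    sub <- dosage[hm, , drop = FALSE]
    sub[stats::runif(length(sub)) < 0.4] <- NA_integer_
    dosage[hm, ] <- sub
  }
  list(sites = data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                          qual = qual,
                          multiallelic = kind == "multiallelic"),
       dosage = dosage,
       truth = data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                          class = "noncoding", ancestral = ref,
                          adaptive = FALSE, slope = 0, p_anc = p,
                          fodder = TRUE))
}

## 30-codon single-exon gene around every coding SNP; the genome carries
## the gene sequence so translation recovers the true class.
build_toy_annotation <- function(cfg, truth_snp, strand) {
  bases <- c("A", "C", "G", "T")
  genome <- lapply(cfg$chrom_lengths, function(L)
    sample(bases, L, replace = TRUE))
  coding_idx <- which(truth_snp$class %in% names(CLASS_TEMPLATE) &
                        !truth_snp$fodder)
  gff <- character(0)
  gene_n <- 0
  for (w in seq_along(coding_idx)) {
    i <- coding_idx[w]
    tpl <- CLASS_TEMPLATE[[truth_snp$class[i]]]
    std <- strand[w]
    target_codon_i <- 10L  # 1-based codon index hosting the SNP
    cds_codons <- c("ATG",
                    sample(SENSE_CODONS, 28, replace = TRUE),
                    "TAA")
    cds_codons[target_codon_i] <- tpl$codon
    cds <- paste(cds_codons, collapse = "")
    ## index (1-based) of the SNP base within the CDS
    cds_i <- (target_codon_i - 1L) * 3L + tpl$offset
    chr <- truth_snp$chrom[i]; p <- truth_snp$pos[i]
    if (std == "+") {
      g0 <- p - cds_i + 1L
      seq_genomic <- strsplit(cds, "")[[1]]
    } else {
      g0 <- p - (90L - cds_i)
      seq_genomic <- rev(unname(COMPLEMENT[strsplit(cds, "")[[1]]]))
    }
    g1 <- g0 + 89L
    if (g0 < 1 || g1 > cfg$chrom_lengths[[chr]]) next
    genome[[chr]][g0:g1] <- seq_genomic
    gene_n <- gene_n + 1
    gid <- sprintf("gene%05d", gene_n)
    mid <- paste0(gid, ".t1")
    gff <- c(gff,
             sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chr, g0, g1, std, gid),
             sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", chr, g0, g1, std, mid, gid),
             sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s", chr, g0, g1, std, mid, mid))
  }
  ## genome must agree with every SNP's REF allele
  nc <- which(!(truth_snp$class %in% names(CLASS_TEMPLATE)))
  for (i in nc) {
    if (nchar(truth_snp$ref[i]) == 1)
      genome[[truth_snp$chrom[i]]][truth_snp$pos[i]] <- truth_snp$ref[i]
  }
  fasta <- Biostrings::DNAStringSet(
    vapply(genome, paste, character(1), collapse = ""))
  names(fasta) <- names(cfg$chrom_lengths)
  list(fasta = fasta,
       gff = c("##gff-version 3", gff))
}

make_climate_grids <- function(cfg, env_coef, pop_lon, pop_lat) {
  nx <- cfg$grid_dim[1]; ny <- cfg$grid_dim[2]
  lon <- seq(min(pop_lon) - 0.5, max(pop_lon) + 0.5, length.out = nx)
  lat <- seq(min(pop_lat) - 0.5, max(pop_lat) + 0.5, length.out = ny)
  cells <- expand.grid(lon = lon, lat = lat)
  cur_vals <- eval_env(env_coef, cells$lon, cells$lat)
  current <- climate_grid(cbind(cells, cur_vals), epoch = "current")
  spatial_sd <- apply(cur_vals, 2, stats::sd)
  spatial_sd[spatial_sd == 0] <- 1
  base_dir <- stats::rnorm(ncol(cur_vals))
  base_dir <- base_dir / sqrt(mean(base_dir^2))
  future <- list(); disp <- list()
  for (m in cfg$models) {
    dir_m <- base_dir + stats::rnorm(ncol(cur_vals), 0, 0.15)
    for (sc in names(cfg$scenario_shift)) {
      shift <- cfg$scenario_shift[[sc]] * dir_m * spatial_sd
      fut_vals <- sweep(as.matrix(cur_vals), 2, shift, "+")
      key <- paste(m, sc, sep = ".")
      future[[key]] <- climate_grid(cbind(cells, as.data.frame(fut_vals)),
                                    epoch = "future", scenario = sc,
                                    model = m)
      disp[[key]] <- data.frame(model = m, scenario = sc,
                                variable = colnames(cur_vals),
                                shift = shift, row.names = NULL)
    }
  }
  list(grids = c(list(current = current), future),
       displacement = do.call(rbind, disp))
}

#' Write a simulated cohort as an on-disk fixture bundle
#'
#' Writes VCF, popmap TSV, environment CSV, climate-grid CSVs, GFF3,
#' FASTA, deleteriousness-score TSV, a truth-table JSON and a manifest
#' (seed + per-file MD5). Re-running with the same seed reproduces
#' byte-identical text payloads.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the manifest, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop2(sprintf("directory %s is not empty (use force = TRUE)", dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_vcf(sim$gm, fp("cohort.vcf"))
  utils::write.table(data.frame(sample = sim$gm$samples,
                                population = unname(sim$gm$pop)),
                     fp("popmap.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(sim$env, fp("env.csv"), row.names = FALSE)
  for (g in names(sim$grids))
    utils::write.csv(as.data.frame(sim$grids[[g]]),
                     fp(sprintf("climate_%s.csv", g)), row.names = FALSE)
  utils::write.table(sim$scores, fp("scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$gff)) writeLines(sim$gff, fp("genes.gff3"))
  if (!is.null(sim$fasta))
    Biostrings::writeXStringSet(sim$fasta, fp("ref.fa"))
  jsonlite::write_json(sim$truth, fp("truth.json"), dataframe = "columns",
                       digits = NA)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(seed = sim$config$seed,
                   n_snps = sim$config$n_snps,
                   n_samples = length(sim$gm$samples),
                   md5 = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Population derived/alt allele-frequency table
#'
#' @param gm a [geno_matrix()].
#' @param snps optional subset of SNP ids ("chrom:pos").
#' @return populations x SNPs matrix of alt-allele frequencies.
#' @export
population_allele_freqs <- function(gm, snps = NULL) {
  ids <- paste(gm$sites$chrom, gm$sites$pos, sep = ":")
  rows <- if (is.null(snps)) seq_along(ids) else match(snps, ids)
  assert_that(!anyNA(rows), "unknown SNP ids requested")
  pops <- unique(gm$pop)
  out <- sapply(pops, function(pp) {
    st <- site_allele_stats(gm, pop_cols(gm, pp))
    st$p[rows]
  })
  out <- matrix(out, nrow = length(rows),
                dimnames = list(ids[rows], pops))
  t(out)
}
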