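test_that("polarization follows the strict majority-homozygote rule", {
  # 10 individuals, 8 hom-ref -> ancestral = ref, dosages unchanged
  d <- matrix(c(rep(0L, 8), 1L, 2L), 1, 10)
  gm <- tiny_gm(d, pos = 100)
  out <- polarize_to_derived(gm)
  expect_equal(out$polarization$status, "polarized")
  expect_identical(out$gm$dosage, gm$dosage)
  # 7 hom-alt -> ancestral = alt; with the reference-bias guard the site
  # is excluded, without it dosages recode 0<->2 and REF/ALT swap
  d2 <- matrix(c(rep(2L, 7), 1L, 1L, 0L), 1, 10)
  gm2 <- tiny_gm(d2, pos = 100, ref = "G", alt = "C")
  strict <- polarize_to_derived(gm2)
  expect_equal(strict$polarization$status, "excluded_nonref")
  expect_equal(nrow(strict$gm$sites), 0)
  loose <- polarize_to_derived(gm2, require_ref_ancestral = FALSE)
  expect_equal(unname(loose$gm$dosage[1, ]), c(rep(0L, 7), 1L, 1L, 2L))
  expect_equal(loose$gm$sites$ref, "C")
  expect_equal(loose$gm$sites$alt, "G")
  # 5 hom-ref / 5 hom-alt: "exceeding 50%" is strict -> tie exclusion
  d3 <- matrix(c(rep(0L, 5), rep(2L, 5)), 1, 10)
  expect_equal(polarize_to_derived(tiny_gm(d3))$polarization$status,
               "excluded_tie")
  expect_error(polarize_to_derived(gm, majority = 1.2), "majority")
})

test_that("polarization is an involution and not a frequency rule", {
  gm <- random_panel(17, n_samples = 20, n_snps = 150, miss_rate = 0.05)
  once <- polarize_to_derived(gm, require_ref_ancestral = FALSE)
  twice <- polarize_to_derived(once$gm, require_ref_ancestral = FALSE)
  expect_identical(once$gm$dosage, twice$gm$dosage)
  expect_identical(once$gm$sites$ref, twice$gm$sites$ref)
  # the rule counts homozygotes, it is not a frequency rule: a site with
  # derived frequency 0.4 polarizes while an all-het site with the same
  # ref/alt balance (frequency 0.5) is a tie
  d <- matrix(c(rep(0L, 6), 2L, 2L, 2L, 2L), 1, 10)
  pol <- polarize_to_derived(tiny_gm(d))
  expect_equal(pol$polarization$status, "polarized")
  expect_equal(mean(pol$gm$dosage) / 2, 0.4)
  d2 <- matrix(1L, 1, 10)
  expect_equal(polarize_to_derived(tiny_gm(d2))$polarization$status,
               "excluded_tie")
})

test_that("effect classification translates codons on both strands", {
  toy <- write_toy_annotation()
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1", "chr1"),
    pos = c(106L, 107L, 111L, 205L, 50L, 127L),
    ref = c("A", "C", "G", "C", "C", "G"),
    alt = c("G", "T", "C", "T", "A", "A"))
  eff <- classify_variant_effects(sites, toy$gff, toy$fasta)
  # AAA -> AAG both Lys
  expect_equal(eff$effect[1], "SYN")
  # CAA -> TAA stop gained
  expect_equal(eff$effect[2], "LoF")
  expect_equal(eff$subtype[2], "stop_gain")
  # GGA -> GCA Gly>Ala missense
  expect_equal(eff$effect[3], "MIS")
  # minus-strand gene: genomic C>T is coding G>A, TGG -> TAG stop
  expect_equal(eff$effect[4], "LoF")
  expect_equal(eff$codon_ref[4], "TGG")
  expect_equal(eff$codon_alt[4], "TAG")
  # outside any CDS
  expect_equal(eff$effect[5], "noncoding")
  # first base of the donor dinucleotide of g3's intron
  expect_equal(eff$effect[6], "LoF")
  expect_equal(eff$subtype[6], "splice")
})

test_that("effect classes agree with direct translation on random genes", {
  toy <- write_toy_annotation()
  gc <- Biostrings::GENETIC_CODE
  # every substitution at every position of the plus-strand gene
  cds <- "ATGAAACAAGGATAA"
  for (i in seq_len(nchar(cds))) {
    refb <- substr(cds, i, i)
    for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
      sites <- data.frame(chrom = "chr1", pos = 100L + i, ref = refb,
                          alt = altb)
      eff <- classify_variant_effects(sites, toy$gff, toy$fasta)
      codon_i <- (i - 1) %/% 3 + 1
      ref_cod <- substr(cds, (codon_i - 1) * 3 + 1, codon_i * 3)
      alt_cod <- ref_cod
      substr(alt_cod, (i - 1) %% 3 + 1, (i - 1) %% 3 + 1) <- altb
      want <- if (gc[[ref_cod]] == gc[[alt_cod]]) "SYN"
        else if (gc[[alt_cod]] == "*") "LoF"
        else if (gc[[ref_cod]] == "*") "LoF"
        else if (codon_i == 1) "LoF" else "MIS"  # start codon ATG
      expect_equal(eff$effect, want,
                   info = sprintf("pos %d %s>%s", 100L + i, refb, altb))
    }
  }
})

test_that("degeneracy annotation classifies 0/2/3/4-fold sites", {
  toy <- write_toy_annotation()
  deg <- annotate_degeneracy(toy$gff, toy$fasta)
  at <- function(chrom, pos) deg$fold[deg$chrom == chrom & deg$pos == pos]
  expect_equal(at("chr1", 112), 4L)  # GGA third base: all Gly
  expect_equal(at("chr1", 111), 0L)  # GGA second base: none Gly
  expect_equal(at("chr1", 106), 2L)  # AAA third base: AAG Lys only
  # minus-strand TGG codon, third base (genomic 203): TGC/TGT Cys, TGA *
  expect_equal(at("chr2", 204), 0L)
})

test_that("missense split honours the 0.5 cutoff and exclusions", {
  ann <- data.frame(chrom = "chr1", pos = 1:5,
                    effect = c("MIS", "MIS", "MIS", "MIS", "SYN"))
  scores <- data.frame(chrom = "chr1", pos = 1:5,
                       score = c(0.49, 0.5, NA, 0.7, 0.1),
                       confidence = c("high", "high", "high", "low", "high"))
  out <- split_missense_by_score(ann, scores)
  expect_equal(out$effect, c("DEL", "TOL", "MIS_excluded", "MIS_excluded",
                             "SYN"))
  scores$score[1] <- 1.2
  expect_error(split_missense_by_score(ann, scores), "\\[0, 1\\]")
})

test_that("load tallies count derived alleles by class and zygosity", {
  # 2 individuals; per-site class and dosages chosen for a hand tally
  cls <- c("SYN", "SYN", "SYN", "DEL", "DEL", "LoF", "TOL")
  d <- rbind(c(1L, 2L),   # SYN: het | hom
             c(2L, 0L),   # SYN: hom | -
             c(1L, 1L),   # SYN: het | het
             c(1L, 2L),   # DEL: het | hom
             c(0L, 2L),   # DEL: -   | hom
             c(2L, 1L),   # LoF: hom | het
             c(1L, 0L))   # TOL: het | -
  gm <- tiny_gm(d, pos = (1:7) * 10)
  ann <- data.frame(chrom = "chr1", pos = (1:7) * 10, effect = cls)
  out <- tally_load_ratios(gm, ann)
  expect_equal(out$syn_het, c(2L, 1L), ignore_attr = TRUE)
  expect_equal(out$syn_hom, c(1L, 1L), ignore_attr = TRUE)
  expect_equal(out$del_syn_het, c(1 / 2, 0 / 1))
  expect_equal(out$del_syn_hom, c(0 / 1, 2 / 1))
  expect_equal(out$lof_syn_hom, c(1 / 1, 0 / 1))
  # zero denominator -> undefined marker
  gm2 <- tiny_gm(matrix(c(0L, 1L), 1, 2), pos = 10)
  ann2 <- data.frame(chrom = "chr1", pos = 10, effect = "DEL")
  out2 <- tally_load_ratios(gm2, ann2)
  expect_true(all(is.na(out2$del_syn_het)))
  # total-SYN denominator variant
  out3 <- tally_load_ratios(gm, ann, denominator = "total_syn")
  expect_equal(out3$del_syn_hom, c(0 / 3, 2 / 2))
})

test_that("per-class counts conserve each individual's derived total", {
  gm <- random_panel(23, n_samples = 8, n_snps = 90, miss_rate = 0.05)
  cls <- sample(c("SYN", "TOL", "DEL", "LoF"), 90, replace = TRUE)
  ann <- data.frame(chrom = "chr1", pos = gm$sites$pos, effect = cls)
  out <- tally_load_ratios(gm, ann)
  carried <- colSums(gm$dosage >= 1, na.rm = TRUE)
  total <- out$syn_het + out$syn_hom + out$tol_het + out$tol_hom +
    out$del_het + out$del_hom + out$lof_het + out$lof_hom
  expect_equal(unname(total), unname(carried))
})

test_that("pi0/pi4 uses all annotated sites in the denominators", {
  toy <- write_toy_annotation()
  # polymorphism at the 4-fold site chr1:112 only -> ratio 0
  gm <- tiny_gm(matrix(c(1L, 1L), 1, 2), pos = 112)
  out <- pi0_pi4_ratio(gm, annotate_degeneracy(toy$gff, toy$fasta), "P1")
  expect_equal(out$ratio, 0)
  expect_gt(out$pi4, 0)
  # variation only at a 0-fold site -> pi4 = 0 -> undefined ratio
  gm2 <- tiny_gm(matrix(c(1L, 1L), 1, 2), pos = 111)
  out2 <- pi0_pi4_ratio(gm2, annotate_degeneracy(toy$gff, toy$fasta), "P1")
  expect_true(is.na(out2$ratio))
  # hand check: pi0 = site pi / number of 0-fold sites
  deg <- annotate_degeneracy(toy$gff, toy$fasta)
  expect_equal(out2$pi0, (2 / 3) / sum(deg$fold == 0))
})

test_that("purging deficit depresses hom DEL/SYN in the purged population", {
  cfg <- synth_config(seed = 77, n_snps = 20000, annotate = FALSE,
                      purging_delta = c(JK = 0.3))
  sim <- simulate_cohort(cfg)
  pol <- polarize_to_derived(sim$gm)
  ann <- data.frame(chrom = sim$truth$snp$chrom, pos = sim$truth$snp$pos,
                    effect = sim$truth$snp$class)
  pm <- attr(tally_load_ratios(pol$gm, ann), "population_means")
  r <- stats::setNames(pm$del_syn_hom, pm$pop)
  expect_equal(names(which.min(r)), "JK")
  expect_lt(r[["JK"]], stats::median(r[names(r) != "JK"]) * 0.9)
})
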