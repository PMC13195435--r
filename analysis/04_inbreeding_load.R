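#!/usr/bin/env Rscript
# Stage 4 — inbreeding and genetic load: per-individual heterozygosity
# and F_IS; runs of homozygosity (> 1 kb, >= 50 SNPs, no hets) classified
# short (1-100 kb) vs long (> 100 kb) with F_ROH; derived-allele
# polarization (majority-homozygote rule, reference ancestral); effect
# classes from the gene models; DEL/TOL split at score 0.5; per-zygosity
# DEL/SYN and LoF/SYN ratios; pi0/pi4.

library(skypurge)

fx <- "results/fixtures"
filt <- read_vcf("results/filtered.vcf", file.path(fx, "popmap.tsv"))
genome_bp <- 4e6  # two 2-Mb chromosomes

hf <- per_individual_het_fis(filt)
cat("Population means of heterozygosity and F_IS:\n")
print(aggregate(cbind(het_rate, f_is) ~ pop, hf, function(x)
  round(mean(x), 3)))

segs <- detect_roh(filt, min_len = 1000, min_snps = 50)
cls <- classify_and_froh(segs, genome_length_bp = genome_bp,
                         samples = filt$samples)
froh_pop <- tapply(cls$froh$f_roh, filt$pop[cls$froh$sample], mean)
cat("Mean F_ROH per population:\n"); print(round(froh_pop, 3))
cat(sprintf("ROH: %d segments (%d long > 100 kb)\n", nrow(cls$segments),
            sum(cls$segments$length_class == "long")))

pol <- polarize_to_derived(filt)
cat(sprintf("Polarization: %d/%d sites kept (ref ancestral)\n",
            nrow(pol$gm$sites), nrow(filt$sites)))
eff <- classify_variant_effects(pol$gm$sites, file.path(fx, "genes.gff3"),
                                file.path(fx, "ref.fa"))
scores <- read.table(file.path(fx, "scores.tsv"), header = TRUE, sep = "\t")
ann <- split_missense_by_score(eff, scores)
cat("Effect classes:\n"); print(table(ann$effect))

loads <- tally_load_ratios(pol$gm, ann)
pm <- attr(loads, "population_means")
cat("Population mean load ratios:\n")
print(cbind(pop = pm$pop, round(pm[-1], 4)))

deg <- annotate_degeneracy(file.path(fx, "genes.gff3"),
                           file.path(fx, "ref.fa"))
p04 <- sapply(unique(filt$pop), function(p)
  pi0_pi4_ratio(filt, deg, p)$ratio)
cat("pi0/pi4 per population:\n"); print(round(p04, 3))

write.csv(hf, "results/het_fis.csv", row.names = FALSE)
write.table(cls$segments, "results/roh_segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(cls$froh, "results/froh.csv", row.names = FALSE)
write.csv(loads, "results/load_counts.csv", row.names = FALSE)
write.csv(data.frame(pop = names(p04), pi0_pi4 = p04),
          "results/pi0_pi4.csv", row.names = FALSE)
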