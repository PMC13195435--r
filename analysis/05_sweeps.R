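#!/usr/bin/env Rscript
# Stage 5 — selective-sweep scan between the southern edge population
# (HDL) and the northeastern edge population (JK): windows in the top 5%
# of both Weir-Cockerham Fst and ln(pi_HDL / pi_JK), merged into regions
# and annotated with overlapping genes.

library(skypurge)

fx <- "results/fixtures"
filt <- read_vcf("results/filtered.vcf", file.path(fx, "popmap.tsv"))
chrom_lengths <- tapply(filt$sites$pos, filt$sites$chrom, max)
w <- make_windows(chrom_lengths)

fst <- windowed_fst(filt, "HDL", "JK", w)
ratio <- ln_pi_ratio(windowed_pi(filt, "HDL", w), windowed_pi(filt, "JK", w))
sw <- joint_outlier_windows(fst, ratio, q = 0.95)

cat(sprintf("Windows: %d jointly defined; thresholds Fst >= %.3f, ln ratio >= %.3f\n",
            nrow(sw$windows), sw$thresholds[["fst"]],
            sw$thresholds[["ln_pi_ratio"]]))
cat(sprintf("Candidates: %d windows -> %d merged regions\n",
            sum(sw$windows$candidate), nrow(sw$regions)))

genes <- annotate_candidate_genes(sw$regions, file.path(fx, "genes.gff3"))
cat(sprintf("Genes overlapping candidate regions: %d\n", nrow(genes)))

write.table(sw$windows, "results/sweep_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sw$regions, "results/sweep_regions.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(genes, "results/sweep_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
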