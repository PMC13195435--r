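#!/usr/bin/env Rscript
# Stage 2 — VCFtools-style site refinement (mean depth >= 3, GQ >= 10,
# QUAL >= 30, MAF >= 0.05, biallelic SNPs only, call rate >= 0.8) and
# PLINK-style LD pruning (100-SNP windows, step 1, r^2 <= 0.5).

library(skypurge)

fx <- "results/fixtures"
gm <- read_vcf(file.path(fx, "cohort.vcf"), file.path(fx, "popmap.tsv"))
filt <- apply_site_filters(gm)
log <- attr(filt, "filter_log")

cat(sprintf("Filtering: %d -> %d sites (%d genotypes GQ-masked)\n",
            log$n_in, log$n_out, log$n_gq_masked_genotypes))
print(log$removed)

pruned <- ld_prune(filt)
cat(sprintf("LD pruning: %d -> %d sites\n", nrow(filt$sites),
            nrow(pruned$sites)))

dir.create("results", showWarnings = FALSE)
write_vcf(filt, "results/filtered.vcf")
write.table(pruned$sites[c("chrom", "pos")], "results/pruned_sites.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(log, "results/filter_log.json", auto_unbox = TRUE,
                     pretty = TRUE)
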