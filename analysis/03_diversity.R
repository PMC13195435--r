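#!/usr/bin/env Rscript
# Stage 3 — windowed diversity and differentiation: per-population pi and
# Tajima's D in 100-kb/10-kb sliding windows, pairwise Weir-Cockerham
# Fst, private alleles (on the LD-pruned set), LD decay, and Mantel
# isolation-by-distance / isolation-by-environment tests.

library(skypurge)

fx <- "results/fixtures"
filt <- read_vcf("results/filtered.vcf", file.path(fx, "popmap.tsv"))
pruned_pos <- read.table("results/pruned_sites.tsv", header = TRUE)
pruned <- filt[paste(filt$sites$chrom, filt$sites$pos) %in%
                 paste(pruned_pos$chrom, pruned_pos$pos), ]
chrom_lengths <- tapply(filt$sites$pos, filt$sites$chrom, max)
w <- make_windows(chrom_lengths)
pops <- unique(filt$pop)

win_tabs <- list()
for (p in pops) {
  win_tabs[[paste0("pi_", p)]] <- windowed_pi(filt, p, w)
  win_tabs[[paste0("D_", p)]] <- windowed_tajimas_d(filt, p, w)
}
pi_mean <- sapply(pops, function(p) mean(win_tabs[[paste0("pi_", p)]]$value))
cat("Mean windowed pi per population:\n")
print(round(sort(pi_mean), 6))

fst <- fst_matrix(filt)
cat(sprintf("Mean pairwise Fst: %.3f (range %.3f-%.3f)\n",
            mean(fst[upper.tri(fst)]), min(fst[upper.tri(fst)]),
            max(fst[upper.tri(fst)])))

priv <- private_allele_counts(pruned)
cat("Private alleles:\n"); print(priv)

decay <- ld_decay_curve(filt, max_dist = 3e5, bin_width = 2e3)
cat(sprintf("LD decay below r2 = 0.2 at ~%s bp\n",
            format(ld_decay_distance(decay, 0.2))))

env <- read.csv(file.path(fx, "env.csv"))
geo <- geo_distance_matrix(env)
gen <- linearized_fst(fst)[env$unit, env$unit]
ibd <- mantel_test(geo, gen, n_perm = 999, seed = 42)
ibe <- mantel_test(env_distance_matrix(env), gen, n_perm = 999, seed = 42)
cat(sprintf("Mantel IBD: r = %.3f, p = %.3f; IBE: r = %.3f, p = %.3f\n",
            ibd$r, ibd$p, ibe$r, ibe$p))

all_windows <- do.call(rbind, win_tabs)
write.table(all_windows, "results/window_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(fst, "results/fst_matrix.csv")
write.csv(data.frame(pop = names(priv), private_alleles = priv),
          "results/private_alleles.csv", row.names = FALSE)
write.csv(decay, "results/ld_decay.csv", row.names = FALSE)
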