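# In-code fixtures shared across test files.

# Quick genotype-matrix builder: dosage is sites x samples.
tiny_gm <- function(dosage, pos = seq_len(nrow(dosage)) * 100,
                    chrom = "chr1", pops = NULL, ref = "A", alt = "T",
                    qual = 100) {
  dosage <- as.matrix(dosage)
  ns <- ncol(dosage)
  samples <- paste0("s", seq_len(ns))
  colnames(dosage) <- samples
  if (is.null(pops)) pops <- rep("P1", ns)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(ref, nrow(dosage)),
                      alt = rep_len(alt, nrow(dosage)),
                      qual = qual, multiallelic = FALSE)
  geno_matrix(sites, dosage, samples, stats::setNames(pops, samples))
}

# Random diploid panel with two populations and optional missingness.
random_panel <- function(seed, n_samples = 20, n_snps = 200,
                         miss_rate = 0.05, n_pops = 2) {
  set.seed(seed)
  p <- runif(n_snps, 0.05, 0.95)
  d <- matrix(rbinom(n_snps * n_samples, 2, rep(p, n_samples)),
              n_snps, n_samples)
  if (miss_rate > 0)
    d[runif(length(d)) < miss_rate] <- NA_integer_
  pops <- rep(paste0("P", seq_len(n_pops)), length.out = n_samples)
  tiny_gm(d, pos = sort(sample.int(1e6, n_snps)), pops = sort(pops))
}

# One-gene annotation written to temp files; returns file paths.
# Plus-strand gene: ATG AAA CAA GGA TAA at 101..115 of a 300-bp chromosome.
# Minus-strand gene on chr2: coding sequence ATG CCC GCA TGG TAA, stored
# reverse-complemented at 201..215.
write_toy_annotation <- function(dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  plus_cds <- "ATGAAACAAGGATAA"
  minus_cds <- "ATGCCCGCATGGTAA"
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  chr1 <- paste0(strrep("C", 100), plus_cds, strrep("G", 185))
  chr2 <- paste0(strrep("A", 200), rc(minus_cds), strrep("G", 85))
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", chr1, ">chr2", chr2), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t115\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t101\t115\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttoy\tCDS\t101\t115\t.\t+\t0\tID=g1.cds;Parent=g1.t1",
    "chr1\ttoy\tgene\t121\t145\t.\t+\t.\tID=g3",
    "chr1\ttoy\tmRNA\t121\t145\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr1\ttoy\tCDS\t121\t126\t.\t+\t0\tID=g3.cds1;Parent=g3.t1",
    "chr1\ttoy\tCDS\t137\t145\t.\t+\t0\tID=g3.cds2;Parent=g3.t1",
    "chr2\ttoy\tgene\t201\t215\t.\t-\t.\tID=g2",
    "chr2\ttoy\tmRNA\t201\t215\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr2\ttoy\tCDS\t201\t215\t.\t-\t0\tID=g2.cds;Parent=g2.t1"), gff)
  list(fasta = fa, gff = gff)
}

# Small cohort configs used by several files (kept cheap).
small_cfg <- function(seed, ...) {
  synth_config(seed = seed, n_snps = 2000,
               chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
               annotate = FALSE, ...)
}
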