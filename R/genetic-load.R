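#' Polarize genotypes to derived-allele dosages
#'
#' The ancestral state at a site is the allele for which more than
#' `majority` of individuals are homozygous; sites with no
#' majority-homozygote class are excluded (`excluded_tie`). When the
#' inferred ancestral allele is the ALT allele, dosages are recoded to
#' derived counts (d' = 2 - d) and the REF/ALT columns are swapped so the
#' ALT column always names the derived allele — which makes polarization
#' an involution. With `require_ref_ancestral` (reference-bias
#' mitigation), sites whose ancestral allele differs from the reference
#' are excluded instead (`excluded_nonref`).
#'
#' @param gm a [geno_matrix()].
#' @param majority strict homozygote-fraction threshold in (0, 1);
#'   default 0.5.
#' @param require_ref_ancestral exclude sites with non-reference ancestral
#'   allele (default TRUE).
#' @param denominator count homozygotes among `"called"` genotypes
#'   (default) or among all `"total"` samples.
#' @return list with `gm` (polarized sites only) and `polarization`
#'   (data.frame chrom, pos, ancestral, derived, status).
#' @export
polarize_to_derived <- function(gm, majority = 0.5,
                                require_ref_ancestral = TRUE,
                                denominator = c("called", "total")) {
  assert_that(majority > 0 && majority < 1, "majority must be in (0, 1)")
  denominator <- match.arg(denominator)
  d <- gm$dosage
  n0 <- rowSums(d == 0L, na.rm = TRUE)
  n2 <- rowSums(d == 2L, na.rm = TRUE)
  denom <- if (denominator == "called") rowSums(!is.na(d))
           else rep(length(gm$samples), nrow(d))
  anc_ref <- denom > 0 & n0 / denom > majority
  anc_alt <- denom > 0 & n2 / denom > majority
  status <- rep("excluded_tie", nrow(d))
  status[anc_ref] <- "polarized"
  status[anc_alt] <- if (require_ref_ancestral) "excluded_nonref" else "polarized"
  ancestral <- ifelse(anc_ref, gm$sites$ref,
                      ifelse(anc_alt, gm$sites$alt, NA_character_))
  derived <- ifelse(anc_ref, gm$sites$alt,
                    ifelse(anc_alt, gm$sites$ref, NA_character_))
  pol <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    ancestral = ancestral, derived = derived,
                    status = status)
  keep <- status == "polarized"
  out <- gm[keep, ]
  flip <- anc_alt[keep]
  if (any(flip)) {
    out$dosage[flip, ] <- 2L - out$dosage[flip, , drop = FALSE]
    tmp <- out$sites$ref[flip]
    out$sites$ref[flip] <- out$sites$alt[flip]
    out$sites$alt[flip] <- tmp
  }
  list(gm = out, polarization = pol)
}

## ---- gene-model plumbing ------------------------------------------------

gff_attr <- function(attributes, key) {
  m <- regexec(paste0("(^|;)\\s*", key, "=([^;]+)"), attributes)
  vapply(regmatches(attributes, m),
         function(g) if (length(g) >= 3) g[3] else NA_character_,
         character(1))
}

## Parse GFF3 into gene spans and per-transcript CDS segment tables.
read_gene_models <- function(gff_path) {
  g <- ape::read.gff(gff_path)
  cds <- g[g$type == "CDS", ]
  genes <- g[g$type == "gene", ]
  tx_of <- gff_attr(as.character(cds$attributes), "Parent")
  tx_of[is.na(tx_of)] <- gff_attr(as.character(cds$attributes), "ID")[is.na(tx_of)]
  cds$tx <- tx_of
  gene_id <- gff_attr(as.character(genes$attributes), "ID")
  list(cds = cds,
       genes = data.frame(gene = gene_id,
                          chrom = as.character(genes$seqid),
                          start = genes$start, end = genes$end,
                          strand = as.character(genes$strand)))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify SNP effects from gene models and a reference sequence
#'
#' Maps each SNP falling in annotated CDS to its codon, translates the
#' reference and alternate codons (reverse-complemented for minus-strand
#' transcripts) and classifies: same amino acid -> `SYN`; different ->
#' `MIS`; stop gain, stop loss or start loss -> `LoF`. SNPs in the
#' canonical 2-bp donor/acceptor dinucleotides of annotated introns are
#' `LoF` (splice). Everything else is `noncoding`. A SNP hit by several
#' transcripts keeps its most severe call (LoF > MIS > SYN).
#'
#' @param sites data.frame with chrom, pos, ref, alt (1-bp alleles).
#' @param gff_path GFF3 file with gene and phased CDS features.
#' @param fasta_path reference FASTA covering all CDS.
#' @return data.frame(chrom, pos, effect, subtype, gene, codon_ref,
#'   codon_alt, aa_ref, aa_alt).
#' @export
classify_variant_effects <- function(sites, gff_path, fasta_path) {
  models <- read_gene_models(gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  key <- paste(sites$chrom, sites$pos)
  ## non-SNP records (indels, multiallelics) stay noncoding
  snp_ok <- sites$ref %in% names(COMPLEMENT) & sites$alt %in% names(COMPLEMENT)
  eff <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    effect = "noncoding", subtype = NA_character_,
                    gene = NA_character_, codon_ref = NA_character_,
                    codon_alt = NA_character_, aa_ref = NA_character_,
                    aa_alt = NA_character_)
  severity <- c(noncoding = 0, SYN = 1, MIS = 2, LoF = 3)
  gc <- Biostrings::GENETIC_CODE
  record <- function(i, effect, subtype, tx, cr = NA, ca = NA,
                     ar = NA, aa = NA) {
    if (severity[[effect]] > severity[[eff$effect[i]]]) {
      eff$effect[i] <<- effect; eff$subtype[i] <<- subtype
      eff$gene[i] <<- tx
      eff$codon_ref[i] <<- cr; eff$codon_alt[i] <<- ca
      eff$aa_ref[i] <<- ar; eff$aa_alt[i] <<- aa
    }
  }
  for (tx in unique(models$cds$tx)) {
    seg <- models$cds[models$cds$tx == tx, ]
    chr <- as.character(seg$seqid[1])
    if (!chr %in% names(seqs)) stop2(sprintf("chromosome %s not in FASTA", chr))
    minus <- as.character(seg$strand[1]) == "-"
    seg <- seg[order(seg$start, decreasing = minus), ]
    chrom_seq <- as.character(seqs[[chr]])
    ## genomic positions in translation order
    cds_pos <- unlist(lapply(seq_len(nrow(seg)), function(k) {
      p <- seg$start[k]:seg$end[k]
      if (minus) rev(p) else p
    }))
    phase <- suppressWarnings(as.integer(as.character(seg$phase[1])))
    if (!is.na(phase) && phase > 0) cds_pos <- cds_pos[-seq_len(phase)]
    if (length(cds_pos) %% 3 != 0) {
      warning(sprintf("CDS length of %s not divisible by 3; skipped", tx),
              call. = FALSE)
      next
    }
    assert_that(max(cds_pos) <= nchar(chrom_seq),
                sprintf("CDS of %s exceeds FASTA bounds", tx))
    ## splice dinucleotides of internal introns
    if (nrow(seg) > 1) {
      by_start <- seg[order(seg$start), ]
      for (k in seq_len(nrow(by_start) - 1)) {
        intron <- c(by_start$end[k] + 1, by_start$start[k + 1] - 1)
        if (intron[2] - intron[1] + 1 >= 4) {
          edge <- c(intron[1], intron[1] + 1, intron[2] - 1, intron[2])
          hits <- which(key %in% paste(chr, edge))
          for (i in hits) record(i, "LoF", "splice", tx)
        }
      }
    }
    ## coding SNPs
    hit <- match(sites$pos, cds_pos)
    hit[sites$chrom != chr | !snp_ok] <- NA
    for (i in which(!is.na(hit))) {
      j <- hit[i]
      codon_i <- (j - 1) %/% 3
      within <- (j - 1) %% 3 + 1
      pos3 <- cds_pos[codon_i * 3 + 1:3]
      bases <- substring(chrom_seq, pos3, pos3)
      if (minus) bases <- unname(COMPLEMENT[bases])
      ref_base <- if (minus) COMPLEMENT[[sites$ref[i]]] else sites$ref[i]
      alt_base <- if (minus) COMPLEMENT[[sites$alt[i]]] else sites$alt[i]
      if (bases[within] != ref_base) {
        warning(sprintf("REF mismatch at %s:%d in %s; site skipped",
                        chr, sites$pos[i], tx), call. = FALSE)
        next
      }
      codon_ref <- paste(bases, collapse = "")
      bases_alt <- bases; bases_alt[within] <- alt_base
      codon_alt <- paste(bases_alt, collapse = "")
      aa_ref <- gc[[codon_ref]]; aa_alt <- gc[[codon_alt]]
      cls <- if (aa_ref == aa_alt) c("SYN", "synonymous")
        else if (aa_alt == "*") c("LoF", "stop_gain")
        else if (aa_ref == "*") c("LoF", "stop_loss")
        else if (codon_i == 0 && codon_ref == "ATG") c("LoF", "start_loss")
        else c("MIS", "missense")
      record(i, cls[1], cls[2], tx, codon_ref, codon_alt, aa_ref, aa_alt)
    }
  }
  eff
}

#' Codon degeneracy of every CDS position
#'
#' Classifies each coding genomic position by how many of the three
#' alternative bases preserve the encoded amino acid: none -> 0-fold, one
#' -> 2-fold, two -> 3-fold, all three -> 4-fold.
#'
#' @inheritParams classify_variant_effects
#' @return data.frame(chrom, pos, fold, gene).
#' @export
annotate_degeneracy <- function(gff_path, fasta_path) {
  models <- read_gene_models(gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  gc <- Biostrings::GENETIC_CODE
  bases4 <- c("A", "C", "G", "T")
  out <- list()
  for (tx in unique(models$cds$tx)) {
    seg <- models$cds[models$cds$tx == tx, ]
    chr <- as.character(seg$seqid[1])
    minus <- as.character(seg$strand[1]) == "-"
    seg <- seg[order(seg$start, decreasing = minus), ]
    chrom_seq <- as.character(seqs[[chr]])
    cds_pos <- unlist(lapply(seq_len(nrow(seg)), function(k) {
      p <- seg$start[k]:seg$end[k]
      if (minus) rev(p) else p
    }))
    phase <- suppressWarnings(as.integer(as.character(seg$phase[1])))
    if (!is.na(phase) && phase > 0) cds_pos <- cds_pos[-seq_len(phase)]
    if (length(cds_pos) %% 3 != 0) next
    n_codon <- length(cds_pos) / 3
    fold <- integer(length(cds_pos))
    for (ci in seq_len(n_codon)) {
      pos3 <- cds_pos[(ci - 1) * 3 + 1:3]
      bases <- substring(chrom_seq, pos3, pos3)
      if (minus) bases <- unname(COMPLEMENT[bases])
      aa0 <- gc[[paste(bases, collapse = "")]]
      for (w in 1:3) {
        alts <- setdiff(bases4, bases[w])
        nsyn <- sum(vapply(alts, function(b) {
          bb <- bases; bb[w] <- b
          gc[[paste(bb, collapse = "")]] == aa0
        }, logical(1)))
        fold[(ci - 1) * 3 + w] <- c(0L, 2L, 3L, 4L)[nsyn + 1]
      }
    }
    out[[tx]] <- data.frame(chrom = chr, pos = cds_pos, fold = fold,
                            gene = tx)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ## a position shared by transcripts keeps its first annotation
  res[!duplicated(paste(res$chrom, res$pos)), ]
}

#' Split missense calls into deleterious vs tolerated
#'
#' Applies an external per-site deleteriousness score (SIFT-style, in
#' [0, 1]): `MIS` sites with score < `cutoff` become `DEL`, score >=
#' `cutoff` become `TOL`; missing or low-confidence scores are excluded
#' from load tallies (`MIS_excluded`).
#'
#' @param ann output of [classify_variant_effects()].
#' @param scores data.frame(chrom, pos, score, [confidence]).
#' @param cutoff score threshold (default 0.5).
#' @export
split_missense_by_score <- function(ann, scores, cutoff = 0.5) {
  assert_that(all(is.na(scores$score) | (scores$score >= 0 & scores$score <= 1)),
              "scores must lie in [0, 1]")
  i <- match(paste(ann$chrom, ann$pos), paste(scores$chrom, scores$pos))
  sc <- scores$score[i]
  lowconf <- if ("confidence" %in% names(scores))
    !is.na(scores$confidence[i]) & scores$confidence[i] == "low" else FALSE
  mis <- ann$effect == "MIS"
  ann$effect[mis & !is.na(sc) & !lowconf & sc < cutoff] <- "DEL"
  ann$effect[mis & !is.na(sc) & !lowconf & sc >= cutoff] <- "TOL"
  ann$effect[mis & (is.na(sc) | lowconf)] <- "MIS_excluded"
  ann$score <- sc
  ann
}

#' Per-individual derived-allele load tallies and ratios
#'
#' Counts derived alleles per effect class and zygosity (het: dosage 1,
#' hom: dosage 2) on a polarized genotype matrix, then forms
#' zygosity-matched ratios (hom DEL / hom SYN etc.). With
#' `denominator = "total_syn"` the ratio denominator is the individual's
#' total SYN count instead.
#'
#' @param gm polarized [geno_matrix()] (from [polarize_to_derived()]).
#' @param ann effect annotation with final classes (after
#'   [split_missense_by_score()]).
#' @param denominator `"matched"` (default) or `"total_syn"`.
#' @return data.frame, one row per sample, with per-class het/hom counts,
#'   the four ratios and population labels; attribute `population_means`
#'   holds per-population mean ratios.
#' @export
tally_load_ratios <- function(gm, ann, denominator = c("matched", "total_syn")) {
  denominator <- match.arg(denominator)
  i <- match(paste(gm$sites$chrom, gm$sites$pos), paste(ann$chrom, ann$pos))
  cls <- ann$effect[i]
  out <- data.frame(sample = gm$samples, pop = unname(gm$pop[gm$samples]))
  for (k in c("SYN", "TOL", "DEL", "LoF")) {
    rows <- which(!is.na(cls) & cls == k)
    d <- gm$dosage[rows, , drop = FALSE]
    out[[paste0(tolower(k), "_het")]] <- colSums(d == 1L, na.rm = TRUE)
    out[[paste0(tolower(k), "_hom")]] <- colSums(d == 2L, na.rm = TRUE)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  syn_total <- out$syn_het + out$syn_hom
  den_het <- if (denominator == "matched") out$syn_het else syn_total
  den_hom <- if (denominator == "matched") out$syn_hom else syn_total
  out$del_syn_het <- ratio(out$del_het, den_het)
  out$del_syn_hom <- ratio(out$del_hom, den_hom)
  out$lof_syn_het <- ratio(out$lof_het, den_het)
  out$lof_syn_hom <- ratio(out$lof_hom, den_hom)
  pm <- stats::aggregate(
    out[c("del_syn_het", "del_syn_hom", "lof_syn_het", "lof_syn_hom")],
    by = list(pop = out$pop), FUN = mean, na.rm = TRUE)
  attr(out, "population_means") <- pm
  out
}

#' Diversity at 0-fold vs 4-fold degenerate sites
#'
#' Mean per-site pi over all annotated 0-fold positions and, separately,
#' all 4-fold positions (monomorphic positions contribute 0 but stay in
#' the denominators), plus their ratio pi0/pi4 — a purifying-selection
#' summary (lower = stronger).
#'
#' @param gm a [geno_matrix()].
#' @param degeneracy output of [annotate_degeneracy()].
#' @param pop population label.
#' @return list(pi0, pi4, ratio, n0_sites, n4_sites).
#' @export
pi0_pi4_ratio <- function(gm, degeneracy, pop) {
  cols <- pop_cols(gm, pop)
  sp <- site_pi(gm, cols)
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  mean_class <- function(fold) {
    sel <- degeneracy$fold == fold
    n_sites <- sum(sel)
    if (n_sites == 0) return(list(pi = NA_real_, n = 0))
    i <- match(paste(degeneracy$chrom[sel], degeneracy$pos[sel]), key_gm)
    list(pi = sum(sp$pi[i[!is.na(i)]]) / n_sites, n = n_sites)
  }
  p0 <- mean_class(0L); p4 <- mean_class(4L)
  ratio <- if (!is.na(p4$pi) && p4$pi > 0) p0$pi / p4$pi else NA_real_
  list(pi0 = p0$pi, pi4 = p4$pi, ratio = ratio,
       n0_sites = p0$n, n4_sites = p4$n)
}
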