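# Genetic diversity (expected heterozygosity) and genetic load
# (frequency-weighted nonsynonymous/synonymous ratio) for arbitrary
# pools of individuals.

#' Alternate-allele frequencies for a pool of individuals
#'
#' Missing genotypes are excluded per SNP from the frequency denominator
#' (no imputation): p = sum(dosages over called individuals) /
#' (2 * number of called individuals). A SNP with zero called alleles in
#' the pool gets `p = NA` and is excluded from downstream means.
#'
#' @param g A [genotype_matrix].
#' @param individuals Character vector of individual IDs to pool, or
#'   `NULL` for all individuals.
#' @return Data frame with columns `snp_id`, `p` (alternate-allele
#'   frequency, `NA` when no alleles were called) and `n_alleles`
#'   (number of called alleles, i.e. 2 x called individuals).
#' @export
allele_frequencies <- function(g, individuals = NULL) {
  d <- g$dosages
  if (!is.null(individuals)) {
    if (length(individuals) == 0L) stopf("empty individual subset")
    unknown <- setdiff(individuals, rownames(d))
    if (length(unknown)) stopf("unknown individual(s): %s",
                               paste(unknown, collapse = ", "))
    d <- d[individuals, , drop = FALSE]
  }
  called <- colSums(!is.na(d))
  n_alleles <- 2L * called
  p <- ifelse(n_alleles > 0L, colSums(d, na.rm = TRUE) / n_alleles, NA_real_)
  data.frame(snp_id = colnames(d), p = as.numeric(p),
             n_alleles = as.integer(n_alleles), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Genetic diversity as mean expected heterozygosity
#'
#' GD is the mean of He = 2p(1-p) across all SNPs with at least one
#' called allele in the pool. SNPs monomorphic in the pool contribute
#' He = 0 to the mean, so GD is a per-genotyped-site average over the
#' whole SNP panel and stays comparable across pools of the same panel.
#'
#' @param freqs Frequency table from [allele_frequencies()].
#' @return GD, a number in `[0, 0.5]`.
#' @export
expected_heterozygosity <- function(freqs) {
  p <- freqs$p[!is.na(freqs$p)]
  if (length(p) == 0L) stopf("no SNPs with called alleles in this pool")
  mean(2 * p * (1 - p))
}

#' Genetic load as the frequency-weighted Pn/Ps ratio
#'
#' Counts the SNPs segregating in the pool (0 < p < 1) in the
#' NONSYNONYMOUS (Pn) and SYNONYMOUS (Ps) classes and their mean
#' alternate-allele frequencies (fn, fs), and returns
#' GL = (Pn * fn) / (Ps * fs). OTHER-class and unannotated SNPs are
#' ignored. Equivalently, GL is the ratio of the summed alternate-allele
#' frequencies of segregating nonsynonymous vs. synonymous SNPs.
#'
#' @param freqs Frequency table from [allele_frequencies()].
#' @param annotation Annotation table from [read_annotation()] (columns
#'   `snp_id`, `functional_class`).
#' @return List with elements `gl`, `pn`, `ps`, `fn`, `fs`.
#' @export
genetic_load <- function(freqs, annotation) {
  cls <- annotation$functional_class[match(freqs$snp_id, annotation$snp_id)]
  cls[is.na(cls)] <- "OTHER"
  seg <- !is.na(freqs$p) & freqs$p > 0 & freqs$p < 1
  p_n <- freqs$p[seg & cls == "NONSYNONYMOUS"]
  p_s <- freqs$p[seg & cls == "SYNONYMOUS"]
  pn <- length(p_n)
  ps <- length(p_s)
  if (ps == 0L) {
    stopf("genetic load undefined: no segregating synonymous SNPs in this pool")
  }
  fn <- if (pn > 0L) mean(p_n) else 0
  fs <- mean(p_s)
  if (fs <= 0) stopf("genetic load undefined: mean synonymous frequency is zero")
  list(gl = (pn * fn) / (ps * fs), pn = pn, ps = ps, fn = fn, fs = fs)
}

#' Ratio of genetic diversity to genetic load
#'
#' The selection score for seed-source sets: higher means more pooled
#' diversity per unit deleterious burden.
#'
#' @param gd Genetic diversity (He), non-negative.
#' @param gl Genetic load, strictly positive.
#' @return `gd / gl`.
#' @export
gd_gl_ratio <- function(gd, gl) {
  if (!is.finite(gl) || gl <= 0) stopf("genetic load must be > 0, got %s", gl)
  if (!is.finite(gd) || gd < 0) stopf("genetic diversity must be >= 0, got %s", gd)
  gd / gl
}

# Core scorer shared by diversity_load_score() and score_sets(): takes a
# frequency vector aligned with a functional-class vector.
.score_from_freqs <- function(p, cls) {
  usable <- !is.na(p)
  if (!any(usable)) stopf("no SNPs with called alleles in this pool")
  gd <- mean(2 * p[usable] * (1 - p[usable]))
  seg <- usable & p > 0 & p < 1
  p_n <- p[seg & cls == "NONSYNONYMOUS"]
  p_s <- p[seg & cls == "SYNONYMOUS"]
  pn <- length(p_n)
  ps <- length(p_s)
  if (ps == 0L || sum(p_s) <= 0) {
    stopf("genetic load undefined: no segregating synonymous SNPs in this pool")
  }
  # (Pn * fn) / (Ps * fs) with fn, fs the class means = ratio of class sums
  gl <- sum(p_n) / sum(p_s)
  list(gd = gd, gl = gl, ratio = gd_gl_ratio(gd, gl),
       pn = pn, ps = ps, n_snps_used = sum(usable))
}

#' Full diversity/load score for one pool of individuals
#'
#' Convenience wrapper computing GD, GL and GD:GL from a genotype matrix,
#' an individual subset and an annotation table in one call.
#'
#' @inheritParams allele_frequencies
#' @param annotation Annotation table from [read_annotation()].
#' @return List with `gd`, `gl`, `ratio`, `pn`, `ps`, `n_snps_used`.
#' @export
diversity_load_score <- function(g, annotation, individuals = NULL) {
  freqs <- allele_frequencies(g, individuals)
  cls <- annotation$functional_class[match(freqs$snp_id, annotation$snp_id)]
  cls[is.na(cls)] <- "OTHER"
  .score_from_freqs(freqs$p, cls)
}
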