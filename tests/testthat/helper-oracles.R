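# Independent brute-force oracles and small in-code fixture builders.
# These recompute everything naively from raw dosages so the tests stay
# independent of the package's vectorized paths.

# Naive per-SNP diversity/load recomputation with explicit loops.
oracle_score <- function(dosages, classes) {
  n_snp <- ncol(dosages)
  p <- rep(NA_real_, n_snp)
  for (j in seq_len(n_snp)) {
    x <- dosages[, j]
    x <- x[!is.na(x)]
    if (length(x) > 0) p[j] <- sum(x) / (2 * length(x))
  }
  usable <- !is.na(p)
  gd <- mean(sapply(which(usable), function(j) 2 * p[j] * (1 - p[j])))
  seg <- usable & p > 0 & p < 1
  pn_idx <- which(seg & classes == "NONSYNONYMOUS")
  ps_idx <- which(seg & classes == "SYNONYMOUS")
  pn <- length(pn_idx)
  ps <- length(ps_idx)
  fn <- if (pn > 0) mean(p[pn_idx]) else 0
  fs <- if (ps > 0) mean(p[ps_idx]) else NA_real_
  gl <- (pn * fn) / (ps * fs)
  list(gd = gd, gl = gl, ratio = gd / gl, pn = pn, ps = ps)
}

# Expected value of the plug-in heterozygosity estimator under the
# Balding-Nichols model: numeric integration over the ancestral Beta of
# E[2p(1-p) | pbar] = 2 pbar (1-pbar) (1-F), times the binomial
# finite-sample factor (1 - 1/(2n)) for the frequency estimated from
# 2n called alleles.
bn_expected_het <- function(beta_a, beta_b, fst, n_ind) {
  inner <- stats::integrate(function(pb) {
    2 * pb * (1 - pb) * stats::dbeta(pb, beta_a, beta_b)
  }, 0, 1)$value
  inner * (1 - fst) * (1 - 1 / (2 * n_ind))
}

# Random small genotype panel with labelled populations, for property
# loops. Frequencies are uniform so monomorphic and fixed sites occur.
random_panel <- function(n_pops = 3, n_per_pop = 4, n_snps = 8,
                         missing_rate = 0.1) {
  pops <- paste0("Q", seq_len(n_pops))
  inds <- as.vector(sapply(pops, function(p) paste0(p, "_", seq_len(n_per_pop))))
  d <- matrix(NA_integer_, length(inds), n_snps,
              dimnames = list(inds, sprintf("chr1:%d:A:G", seq_len(n_snps) * 5)))
  for (i in seq_len(n_pops)) {
    p <- runif(n_snps)
    rows <- ((i - 1) * n_per_pop + 1):(i * n_per_pop)
    d[rows, ] <- matrix(rbinom(n_per_pop * n_snps, 2, rep(p, each = n_per_pop)),
                        nrow = n_per_pop)
  }
  d[runif(length(d)) < missing_rate] <- NA_integer_
  classes <- sample(c("NONSYNONYMOUS", "SYNONYMOUS", "OTHER"), n_snps,
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
  # guarantee a segregating SNP in both load classes (true of any real
  # exome panel) so GD:GL is defined for every pooled subset
  j_s <- which(classes == "SYNONYMOUS")[1]
  if (is.na(j_s)) { classes[1] <- "SYNONYMOUS"; j_s <- 1 }
  j_n <- which(classes == "NONSYNONYMOUS")[1]
  if (is.na(j_n)) { classes[2] <- "NONSYNONYMOUS"; j_n <- 2 }
  for (i in seq_len(n_pops)) d[(i - 1) * n_per_pop + 1, c(j_s, j_n)] <- 1L
  list(genotypes = genotype_matrix(d, setNames(rep(pops, each = n_per_pop), inds)),
       annotation = data.frame(snp_id = colnames(d), effect = "x",
                               functional_class = classes,
                               stringsAsFactors = FALSE),
       classes = classes)
}

extdata <- function(f) system.file("extdata", f, package = "seedopt")
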