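# Synthetic genotype panels (Balding-Nichols drift model with a
# deleterious-frequency inflation knob) and plot-structured field-trial
# trait tables, so every pipeline stage is testable without any
# external data.

#' Configuration for the Balding-Nichols genotype simulator
#'
#' Ancestral alternate-allele frequencies are drawn per locus from
#' `Beta(beta_a, beta_b)`; each population's frequency then drifts as
#' `Beta(pbar * (1-F)/F, (1-pbar) * (1-F)/F)` (the Balding-Nichols
#' model, with per-population Fst-like parameter `F`). Nonsynonymous
#' loci get their population frequency replaced by
#' `min(lambda * p, 0.5)` — a minimal frequency-inflation mechanism that
#' differentiates populations in genetic load while keeping deleterious
#' variants at intermediate frequency (drift load, not fixation).
#' Genotypes are `Binomial(2, p)` dosages with uniform missingness.
#'
#' @param k Number of populations.
#' @param n_per_pop Individuals per population.
#' @param l_nonsyn,l_syn,l_other Locus counts per functional class.
#' @param beta_a,beta_b Ancestral-frequency Beta shape parameters.
#' @param fst Per-population drift parameter(s) in (0, 1); recycled to
#'   length `k`.
#' @param lambda Per-population nonsynonymous frequency inflation(s)
#'   (>= 1); recycled to length `k`.
#' @param missing_rate Probability a genotype call is missing.
#' @param seed Integer seed.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(k = 23L, n_per_pop = 6L,
                              l_nonsyn = 2000L, l_syn = 2000L, l_other = 1000L,
                              beta_a = 0.4, beta_b = 1.6,
                              fst = seq(0.05, 0.25, length.out = k),
                              lambda = seq(1, 1.5, length.out = k),
                              missing_rate = 0.05, seed = 1L) {
  stopifnot(k >= 1, n_per_pop >= 1, l_nonsyn >= 1, l_syn >= 1, l_other >= 1)
  if (beta_a <= 0 || beta_b <= 0) stopf("Beta shape parameters must be > 0")
  fst <- rep_len(fst, k)
  lambda <- rep_len(lambda, k)
  if (any(fst <= 0 | fst >= 1)) stopf("drift F must lie in (0, 1)")
  if (any(lambda < 1)) stopf("inflation lambda must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing rate must be in [0, 1)")
  structure(list(k = as.integer(k), n_per_pop = as.integer(n_per_pop),
                 l_nonsyn = as.integer(l_nonsyn), l_syn = as.integer(l_syn),
                 l_other = as.integer(l_other),
                 beta_a = beta_a, beta_b = beta_b, fst = fst, lambda = lambda,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "genome_sim_config")
}

#' Simulate a genotype panel under drift and load differentiation
#'
#' @param cfg A [genome_sim_config()].
#' @return List with `genotypes` (a [genotype_matrix]), `annotation`
#'   (data frame as from [read_annotation()]), `pop_map` (data frame
#'   `individual`, `population`), and two calibration outputs: `p_anc`
#'   (the latent ancestral frequencies) and `latent_freqs` (the k x L
#'   matrix of post-drift, post-inflation population frequencies the
#'   genotypes were drawn from).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  with_seed(cfg$seed, {
    l_total <- cfg$l_nonsyn + cfg$l_syn + cfg$l_other
    classes <- rep(c("NONSYNONYMOUS", "SYNONYMOUS", "OTHER"),
                   times = c(cfg$l_nonsyn, cfg$l_syn, cfg$l_other))
    effect <- c(NONSYNONYMOUS = "missense_variant",
                SYNONYMOUS = "synonymous_variant",
                OTHER = "intergenic_region")[classes]
    ref <- sample(c("A", "C", "G", "T"), l_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    snp_key <- paste("chr1", seq_len(l_total) * 10L, ref, alt, sep = ":")

    p_anc <- stats::rbeta(l_total, cfg$beta_a, cfg$beta_b)
    pops <- sprintf("P%02d", seq_len(cfg$k))
    inds <- as.vector(vapply(pops, function(p)
      sprintf("%s_I%d", p, seq_len(cfg$n_per_pop)), character(cfg$n_per_pop)))
    pop_of <- stats::setNames(rep(pops, each = cfg$n_per_pop), inds)

    d <- matrix(NA_integer_, nrow = length(inds), ncol = l_total,
                dimnames = list(inds, snp_key))
    is_nonsyn <- classes == "NONSYNONYMOUS"
    latent <- matrix(NA_real_, nrow = cfg$k, ncol = l_total,
                     dimnames = list(pops, snp_key))
    for (i in seq_len(cfg$k)) {
      theta <- (1 - cfg$fst[i]) / cfg$fst[i]
      p_pop <- stats::rbeta(l_total, p_anc * theta, (1 - p_anc) * theta)
      p_pop[is_nonsyn] <- pmin(cfg$lambda[i] * p_pop[is_nonsyn], 0.5)
      latent[i, ] <- p_pop
      rows <- which(pop_of == pops[i])
      geno <- stats::rbinom(length(rows) * l_total, 2L,
                            rep(p_pop, each = length(rows)))
      d[rows, ] <- matrix(geno, nrow = length(rows))
    }
    if (cfg$missing_rate > 0) {
      d[stats::runif(length(d)) < cfg$missing_rate] <- NA_integer_
    }
    ann <- data.frame(snp_id = snp_key, effect = unname(effect),
                      functional_class = classes, stringsAsFactors = FALSE)
    list(genotypes = genotype_matrix(d, pop_of),
         annotation = ann,
         pop_map = data.frame(individual = inds,
                              population = unname(pop_of[inds]),
                              stringsAsFactors = FALSE),
         p_anc = stats::setNames(p_anc, snp_key),
         latent_freqs = latent)
  })
}

#' Configuration for the field-trial trait simulator
#'
#' Emulates a plot-structured monitoring design: single-source circular
#' plots of `seedlings_per_plot` plants, `plots_per_source` replicate
#' plots per source within each site. Each seedling survives with its
#' source's survival probability; surviving seedlings get
#' `height = mu_s + g + e` with `g ~ N(0, V_G)`, `e ~ N(0, V_E)` and
#' `V_G = h2/(1-h2) * v_e`, so the within-source genetic fraction of
#' phenotypic variance equals the target broad-sense heritability.
#'
#' @param design Data frame with one row per site x source and columns
#'   `site`, `source`, `mean_cm` (> 0) and `survival` (in `[0, 1]`).
#' @param h2 Target broad-sense heritability in `[0, 1)`.
#' @param v_e Residual (environmental) variance in cm^2.
#' @param plots_per_source Replicate plots per source within a site.
#' @param seedlings_per_plot Seedlings planted per plot.
#' @param seed Integer seed.
#' @return A `trial_sim_config` list.
#' @export
trial_sim_config <- function(design, h2 = 0.3962, v_e = 1.2,
                             plots_per_source = 5L, seedlings_per_plot = 40L,
                             seed = 1L) {
  need <- c("site", "source", "mean_cm", "survival")
  miss <- setdiff(need, names(design))
  if (length(miss)) stopf("design is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(design$mean_cm <= 0)) stopf("trait means must be > 0")
  if (any(design$survival < 0 | design$survival > 1)) {
    stopf("survival probabilities must lie in [0, 1]")
  }
  if (h2 < 0 || h2 >= 1) stopf("target H^2 must lie in [0, 1)")
  if (v_e < 0) stopf("residual variance must be >= 0")
  stopifnot(plots_per_source >= 1, seedlings_per_plot >= 1)
  structure(list(design = design, h2 = h2, v_e = v_e,
                 plots_per_source = as.integer(plots_per_source),
                 seedlings_per_plot = as.integer(seedlings_per_plot),
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Simulate a seedling monitoring table
#'
#' @param cfg A [trial_sim_config()].
#' @return A `trait_table` data frame (`site`, `source`, `plot`,
#'   `height_cm`, `alive`); dead seedlings have missing height. The
#'   latent genetic and environmental deviations are attached as the
#'   `"latent"` attribute (data frame with columns `g` and `e`) for
#'   calibration checks.
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  v_g <- if (cfg$h2 > 0) cfg$h2 / (1 - cfg$h2) * cfg$v_e else 0
  with_seed(cfg$seed, {
    rows <- list()
    for (r in seq_len(nrow(cfg$design))) {
      site <- cfg$design$site[r]
      src <- cfg$design$source[r]
      for (pl in seq_len(cfg$plots_per_source)) {
        n <- cfg$seedlings_per_plot
        alive <- stats::runif(n) < cfg$design$survival[r]
        g <- stats::rnorm(n, 0, sqrt(v_g))
        e <- stats::rnorm(n, 0, sqrt(cfg$v_e))
        h <- cfg$design$mean_cm[r] + g + e
        h[!alive] <- NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, source = src,
          plot = sprintf("%s_%s_plot%02d", site, src, pl),
          height_cm = h, alive = alive, g = g, e = e,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    latent <- out[, c("g", "e")]
    out <- out[, c("site", "source", "plot", "height_cm", "alive")]
    rownames(out) <- NULL
    attr(out, "latent") <- latent
    class(out) <- c("trait_table", "data.frame")
    out
  })
}

#' Write a self-contained synthetic fixture data set
#'
#' Generates a genotype panel and field trial under a named preset and
#' writes `genotypes.vcf`, `annotation.tsv`, `population_map.tsv`,
#' `traits.csv` and `config.yaml` into `out_dir`. Output is byte-stable
#' for a given seed. The `tiny` preset is a seconds-scale smoke panel;
#' `paper_like` emulates a realistic candidate panel: 23 populations of
#' 6 individuals, a 5000-SNP exome-style panel split into
#' nonsynonymous/synonymous/other classes, heterogeneous drift and load
#' inflation, and a 4-source field trial with heritability 0.3962 and
#' survival 0.75-0.95.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset `"tiny"` or `"paper_like"`.
#' @param seed Integer seed.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_fixture <- function(out_dir, preset = c("tiny", "paper_like"),
                          seed = 1L, force = FALSE) {
  preset <- match.arg(preset)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stopf("directory %s is not empty; use force = TRUE to overwrite", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "tiny") {
    gcfg <- genome_sim_config(k = 4L, n_per_pop = 3L, l_nonsyn = 12L,
                              l_syn = 12L, l_other = 6L,
                              fst = c(0.05, 0.1, 0.15, 0.2),
                              lambda = c(1, 1.1, 1.25, 1.4),
                              missing_rate = 0.02, seed = seed)
    design <- data.frame(site = "S1",
                         source = c("P01", "P02", "P03"),
                         mean_cm = c(28.1, 25.7, 26.2),
                         survival = c(0.90, 0.80, 0.85))
    tcfg <- trial_sim_config(design, plots_per_source = 2L,
                             seedlings_per_plot = 10L, seed = seed + 1L)
    n_search <- 2L
  } else {
    gcfg <- genome_sim_config(seed = seed)
    design <- data.frame(site = "S1",
                         source = c("P01", "P05", "P09", "P13"),
                         mean_cm = c(28.1, 25.7, 26.2, 26.5),
                         survival = c(0.95, 0.75, 0.85, 0.90))
    tcfg <- trial_sim_config(design, seed = seed + 1L)
    n_search <- 4L
  }
  sim <- simulate_genotypes(gcfg)
  traits <- simulate_trial(tcfg)

  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             annotation = file.path(out_dir, "annotation.tsv"),
             pop_map = file.path(out_dir, "population_map.tsv"),
             traits = file.path(out_dir, "traits.csv"),
             config = file.path(out_dir, "config.yaml"))
  write_vcf(sim$genotypes, paths[["vcf"]])
  ann <- sim$annotation
  key <- do.call(rbind, strsplit(ann$snp_id, ":", fixed = TRUE))
  ann_out <- data.frame(chrom = key[, 1], pos = key[, 2], ref = key[, 3],
                        alt = key[, 4], effect = ann$effect,
                        stringsAsFactors = FALSE)
  utils::write.table(ann_out, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pop_map, paths[["pop_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- as.data.frame(traits)
  tr$alive <- as.integer(tr$alive)
  utils::write.csv(tr, paths[["traits"]], row.names = FALSE, quote = FALSE,
                   na = "")
  yaml::write_yaml(list(
    preset = preset, seed = as.integer(seed),
    vcf = "genotypes.vcf", pop_map = "population_map.tsv",
    annotation = "annotation.tsv", traits = "traits.csv",
    n_sources = n_search, h2 = tcfg$h2,
    boot_n = 200L, boot_reps = 1000L, iqr_multiplier = 1.5,
    n_planted = tcfg$seedlings_per_plot),
    paths[["config"]])
  invisible(paths)
}
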