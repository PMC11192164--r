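# The Balding-Nichols genotype simulator and the field-trial simulator.

test_that("simulator configs validate their parameters", {
  expect_error(genome_sim_config(fst = 0), "\\(0, 1\\)")
  expect_error(genome_sim_config(lambda = 0.5), ">= 1")
  expect_error(genome_sim_config(missing_rate = 1), "missing rate")
  expect_error(genome_sim_config(beta_a = -1), "> 0")
  design <- data.frame(site = "S", source = "A", mean_cm = 25, survival = 0.9)
  expect_error(trial_sim_config(design, h2 = 1.2), "\\[0, 1\\)")
  expect_error(trial_sim_config(transform(design, survival = 2)), "survival")
  expect_error(trial_sim_config(transform(design, mean_cm = -1)), "> 0")
})

test_that("with vanishing drift, population frequencies collapse to ancestral", {
  cfg <- genome_sim_config(k = 2, n_per_pop = 4, l_nonsyn = 1, l_syn = 2000,
                           l_other = 1, fst = 1e-4, lambda = 1,
                           missing_rate = 0, seed = 31)
  sim <- simulate_genotypes(cfg)
  dev <- abs(sweep(sim$latent_freqs, 2, sim$p_anc))
  expect_gte(mean(dev <= 0.05), 0.99)
})

test_that("simulated heterozygosity matches the Balding-Nichols expectation", {
  cfg <- genome_sim_config(k = 3, n_per_pop = 6, l_nonsyn = 1, l_syn = 10000,
                           l_other = 1, beta_a = 0.4, beta_b = 1.6,
                           fst = 0.1, lambda = 1, missing_rate = 0, seed = 32)
  sim <- simulate_genotypes(cfg)
  g <- sim$genotypes
  syn_ids <- sim$annotation$snp_id[sim$annotation$functional_class == "SYNONYMOUS"]
  theo <- bn_expected_het(0.4, 1.6, fst = 0.1, n_ind = 6)
  for (pop in population_ids(g)) {
    f <- allele_frequencies(g, individual_ids(g)[g$populations == pop])
    he <- mean(2 * f$p[f$snp_id %in% syn_ids] * (1 - f$p[f$snp_id %in% syn_ids]))
    expect_lt(abs(he - theo) / theo, 0.02)
  }
})

test_that("equal inflation gives symmetric loads; higher inflation raises load", {
  cfg <- genome_sim_config(k = 3, n_per_pop = 6, l_nonsyn = 10000,
                           l_syn = 10000, l_other = 1, fst = 0.1, lambda = 1,
                           missing_rate = 0, seed = 33)
  sim <- simulate_genotypes(cfg)
  gl_sym <- sapply(population_ids(sim$genotypes), function(pop) {
    diversity_load_score(sim$genotypes, sim$annotation,
                         individual_ids(sim$genotypes)[
                           sim$genotypes$populations == pop])$gl
  })
  expect_lt(max(gl_sym) / min(gl_sym) - 1, 0.1)

  cfg2 <- genome_sim_config(k = 3, n_per_pop = 6, l_nonsyn = 10000,
                            l_syn = 10000, l_other = 1, fst = 0.1,
                            lambda = c(1, 1.5, 2), missing_rate = 0, seed = 34)
  sim2 <- simulate_genotypes(cfg2)
  gl <- sapply(population_ids(sim2$genotypes), function(pop) {
    diversity_load_score(sim2$genotypes, sim2$annotation,
                         individual_ids(sim2$genotypes)[
                           sim2$genotypes$populations == pop])$gl
  })
  # populations ranked by lambda are ranked identically by estimated GL
  expect_identical(order(gl), 1:3)
})

test_that("a designed low-load population anchors the best set at every n", {
  cfg <- genome_sim_config(k = 5, n_per_pop = 6, l_nonsyn = 4000, l_syn = 4000,
                           l_other = 100, fst = 0.1,
                           lambda = c(1, 2, 2, 2, 2), missing_rate = 0.02,
                           seed = 35)
  sim <- simulate_genotypes(cfg)
  for (n in 1:3) {
    ranked <- rank_sets(score_sets(sim$genotypes, sim$annotation,
                                   enumerate_sets(population_ids(sim$genotypes), n)))
    expect_match(ranked$set_id[1], "P01")
  }
})

test_that("on a heterogeneous panel the best 4-set beats every single source", {
  cfg <- genome_sim_config(k = 8, n_per_pop = 6, l_nonsyn = 3000, l_syn = 3000,
                           l_other = 500, fst = seq(0.05, 0.25, length.out = 8),
                           lambda = seq(1, 1.5, length.out = 8),
                           missing_rate = 0.05, seed = 36)
  sim <- simulate_genotypes(cfg)
  pops <- population_ids(sim$genotypes)
  singles <- score_sets(sim$genotypes, sim$annotation, as.list(pops))
  best4 <- max(score_sets(sim$genotypes, sim$annotation,
                          enumerate_sets(pops, 4))$ratio)
  expect_gte(best4, max(singles$ratio))
})

test_that("trial simulator honors degenerate and calibrated settings", {
  design <- data.frame(site = "S1", source = "A", mean_cm = 25, survival = 1)
  tr0 <- simulate_trial(trial_sim_config(design, h2 = 0, v_e = 0,
                                         plots_per_source = 2,
                                         seedlings_per_plot = 5, seed = 41))
  expect_true(all(tr0$height_cm == 25))
  expect_true(all(tr0$alive))

  # n = 800 with known generating H2: realized genetic fraction of V_P
  tr <- simulate_trial(trial_sim_config(design, h2 = 0.3962, v_e = 1.2,
                                        plots_per_source = 20,
                                        seedlings_per_plot = 40, seed = 42))
  expect_identical(nrow(tr), 800L)
  lat <- attr(tr, "latent")
  h2_hat <- var(lat$g) / var(tr$height_cm)
  expect_lt(abs(h2_hat - 0.3962), 0.08)
})

test_that("plot survivorship concentrates around the survival probability", {
  design <- data.frame(site = "S1", source = "A", mean_cm = 25, survival = 0.75)
  tr <- simulate_trial(trial_sim_config(design, plots_per_source = 5,
                                        seedlings_per_plot = 40, seed = 43))
  s <- survivorship_summary(tr, n_planted = 40)
  expect_true(all(abs(s$plots$proportion - 0.75) <= 0.1 + 1e-9))
  expect_lt(abs(s$sources$mean_proportion - 0.75), 0.1)
})

test_that("fixture writer emits parseable, byte-stable file sets", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- write_fixture(d1, "tiny", seed = 7)
  p2 <- write_fixture(d2, "tiny", seed = 7)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  g <- suppressMessages(read_genotypes(p1[["vcf"]], p1[["pop_map"]]))
  ann <- read_annotation(p1[["annotation"]])
  tr <- read_traits(p1[["traits"]])
  expect_identical(length(population_ids(g)), 4L)
  expect_setequal(snp_ids(g), ann$snp_id)
  expect_s3_class(tr, "trait_table")

  expect_error(write_fixture(d1, "tiny", seed = 7), "not empty")
  expect_silent(write_fixture(d1, "tiny", seed = 8, force = TRUE))
})
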