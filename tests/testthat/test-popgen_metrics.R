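# Genetic diversity (He) and genetic load (Pn*fn / Ps*fs).

make_geno <- function(d) {
  rownames(d) <- paste0("i", seq_len(nrow(d)))
  colnames(d) <- sprintf("chr1:%d:A:G", seq_len(ncol(d)) * 10)
  genotype_matrix(d, setNames(rep("P1", nrow(d)), rownames(d)))
}

ann_for <- function(g, classes) {
  data.frame(snp_id = snp_ids(g), effect = "x", functional_class = classes,
             stringsAsFactors = FALSE)
}

test_that("allele frequencies exclude missing genotypes from denominators", {
  g <- make_geno(matrix(c(0L, 1L, 2L), ncol = 1))
  expect_equal(allele_frequencies(g)$p, 0.5)

  g2 <- make_geno(matrix(c(NA, 2L), ncol = 1))
  f2 <- allele_frequencies(g2)
  expect_equal(f2$p, 1.0)
  expect_identical(f2$n_alleles, 2L)

  # 6 individuals x 5 SNPs, frequencies worked out by hand
  d <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L,   # p = 6/12 = 0.5
                0L, 0L, 0L, 0L, 0L, 1L,   # p = 1/12
                2L, 2L, 2L, 2L, 2L, 2L,   # p = 1
                NA, NA, 0L, 1L, 1L, 0L,   # p = 2/8 = 0.25
                NA, NA, NA, NA, NA, NA),  # no calls
              nrow = 6)
  f <- allele_frequencies(make_geno(d))
  expect_equal(f$p, c(0.5, 1 / 12, 1, 0.25, NA))
  expect_identical(f$n_alleles, c(12L, 12L, 12L, 8L, 0L))
  expect_error(allele_frequencies(make_geno(d), character(0)), "empty")
})

test_that("expected heterozygosity averages 2p(1-p) over usable SNPs", {
  f1 <- data.frame(snp_id = "s", p = 0.5, n_alleles = 4L)
  expect_equal(expected_heterozygosity(f1), 0.5)

  mono <- data.frame(snp_id = c("a", "b"), p = c(0, 1), n_alleles = 4L)
  expect_equal(expected_heterozygosity(mono), 0)

  f3 <- data.frame(snp_id = c("a", "b", "c"), p = c(0.1, 0.2, 0.5),
                   n_alleles = 6L)
  expect_equal(expected_heterozygosity(f3), (0.18 + 0.32 + 0.5) / 3)
  expect_equal(expected_heterozygosity(f3), 1 / 3)

  none <- data.frame(snp_id = "a", p = NA_real_, n_alleles = 0L)
  expect_error(expected_heterozygosity(none), "no SNPs")
})

test_that("genetic load is the frequency-weighted Pn/Ps ratio", {
  mk <- function(p, cls) {
    list(freqs = data.frame(snp_id = paste0("s", seq_along(p)), p = p,
                            n_alleles = 8L),
         ann = data.frame(snp_id = paste0("s", seq_along(p)), effect = "x",
                          functional_class = cls))
  }
  x <- mk(c(0.2, 0.2, 0.2, 0.2),
          c("NONSYNONYMOUS", "NONSYNONYMOUS", "SYNONYMOUS", "SYNONYMOUS"))
  expect_equal(genetic_load(x$freqs, x$ann)$gl, 1.0)

  x <- mk(c(0.5, 0.5, 0.25, 0.25),
          c("NONSYNONYMOUS", "NONSYNONYMOUS", "SYNONYMOUS", "SYNONYMOUS"))
  expect_equal(genetic_load(x$freqs, x$ann)$gl, (2 * 0.5) / (2 * 0.25))

  x <- mk(c(0.1, 0.3, 0.4),
          c("NONSYNONYMOUS", "NONSYNONYMOUS", "SYNONYMOUS"))
  l <- genetic_load(x$freqs, x$ann)
  expect_equal(l$gl, (2 * 0.2) / (1 * 0.4))
  expect_identical(c(l$pn, l$ps), c(2L, 1L))

  # fixed (p = 1) and absent (p = 0) sites are not segregating
  x <- mk(c(0.2, 1, 0, 0.2),
          c("NONSYNONYMOUS", "NONSYNONYMOUS", "SYNONYMOUS", "SYNONYMOUS"))
  expect_identical(genetic_load(x$freqs, x$ann)$pn, 1L)

  x <- mk(c(0.2, 0.5), c("NONSYNONYMOUS", "OTHER"))
  expect_error(genetic_load(x$freqs, x$ann), "undefined")
})

test_that("GD:GL reproduces the ratios of the selected source combinations", {
  expect_equal(round(gd_gl_ratio(0.174, 0.961), 3), 0.181)
  expect_equal(round(gd_gl_ratio(0.176, 0.962), 3), 0.183)
  expect_equal(round(gd_gl_ratio(0.178, 1.011), 3), 0.176)
  expect_error(gd_gl_ratio(0.1, 0), "> 0")
  expect_error(gd_gl_ratio(0.1, -1), "> 0")
})

test_that("GD and GL obey the pooling invariants", {
  set.seed(101)
  for (rep in 1:10) {
    panel <- random_panel()
    g <- panel$genotypes
    sc <- diversity_load_score(g, panel$annotation)
    # biallelic He bound
    expect_gte(sc$gd, 0)
    expect_lte(sc$gd, 0.5)
    # duplicating every individual leaves GD and GL unchanged
    d2 <- rbind(g$dosages, g$dosages)
    rownames(d2) <- c(rownames(g$dosages), paste0(rownames(g$dosages), "_dup"))
    pops2 <- setNames(rep(g$populations, 2), rownames(d2))
    sc2 <- diversity_load_score(genotype_matrix(d2, pops2), panel$annotation)
    expect_equal(sc2$gd, sc$gd)
    expect_equal(sc2$gl, sc$gl)
  }
})

test_that("pooled GD dominates the mean of per-population GDs (Wahlund)", {
  set.seed(202)
  for (rep in 1:10) {
    # two equal-sized populations, complete data so the pooled frequency
    # is the exact mean of the population frequencies
    panel <- random_panel(n_pops = 2, n_per_pop = 5, n_snps = 12,
                          missing_rate = 0)
    g <- panel$genotypes
    pops <- population_ids(g)
    gd_pool <- expected_heterozygosity(allele_frequencies(g))
    gd_each <- sapply(pops, function(p) {
      expected_heterozygosity(
        allele_frequencies(g, individual_ids(g)[g$populations == p]))
    })
    expect_gte(gd_pool, mean(gd_each) - 1e-12)
  }
})

test_that("GL equals 1 when nonsynonymous and synonymous frequencies match", {
  set.seed(303)
  for (rep in 1:5) {
    p <- runif(6, 0.05, 0.95)
    freqs <- data.frame(snp_id = paste0("s", 1:12), p = c(p, sample(p)),
                        n_alleles = 10L)
    ann <- data.frame(snp_id = paste0("s", 1:12), effect = "x",
                      functional_class = rep(c("NONSYNONYMOUS", "SYNONYMOUS"),
                                             each = 6))
    expect_equal(genetic_load(freqs, ann)$gl, 1.0)
  }
})

test_that("vectorized scoring matches the brute-force oracle on small panels", {
  set.seed(404)
  for (rep in 1:10) {
    panel <- random_panel(n_pops = 2, n_per_pop = 4,
                          n_snps = sample(4:10, 1))
    sc <- diversity_load_score(panel$genotypes, panel$annotation)
    or <- oracle_score(panel$genotypes$dosages, panel$classes)
    expect_equal(sc$gd, or$gd)
    expect_equal(sc$gl, or$gl)
    expect_equal(sc$ratio, or$ratio)
    expect_identical(c(sc$pn, sc$ps), c(or$pn, or$ps))
  }
})
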