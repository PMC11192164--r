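# Trait evolvability (CV_G) for single and pooled seed sources, with
# Tukey outlier filtering, heritability scaling of phenotypic variance,
# bootstrap of the pooled estimate, fold-gain summaries, and
# survivorship proportions.

#' Tukey interquartile-range outlier filter
#'
#' Removes values outside `[Q1 - m*IQR, Q3 + m*IQR]`, with quartiles
#' computed by the linear-interpolation convention
#' (`stats::quantile(type = 7)`). Single pass: re-filtering the kept
#' values may remove more (the fences shrink), so the filter is
#' deliberately not idempotent.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param multiplier Fence multiplier `m` (classic Tukey value 1.5).
#' @return List with `kept` (input order preserved) and `removed`.
#' @export
tukey_filter <- function(values, multiplier = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stopf("need at least 4 finite values, got %d",
                                 length(values))
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  keep <- values >= lo & values <= hi
  list(kept = values[keep], removed = values[!keep])
}

#' Genetic variance from phenotypic variance and heritability
#'
#' With no pedigree available, the genetic component of trait variance is
#' approximated as `V_G = H^2 * V_P` using an external broad-sense
#' heritability estimate.
#'
#' @param v_p Phenotypic variance (>= 0).
#' @param h2 Broad-sense heritability in `[0, 1]`.
#' @return `V_G = h2 * v_p`.
#' @export
genetic_variance <- function(v_p, h2) {
  if (!is.finite(v_p) || v_p < 0) stopf("V_P must be >= 0, got %s", v_p)
  if (!is.finite(h2) || h2 < 0 || h2 > 1) stopf("H^2 must be in [0, 1], got %s", h2)
  h2 * v_p
}

#' Evolvability: the genetic coefficient of variation
#'
#' `CV_G = sqrt(V_G) / xbar`, a scale-free measure of a trait's capacity
#' to respond to selection.
#'
#' @param v_g Genetic variance (>= 0).
#' @param xbar Trait mean (> 0).
#' @return `CV_G`.
#' @export
evolvability <- function(v_g, xbar) {
  if (!is.finite(v_g) || v_g < 0) stopf("V_G must be >= 0, got %s", v_g)
  if (!is.finite(xbar) || xbar <= 0) stopf("trait mean must be > 0, got %s", xbar)
  sqrt(v_g) / xbar
}

#' Bootstrap the pooled evolvability estimate
#'
#' Draws `B` bootstrap replicates of `N` heights sampled with
#' replacement from the pooled (already outlier-filtered) heights; each
#' replicate computes `V_P` (denominator n-1), `V_G = h2 * V_P` and
#' `CV_G = sqrt(V_G) / mean`. Subsampling to `N` puts the pooled
#' estimate on the same sample-size footing as the single-source
#' estimates.
#'
#' @param heights Numeric vector of pooled heights (outliers removed).
#' @param h2 Broad-sense heritability in `[0, 1]`.
#' @param n_boot Resample size `N` (>= 2).
#' @param reps Number of bootstrap replicates `B` (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   `(mean, sd)` exactly.
#' @return List with `mean` and `sd` of the replicate `CV_G` values.
#' @export
bootstrap_pooled_cvg <- function(heights, h2, n_boot = 200L, reps = 1000L,
                                 seed = NULL) {
  heights <- heights[is.finite(heights)]
  if (length(heights) == 0L) stopf("no finite heights to bootstrap")
  if (n_boot < 2L) stopf("resample size N must be >= 2, got %d", n_boot)
  if (reps < 1L) stopf("number of replicates must be >= 1, got %d", reps)
  cvg <- with_seed(seed, {
    idx <- sample.int(length(heights), n_boot * reps, replace = TRUE)
    m <- matrix(heights[idx], nrow = n_boot, ncol = reps)
    means <- colMeans(m)
    v_p <- (colSums(m^2) - n_boot * means^2) / (n_boot - 1)
    v_p <- pmax(v_p, 0)  # guard tiny negative from floating-point cancellation
    sqrt(h2 * v_p) / means
  })
  list(mean = mean(cvg), sd = stats::sd(cvg))
}

#' Fold gain of pooled over single-source evolvability
#'
#' `pooled CV_G / min(single-source CV_G over sources with CV_G > 0)`,
#' reported to 1 decimal place — the "up to X times higher" summary of
#' what pooling buys over the least evolvable single source.
#'
#' @param pooled_cvg Pooled `CV_G` (>= 0).
#' @param single_cvgs Numeric vector of single-source `CV_G` values.
#' @return The fold gain, rounded to 1 decimal place.
#' @export
fold_gain <- function(pooled_cvg, single_cvgs) {
  if (!is.finite(pooled_cvg) || pooled_cvg < 0) {
    stopf("pooled CV_G must be >= 0, got %s", pooled_cvg)
  }
  if (any(!is.finite(single_cvgs) | single_cvgs < 0)) {
    stopf("single-source CV_G values must be >= 0")
  }
  pos <- single_cvgs[single_cvgs > 0]
  if (length(pos) == 0L) stopf("all single-source CV_G values are zero")
  round(pooled_cvg / min(pos), 1)
}

#' Per-plot and per-source survivorship proportions
#'
#' Survivorship is the proportion of alive plants out of the number
#' initially planted within each plot; source-level survivorship within
#' a site is the mean of its plot proportions.
#'
#' @param traits A trait table from [read_traits()] or [simulate_trial()].
#' @param n_planted Number of seedlings initially planted per plot.
#' @return List with data frames `plots` (site, source, plot, n_alive,
#'   n_planted, proportion) and `sources` (site, source, mean_proportion,
#'   n_plots).
#' @export
survivorship_summary <- function(traits, n_planted = 40L) {
  key <- interaction(traits$site, traits$source, traits$plot, drop = TRUE)
  agg <- do.call(rbind, lapply(split(traits, key), function(d) {
    data.frame(site = d$site[1], source = d$source[1], plot = d$plot[1],
               n_alive = sum(d$alive), n_planted = as.integer(n_planted),
               stringsAsFactors = FALSE)
  }))
  if (any(agg$n_alive > agg$n_planted)) {
    bad <- agg[agg$n_alive > agg$n_planted, ]
    stopf("plot %s has %d alive plants but only %d planted",
          bad$plot[1], bad$n_alive[1], bad$n_planted[1])
  }
  agg$proportion <- agg$n_alive / agg$n_planted
  agg <- agg[order(agg$site, agg$source, agg$plot), ]
  rownames(agg) <- NULL
  src_key <- interaction(agg$site, agg$source, drop = TRUE)
  src <- do.call(rbind, lapply(split(agg, src_key), function(d) {
    data.frame(site = d$site[1], source = d$source[1],
               mean_proportion = mean(d$proportion), n_plots = nrow(d),
               stringsAsFactors = FALSE)
  }))
  src <- src[order(src$site, src$source), ]
  rownames(src) <- NULL
  list(plots = agg, sources = src)
}

#' Evolvability table for single and pooled sources per site
#'
#' For each site: per source, alive seedling heights are outlier-filtered
#' (Tukey fences within source), then the trait mean, phenotypic variance
#' `V_P` (denominator n-1), `V_G = h2 * V_P` and `CV_G = sqrt(V_G)/mean`
#' are computed. A `pooled` row per site pools the filtered heights of
#' all its sources; its `CV_G` and `boot_sd` come from the
#' `N`-subsampled bootstrap ([bootstrap_pooled_cvg()]) so pooled and
#' single-source estimates are comparable despite the larger pooled n.
#'
#' @param traits A trait table from [read_traits()] or [simulate_trial()].
#' @param h2 Broad-sense heritability in `[0, 1]`.
#' @param iqr_multiplier Tukey fence multiplier.
#' @param n_boot,reps Bootstrap resample size and replicate count.
#' @param seed Optional integer seed for the bootstraps.
#' @return Data frame with columns `site`, `source` (source ID or
#'   `"pooled"`), `xbar`, `v_p`, `v_g`, `cv_g`, `boot_sd` (`NA` for
#'   single sources), `n_used`, `n_removed`.
#' @export
evolvability_table <- function(traits, h2, iqr_multiplier = 1.5,
                               n_boot = 200L, reps = 1000L, seed = NULL) {
  sites <- unique(traits$site)
  boot_seeds <- if (is.null(seed)) {
    rep(list(NULL), length(sites))
  } else {
    as.list(seed + seq_along(sites) - 1L)
  }
  out <- list()
  for (i in seq_along(sites)) {
    site <- sites[i]
    d <- traits[traits$site == site, , drop = FALSE]
    pooled_heights <- numeric(0)
    for (src in unique(d$source)) {
      h <- d$height_cm[d$source == src & d$alive]
      h <- h[is.finite(h)]
      filt <- tukey_filter(h, iqr_multiplier)
      xbar <- mean(filt$kept)
      v_p <- stats::var(filt$kept)
      v_g <- genetic_variance(v_p, h2)
      out[[length(out) + 1L]] <- data.frame(
        site = site, source = src, xbar = xbar, v_p = v_p, v_g = v_g,
        cv_g = evolvability(v_g, xbar), boot_sd = NA_real_,
        n_used = length(filt$kept), n_removed = length(filt$removed),
        stringsAsFactors = FALSE)
      pooled_heights <- c(pooled_heights, filt$kept)
    }
    xbar <- mean(pooled_heights)
    v_p <- stats::var(pooled_heights)
    v_g <- genetic_variance(v_p, h2)
    boot <- bootstrap_pooled_cvg(pooled_heights, h2, n_boot = n_boot,
                                 reps = reps, seed = boot_seeds[[i]])
    out[[length(out) + 1L]] <- data.frame(
      site = site, source = "pooled", xbar = xbar, v_p = v_p, v_g = v_g,
      cv_g = boot$mean, boot_sd = boot$sd,
      n_used = length(pooled_heights), n_removed = 0L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
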