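# Exhaustive enumeration, scoring, ranking and saturation analysis of
# n-population seed-source sets.

#' Enumerate all size-n subsets of the candidate populations
#'
#' Subsets are emitted sorted internally and in deterministic
#' lexicographic order, exactly `choose(k, n)` of them.
#'
#' @param population_ids Character vector of distinct population IDs.
#' @param n Set size, `1 <= n <= length(population_ids)`.
#' @return List of character vectors, each a sorted size-n set.
#' @export
enumerate_sets <- function(population_ids, n) {
  if (anyDuplicated(population_ids)) stopf("duplicated population IDs")
  k <- length(population_ids)
  if (n < 1L || n > k) stopf("set size n = %d outside 1..%d", n, k)
  utils::combn(sort(population_ids), n, simplify = FALSE)
}

# Per-population sufficient statistics for pooled allele frequencies:
# summed alternate-allele dosages and called-allele counts per SNP.
# Pooling a set is then two row-sums instead of touching raw genotypes.
.pool_stats <- function(g) {
  d <- g$dosages
  d0 <- d
  d0[is.na(d0)] <- 0L
  pops <- g$populations
  list(alt = rowsum(d0, pops),
       alleles = 2L * rowsum((!is.na(d)) + 0L, pops))
}

.class_vector <- function(g, annotation) {
  cls <- annotation$functional_class[match(snp_ids(g), annotation$snp_id)]
  cls[is.na(cls)] <- "OTHER"
  cls
}

#' Score pooled n-population sets by GD, GL and GD:GL
#'
#' For each set, the individuals of all member populations are pooled,
#' pooled alternate-allele frequencies computed, and GD, GL and GD:GL
#' derived as in [diversity_load_score()]. Output rows match the input
#' set order.
#'
#' @param g A [genotype_matrix].
#' @param annotation Annotation table from [read_annotation()].
#' @param sets List of character vectors of population IDs (e.g. from
#'   [enumerate_sets()]), each with distinct members.
#' @return Data frame with columns `set_id` (members joined by `+` in
#'   sorted order), `n_sources`, `gd`, `gl`, `ratio`, `pn`, `ps`,
#'   `n_snps_used`.
#' @export
score_sets <- function(g, annotation, sets) {
  if (is.character(sets)) sets <- list(sets)
  known <- population_ids(g)
  for (s in sets) {
    if (anyDuplicated(s)) stopf("set contains a repeated population: %s",
                                paste(s, collapse = "+"))
    unknown <- setdiff(s, known)
    if (length(unknown)) stopf("population(s) with zero genotyped individuals: %s",
                               paste(unknown, collapse = ", "))
  }
  stats <- .pool_stats(g)
  cls <- .class_vector(g, annotation)
  rows <- lapply(sets, function(s) {
    alt <- colSums(stats$alt[s, , drop = FALSE])
    alleles <- colSums(stats$alleles[s, , drop = FALSE])
    p <- ifelse(alleles > 0L, alt / alleles, NA_real_)
    sc <- .score_from_freqs(p, cls)
    data.frame(set_id = paste(sort(s), collapse = "+"),
               n_sources = length(s), gd = sc$gd, gl = sc$gl,
               ratio = sc$ratio, pn = sc$pn, ps = sc$ps,
               n_snps_used = sc$n_snps_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank scored sets and attach count-based percentiles
#'
#' Sets are ranked by GD:GL descending, ties broken lexicographically on
#' the sorted population IDs. The percentile of a set is
#' `100 * (#sets with ratio <= its ratio) / #sets`, so the unique best
#' set sits at the 100th percentile.
#'
#' @param scores Data frame from [score_sets()].
#' @return `scores` reordered best-first with added `rank` and
#'   `percentile` columns.
#' @export
rank_sets <- function(scores) {
  ord <- order(-scores$ratio, scores$set_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$percentile <- 100 * rank(out$ratio, ties.method = "max") / nrow(out)
  rownames(out) <- NULL
  out
}

#' Rank and percentile of a chosen source set
#'
#' @param scores Data frame from [score_sets()].
#' @param chosen_set Character vector of population IDs; must be one of
#'   the scored sets.
#' @return List with `rank` (1 = best), `percentile`, and the chosen
#'   set's `ratio`.
#' @export
rank_and_percentile <- function(scores, chosen_set) {
  id <- paste(sort(chosen_set), collapse = "+")
  ranked <- rank_sets(scores)
  i <- match(id, ranked$set_id)
  if (is.na(i)) stopf("chosen set %s is not among the scored sets", id)
  list(rank = ranked$rank[i], percentile = ranked$percentile[i],
       ratio = ranked$ratio[i])
}

#' GD:GL saturation curve over source-set size
#'
#' Enumerates and scores every size-n set for each n in
#' `n_min..n_max` and reports the best and mean GD:GL, tracing how the
#' attainable score saturates as more sources are pooled.
#'
#' @param g A [genotype_matrix].
#' @param annotation Annotation table from [read_annotation()].
#' @param n_min,n_max Range of set sizes.
#' @param cap Maximum number of sets to enumerate for a single size
#'   (guard against combinatorial blow-up).
#' @return Data frame with columns `n`, `n_sets`, `best_ratio`,
#'   `mean_ratio`.
#' @export
saturation_curve <- function(g, annotation, n_min = 1L, n_max, cap = 1e6) {
  k <- length(population_ids(g))
  if (n_max > k) stopf("n_max = %d exceeds the %d candidate populations", n_max, k)
  if (n_min < 1L || n_min > n_max) stopf("need 1 <= n_min <= n_max")
  sizes <- seq.int(n_min, n_max)
  counts <- choose(k, sizes)
  if (any(counts > cap)) {
    stopf("enumeration of C(%d, %d) = %.0f sets exceeds the cap (%g); raise `cap` to override",
          k, sizes[which.max(counts)], max(counts), cap)
  }
  rows <- lapply(sizes, function(n) {
    sc <- score_sets(g, annotation, enumerate_sets(population_ids(g), n))
    data.frame(n = n, n_sets = nrow(sc), best_ratio = max(sc$ratio),
               mean_ratio = mean(sc$ratio))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
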