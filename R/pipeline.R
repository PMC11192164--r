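# Run configuration and the end-to-end score -> optimize -> evolvability
# pipeline with TSV/JSON report assembly.

#' Build a run configuration
#'
#' @param vcf,pop_map,annotation,traits Input file paths (VCF genotypes,
#'   individual-to-population TSV, SnpEff-style annotation TSV,
#'   monitoring CSV).
#' @param n_sources Source-set size to optimize over.
#' @param chosen_set Optional character vector: the set actually chosen
#'   for planting, to be placed on the ranked distribution.
#' @param include,exclude Optional character vectors restricting the
#'   candidate populations (qualitative vetting: access, cone crop,
#'   expert opinion).
#' @param h2 Broad-sense heritability used to scale `V_P` to `V_G`.
#' @param boot_n,boot_reps Bootstrap resample size and replicate count
#'   for the pooled evolvability.
#' @param iqr_multiplier Tukey outlier fence multiplier.
#' @param n_planted Seedlings initially planted per plot.
#' @param seed Integer seed driving all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf, pop_map, annotation, traits,
                       n_sources = 4L, chosen_set = NULL,
                       include = NULL, exclude = NULL,
                       h2 = 0.3962, boot_n = 200L, boot_reps = 1000L,
                       iqr_multiplier = 1.5, n_planted = 40L, seed = 1L) {
  if (h2 < 0 || h2 > 1) stopf("H^2 must lie in [0, 1], got %s", h2)
  if (n_sources < 1L) stopf("n_sources must be >= 1")
  if (boot_n < 1L || boot_reps < 1L) stopf("bootstrap N and reps must be >= 1")
  structure(list(vcf = vcf, pop_map = pop_map, annotation = annotation,
                 traits = traits, n_sources = as.integer(n_sources),
                 chosen_set = chosen_set, include = include, exclude = exclude,
                 h2 = h2, boot_n = as.integer(boot_n),
                 boot_reps = as.integer(boot_reps),
                 iqr_multiplier = iqr_multiplier,
                 n_planted = as.integer(n_planted), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y[names(y) %in% names(formals(run_config))]
  for (f in c("vcf", "pop_map", "annotation", "traits")) {
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]])) {
      y[[f]] <- file.path(dirname(path), y[[f]])
    }
  }
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full seed-sourcing pipeline
#'
#' Reads the genotype panel, annotation and monitoring data; scores each
#' candidate population; enumerates, scores and ranks all
#' `n_sources`-sets (after include/exclude vetting); places the chosen
#' set (if any) on the ranked distribution; computes the evolvability
#' table and survivorship summary; and writes `ranked_sets.tsv`,
#' `evolvability.tsv`, `survivorship.tsv` and `report.json` into
#' `out_dir`. Output is byte-identical for identical config and seed.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report list (also serialized to
#'   `report.json`): elements `sets`, `chosen_percentile`,
#'   `evolvability`, `survivorship`, plus per-population scores under
#'   `populations` and the `seed` used.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  g <- .stage("read_genotypes",
              read_genotypes(config$vcf, read_population_map(config$pop_map)))
  ann <- .stage("read_annotation", read_annotation(config$annotation))
  traits <- .stage("read_traits", read_traits(config$traits))

  cand <- population_ids(g)
  if (!is.null(config$include)) cand <- intersect(cand, config$include)
  if (!is.null(config$exclude)) cand <- setdiff(cand, config$exclude)
  if (config$n_sources > length(cand)) {
    stopf("n_sources = %d exceeds the %d candidate populations",
          config$n_sources, length(cand))
  }

  pop_scores <- .stage("score", {
    score_sets(g, ann, as.list(cand))
  })
  ranked <- .stage("optimize", {
    rank_sets(score_sets(g, ann, enumerate_sets(cand, config$n_sources)))
  })
  chosen <- if (!is.null(config$chosen_set)) {
    .stage("optimize", rank_and_percentile(ranked, config$chosen_set))
  }
  evol <- .stage("evolvability", {
    evolvability_table(traits, h2 = config$h2,
                       iqr_multiplier = config$iqr_multiplier,
                       n_boot = config$boot_n, reps = config$boot_reps,
                       seed = config$seed)
  })
  surv <- .stage("survivorship",
                 survivorship_summary(traits, n_planted = config$n_planted))

  utils::write.table(round_df(ranked), file.path(out_dir, "ranked_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round_df(evol), file.path(out_dir, "evolvability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round_df(surv$plots),
                     file.path(out_dir, "survivorship.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    seed = config$seed,
    populations = pop_scores,
    sets = ranked,
    chosen_percentile = if (is.null(chosen)) NULL else chosen$percentile,
    chosen_rank = if (is.null(chosen)) NULL else chosen$rank,
    evolvability = evol,
    survivorship = surv)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}
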