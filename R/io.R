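# Readers and writers for the standard formats the pipeline touches:
# VCF genotypes (read via vcfR), SnpEff-style annotation tables,
# population maps, and seedling monitoring tables.

#' Read a two-column individual-to-population map
#'
#' @param path Tab-separated file with columns `individual` and
#'   `population` (header required).
#' @return Named character vector mapping individual to population ID.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("individual", "population")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("population map is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(tab$individual)) stopf("duplicated individuals in population map")
  stats::setNames(as.character(tab$population), tab$individual)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF v4.x file, keeps biallelic SNP records only (multiallelic
#' sites and indels are skipped, with the skipped count reported via
#' `message()`), and converts the GT field to alternate-allele dosages.
#' Phased and unphased genotypes are treated identically; `./.` becomes a
#' missing dosage.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param population_map Named character vector (as returned by
#'   [read_population_map()]) or a path to a population map file. Every
#'   sample in the VCF must be present in the map.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, population_map) {
  if (is.character(population_map) && length(population_map) == 1L &&
      is.null(names(population_map))) {
    population_map <- read_population_map(population_map)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  nuc <- c("A", "C", "G", "T")
  keep <- !is.na(alt) & ref %in% nuc & alt %in% nuc
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("read_genotypes: skipped %d non-biallelic-SNP record(s)", n_skipped))
  }
  if (!any(keep)) stopf("no biallelic SNP records in %s", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (is.null(samples) || length(samples) == 0L) {
    stopf("VCF %s has no sample genotype columns", path)
  }
  unmapped <- setdiff(samples, names(population_map))
  if (length(unmapped)) {
    stopf("individual(s) in VCF absent from population map: %s",
          paste(unmapped, collapse = ", "))
  }

  snp_keys <- paste(fix[keep, "CHROM"], fix[keep, "POS"], ref[keep], alt[keep],
                    sep = ":")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dosage_of <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                 "./." = NA_integer_, "." = NA_integer_)
  known <- is.na(gt) | gt %in% names(dosage_of)
  if (!all(known)) {
    stopf("unparseable GT value(s): %s",
          paste(utils::head(unique(gt[!known]), 5), collapse = ", "))
  }
  d <- matrix(dosage_of[gt], nrow = nrow(gt), ncol = ncol(gt))
  d <- t(d)  # individuals x SNPs
  dimnames(d) <- list(samples, snp_keys)
  attr_counts <- c(retained = sum(keep), skipped = n_skipped)
  g <- genotype_matrix(d, population_map)
  attr(g, "record_counts") <- attr_counts
  g
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Serializes dosages back to GT fields (`0 -> 0/0`, `1 -> 0/1`,
#' `2 -> 1/1`, `NA -> ./.`), reconstructing CHROM/POS/REF/ALT from the
#' `chrom:pos:ref:alt` SNP keys. Output is plain text and byte-stable, so
#' round-tripping through [read_genotypes()] reproduces the dosages
#' exactly.
#'
#' @param g A [genotype_matrix].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  parts <- strsplit(snp_ids(g), ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stopf("SNP ID(s) not of the form chrom:pos:ref:alt: %s",
                      paste(utils::head(snp_ids(g)[bad], 3), collapse = ", "))
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- vapply(parts, `[`, "", 2L)
  ref <- vapply(parts, `[`, "", 3L)
  alt <- vapply(parts, `[`, "", 4L)
  gt_of <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  d <- g$dosages
  gt <- matrix(gt_of[as.character(d)], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=seedopt",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individual_ids(g)), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# The SnpEff effect categories treated as amino-acid-changing when
# computing genetic load. Matching is case-insensitive and accepts both
# space- and underscore-delimited spellings.
.nonsyn_effects <- c("missense_variant", "splice_acceptor_variant",
                     "splice_donor_variant", "splice_region_variant",
                     "start_lost", "stop_gained", "stop_lost")
.syn_effects <- "synonymous_variant"

#' Map a SnpEff effect label to a functional class
#'
#' @param effect Character vector of raw effect labels. Compound labels
#'   joined with `&` (SnpEff style) are split and the worst consequence
#'   wins: NONSYNONYMOUS beats SYNONYMOUS beats OTHER.
#' @return Character vector in `{"NONSYNONYMOUS", "SYNONYMOUS", "OTHER"}`.
#' @export
classify_effect <- function(effect) {
  vapply(strsplit(as.character(effect), "[&,;]"), function(labels) {
    labels <- gsub("[ .]+", "_", tolower(trimws(labels)))
    if (any(labels %in% .nonsyn_effects)) "NONSYNONYMOUS"
    else if (any(labels %in% .syn_effects)) "SYNONYMOUS"
    else "OTHER"
  }, character(1))
}

#' Read a per-SNP functional annotation table
#'
#' Expects a tab-separated table with columns `chrom`, `pos`, `ref`,
#' `alt`, `effect` (SnpEff-style labels). Each SNP resolves to exactly one
#' functional class; when several rows annotate the same SNP the worst
#' consequence wins (NONSYNONYMOUS > SYNONYMOUS > OTHER).
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `snp_id`, `effect`, `functional_class`,
#'   one row per SNP.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "effect")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("annotation table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  tab$snp_id <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  tab$functional_class <- classify_effect(tab$effect)
  if (anyDuplicated(tab$snp_id)) {
    rank_of <- c(NONSYNONYMOUS = 1L, SYNONYMOUS = 2L, OTHER = 3L)
    ord <- order(tab$snp_id, rank_of[tab$functional_class])
    tab <- tab[ord, ]
    tab <- tab[!duplicated(tab$snp_id), ]
  }
  rownames(tab) <- NULL
  tab[, c("snp_id", "effect", "functional_class")]
}

#' Read a seedling monitoring table
#'
#' Comma-separated with header `site,source,plot,height_cm,alive`.
#' `alive` accepts 0/1/true/false (any case). Dead seedlings always get a
#' missing height; an alive seedling with a non-positive recorded height
#' is rejected with its row number.
#'
#' @param path Path to the CSV.
#' @return Data frame (class `trait_table`) with columns `site`, `source`,
#'   `plot`, `height_cm`, `alive`.
#' @export
read_traits <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("site", "source", "plot", "height_cm", "alive")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("trait table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  alive_raw <- tolower(trimws(as.character(tab$alive)))
  ok <- alive_raw %in% c("0", "1", "true", "false")
  if (!all(ok)) stopf("unparseable `alive` value at row %d: '%s'",
                      which(!ok)[1], alive_raw[which(!ok)[1]])
  tab$alive <- alive_raw %in% c("1", "true")
  tab$height_cm <- suppressWarnings(as.numeric(tab$height_cm))
  tab$height_cm[!tab$alive] <- NA_real_
  bad <- tab$alive & !is.na(tab$height_cm) & tab$height_cm <= 0
  if (any(bad)) stopf("alive seedling with non-positive height at row %d",
                      which(bad)[1])
  multi_site <- tapply(tab$site, tab$plot, function(s) length(unique(s)))
  if (any(multi_site > 1)) {
    stopf("plot(s) assigned to more than one site: %s",
          paste(names(multi_site)[multi_site > 1], collapse = ", "))
  }
  multi_src <- tapply(tab$source, tab$plot, function(s) length(unique(s)))
  if (any(multi_src > 1)) {
    stopf("plot(s) planted with more than one source: %s",
          paste(names(multi_src)[multi_src > 1], collapse = ", "))
  }
  class(tab) <- c("trait_table", "data.frame")
  tab
}
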