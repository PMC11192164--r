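#' Construct a genotype matrix with population labels
#'
#' The central genotype container: an individuals x SNPs matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for a missing genotype),
#' with every individual assigned to exactly one candidate source
#' population. SNP identifiers follow the `chrom:pos:ref:alt` key
#' convention, so every column is implicitly biallelic.
#'
#' @param dosages Integer matrix, individuals in rows (rownames are
#'   individual IDs), SNPs in columns (colnames are `chrom:pos:ref:alt`
#'   keys). Values must be 0, 1, 2 or `NA`.
#' @param populations Named character vector mapping every individual ID
#'   to its population ID.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` and `populations`.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("i1", "i2"), c("chr1:1:A:G", "chr1:5:C:T")))
#' g <- genotype_matrix(d, c(i1 = "P1", i2 = "P2"))
#' @export
genotype_matrix <- function(dosages, populations) {
  if (!is.matrix(dosages)) stopf("`dosages` must be a matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    stopf("`dosages` must carry individual IDs as rownames and SNP IDs as colnames")
  }
  if (anyDuplicated(rownames(dosages))) stopf("duplicated individual IDs")
  if (anyDuplicated(colnames(dosages))) stopf("duplicated SNP IDs")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA; found %s",
                      paste(unique(dosages[bad]), collapse = ", "))
  storage.mode(dosages) <- "integer"
  inds <- rownames(dosages)
  missing_pop <- setdiff(inds, names(populations))
  if (length(missing_pop)) {
    stopf("no population label for individual(s): %s",
          paste(missing_pop, collapse = ", "))
  }
  populations <- stats::setNames(as.character(populations[inds]), inds)
  structure(list(dosages = dosages, populations = populations),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, %d populations\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$populations))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
individual_ids <- function(g) rownames(g$dosages)

#' @rdname genotype_matrix
#' @export
snp_ids <- function(g) colnames(g$dosages)

#' @rdname genotype_matrix
#' @export
population_ids <- function(g) sort(unique(g$populations))

# individuals belonging to a set of populations
members_of <- function(g, populations) {
  unknown <- setdiff(populations, g$populations)
  if (length(unknown)) {
    stopf("population(s) with zero genotyped individuals: %s",
          paste(unknown, collapse = ", "))
  }
  individual_ids(g)[g$populations %in% populations]
}
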