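#' Labelled biallelic genotype table
#'
#' The central data container: diploid genotypes at biallelic
#' insertion/deletion loci for a set of labelled individuals. The insertion
#' allele is coded 1 and the deletion allele 0, so an unphased genotype is
#' fully described by its insertion-allele dosage (0, 1 or 2; `NA` for a
#' missing genotype). Each sample carries a population label and a
#' continental superpopulation label; each population must map to exactly
#' one superpopulation.
#'
#' @param dosage integer matrix, samples x loci, entries in \{0, 1, 2, NA\}.
#'   Row names (if any) are used as sample ids.
#' @param population character vector of per-sample population labels.
#' @param superpopulation character vector of per-sample continental labels.
#' @param loci data frame with columns `locus_id`, `chromosome`, `position`
#'   (one row per locus, ids unique). Defaults to autogenerated ids.
#' @param sample_ids character vector of unique sample identifiers.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `dosage`, `sample_ids`, `population`, `superpopulation`, `loci`.
#' @examples
#' gt <- genotype_table(matrix(c(2L, 1L, 0L, NA), 2, 2),
#'                      population = c("P1", "P1"),
#'                      superpopulation = c("S1", "S1"))
#' n_samples(gt)
#' @export
genotype_table <- function(dosage, population, superpopulation,
                           loci = NULL, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  L <- ncol(dosage)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  }
  if (is.null(loci)) {
    loci <- data.frame(locus_id = sprintf("L%04d", seq_len(L)),
                       chromosome = "1",
                       position = seq_len(L) * 1000L,
                       stringsAsFactors = FALSE)
  }
  obj <- structure(list(dosage = dosage,
                        sample_ids = as.character(sample_ids),
                        population = as.character(population),
                        superpopulation = as.character(superpopulation),
                        loci = loci),
                   class = "genotype_table")
  validate_genotype_table(obj)
}

#' Validate a genotype table
#'
#' Checks the container invariants: dimensions agree, dosages lie in
#' \{0,1,2,NA\}, sample and locus ids are unique, and every population label
#' maps to a single superpopulation.
#'
#' @param x a `genotype_table`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  n <- nrow(x$dosage)
  L <- ncol(x$dosage)
  if (length(x$sample_ids) != n)
    stop("sample_ids length (", length(x$sample_ids),
         ") does not match number of dosage rows (", n, ")")
  if (anyDuplicated(x$sample_ids))
    stop("sample ids must be unique")
  if (length(x$population) != n || length(x$superpopulation) != n)
    stop("population and superpopulation labels must have one entry per sample")
  if (nrow(x$loci) != L)
    stop("loci table has ", nrow(x$loci), " rows but dosage has ", L, " columns")
  if (anyDuplicated(x$loci$locus_id))
    stop("locus ids must be unique")
  bad <- x$dosage[!is.na(x$dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  map <- unique(data.frame(pop = x$population, sup = x$superpopulation))
  if (anyDuplicated(map$pop))
    stop("each population must map to exactly one superpopulation")
  rownames(x$dosage) <- x$sample_ids
  colnames(x$dosage) <- x$loci$locus_id
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosage), "samples x", ncol(x$dosage), "loci\n")
  cat("  populations:", length(unique(x$population)),
      " superpopulations:", length(unique(x$superpopulation)), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(x) ncol(x$dosage)

#' Subset a genotype table by sample
#' @param x a `genotype_table`.
#' @param i logical or integer sample index.
#' @param ... ignored.
#' @return a `genotype_table` with the selected samples.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  genotype_table(x$dosage[i, , drop = FALSE],
                 population = x$population[i],
                 superpopulation = x$superpopulation[i],
                 loci = x$loci,
                 sample_ids = x$sample_ids[i])
}

#' Population to superpopulation lookup
#' @param x a `genotype_table`.
#' @return named character vector mapping population -> superpopulation.
#' @export
population_map <- function(x) {
  map <- unique(data.frame(pop = x$population, sup = x$superpopulation,
                           stringsAsFactors = FALSE))
  stats::setNames(map$sup, map$pop)
}
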