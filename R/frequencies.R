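#' Per-population insertion-allele frequencies
#'
#' Counts insertion alleles per (group, locus) over non-missing genotypes.
#' `n` is the diploid sample size actually typed, so frequencies remain
#' valid when genotypes are missing. Cells with no typed genotype at all
#' are dropped with a warning.
#'
#' @param table a [genotype_table()].
#' @param group_by label level to group on: `"population"` (default) or
#'   `"superpopulation"`.
#' @return a data frame of class `locus_freqs` with columns `population`
#'   (the group label), `locus_id`, `p_ins`, `n`.
#' @examples
#' gt <- genotype_table(matrix(c(2L, 1L, 1L, 0L), 2, 2),
#'                      population = c("P1", "P1"),
#'                      superpopulation = c("S1", "S1"))
#' allele_frequencies(gt)
#' @export
allele_frequencies <- function(table,
                               group_by = c("population", "superpopulation")) {
  group_by <- match.arg(group_by)
  validate_genotype_table(table)
  groups <- table[[group_by]]
  out <- list()
  for (g in unique(groups)) {
    d <- table$dosage[groups == g, , drop = FALSE]
    n <- colSums(!is.na(d))
    counts <- colSums(d, na.rm = TRUE)
    if (any(n == 0)) {
      warning("all genotypes missing for group ", g, " at loci: ",
              paste(table$loci$locus_id[n == 0], collapse = ", "),
              "; cells dropped")
    }
    keep <- n > 0
    out[[g]] <- data.frame(population = g,
                           locus_id = table$loci$locus_id[keep],
                           p_ins = counts[keep] / (2 * n[keep]),
                           n = n[keep],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("locus_freqs", "data.frame")
  res
}

#' Frequency matrix from long-format frequencies
#'
#' @param freqs a `locus_freqs` data frame (columns `population`,
#'   `locus_id`, `p_ins`, `n`).
#' @return numeric matrix, populations x loci, of insertion frequencies.
#' @export
freq_matrix <- function(freqs) {
  pops <- unique(freqs$population)
  loci <- unique(freqs$locus_id)
  m <- matrix(NA_real_, length(pops), length(loci),
              dimnames = list(pops, loci))
  m[cbind(match(freqs$population, pops), match(freqs$locus_id, loci))] <-
    freqs$p_ins
  m
}

#' Genotype counts per population and locus
#'
#' Tabulates homozygote-insertion, heterozygote and homozygote-deletion
#' counts, the inputs to the exact Hardy-Weinberg test and the forensic
#' parameter suite.
#'
#' @inheritParams allele_frequencies
#' @return data frame with columns `population`, `locus_id`, `n_II`,
#'   `n_ID`, `n_DD`.
#' @export
genotype_counts <- function(table,
                            group_by = c("population", "superpopulation")) {
  group_by <- match.arg(group_by)
  validate_genotype_table(table)
  groups <- table[[group_by]]
  out <- list()
  for (g in unique(groups)) {
    d <- table$dosage[groups == g, , drop = FALSE]
    out[[g]] <- data.frame(population = g,
                           locus_id = table$loci$locus_id,
                           n_II = colSums(d == 2, na.rm = TRUE),
                           n_ID = colSums(d == 1, na.rm = TRUE),
                           n_DD = colSums(d == 0, na.rm = TRUE),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a frequency table from explicit values
#'
#' Convenience constructor for `locus_freqs` objects, e.g. to enter
#' published per-population frequency tables by hand.
#'
#' @param population,locus_id,p_ins,n vectors of equal length (recycled).
#' @return a `locus_freqs` data frame.
#' @export
locus_freqs <- function(population, locus_id, p_ins, n) {
  res <- data.frame(population = population, locus_id = locus_id,
                    p_ins = p_ins, n = n, stringsAsFactors = FALSE)
  stopifnot(all(res$p_ins >= 0 & res$p_ins <= 1), all(res$n >= 1))
  class(res) <- c("locus_freqs", "data.frame")
  res
}
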