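#' Read genotypes from a PLINK text ped/map pair
#'
#' Parses whitespace-delimited ped/map files as produced by PLINK's
#' `--recode` for text output. The ped file carries six leading metadata
#' columns (family, individual, father, mother, sex, phenotype) followed by
#' two allele columns per locus; the map file has one row per locus
#' (chromosome, locus id, genetic distance, position). Allele strings are
#' recoded to the internal insertion/deletion codes via `allele_map`; the
#' ped missing code `"0"` becomes a missing genotype.
#'
#' Population labels are not part of the ped dialect: they are supplied
#' through `sample_pop` (sample id -> population) and `pop_super`
#' (population -> superpopulation), either as two-column data frames or as
#' paths to headerless tab-separated files, mirroring the panel files that
#' usually accompany 1000 Genomes ped extracts.
#'
#' @param ped_path path to the ped file.
#' @param map_path path to the map file.
#' @param allele_map named vector mapping allele strings to codes 0/1,
#'   e.g. `c(I = 1, D = 0)`. A locus allele string absent from the map (and
#'   not the missing code `"0"`) is an error naming the locus and sample.
#' @param sample_pop sample-to-population labels (data frame or TSV path);
#'   samples without an entry get population `"UNK"`.
#' @param pop_super population-to-superpopulation labels (data frame or TSV
#'   path); populations without an entry get superpopulation `"UNK"`.
#' @return a [genotype_table()].
#' @seealso [write_ped_map()] for the inverse operation.
#' @export
read_ped_map <- function(ped_path, map_path, allele_map = c(I = 1, D = 0),
                         sample_pop = NULL, pop_super = NULL) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4)
    stop("map file must have 4 columns: chromosome, locus id, cM, position")
  loci <- data.frame(locus_id = map[[2]], chromosome = map[[1]],
                     position = as.integer(map[[4]]), stringsAsFactors = FALSE)
  L <- nrow(loci)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(fields)
  if (length(widths) && any(widths != 6 + 2 * L))
    stop("ped/map mismatch: expected ", 6 + 2 * L,
         " columns per ped row for ", L, " loci, found ",
         paste(unique(widths[widths != 6 + 2 * L]), collapse = ", "))

  n <- length(fields)
  sample_ids <- vapply(fields, `[[`, character(1), 2L)
  dosage <- matrix(NA_integer_, n, L)
  code_of <- function(a, sample, locus) {
    if (a == "0") return(NA_integer_)
    if (!a %in% names(allele_map))
      stop("unknown allele '", a, "' at locus ", locus, " for sample ", sample)
    as.integer(allele_map[[a]])
  }
  for (s in seq_len(n)) {
    row <- fields[[s]]
    for (l in seq_len(L)) {
      a1 <- row[6 + 2 * l - 1]
      a2 <- row[6 + 2 * l]
      c1 <- code_of(a1, sample_ids[s], loci$locus_id[l])
      c2 <- code_of(a2, sample_ids[s], loci$locus_id[l])
      # half-missing genotypes are treated as missing (CE convention)
      dosage[s, l] <- if (is.na(c1) || is.na(c2)) NA_integer_ else c1 + c2
    }
  }

  sp <- read_two_col(sample_pop, c("sample_id", "population"))
  ps <- read_two_col(pop_super, c("population", "superpopulation"))
  pop <- if (is.null(sp)) rep("UNK", n) else {
    idx <- match(sample_ids, sp$sample_id)
    ifelse(is.na(idx), "UNK", sp$population[idx])
  }
  sup <- if (is.null(ps)) rep("UNK", n) else {
    idx <- match(pop, ps$population)
    ifelse(is.na(idx), "UNK", ps$superpopulation[idx])
  }
  genotype_table(dosage, population = pop, superpopulation = sup,
                 loci = loci, sample_ids = sample_ids)
}

read_two_col <- function(x, nms) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.table(x, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stats::setNames(x[, 1:2], nms)
}

#' Write a genotype table as a PLINK text ped/map pair
#'
#' The inverse of [read_ped_map()]: a table written with the default allele
#' strings reads back bit-identically with the default `allele_map`.
#' Missing genotypes are serialised as the ped `"0 0"` convention. A
#' heterozygote is written insertion-first (phase is not represented).
#'
#' @param table a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @param allele_strings named character vector giving the allele string for
#'   codes `"1"` (insertion) and `"0"` (deletion). The defaults `I`/`D`
#'   avoid colliding with the ped missing code `"0"`.
#' @return invisibly, the ped path.
#' @export
write_ped_map <- function(table, ped_path, map_path,
                          allele_strings = c(`1` = "I", `0` = "D")) {
  validate_genotype_table(table)
  loci <- table$loci
  utils::write.table(
    data.frame(loci$chromosome, loci$locus_id, 0, loci$position),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  ins <- allele_strings[["1"]]
  del <- allele_strings[["0"]]
  geno_str <- c(`0` = paste(del, del), `1` = paste(ins, del), `2` = paste(ins, ins))
  n <- n_samples(table)
  rows <- character(n)
  for (s in seq_len(n)) {
    d <- table$dosage[s, ]
    g <- ifelse(is.na(d), "0 0", geno_str[as.character(d)])
    meta <- c(table$population[s], table$sample_ids[s], "0", "0", "0", "-9")
    rows[s] <- paste(c(meta, g), collapse = " ")
  }
  writeLines(rows, ped_path)
  invisible(ped_path)
}

#' Read a genotype table from a dosage CSV
#'
#' Expects columns `sample_id`, `population`, `superpopulation`, then one
#' column per locus holding the insertion-allele dosage in \{0, 1, 2, NA\}.
#'
#' @param csv_path path to the CSV file.
#' @return a [genotype_table()].
#' @export
read_csv_genotypes <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "population", "superpopulation")
  if (!all(need %in% names(df)))
    stop("CSV must start with columns: ", paste(need, collapse = ", "))
  locus_cols <- setdiff(names(df), need)
  dosage <- as.matrix(df[, locus_cols, drop = FALSE])
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosage values must be 0, 1, 2 or NA; found: ",
         paste(utils::head(setdiff(unique(vals), 0:2)), collapse = ", "))
  genotype_table(dosage,
                 population = df$population,
                 superpopulation = df$superpopulation,
                 loci = data.frame(locus_id = locus_cols,
                                   chromosome = "NA",
                                   position = seq_along(locus_cols),
                                   stringsAsFactors = FALSE),
                 sample_ids = df$sample_id)
}

#' Write a genotype table as a dosage CSV
#'
#' @param table a [genotype_table()].
#' @param csv_path output path.
#' @return invisibly, the path.
#' @seealso [read_csv_genotypes()]
#' @export
write_csv_genotypes <- function(table, csv_path) {
  validate_genotype_table(table)
  df <- data.frame(sample_id = table$sample_ids,
                   population = table$population,
                   superpopulation = table$superpopulation,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$dosage, check.names = FALSE))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}
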