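#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Exact test conditioning on the observed allele counts (Levene's
#' distribution). With `n` diploids, `n_ins` insertion alleles and `h`
#' heterozygotes, the conditional probability is
#' \deqn{P(h) = \frac{n!\, 2^h\, n_{ins}!\, n_{del}!}{n_{II}!\, h!\, n_{DD}!\,(2n)!}}
#' and the two-sided p-value sums `P(h')` over all admissible heterozygote
#' counts with `P(h') <= P(h_obs)` (the standard exact-test convention).
#' The mid-p variant halves the weight of the observed configuration.
#'
#' @param n_II,n_ID,n_DD genotype counts (insertion homozygote,
#'   heterozygote, deletion homozygote).
#' @param midp logical; use the mid-p correction (default `FALSE`).
#' @param alpha nominal significance level before correction.
#' @param n_tests number of tests for Bonferroni correction of `alpha`.
#' @return list of class `popkit_test` with `statistic` (observed
#'   heterozygote count), `p_value`, `bonferroni_alpha`, `significant`.
#' @examples
#' hwe_exact_test(1, 0, 1)$p_value  # 1/3 by full enumeration
#' @export
hwe_exact_test <- function(n_II, n_ID, n_DD, midp = FALSE,
                           alpha = 0.05, n_tests = 1) {
  counts <- c(n_II, n_ID, n_DD)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype is required")
  n_ins <- 2 * n_II + n_ID
  n_del <- 2 * n_DD + n_ID
  m <- min(n_ins, n_del)
  hs <- seq(m %% 2, m, by = 2)  # heterozygote counts sharing allele parity
  logp <- lfactorial(n) + hs * log(2) + lfactorial(n_ins) + lfactorial(n_del) -
    lfactorial((n_ins - hs) / 2) - lfactorial(hs) -
    lfactorial((n_del - hs) / 2) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hs == n_ID)
  tol <- 1e-12
  inc <- prob <= prob[obs] * (1 + tol)
  p <- sum(prob[inc])
  if (midp) p <- p - prob[obs] / 2
  p <- min(1, p)
  new_test(statistic = n_ID, p_value = p, alpha = alpha, n_tests = n_tests)
}

new_test <- function(statistic, p_value, alpha, n_tests) {
  thr <- bonferroni(alpha, n_tests)
  structure(list(statistic = statistic, p_value = p_value,
                 bonferroni_alpha = thr,
                 significant = p_value < thr),
            class = "popkit_test")
}

#' @export
print.popkit_test <- function(x, ...) {
  cat(sprintf("statistic = %g, p = %.6g (threshold %.6g, %s)\n",
              x$statistic, x$p_value, x$bonferroni_alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (e.g. 0.05).
#' @param n_tests number of tests performed.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni(0.05, 56)   # 0.000893 for a 56-locus panel
#' @export
bonferroni <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' A composite-LD style test on insertion-allele dosages: the statistic is
#' `n` times the squared Pearson correlation of the paired dosages. The
#' null distribution is obtained by randomly re-pairing the dosage vectors
#' (`n_perm` permutations) and the p-value is
#' `(1 + #\{perm stat >= observed\}) / (1 + n_perm)`. For `n <= 7` an exact
#' enumeration over all `n!` pairings is available.
#'
#' @param gA,gB numeric dosage vectors for the two loci; pairs with a
#'   missing value at either locus are dropped.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation draw (required unless
#'   `exact = TRUE`).
#' @param exact logical; enumerate all pairings instead of sampling
#'   (only for `n <= 7`).
#' @inheritParams hwe_exact_test
#' @return a `popkit_test` (statistic `n * r^2`).
#' @export
ld_test <- function(gA, gB, n_perm = 9999, seed = NULL, exact = FALSE,
                    alpha = 0.05, n_tests = 1) {
  keep <- !is.na(gA) & !is.na(gB)
  gA <- as.numeric(gA[keep]); gB <- as.numeric(gB[keep])
  n <- length(gA)
  if (n < 2) stop("need at least 2 complete dosage pairs")
  if (stats::sd(gA) == 0 || stats::sd(gB) == 0) {
    warning("zero dosage variance at one locus; LD test undefined, p = 1")
    return(new_test(statistic = 0, p_value = 1, alpha = alpha, n_tests = n_tests))
  }
  stat <- n * stats::cor(gA, gB)^2
  tol <- 1e-12
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    ps <- apply(perms, 1, function(ix) n * stats::cor(gA, gB[ix])^2)
    p <- mean(ps >= stat - tol)
  } else {
    if (is.null(seed)) stop("seed is required for the permutation draw")
    set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      s <- n * stats::cor(gA, sample(gB))^2
      if (s >= stat - tol) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  new_test(statistic = stat, p_value = p, alpha = alpha, n_tests = n_tests)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Hardy-Weinberg tests for every population x locus cell
#'
#' @inheritParams allele_frequencies
#' @param midp logical, passed to [hwe_exact_test()].
#' @param alpha family-wise significance level.
#' @return data frame with one row per (population, locus): heterozygote
#'   count, p-value, Bonferroni threshold (`alpha` / number of loci, the
#'   per-population correction) and significance flag.
#' @export
hwe_test_table <- function(table, midp = FALSE, alpha = 0.05) {
  counts <- genotype_counts(table)
  n_tests <- length(unique(counts$locus_id))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    t <- hwe_exact_test(counts$n_II[i], counts$n_ID[i], counts$n_DD[i],
                        midp = midp, alpha = alpha, n_tests = n_tests)
    data.frame(statistic = t$statistic, p_value = t$p_value,
               bonferroni_alpha = t$bonferroni_alpha,
               significant = t$significant)
  })
  cbind(counts[, c("population", "locus_id")], do.call(rbind, res))
}

#' Pairwise LD tests within each population
#'
#' Runs [ld_test()] for every locus pair inside each population. The
#' Bonferroni threshold uses the total number of tests actually run.
#'
#' @inheritParams allele_frequencies
#' @param n_perm permutations per test.
#' @param seed integer seed; each test gets a distinct derived seed.
#' @param alpha family-wise significance level.
#' @return long data frame: `population`, `locus_a`, `locus_b`,
#'   `statistic`, `p_value`, `bonferroni_alpha`, `significant`.
#' @export
ld_test_table <- function(table, n_perm = 999, seed = 1, alpha = 0.05) {
  validate_genotype_table(table)
  pops <- unique(table$population)
  ids <- table$loci$locus_id
  L <- length(ids)
  pairs <- utils::combn(L, 2)
  n_tests <- length(pops) * ncol(pairs)
  rows <- vector("list", n_tests)
  k <- 1L
  for (pop in pops) {
    d <- table$dosage[table$population == pop, , drop = FALSE]
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      t <- suppressWarnings(
        ld_test(d[, a], d[, b], n_perm = n_perm,
                seed = derive_seed(seed, paste(pop, a, b)),
                alpha = alpha, n_tests = n_tests))
      rows[[k]] <- data.frame(population = pop, locus_a = ids[a],
                              locus_b = ids[b], statistic = t$statistic,
                              p_value = t$p_value,
                              bonferroni_alpha = t$bonferroni_alpha,
                              significant = t$significant,
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}

#' Forensic parameters for one biallelic locus
#'
#' From genotype counts, with `p` the insertion frequency, `q = 1 - p`,
#' `h` the observed heterozygosity and `H = 1 - h`:
#' * `Ho = h` (observed heterozygosity),
#' * `He = 2n/(2n-1) * (1 - p^2 - q^2)` (unbiased gene diversity),
#' * `PIC = 1 - p^2 - q^2 - 2 p^2 q^2` (Botstein),
#' * `MP` = sum of squared observed genotype frequencies, `PD = 1 - MP`,
#' * `PE = h^2 (1 - 2 h H^2)` (trio exclusion from observed heterozygosity).
#'
#' @inheritParams hwe_exact_test
#' @return one-row data frame with columns `Ho`, `He`, `PIC`, `MP`, `PD`, `PE`.
#' @examples
#' forensic_params(3, 5, 2)  # Ho 0.5, PD 0.62, PE 0.1875
#' @export
forensic_params <- function(n_II, n_ID, n_DD) {
  n <- n_II + n_ID + n_DD
  if (n < 2) stop("at least 2 genotypes are required")
  p <- (2 * n_II + n_ID) / (2 * n)
  q <- 1 - p
  h <- n_ID / n
  H <- 1 - h
  gf <- c(n_II, n_ID, n_DD) / n
  MP <- sum(gf^2)
  data.frame(Ho = h,
             He = (2 * n / (2 * n - 1)) * (1 - p^2 - q^2),
             PIC = 1 - p^2 - q^2 - 2 * p^2 * q^2,
             MP = MP,
             PD = 1 - MP,
             PE = h^2 * (1 - 2 * h * H^2))
}

#' Forensic parameters for every population x locus cell
#'
#' @inheritParams allele_frequencies
#' @return data frame with `population`, `locus_id` and the
#'   [forensic_params()] columns.
#' @export
forensic_params_table <- function(table,
                                  group_by = c("population", "superpopulation")) {
  counts <- genotype_counts(table, group_by = group_by)
  vals <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    forensic_params(counts$n_II[i], counts$n_ID[i], counts$n_DD[i])))
  cbind(counts[, c("population", "locus_id")], vals)
}

#' Cumulative powers of discrimination and exclusion for a panel
#'
#' `CPD = 1 - prod(1 - PD_i)` and `CPE = 1 - prod(1 - PE_i)` over the
#' panel's loci, accumulated in log space so panels of many strong loci do
#' not underflow.
#'
#' @param per_locus data frame with columns `PD` and `PE` (one row per
#'   locus), e.g. from [forensic_params_table()] for one population.
#' @return named numeric vector `c(CPD = ..., CPE = ...)`.
#' @export
cumulative_power <- function(per_locus) {
  if (nrow(per_locus) < 1) stop("at least one locus is required")
  c(CPD = -expm1(sum(log1p(-per_locus$PD))),
    CPE = -expm1(sum(log1p(-per_locus$PE))))
}
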