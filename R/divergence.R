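#' Pairwise F_ST between two populations
#'
#' Two estimators are offered. The default `"nei"` is the two-population
#' Nei G_ST: per locus, `Hs` is the mean within-population gene diversity
#' `1 - p^2 - q^2` of the two populations and `Ht` the diversity of their
#' unweighted mean frequency; the panel estimate is the ratio of sums
#' `(sum(Ht) - sum(Hs)) / sum(Ht)` (clamped at 0). `"wc"` is the
#' Weir-Cockerham theta for two populations using sample sizes from the
#' frequency table and Hardy-Weinberg expected heterozygosity; it estimates
#' the Balding-Nichols divergence parameter directly (the G_ST variant is
#' downward biased by construction, roughly `F / (2 - F)` under that
#' model — see the package vignette).
#'
#' @param freqs a `locus_freqs` data frame.
#' @param pop_a,pop_b population labels present in `freqs`.
#' @param method `"nei"` (default) or `"wc"`.
#' @return the F_ST estimate (single number in `[0, 1]`).
#' @examples
#' f <- locus_freqs(c("A", "B"), "L1", c(0.9, 0.1), 100)
#' pairwise_fst(f, "A", "B")  # 0.64
#' @export
pairwise_fst <- function(freqs, pop_a, pop_b, method = c("nei", "wc")) {
  method <- match.arg(method)
  ab <- shared_freqs(freqs, pop_a, pop_b)
  p1 <- ab$p1; p2 <- ab$p2
  if (method == "nei") {
    hs <- ((1 - p1^2 - (1 - p1)^2) + (1 - p2^2 - (1 - p2)^2)) / 2
    pb <- (p1 + p2) / 2
    ht <- 1 - pb^2 - (1 - pb)^2
    if (sum(ht) <= 0) return(0)
    max(0, (sum(ht) - sum(hs)) / sum(ht))
  } else {
    n1 <- ab$n1; n2 <- ab$n2
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    den <- sum(a + b + cc)
    if (den <= 0) return(0)
    max(0, sum(a) / den)
  }
}

shared_freqs <- function(freqs, pop_a, pop_b) {
  fa <- freqs[freqs$population == pop_a, ]
  fb <- freqs[freqs$population == pop_b, ]
  common <- intersect(fa$locus_id, fb$locus_id)
  if (length(common) == 0)
    stop("populations ", pop_a, " and ", pop_b, " share no typed loci")
  ia <- match(common, fa$locus_id)
  ib <- match(common, fb$locus_id)
  list(p1 = fa$p_ins[ia], p2 = fb$p_ins[ib],
       n1 = fa$n[ia], n2 = fb$n[ib], loci = common)
}

#' Nei's D_A genetic distance between two populations
#'
#' `D_A = 1/L * sum_l (1 - sum_alleles sqrt(x_l y_l))` over the insertion
#' and deletion alleles of the shared loci.
#'
#' @inheritParams pairwise_fst
#' @return the D_A distance in `[0, 1]`.
#' @examples
#' f <- locus_freqs(c("A", "B"), "L1", c(0.9, 0.1), 100)
#' nei_da(f, "A", "B")  # 0.4
#' @export
nei_da <- function(freqs, pop_a, pop_b) {
  ab <- shared_freqs(freqs, pop_a, pop_b)
  p1 <- ab$p1; p2 <- ab$p2
  mean(1 - (sqrt(p1 * p2) + sqrt((1 - p1) * (1 - p2))))
}

#' Full pairwise distance matrix over populations
#'
#' @param freqs a `locus_freqs` data frame.
#' @param metric `"FST"` (see [pairwise_fst()]) or `"DA"` (see [nei_da()]).
#' @param method F_ST estimator, passed through to [pairwise_fst()].
#' @return symmetric matrix with zero diagonal, labelled by population,
#'   with attribute `metric_name`.
#' @export
distance_matrix <- function(freqs, metric = c("FST", "DA"),
                            method = c("nei", "wc")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  pops <- unique(freqs$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      v <- if (metric == "FST")
        pairwise_fst(freqs, pops[i], pops[j], method = method)
      else nei_da(freqs, pops[i], pops[j])
      m[i, j] <- m[j, i] <- v
    }
  }
  attr(m, "metric_name") <- metric
  m
}

#' Rosenberg informativeness for assignment at one locus
#'
#' For `K` groups with insertion frequencies `p_i`,
#' \deqn{I_n = \sum_j \left[-\bar p_j \ln \bar p_j +
#'   \frac{1}{K}\sum_i p_{ij}\ln p_{ij}\right]}
#' summed over the insertion and deletion alleles, with the unweighted mean
#' \eqn{\bar p_j} over groups and `0 ln 0 = 0`. Measured in nats;
#' `I_n / ln(2)` is the population-specific divergence (PSD) scale.
#'
#' @param p numeric vector of per-group insertion frequencies (length K >= 2).
#' @return `I_n` in nats, in `[0, ln K]`.
#' @examples
#' informativeness_in(c(0.9, 0.1))  # 0.368
#' @export
informativeness_in <- function(p) {
  if (length(p) < 2) stop("need at least two groups")
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0, 1]")
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  term <- function(pj) -xlogx(mean(pj)) + mean(xlogx(pj))
  term(p) + term(1 - p)
}

#' Per-locus and cumulative informativeness for a grouping
#'
#' Computes `I_n` per locus on group-level mean frequencies and its sum
#' over the panel (informativeness is additive over independent loci).
#' Two groupings are supported, mirroring how multi-continent panels are
#' screened: `focal` one-vs-rest (the focal superpopulation against the
#' pooled remainder, K = 2), and a named `pair` of groups. With neither,
#' all groups enter jointly (K = number of groups).
#'
#' Group-level frequencies are unweighted means of the member populations'
#' frequencies; set `group_by` in [allele_frequencies()] to
#' `"superpopulation"` to weight by sample instead.
#'
#' @param freqs a `locus_freqs` data frame (populations = groups, or finer).
#' @param groups named character vector mapping each population in `freqs`
#'   to its group (e.g. [population_map()] output); `NULL` treats each
#'   population as its own group.
#' @param focal optional group label for one-vs-rest mode.
#' @param pair optional character vector of two group labels.
#' @return list with `per_locus` (data frame `locus_id`, `I_n`, `PSD`) and
#'   `cumulative` (sum of `I_n`).
#' @export
informativeness_table <- function(freqs, groups = NULL, focal = NULL,
                                  pair = NULL) {
  fm <- freq_matrix(freqs)
  if (!is.null(groups)) {
    glab <- groups[rownames(fm)]
    if (anyNA(glab)) stop("groups must cover every population in freqs")
    fm <- apply(fm, 2, function(col) tapply(col, glab, mean))
    if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1,
                                       dimnames = list(unique(glab), colnames(fm)))
  }
  if (!is.null(focal)) {
    if (!focal %in% rownames(fm)) stop("focal group '", focal, "' not found")
    rest <- colMeans(fm[setdiff(rownames(fm), focal), , drop = FALSE])
    fm <- rbind(fm[focal, ], rest)
    rownames(fm) <- c(focal, "rest")
  } else if (!is.null(pair)) {
    if (!all(pair %in% rownames(fm))) stop("pair groups not found")
    fm <- fm[pair, , drop = FALSE]
  }
  if (nrow(fm) < 2) stop("grouping must define at least two groups")
  In <- apply(fm, 2, informativeness_in)
  list(per_locus = data.frame(locus_id = colnames(fm), I_n = In,
                              PSD = In / log(2), row.names = NULL),
       cumulative = sum(In))
}
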