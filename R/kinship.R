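#' Kinship hypotheses as IBD-sharing coefficients
#'
#' A pairwise relationship is summarised by the probabilities
#' `(k0, k1, k2)` that the pair shares 0, 1 or 2 alleles identical by
#' descent at a locus. Built-ins: `unrelated` (1, 0, 0), `half_sib`
#' (0.5, 0.5, 0) — which also covers avuncular and grandparent-grandchild —
#' and `full_sib` (0.25, 0.5, 0.25).
#'
#' @param name one of `"unrelated"`, `"half_sib"`, `"full_sib"`, or any
#'   label when `k` is given explicitly.
#' @param k optional numeric vector `(k0, k1, k2)` summing to 1.
#' @return object of class `kinship_model` with fields `name`, `k0`,
#'   `k1`, `k2`.
#' @examples
#' kinship_model("full_sib")
#' kinship_model("parent_child", k = c(0, 1, 0))
#' @export
kinship_model <- function(name, k = NULL) {
  if (is.null(k)) {
    k <- switch(name,
                unrelated = c(1, 0, 0),
                half_sib = c(0.5, 0.5, 0),
                full_sib = c(0.25, 0.5, 0.25),
                stop("unknown model '", name,
                     "'; give k = c(k0, k1, k2) for a custom relationship"))
  }
  if (length(k) != 3 || any(k < 0) || any(k > 1) || abs(sum(k) - 1) > 1e-9)
    stop("k must be three probabilities summing to 1")
  structure(list(name = name, k0 = k[1], k1 = k[2], k2 = k[3]),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat(sprintf("kinship_model '%s': k0=%g k1=%g k2=%g\n",
              x$name, x$k0, x$k1, x$k2))
  invisible(x)
}

# HWE genotype probabilities indexed by dosage 0 (DD), 1 (ID), 2 (II)
hwe_geno_probs <- function(p) {
  q <- 1 - p
  c(q^2, 2 * p * q, p^2)
}

# P(second genotype | first genotype, one allele shared IBD):
# the shared allele is a random allele of g1; the other is a fresh draw.
# Rows/cols indexed by dosage 0,1,2.
ibd1_transition <- function(p) {
  q <- 1 - p
  matrix(c(q,     p,     0,
           q / 2, 1 / 2, p / 2,
           0,     q,     p),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("0", "1", "2"), c("0", "1", "2")))
}

#' Joint probability of a genotype pair under a kinship model
#'
#' Mixture over the IBD states:
#' `P = k0 P(g1)P(g2) + k1 P(g1) T(g2|g1) + k2 P(g1) [g1 = g2]`,
#' with Hardy-Weinberg genotype probabilities and the one-IBD transition
#' kernel `T`.
#'
#' @param g1,g2 genotypes as insertion dosages in \{0, 1, 2\}.
#' @param p insertion-allele frequency, strictly inside (0, 1).
#' @param model a [kinship_model()].
#' @return the joint probability.
#' @examples
#' joint_genotype_prob(2, 2, 0.5, kinship_model("full_sib"))  # 0.140625
#' @export
joint_genotype_prob <- function(g1, g2, p, model) {
  if (p <= 0 || p >= 1) stop("p must be strictly inside (0, 1)")
  stopifnot(g1 %in% 0:2, g2 %in% 0:2)
  gp <- hwe_geno_probs(p)
  tr <- ibd1_transition(p)
  gp[g1 + 1] * (model$k0 * gp[g2 + 1] +
                model$k1 * tr[g1 + 1, g2 + 1] +
                model$k2 * as.numeric(g1 == g2))
}

#' Per-locus likelihood ratio for a relationship hypothesis
#'
#' `LR = P(g1, g2 | model) / P(g1, g2 | unrelated)`, which reduces to
#' `k0 + k1 T(g2|g1)/P(g2) + k2 [g1 = g2]/P(g2)`.
#'
#' @inheritParams joint_genotype_prob
#' @return the likelihood ratio.
#' @examples
#' lr_locus(2, 2, 0.5, kinship_model("full_sib"))  # 2.25
#' @export
lr_locus <- function(g1, g2, p, model) {
  if (p <= 0 || p >= 1) stop("p must be strictly inside (0, 1)")
  stopifnot(g1 %in% 0:2, g2 %in% 0:2)
  gp <- hwe_geno_probs(p)
  tr <- ibd1_transition(p)
  model$k0 + model$k1 * tr[g1 + 1, g2 + 1] / gp[g2 + 1] +
    model$k2 * as.numeric(g1 == g2) / gp[g2 + 1]
}

#' Simulate genotype pairs under a kinship model
#'
#' For each pair and locus, an IBD state is drawn with probabilities
#' `(k0, k1, k2)`; shared alleles are copied, remaining alleles drawn
#' independently from the population allele frequencies (Hardy-Weinberg
#' within the population, loci independent — the assumptions the panel
#' screening verifies). The combined likelihood ratio of the pair under
#' `model` versus unrelatedness is the product over loci, accumulated in
#' log10 space. Monomorphic loci (p of 0 or 1) contribute no evidence and
#' are skipped with a warning.
#'
#' @param freqs a `locus_freqs` data frame for a single population (columns
#'   `locus_id`, `p_ins`).
#' @param model a [kinship_model()] (the H1 relationship).
#' @param n_pairs number of pairs to simulate.
#' @param seed integer seed; the draw is reproducible bit-for-bit.
#' @return list of class `pair_sample`: `log10_lr` (length `n_pairs`),
#'   `g1`, `g2` (pair x locus dosage matrices), `model`, `locus_ids`.
#' @export
simulate_pairs <- function(freqs, model, n_pairs, seed) {
  p <- freqs$p_ins
  keep <- p > 0 & p < 1
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic loci skipped (LR = 1)")
    p <- p[keep]
  }
  L <- length(p)
  if (L == 0) stop("no polymorphic loci to simulate from")
  set.seed(seed)
  k <- c(model$k0, model$k1, model$k2)
  g1 <- matrix(0L, n_pairs, L)
  g2 <- matrix(0L, n_pairs, L)
  for (l in seq_len(L)) {
    pl <- p[l]
    a1 <- stats::rbinom(n_pairs, 1, pl)  # individual 1 alleles
    a2 <- stats::rbinom(n_pairs, 1, pl)
    ibd <- sample.int(3, n_pairs, replace = TRUE, prob = k) - 1L
    b1 <- stats::rbinom(n_pairs, 1, pl)  # individual 2 non-shared alleles
    b2 <- stats::rbinom(n_pairs, 1, pl)
    # which of individual 1's alleles is passed when exactly one is shared
    pick <- stats::rbinom(n_pairs, 1, 0.5)
    shared1 <- ifelse(pick == 1, a1, a2)
    g1[, l] <- a1 + a2
    g2[, l] <- ifelse(ibd == 0, b1 + b2,
                      ifelse(ibd == 1, shared1 + b2, a1 + a2))
  }
  log10_lr <- numeric(n_pairs)
  for (l in seq_len(L)) {
    lrs <- outer(0:2, 0:2,
                 Vectorize(function(x, y) lr_locus(x, y, p[l], model)))
    log10_lr <- log10_lr + log10(lrs[cbind(g1[, l] + 1, g2[, l] + 1)])
  }
  structure(list(log10_lr = log10_lr, g1 = g1, g2 = g2, model = model,
                 locus_ids = freqs$locus_id[keep]),
            class = "pair_sample")
}

#' Proportion of pairs exceeding likelihood-ratio thresholds
#'
#' For simulated related pairs this is the sensitivity of the panel at each
#' LR decision threshold; applied to simulated unrelated pairs it gives the
#' corresponding false-positive rate.
#'
#' @param log10_lrs numeric vector of combined log10 likelihood ratios
#'   (or a `pair_sample`).
#' @param thresholds positive LR thresholds (natural scale).
#' @return named numeric vector of proportions with `LR >= threshold`.
#' @export
threshold_accuracy <- function(log10_lrs, thresholds = c(1, 10, 100, 1000, 10000)) {
  if (inherits(log10_lrs, "pair_sample")) log10_lrs <- log10_lrs$log10_lr
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  out <- vapply(thresholds, function(t) mean(log10_lrs >= log10(t)), numeric(1))
  names(out) <- paste0("LR>=", format(thresholds, scientific = FALSE, trim = TRUE))
  out
}
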