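#' Specification of a synthetic structured genotype panel
#'
#' Describes a hierarchical Balding-Nichols world: a global ancestor, a set
#' of continental superpopulations diverged from it at `fst_between`,
#' sub-populations diverged from their superpopulation at `fst_within`, and
#' optional target groups nested inside one superpopulation at their own
#' (typically small) divergence — the situation of a study panel genotyped
#' alongside a continental reference.
#'
#' The `"paper_like"` preset mirrors a 1000-Genomes-style reference: five
#' superpopulations with 7/5/5/5/4 sub-populations and three target groups
#' nested in the East-Asian-analogue cluster with divergence 0.01, sized in
#' the ratio of a 180/144/102-individual study scaled by `n_per_pop / 20`.
#'
#' @param superpopulations named list: superpopulation -> named integer
#'   vector of sub-population sizes.
#' @param target_groups data frame with columns `name`, `n`, `parent`,
#'   `f` (divergence of the group from its parent superpopulation).
#' @param n_loci number of loci to draw per call of
#'   [balding_nichols_freqs()].
#' @param fst_between,fst_within divergence parameters in (0, 1).
#' @param ancestral_maf_range interval within (0, 0.5] for the ancestral
#'   minor-allele frequency.
#' @param seed integer seed.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(superpopulations, target_groups = NULL, n_loci = 500,
                       fst_between = 0.15, fst_within = 0.02,
                       ancestral_maf_range = c(0.2, 0.5), seed = 1) {
  stopifnot(fst_between > 0, fst_between < 1, fst_within > 0, fst_within < 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2])
  if (!is.null(target_groups)) {
    stopifnot(all(c("name", "n", "parent", "f") %in% names(target_groups)),
              all(target_groups$parent %in% names(superpopulations)),
              all(target_groups$f > 0 & target_groups$f < 1),
              all(target_groups$n >= 1))
  }
  stopifnot(all(unlist(superpopulations) >= 1))
  structure(list(superpopulations = superpopulations,
                 target_groups = target_groups,
                 n_loci = n_loci,
                 fst_between = fst_between, fst_within = fst_within,
                 ancestral_maf_range = ancestral_maf_range,
                 seed = seed),
            class = "panel_spec")
}

#' @rdname panel_spec
#' @param preset currently `"paper_like"`.
#' @param n_per_pop sub-population sample size for the preset (default 20,
#'   keeping the full pipeline fast; use 96 for 1000G-scale panels).
#' @param seed integer seed.
#' @export
panel_spec_preset <- function(preset = "paper_like", n_per_pop = 20, seed = 1) {
  preset <- match.arg(preset)
  subpops <- function(prefix, k, n) stats::setNames(rep(n, k),
                                                    paste0(prefix, seq_len(k)))
  scale <- n_per_pop / 20
  panel_spec(
    superpopulations = list(AFR = subpops("AFR", 7, n_per_pop),
                            EUR = subpops("EUR", 5, n_per_pop),
                            EAS = subpops("EAS", 5, n_per_pop),
                            SAS = subpops("SAS", 5, n_per_pop),
                            AMR = subpops("AMR", 4, n_per_pop)),
    target_groups = data.frame(name = c("TG1", "TG2", "TG3"),
                               n = pmax(4, round(c(18, 14, 10) * scale)),
                               parent = "EAS",
                               f = 0.01,
                               stringsAsFactors = FALSE),
    n_loci = 500,
    seed = seed)
}

beta_draw <- function(parent, f) {
  if (f < 1e-8) return(parent)  # degenerate divergence: exact copy
  x <- stats::rbeta(length(parent),
                    parent * (1 - f) / f,
                    (1 - parent) * (1 - f) / f)
  pmin(pmax(x, 1e-6), 1 - 1e-6)
}

#' Draw hierarchical Balding-Nichols allele frequencies
#'
#' Ancestral insertion frequencies are uniform on the ancestral MAF range,
#' reflected to the upper half with probability 1/2; each superpopulation
#' frequency is a Beta draw with mean the ancestral frequency and
#' divergence `fst_between`; sub-population and target-group frequencies
#' are Beta draws around their parent superpopulation at `fst_within` or
#' the group's own `f`. Deterministic given `spec$seed` (override with
#' `seed`).
#'
#' @param spec a [panel_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return list of class `bn_freqs`: `ancestral` (length `n_loci`),
#'   `superpop` (superpopulations x loci matrix), `freqs` (`locus_freqs`
#'   data frame over all sub-populations and target groups; `n` is the
#'   group's diploid size), `pop_map` (population -> superpopulation;
#'   target groups map to their parent), `pop_sizes`, `is_target`.
#' @export
balding_nichols_freqs <- function(spec, seed = NULL) {
  set.seed(if (is.null(seed)) spec$seed else seed)
  L <- spec$n_loci
  maf <- stats::runif(L, spec$ancestral_maf_range[1], spec$ancestral_maf_range[2])
  flip <- stats::runif(L) < 0.5
  anc <- ifelse(flip, 1 - maf, maf)
  sups <- names(spec$superpopulations)
  sup_f <- matrix(NA_real_, length(sups), L, dimnames = list(sups, NULL))
  for (s in sups) sup_f[s, ] <- beta_draw(anc, spec$fst_between)

  pops <- character(0); parent <- character(0); sizes <- integer(0)
  is_target <- logical(0)
  rows <- list()
  for (s in sups) {
    for (p in names(spec$superpopulations[[s]])) {
      pf <- beta_draw(sup_f[s, ], spec$fst_within)
      rows[[p]] <- pf
      pops <- c(pops, p); parent <- c(parent, s)
      sizes <- c(sizes, spec$superpopulations[[s]][[p]])
      is_target <- c(is_target, FALSE)
    }
  }
  if (!is.null(spec$target_groups)) {
    for (i in seq_len(nrow(spec$target_groups))) {
      tg <- spec$target_groups[i, ]
      rows[[tg$name]] <- beta_draw(sup_f[tg$parent, ], tg$f)
      pops <- c(pops, tg$name); parent <- c(parent, tg$parent)
      sizes <- c(sizes, tg$n)
      is_target <- c(is_target, TRUE)
    }
  }
  locus_ids <- sprintf("L%05d", seq_len(L))
  freqs <- do.call(rbind, lapply(seq_along(pops), function(i)
    data.frame(population = pops[i], locus_id = locus_ids,
               p_ins = rows[[pops[i]]], n = sizes[i],
               stringsAsFactors = FALSE)))
  rownames(freqs) <- NULL
  class(freqs) <- c("locus_freqs", "data.frame")
  structure(list(ancestral = anc, superpop = `colnames<-`(sup_f, locus_ids),
                 freqs = freqs,
                 pop_map = stats::setNames(parent, pops),
                 pop_sizes = stats::setNames(sizes, pops),
                 is_target = stats::setNames(is_target, pops)),
            class = "bn_freqs")
}

#' Ancestry-informative marker selection filter
#'
#' The screening rule used to assemble AIM-InDel panels from a continental
#' frequency database: keep a biallelic locus when (1) its global
#' minor-allele frequency is at least `min_maf`; (2) the largest pairwise
#' frequency difference among the three designated "major" continental
#' groups (African / European / East-Asian analogues) exceeds
#' `min_diff_major`; and (3) the largest difference in any pair involving
#' the remaining groups exceeds `min_diff_minor`. `max_indel_len` is
#' carried as panel metadata only (fragment-length constraint of
#' capillary-electrophoresis InDel assays).
#'
#' @param min_maf minimum global minor-allele frequency (default 0.1).
#' @param min_diff_major threshold for the major groups (default 0.5).
#' @param min_diff_minor threshold for the remaining groups (default 0.2).
#' @param max_indel_len metadata, bp (default 20).
#' @return list of class `aim_filter_spec`.
#' @export
aim_filter_spec <- function(min_maf = 0.1, min_diff_major = 0.5,
                            min_diff_minor = 0.2, max_indel_len = 20) {
  stopifnot(min_maf >= 0, min_maf <= 1, min_diff_major >= 0,
            min_diff_major <= 1, min_diff_minor >= 0, min_diff_minor <= 1)
  structure(list(min_maf = min_maf, min_diff_major = min_diff_major,
                 min_diff_minor = min_diff_minor,
                 max_indel_len = max_indel_len),
            class = "aim_filter_spec")
}

#' Apply the AIM selection filter to superpopulation frequencies
#'
#' @param superpop_freqs numeric matrix, superpopulations x loci, of
#'   insertion frequencies (>= 3 rows).
#' @param filter an [aim_filter_spec()].
#' @param major_groups row names of the three "major" groups the
#'   `min_diff_major` rule applies to (default first three rows).
#' @return integer vector of retained locus column indices (empty, with a
#'   warning, when nothing passes).
#' @export
apply_aim_filter <- function(superpop_freqs, filter = aim_filter_spec(),
                             major_groups = rownames(superpop_freqs)[1:3]) {
  stopifnot(nrow(superpop_freqs) >= 3, all(major_groups %in% rownames(superpop_freqs)))
  pbar <- colMeans(superpop_freqs)
  maf_ok <- pmin(pbar, 1 - pbar) >= filter$min_maf
  rng <- function(m) apply(m, 2, max) - apply(m, 2, min)
  major <- superpop_freqs[major_groups, , drop = FALSE]
  major_ok <- rng(major) > filter$min_diff_major
  minor_groups <- setdiff(rownames(superpop_freqs), major_groups)
  if (length(minor_groups) == 0) {
    minor_ok <- rep(TRUE, ncol(superpop_freqs))
  } else {
    # largest difference over pairs with at least one non-major group
    minor_ok <- vapply(seq_len(ncol(superpop_freqs)), function(l) {
      p <- superpop_freqs[, l]
      pm <- p[minor_groups]
      max(abs(outer(pm, p, "-"))) > filter$min_diff_minor
    }, logical(1))
  }
  keep <- unname(which(maf_ok & major_ok & minor_ok))
  if (length(keep) == 0) warning("no locus passes the AIM filter")
  keep
}

#' Sample diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual's insertion dosage at each locus is Binomial(2, p) with
#' its population's frequency; loci are independent (no linkage
#' disequilibrium by construction).
#'
#' @param freqs a `locus_freqs` data frame with per-(population, locus)
#'   frequencies.
#' @param pop_sizes named integer vector of diploid sample sizes per
#'   population.
#' @param pop_map named character vector population -> superpopulation.
#' @param seed integer seed.
#' @return a [genotype_table()].
#' @export
sample_genotypes <- function(freqs, pop_sizes, pop_map, seed) {
  set.seed(seed)
  pops <- names(pop_sizes)
  locus_ids <- unique(freqs$locus_id)
  L <- length(locus_ids)
  blocks <- list()
  pop_lab <- character(0); ids <- character(0)
  for (pop in pops) {
    fp <- freqs[freqs$population == pop, ]
    p <- fp$p_ins[match(locus_ids, fp$locus_id)]
    if (anyNA(p)) stop("missing frequencies for population ", pop)
    n <- pop_sizes[[pop]]
    blocks[[pop]] <- matrix(stats::rbinom(n * L, 2, rep(p, each = n)), n, L)
    pop_lab <- c(pop_lab, rep(pop, n))
    ids <- c(ids, sprintf("%s_%03d", pop, seq_len(n)))
  }
  dosage <- do.call(rbind, blocks)
  genotype_table(dosage,
                 population = pop_lab,
                 superpopulation = unname(pop_map[pop_lab]),
                 loci = data.frame(locus_id = locus_ids, chromosome = "1",
                                   position = seq_len(L) * 1000L,
                                   stringsAsFactors = FALSE),
                 sample_ids = ids)
}

#' Generate a reference panel of AIM-like loci
#'
#' Draws Balding-Nichols loci in batches, applies the AIM selection filter
#' to the superpopulation-level frequencies (major groups: the AFR, EUR
#' and EAS analogues) and repeats until `n_loci` loci pass; then samples
#' Hardy-Weinberg genotypes for every sub-population and target group at
#' the retained loci. This reproduces the statistical situation of a
#' curated ancestry panel: strongly differentiated, common, unlinked
#' biallelic markers.
#'
#' @param preset passed to [panel_spec_preset()], or give `spec` directly.
#' @param spec optional [panel_spec()] overriding the preset.
#' @param n_loci number of retained loci (default 56).
#' @param n_per_pop preset sub-population size (default 20).
#' @param filter an [aim_filter_spec()].
#' @param seed integer seed (drives locus generation and genotype draw).
#' @param max_batches safety cap on generation rounds.
#' @return list of class `reference_panel`: `table` (a
#'   [genotype_table()]), `freqs` (true generating frequencies at the
#'   retained loci, a `locus_freqs` data frame), `superpop_freqs`
#'   (superpopulation-level truth), `spec`, `filter`.
#' @export
make_reference_panel <- function(preset = "paper_like", spec = NULL,
                                 n_loci = 56, n_per_pop = 20,
                                 filter = aim_filter_spec(), seed = 1,
                                 max_batches = 50) {
  if (is.null(spec)) spec <- panel_spec_preset(preset, n_per_pop = n_per_pop,
                                               seed = seed)
  major <- names(spec$superpopulations)[
    names(spec$superpopulations) %in% c("AFR", "EUR", "EAS")]
  if (length(major) != 3) major <- names(spec$superpopulations)[1:3]

  kept_freqs <- list(); kept_sup <- list()
  total <- 0L; batch <- 0L
  meta <- NULL
  while (total < n_loci) {
    batch <- batch + 1L
    if (batch > max_batches)
      stop("AIM filter retained fewer than ", n_loci, " loci after ",
           max_batches, " batches; relax the filter or the divergence spec")
    bn <- balding_nichols_freqs(spec, seed = derive_seed(seed, paste0("batch", batch)))
    keep <- suppressWarnings(apply_aim_filter(bn$superpop, filter, major_groups = major))
    if (length(keep) == 0) next
    ids <- colnames(bn$superpop)[keep]
    kept_sup[[batch]] <- bn$superpop[, keep, drop = FALSE]
    kept_freqs[[batch]] <- bn$freqs[bn$freqs$locus_id %in% ids, ]
    # batch-qualify ids so batches never collide
    kept_freqs[[batch]]$locus_id <- paste0("b", batch, "_", kept_freqs[[batch]]$locus_id)
    colnames(kept_sup[[batch]]) <- paste0("b", batch, "_", colnames(kept_sup[[batch]]))
    total <- total + length(keep)
    meta <- bn
  }
  sup <- do.call(cbind, kept_sup)[, seq_len(n_loci), drop = FALSE]
  freqs <- do.call(rbind, kept_freqs)
  freqs <- freqs[freqs$locus_id %in% colnames(sup), ]
  # relabel retained loci as a clean panel
  panel_ids <- stats::setNames(sprintf("AIM%03d", seq_len(n_loci)), colnames(sup))
  freqs$locus_id <- unname(panel_ids[freqs$locus_id])
  colnames(sup) <- unname(panel_ids)
  freqs <- freqs[order(match(freqs$population, names(meta$pop_sizes)),
                       match(freqs$locus_id, colnames(sup))), ]
  rownames(freqs) <- NULL
  class(freqs) <- c("locus_freqs", "data.frame")

  table <- sample_genotypes(freqs, meta$pop_sizes, meta$pop_map,
                            seed = derive_seed(seed, "genotypes"))
  structure(list(table = table, freqs = freqs, superpop_freqs = sup,
                 pop_map = meta$pop_map, is_target = meta$is_target,
                 spec = spec, filter = filter),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", n_samples(x$table), "samples,",
      n_loci(x$table), "AIM-like loci,",
      length(unique(x$table$population)), "populations\n")
  invisible(x)
}
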