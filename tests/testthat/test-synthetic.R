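test_that("panel specs validate their parameters", {
  expect_s3_class(panel_spec_preset(), "panel_spec")
  expect_error(panel_spec(list(A = c(A1 = 10)), fst_between = 0), "fst_between")
  expect_error(panel_spec(list(A = c(A1 = 10)),
                          ancestral_maf_range = c(0.2, 0.7)), "maf")
  expect_error(panel_spec(list(A = c(A1 = 10)),
                          target_groups = data.frame(name = "T", n = 5,
                                                     parent = "B", f = 0.01)),
               "parent")
})

test_that("Balding-Nichols draws are reproducible and centred on their parents", {
  spec <- panel_spec(list(A = c(A1 = 50, A2 = 50), B = c(B1 = 50)),
                     n_loci = 2000, fst_between = 0.1, fst_within = 0.02,
                     seed = 171)
  bn1 <- balding_nichols_freqs(spec)
  bn2 <- balding_nichols_freqs(spec)
  expect_identical(bn1$freqs$p_ins, bn2$freqs$p_ins)
  # Beta mean identity: sub-population frequencies average to the parent
  a1 <- bn1$freqs$p_ins[bn1$freqs$population == "A1"]
  dev <- a1 - bn1$superpop["A", ]
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se + 1e-3)
  # superpopulations average to the ancestral frequency
  dev2 <- bn1$superpop["A", ] - bn1$ancestral
  expect_lt(abs(mean(dev2)), 3 * sd(dev2) / sqrt(length(dev2)) + 1e-3)
  # degenerate divergence copies the parent exactly
  spec0 <- panel_spec(list(A = c(A1 = 10)), n_loci = 50, fst_between = 1e-9,
                      fst_within = 1e-9, seed = 3)
  bn0 <- balding_nichols_freqs(spec0)
  expect_equal(bn0$freqs$p_ins, unname(bn0$ancestral))
})

test_that("AIM filter applies the three selection rules", {
  sup <- rbind(AFR = c(0.90, 0.50, 0.96, 0.90),
               EUR = c(0.20, 0.50, 0.30, 0.20),
               EAS = c(0.30, 0.50, 0.35, 0.30),
               SAS = c(0.40, 0.50, 0.33, 0.61),
               AMR = c(0.50, 0.50, 0.32, 0.62))
  keep <- apply_aim_filter(sup, aim_filter_spec(),
                           major_groups = c("AFR", "EUR", "EAS"))
  # locus 1: major range 0.7 > 0.5, MAF 0.46, minor diffs fine -> retained
  expect_true(1 %in% keep)
  # locus 2: all frequencies equal -> rejected
  expect_false(2 %in% keep)
  # locus 3: major range 0.66, minor diffs up to 0.63 -> retained
  expect_true(3 %in% keep)
  # locus 4 passes all three rules
  expect_true(4 %in% keep)
  # a rare locus fails on MAF regardless of differences
  sup2 <- rbind(AFR = 0.16, EUR = 0.001, EAS = 0.001, SAS = 0.05, AMR = 0.05)
  expect_warning(k2 <- apply_aim_filter(sup2, aim_filter_spec(),
                                        major_groups = c("AFR", "EUR", "EAS")))
  expect_length(k2, 0)
})

test_that("sampled genotypes respect Hardy-Weinberg and fixed loci", {
  f1 <- locus_freqs("P", "L1", 1, 30)
  gt <- sample_genotypes(f1, c(P = 30), c(P = "S"), seed = 181)
  expect_true(all(gt$dosage == 2))
  # HWE exact-test rejection rate across loci stays near nominal
  spec <- panel_spec(list(A = c(A1 = 200)), n_loci = 400, fst_between = 0.05,
                     fst_within = 1e-9, seed = 182)
  bn <- balding_nichols_freqs(spec)
  gt2 <- sample_genotypes(bn$freqs, bn$pop_sizes, bn$pop_map, seed = 183)
  hw <- hwe_test_table(gt2)
  expect_lte(mean(hw$p_value <= 0.05), 0.08)
  # bit-for-bit reproducibility
  gt3 <- sample_genotypes(bn$freqs, bn$pop_sizes, bn$pop_map, seed = 183)
  expect_identical(gt2$dosage, gt3$dosage)
})

test_that("the paper-like reference panel honours its construction contract", {
  panel <- make_reference_panel(seed = 191)
  expect_equal(n_loci(panel$table), 56)
  expect_equal(length(unique(panel$table$population)), 29)
  expect_equal(length(unique(panel$table$superpopulation)), 5)
  expect_equal(sort(names(panel$is_target)[panel$is_target]),
               c("TG1", "TG2", "TG3"))
  # every retained locus passes the AIM filter on the generating truth
  keep <- apply_aim_filter(panel$superpop_freqs, panel$filter,
                           major_groups = c("AFR", "EUR", "EAS"))
  expect_equal(keep, seq_len(56))
  # target groups sit inside their parent superpopulation
  freqs <- allele_frequencies(panel$table)
  fst <- distance_matrix(freqs, "FST")
  refs <- setdiff(rownames(fst), c("TG1", "TG2", "TG3"))
  for (tg in c("TG1", "TG2", "TG3")) {
    nearest <- refs[which.min(fst[tg, refs])]
    expect_equal(unname(panel$pop_map[nearest]), "EAS",
                 label = paste("nearest reference of", tg))
  }
  # individual-level PCA splits the AFR and EAS analogue clusters
  enc <- encode(panel$table)
  ord <- pca_ordination(enc$x, standardize = FALSE, k = 2)
  sup <- panel$table$superpopulation
  afr <- ord$coordinates[sup == "AFR", 1:2, drop = FALSE]
  eas <- ord$coordinates[sup == "EAS", 1:2, drop = FALSE]
  # silhouette-style check: every AFR point closer to the AFR centroid
  ca <- colMeans(afr); ce <- colMeans(eas)
  dsep <- function(m, c1, c2)
    mean(sqrt(rowSums(sweep(m, 2, c1)^2)) < sqrt(rowSums(sweep(m, 2, c2)^2)))
  expect_gt(dsep(afr, ca, ce), 0.99)
  expect_gt(dsep(eas, ce, ca), 0.99)
})

test_that("panel generation is deterministic in its seed", {
  p1 <- make_reference_panel(n_per_pop = 6, n_loci = 12, seed = 201)
  p2 <- make_reference_panel(n_per_pop = 6, n_loci = 12, seed = 201)
  expect_identical(p1$table$dosage, p2$table$dosage)
  expect_identical(p1$freqs$p_ins, p2$freqs$p_ins)
  p3 <- make_reference_panel(n_per_pop = 6, n_loci = 12, seed = 202)
  expect_false(identical(p1$table$dosage, p3$table$dosage))
})
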