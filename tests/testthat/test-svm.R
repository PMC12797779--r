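digest_features <- function(x) c(dim(x), sum(x), sum(x^2), sum(x * seq_along(x)))

make_blobs <- function(n_per = 30, classes = c("A", "B"), sep = 6, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(i)
    matrix(rnorm(n_per * 4, mean = i * sep), n_per, 4)))
  colnames(x) <- paste0("f", 1:4)
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  list(x = x, y = factor(rep(classes, each = n_per)),
       sample_ids = rownames(x))
}

test_that("encoding exposes dosages and training-only imputation", {
  gt <- tiny_table()
  enc <- encode(gt)
  expect_equal(unname(enc$x[, 1]), c(2, 1, 1))
  expect_equal(levels(enc$y), c("S1", "S2"))
  # imputation means come from the training rows only
  train_x <- matrix(c(2, 0, NA, 1, 1, 1), 3, 2,
                    dimnames = list(NULL, c("a", "b")))
  imp <- fit_imputer(train_x)
  test_x <- matrix(c(NA, NA), 1, 2, dimnames = list(NULL, c("a", "b")))
  filled <- apply_imputer(imp, test_x)
  expect_equal(unname(filled[1, ]), c(1, 1))  # means of (2,0) and (1,1,1)
  # perturbing the test set does not move the imputed values
  test_x2 <- matrix(c(NA, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(apply_imputer(imp, test_x2)[1, "a"], c(a = 1))
  # all-missing training locus dropped with a warning; absent locus errors
  train_bad <- cbind(train_x, cc = NA_real_)
  expect_warning(imp2 <- fit_imputer(train_bad), "all-missing")
  expect_equal(imp2$keep, c("a", "b"))
  expect_error(apply_imputer(imp, test_x[, "a", drop = FALSE]), "missing")
})

test_that("weighted F1 matches the confusion-matrix hand computation", {
  sc <- weighted_f1(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(sc$per_class), c(2 / 3, 0.8))
  expect_equal(sc$weighted, 0.5 * 2 / 3 + 0.5 * 0.8)
  perfect <- weighted_f1(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(perfect$per_class), rep(1, 3))
  # invariant to a bijective relabelling
  ren <- weighted_f1(c("X", "X", "Y", "Y"), c("X", "Y", "Y", "Y"))
  expect_equal(ren$weighted, sc$weighted)
  # absent predictions give F1 = 0, not NaN
  none <- weighted_f1(c("A", "B"), c("B", "A"))
  expect_equal(unname(none$per_class), c(0, 0))
  expect_error(weighted_f1(character(0), character(0)), "empty")
})

test_that("tuned SVM separates blobs and is deterministic in its seed", {
  blobs <- make_blobs()
  fit1 <- tune_and_train(blobs$x, blobs$y, budget = 8, seed = 5)
  expect_equal(weighted_f1(blobs$y, predict(fit1$model, blobs$x))$weighted, 1)
  fit2 <- tune_and_train(blobs$x, blobs$y, budget = 8, seed = 5)
  expect_equal(c(fit1$C, fit1$gamma), c(fit2$C, fit2$gamma))
  expect_equal(fit1$cv_f1, fit2$cv_f1)
  fit3 <- tune_and_train(blobs$x, blobs$y, budget = 8, seed = 6)
  expect_false(identical(fit1$C, fit3$C))
  few <- c(1:2, 31:32)  # two members per class: cannot stratify 4 folds
  expect_error(tune_and_train(blobs$x[few, ], droplevels(blobs$y[few]),
                              budget = 2, seed = 1),
               "fewer than")
})

test_that("held-out classification is strong on the default reference panel", {
  panel <- make_reference_panel(seed = 151)  # 56 AIM loci, 26 reference pops
  enc <- encode(panel$table[!panel$table$population %in% c("TG1", "TG2", "TG3")])
  split <- stratified_split(enc$y, 0.2, seed = 152)
  fit <- tune_and_train(enc$x[split$train, ], droplevels(enc$y[split$train]),
                        budget = 10, seed = 153)
  f1 <- weighted_f1(enc$y[split$test],
                    predict(fit$model, enc$x[split$test, ]))$weighted
  expect_gt(f1, 0.95)
})

test_that("label-noise injection preserves the label multiset and reports mismatch", {
  y <- factor(rep(c("A", "B", "C", "D", "E"), each = 20))
  z0 <- inject_label_noise(y, 0, seed = 1)
  expect_identical(z0$labels, y)
  expect_equal(z0$realized_mismatch, 0)
  z1 <- inject_label_noise(y, 1, seed = 2)
  expect_equal(as.vector(table(z1$labels)), as.vector(table(y)))
  expect_false(identical(z1$labels, y))
  # nominal 0.5 with 5 equal classes: realised mismatch near 0.5 * (1 - 1/5)
  reals <- vapply(1:200, function(s)
    inject_label_noise(y, 0.5, seed = s)$realized_mismatch, numeric(1))
  expect_lt(abs(mean(reals) - 0.5 * (1 - 0.2)), 0.02)
  # resample mechanism draws from the class universe
  z2 <- inject_label_noise(y, 0.5, seed = 3, mechanism = "resample")
  expect_true(all(z2$labels %in% levels(y)))
  expect_error(inject_label_noise(y, 1.2, seed = 1), "fraction")
})

test_that("noise injection touches labels only, never features", {
  blobs <- make_blobs(n_per = 20, classes = c("A", "B", "C"))
  before <- digest_features(blobs$x)
  inject_label_noise(blobs$y, 0.6, seed = 9)
  expect_identical(digest_features(blobs$x), before)
})

test_that("noise experiment degrades with noise and keeps robust classes robust", {
  # 5 classes: A and B far from everything, C/D/E close together
  set.seed(161)
  centers <- rbind(A = c(12, 0), B = c(-12, 0),
                   C = c(0, 0), D = c(0, 1.2), E = c(0, 2.4))
  mk <- function(n_per, seed) {
    set.seed(seed)
    x <- do.call(rbind, lapply(rownames(centers), function(cl)
      sweep(matrix(rnorm(n_per * 2), n_per, 2), 2, centers[cl, ], "+")))
    colnames(x) <- c("f1", "f2")
    rownames(x) <- sprintf("s%d_%03d", seed, seq_len(nrow(x)))
    list(x = x, y = factor(rep(rownames(centers), each = n_per)),
         sample_ids = rownames(x))
  }
  train <- mk(16, 162)
  test <- mk(10, 163)
  ne <- noise_experiment(train, test, fractions = c(0.01, 0.4, 0.8),
                         repetitions = 2, seed = 164, budget = 6,
                         cv_folds = 4)
  expect_equal(ne$results$rep[ne$results$class == "weighted" &
                                ne$results$set == "test"],
               rep(1:2, times = 3))
  expect_true(all(ne$results$realized_mismatch >= 0 &
                    ne$results$realized_mismatch <= 1))
  s <- ne$summary
  w <- s[s$class == "weighted" & s$set == "test", ]
  expect_lt(w$f1[w$fraction == 0.8], w$f1[w$fraction == 0.01])
  # well-separated classes hold up better at heavy noise than the close trio
  heavy <- s[s$fraction == 0.4 & s$set == "test", ]
  strong <- mean(heavy$f1[heavy$class %in% c("A", "B")])
  weak <- mean(heavy$f1[heavy$class %in% c("C", "D", "E")])
  expect_gt(strong, weak)
  # identical seed reproduces identical scores
  ne2 <- noise_experiment(train, test, fractions = 0.01, repetitions = 1,
                          seed = 164, budget = 6, cv_folds = 4)
  expect_equal(ne2$results$f1,
               ne$results$f1[ne$results$fraction == 0.01 & ne$results$rep == 1])
  expect_error(noise_experiment(train, train, fractions = 0, seed = 1),
               "share sample ids")
})
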