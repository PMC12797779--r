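#' Encode a genotype table as an SVM feature matrix
#'
#' Features are per-locus insertion-allele dosages; the class label is the
#' superpopulation. Missing dosages are left as `NA` here — imputation is
#' fit on the training split only (see [fit_imputer()]) so no information
#' leaks from evaluation data.
#'
#' @param table a [genotype_table()].
#' @return list with `x` (numeric samples x loci matrix), `y` (factor of
#'   superpopulation labels), `sample_ids`.
#' @export
encode <- function(table) {
  validate_genotype_table(table)
  x <- table$dosage
  storage.mode(x) <- "double"
  list(x = x, y = factor(table$superpopulation), sample_ids = table$sample_ids)
}

#' Fit / apply training-set mean imputation
#'
#' `fit_imputer` records per-locus means over the non-missing training
#' dosages and flags loci that are entirely missing in training (dropped
#' with a warning). `apply_imputer` fills missing values in any matrix with
#' those training means and errors if a recorded locus is absent.
#'
#' @param train_x training feature matrix (may contain `NA`).
#' @return `fit_imputer`: list with `means` and `keep`;
#'   `apply_imputer`: the imputed matrix restricted to kept loci.
#' @export
fit_imputer <- function(train_x) {
  means <- colMeans(train_x, na.rm = TRUE)
  keep <- !is.nan(means)
  if (!all(keep))
    warning("dropping ", sum(!keep), " all-missing training locus/loci: ",
            paste(utils::head(colnames(train_x)[!keep]), collapse = ", "))
  list(means = means[keep], keep = colnames(train_x)[keep])
}

#' @rdname fit_imputer
#' @param imputer a fitted imputer.
#' @param x feature matrix to impute.
#' @export
apply_imputer <- function(imputer, x) {
  if (!all(imputer$keep %in% colnames(x)))
    stop("matrix is missing training loci: ",
         paste(utils::head(setdiff(imputer$keep, colnames(x))), collapse = ", "))
  x <- x[, imputer$keep, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- imputer$means[j]
  }
  x
}

#' Stratified train/test split
#'
#' Splits sample indices so each class contributes `test_frac` of its
#' members (rounded) to the test set; deterministic given `seed`.
#'
#' @param y factor of class labels.
#' @param test_frac fraction assigned to the test set (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_frac = 0.2, seed) {
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * test_frac)
    test <- c(test, idx[sample.int(length(idx), n_test)])
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Per-class and weighted F1 scores
#'
#' Per-class F1 is `2PR/(P+R)` (defined as 0 when precision and recall are
#' both 0); the weighted F1 averages per-class F1 with weights proportional
#' to the true class sizes.
#'
#' @param true,predicted label vectors of equal length.
#' @return list with `per_class` (named vector over the true-label
#'   universe) and `weighted`.
#' @examples
#' weighted_f1(c("A", "A", "B", "B"), c("A", "B", "B", "B"))$weighted  # 0.7333
#' @export
weighted_f1 <- function(true, predicted) {
  if (length(true) == 0) stop("empty input")
  if (length(true) != length(predicted)) stop("length mismatch")
  true <- as.character(true); predicted <- as.character(predicted)
  classes <- sort(unique(true))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  w <- as.numeric(table(factor(true, levels = classes))) / length(true)
  list(per_class = f1, weighted = sum(w * f1))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    if (length(idx) < k)
      stop("class ", cl, " has fewer than ", k, " samples; cannot stratify folds")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune and train an RBF-kernel SVM for ancestry classification
#'
#' Hyperparameters `C` and `gamma` are chosen by randomised search over
#' log-uniform ranges, scoring each candidate by stratified k-fold
#' cross-validated weighted F1 on the training data, then refitting on the
#' full training set. The search is a derivative-free global optimiser in
#' the same spirit as Bayesian optimisation; with the budgets used here the
#' two explore the 2-D log-space comparably, and the randomised form keeps
#' the result deterministic given `seed` with no extra dependency.
#'
#' @param x training feature matrix (no missing values; see
#'   [apply_imputer()]).
#' @param y factor of training labels (every class with >= `cv_folds`
#'   members).
#' @param cv_folds folds for cross-validation (default 4).
#' @param budget number of (C, gamma) evaluations (default 40).
#' @param c_range,gamma_range log-uniform search bounds.
#' @param seed integer seed controlling the search and fold assignment.
#' @return list of class `svm_fit`: `model` (an `e1071::svm`), `C`,
#'   `gamma`, `cv_f1` (best cross-validated weighted F1), `trace`
#'   (data frame of all evaluations).
#' @export
tune_and_train <- function(x, y, cv_folds = 4, budget = 40,
                           c_range = c(1e-2, 1e3),
                           gamma_range = c(1e-4, 1e1), seed = 1) {
  y <- droplevels(factor(y))
  if (anyNA(x)) stop("feature matrix contains NA; impute first")
  fold <- stratified_folds(y, cv_folds, derive_seed(seed, "folds"))
  set.seed(derive_seed(seed, "search"))
  cand_C <- exp(stats::runif(budget, log(c_range[1]), log(c_range[2])))
  cand_g <- exp(stats::runif(budget, log(gamma_range[1]), log(gamma_range[2])))
  score <- numeric(budget)
  for (i in seq_len(budget)) {
    f1s <- numeric(cv_folds)
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cand_C[i], gamma = cand_g[i], scale = FALSE)
      pred <- stats::predict(m, x[!tr, , drop = FALSE])
      f1s[k] <- weighted_f1(y[!tr], pred)$weighted
    }
    score[i] <- mean(f1s)
  }
  best <- which.max(score)
  model <- e1071::svm(x, y, kernel = "radial", cost = cand_C[best],
                      gamma = cand_g[best], scale = FALSE)
  structure(list(model = model, C = cand_C[best], gamma = cand_g[best],
                 cv_f1 = score[best],
                 trace = data.frame(C = cand_C, gamma = cand_g, cv_f1 = score)),
            class = "svm_fit")
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("RBF SVM: C = %.4g, gamma = %.4g (CV weighted F1 = %.4f)\n",
              x$C, x$gamma, x$cv_f1))
  invisible(x)
}

#' Inject label noise by shuffling a random subset of labels
#'
#' `ceiling(fraction * N)` positions are chosen uniformly without
#' replacement and their labels permuted among themselves by a uniform
#' random permutation (so the overall label multiset is preserved). With
#' `mechanism = "resample"` the selected labels are instead replaced by
#' uniform draws from the class universe. Because a shuffled label can
#' land back on its own class, the realised fraction of changed labels is
#' below the nominal fraction; it is always reported.
#'
#' @param labels vector or factor of class labels.
#' @param fraction nominal noise fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param mechanism `"shuffle"` (default) or `"resample"`.
#' @return list with `labels` (noisy labels, same type as input) and
#'   `realized_mismatch` (fraction of all labels actually changed).
#' @export
inject_label_noise <- function(labels, fraction, seed,
                               mechanism = c("shuffle", "resample")) {
  mechanism <- match.arg(mechanism)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  set.seed(seed)
  n <- length(labels)
  out <- labels
  m <- ceiling(fraction * n)
  if (m > 0) {
    idx <- sample.int(n, m)
    if (mechanism == "shuffle") {
      out[idx] <- out[idx][sample.int(m)]
    } else {
      classes <- if (is.factor(labels)) levels(labels) else unique(labels)
      out[idx] <- sample(classes, m, replace = TRUE)
    }
  }
  list(labels = out, realized_mismatch = mean(out != labels))
}

#' Label-noise robustness experiment
#'
#' For each nominal noise fraction and repetition: inject noise into the
#' training labels only, tune and train the SVM, and score per-class and
#' weighted F1 on the untouched test set (and external set if given).
#' Repetition means per fraction summarise the protocol.
#'
#' @param train,test,external encoded feature sets (lists with `x`, `y`,
#'   as returned by [encode()]); `external` may be `NULL`. Missing values
#'   are imputed from the (noisy-label-free) training features.
#' @param fractions nominal noise fractions
#'   (default `c(0.01, 0.1, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8)`, i.e. the
#'   normal:noisy ratios 99:1 through 2:8).
#' @param repetitions repetitions per fraction (default 10).
#' @param seed integer seed; every (fraction, repetition) derives its own.
#' @param budget,cv_folds tuning parameters, see [tune_and_train()].
#' @return list of class `noise_experiment`: `results` (long data frame:
#'   `fraction`, `rep`, `realized_mismatch`, `set`, `class` — a class label
#'   or `"weighted"` — and `f1`) and `summary` (means over repetitions).
#' @export
noise_experiment <- function(train, test, external = NULL,
                             fractions = c(0.01, 0.1, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8),
                             repetitions = 10, seed = 1,
                             budget = 40, cv_folds = 4) {
  if (length(intersect(train$sample_ids, test$sample_ids)) > 0)
    stop("train and test sets share sample ids")
  imp <- fit_imputer(train$x)
  xtr <- apply_imputer(imp, train$x)
  xte <- apply_imputer(imp, test$x)
  xex <- if (!is.null(external)) apply_imputer(imp, external$x)
  rows <- list()
  for (f in fractions) {
    for (r in seq_len(repetitions)) {
      s <- derive_seed(seed, sprintf("noise_%g_rep_%d", f, r))
      noisy <- inject_label_noise(train$y, f, seed = s)
      fit <- tune_and_train(xtr, noisy$labels, cv_folds = cv_folds,
                            budget = budget, seed = s)
      score_set <- function(x, y, set_name) {
        sc <- weighted_f1(y, stats::predict(fit$model, x))
        data.frame(fraction = f, rep = r,
                   realized_mismatch = noisy$realized_mismatch,
                   set = set_name,
                   class = c(names(sc$per_class), "weighted"),
                   f1 = c(sc$per_class, sc$weighted),
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- score_set(xte, test$y, "test")
      if (!is.null(external))
        rows[[length(rows) + 1]] <- score_set(xex, external$y, "external")
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- stats::aggregate(f1 ~ fraction + set + class, data = results, FUN = mean)
  structure(list(results = results, summary = summary),
            class = "noise_experiment")
}
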