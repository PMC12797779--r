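#' Run the full panel analysis pipeline
#'
#' Orchestrates the stages of the panel characterisation workflow —
#' `simulate` (or ingest), `stats`, `kinship`, `divergence`, `ordination`,
#' `bga` — from a single configuration, writing per-stage CSV outputs and
#' a JSON run manifest under `out_dir`. Every stage derives its own seed
#' deterministically from the global seed, so identical configurations
#' yield byte-identical CSV outputs.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with elements:
#' \describe{
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{seed}{global integer seed (default 1).}
#'   \item{stages}{character vector of stages to run (default all).}
#'   \item{input}{either `list(preset = "paper_like", n_per_pop =, n_loci =)`
#'     for synthetic data or `list(csv = path)` for a dosage CSV.}
#'   \item{stats}{`list(ld_populations =, ld_n_perm =)`; LD testing is run
#'     only for the listed populations (default: the simulated target
#'     groups, or none for CSV input).}
#'   \item{kinship}{`list(population =, models =, n_pairs =, thresholds =)`.}
#'   \item{bga}{`list(fractions =, repetitions =, budget =, cv_folds =,
#'     test_frac =, external_superpops =)`.}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`). A failing stage halts the run with the stage named;
#'   outputs of completed stages are retained.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  all_stages <- c("simulate", "stats", "kinship", "divergence", "ordination", "bga")
  stages <- if (is.null(config$stages)) all_stages else config$stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = seed, stages = list())
  state <- new.env()
  write_csv6 <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% stages) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(fun(derive_seed(seed, name)),
               error = function(e) stop("stage '", name, "' failed: ",
                                        conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "complete",
      seed = derive_seed(seed, name),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      warnings = warns)
    invisible(res)
  }

  ## --- simulate / ingest ---------------------------------------------------
  run_stage("simulate", function(sseed) {
    d <- file.path(out_dir, "sim"); dir.create(d, showWarnings = FALSE)
    input <- config$input
    if (!is.null(input$csv)) {
      state$table <- read_csv_genotypes(input$csv)
      state$target_pops <- input$target_populations
    } else {
      n_per_pop <- if (is.null(input$n_per_pop)) 20 else input$n_per_pop
      n_loci <- if (is.null(input$n_loci)) 56 else input$n_loci
      panel <- make_reference_panel(n_loci = n_loci, n_per_pop = n_per_pop,
                                    seed = sseed)
      state$table <- panel$table
      state$panel <- panel
      state$target_pops <- names(panel$is_target)[panel$is_target]
      write_csv_genotypes(panel$table, file.path(d, "table.csv"))
      write_csv6(panel$freqs, file.path(d, "freqs.csv"))
      yaml::write_yaml(list(preset = "paper_like", n_per_pop = n_per_pop,
                            n_loci = n_loci, seed = sseed),
                       file.path(d, "spec.yaml"))
    }
    invisible(NULL)
  })
  if (is.null(state$table))
    stop("no input available: enable the 'simulate' stage or provide input$csv")

  ## --- stats ---------------------------------------------------------------
  run_stage("stats", function(sseed) {
    d <- file.path(out_dir, "stats"); dir.create(d, showWarnings = FALSE)
    freqs <- allele_frequencies(state$table)
    state$freqs <- freqs
    write_csv6(freqs, file.path(d, "frequencies.csv"))
    write_csv6(forensic_params_table(state$table),
               file.path(d, "forensic_params.csv"))
    write_csv6(hwe_test_table(state$table), file.path(d, "hwe.csv"))
    fp <- forensic_params_table(state$table)
    cum <- do.call(rbind, lapply(split(fp, fp$population), function(g) {
      cp <- cumulative_power(g)
      data.frame(population = g$population[1], CPD = cp[["CPD"]],
                 CPE = cp[["CPE"]])
    }))
    write_csv6(cum, file.path(d, "cumulative_power.csv"))
    ld_pops <- if (!is.null(config$stats$ld_populations))
      config$stats$ld_populations else state$target_pops
    if (length(ld_pops)) {
      n_perm <- if (is.null(config$stats$ld_n_perm)) 199 else config$stats$ld_n_perm
      sub <- state$table[state$table$population %in% ld_pops]
      write_csv6(ld_test_table(sub, n_perm = n_perm, seed = sseed),
                 file.path(d, "ld.csv"))
    }
    invisible(NULL)
  })

  ## --- kinship -------------------------------------------------------------
  run_stage("kinship", function(sseed) {
    d <- file.path(out_dir, "kinship"); dir.create(d, showWarnings = FALSE)
    cfg <- config$kinship
    if (is.null(state$freqs)) state$freqs <- allele_frequencies(state$table)
    pops <- cfg$population
    if (is.null(pops)) pops <- if (length(state$target_pops))
      state$target_pops else unique(state$freqs$population)[1]
    models <- if (is.null(cfg$models)) c("full_sib", "half_sib") else cfg$models
    n_pairs <- if (is.null(cfg$n_pairs)) 1000 else cfg$n_pairs
    thresholds <- if (is.null(cfg$thresholds)) c(1, 10, 100, 1000, 10000)
      else cfg$thresholds
    acc_rows <- list(); lr_rows <- list()
    for (pop in pops) {
      fp <- state$freqs[state$freqs$population == pop, ]
      for (mod in models) {
        sim <- suppressWarnings(
          simulate_pairs(fp, kinship_model(mod), n_pairs,
                         seed = derive_seed(sseed, paste(pop, mod))))
        un <- suppressWarnings(
          simulate_pairs(fp, kinship_model("unrelated"), n_pairs,
                         seed = derive_seed(sseed, paste(pop, mod, "h0"))))
        un$log10_lr <- recompute_lr(un, fp, kinship_model(mod))
        acc <- threshold_accuracy(sim, thresholds)
        fpr <- threshold_accuracy(un$log10_lr, thresholds)
        acc_rows[[paste(pop, mod)]] <- data.frame(
          population = pop, model = mod, threshold = thresholds,
          sensitivity = unname(acc), false_positive_rate = unname(fpr))
        lr_rows[[paste(pop, mod)]] <- data.frame(
          population = pop, model = mod, hypothesis = rep(c("H1", "H0"),
                                                          each = n_pairs),
          log10_lr = c(sim$log10_lr, un$log10_lr))
      }
    }
    write_csv6(do.call(rbind, acc_rows), file.path(d, "accuracy.csv"))
    write_csv6(do.call(rbind, lr_rows), file.path(d, "log10lr.csv"))
    invisible(NULL)
  })

  ## --- divergence ----------------------------------------------------------
  run_stage("divergence", function(sseed) {
    d <- file.path(out_dir, "divergence"); dir.create(d, showWarnings = FALSE)
    if (is.null(state$freqs)) state$freqs <- allele_frequencies(state$table)
    fst <- distance_matrix(state$freqs, "FST")
    da <- distance_matrix(state$freqs, "DA")
    state$fst <- fst; state$da <- da
    write_labelled_matrix(fst, file.path(d, "fst.csv"))
    write_labelled_matrix(da, file.path(d, "da.csv"))
    groups <- population_map(state$table)
    sups <- unique(unname(groups))
    rows <- list(); cum <- list()
    for (s in sups) {
      it <- informativeness_table(state$freqs, groups = groups, focal = s)
      rows[[s]] <- cbind(group = s, it$per_locus)
      cum[[s]] <- data.frame(group = s, cumulative_In = it$cumulative)
    }
    write_csv6(do.call(rbind, rows), file.path(d, "in_values.csv"))
    write_csv6(do.call(rbind, cum), file.path(d, "in_cumulative.csv"))
    invisible(NULL)
  })

  ## --- ordination ----------------------------------------------------------
  run_stage("ordination", function(sseed) {
    d <- file.path(out_dir, "ordination"); dir.create(d, showWarnings = FALSE)
    if (is.null(state$freqs)) state$freqs <- allele_frequencies(state$table)
    fm <- freq_matrix(state$freqs)
    pca <- pca_ordination(fm, standardize = TRUE)
    write_labelled_matrix(pca$coordinates[, 1:min(5, ncol(pca$coordinates)),
                                          drop = FALSE],
                          file.path(d, "pca_coords.csv"), label = "population")
    write_labelled_matrix(pca$cos2[, 1:min(5, ncol(pca$cos2)), drop = FALSE],
                          file.path(d, "pca_cos2.csv"), label = "locus_id")
    if (is.null(state$fst)) state$fst <- distance_matrix(state$freqs, "FST")
    if (is.null(state$da)) state$da <- distance_matrix(state$freqs, "DA")
    mds <- classical_mds(state$fst, k = 2)
    write_labelled_matrix(mds$coordinates, file.path(d, "mds_coords.csv"),
                          label = "population")
    ape::write.tree(nj_tree(state$da), file.path(d, "nj_tree.nwk"))
    ord <- hclust_order(fm)
    utils::write.csv(data.frame(population = rownames(fm)[ord$row_order]),
                     file.path(d, "heatmap_row_order.csv"), row.names = FALSE,
                     quote = FALSE)
    invisible(NULL)
  })

  ## --- bga -----------------------------------------------------------------
  run_stage("bga", function(sseed) {
    d <- file.path(out_dir, "bga"); dir.create(d, showWarnings = FALSE)
    cfg <- config$bga
    targets <- state$target_pops
    is_ext <- state$table$population %in% targets
    ref <- state$table[!is_ext]
    ext <- if (any(is_ext)) encode(state$table[is_ext])
    enc <- encode(ref)
    split <- stratified_split(enc$y,
                              test_frac = if (is.null(cfg$test_frac)) 0.2
                                          else cfg$test_frac,
                              seed = derive_seed(sseed, "split"))
    train <- list(x = enc$x[split$train, , drop = FALSE],
                  y = droplevels(enc$y[split$train]),
                  sample_ids = enc$sample_ids[split$train])
    test <- list(x = enc$x[split$test, , drop = FALSE],
                 y = droplevels(enc$y[split$test]),
                 sample_ids = enc$sample_ids[split$test])
    fractions <- if (is.null(cfg$fractions))
      c(0.01, 0.1, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8) else cfg$fractions
    reps <- if (is.null(cfg$repetitions)) 10 else cfg$repetitions
    budget <- if (is.null(cfg$budget)) 40 else cfg$budget
    cv_folds <- if (is.null(cfg$cv_folds)) 4 else cfg$cv_folds
    # clean-label baseline
    imp <- fit_imputer(train$x)
    fit <- tune_and_train(apply_imputer(imp, train$x), train$y,
                          cv_folds = cv_folds, budget = budget,
                          seed = derive_seed(sseed, "baseline"))
    base <- list(
      C = fit$C, gamma = fit$gamma, cv_f1 = fit$cv_f1,
      test_weighted_f1 = weighted_f1(
        test$y, stats::predict(fit$model, apply_imputer(imp, test$x)))$weighted)
    if (!is.null(ext))
      base$external_weighted_f1 <- weighted_f1(
        ext$y, stats::predict(fit$model, apply_imputer(imp, ext$x)))$weighted
    jsonlite::write_json(base, file.path(d, "chosen_hyperparams.json"),
                         auto_unbox = TRUE, digits = NA)
    ne <- noise_experiment(train, test, external = ext,
                           fractions = fractions, repetitions = reps,
                           seed = derive_seed(sseed, "noise"),
                           budget = budget, cv_folds = cv_folds)
    write_csv6(ne$results, file.path(d, "f1_by_fraction.csv"))
    write_csv6(ne$summary, file.path(d, "f1_summary.csv"))
    invisible(NULL)
  })

  manifest$stages <- manifest$stages[all_stages]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# total per-pair log10 LR recomputed locus by locus (also the test oracle)
recompute_lr <- function(pairs, freqs, model) {
  p <- freqs$p_ins[match(pairs$locus_ids, freqs$locus_id)]
  out <- numeric(length(pairs$log10_lr))
  for (i in seq_along(out)) {
    s <- 0
    for (l in seq_along(p)) {
      s <- s + log10(lr_locus(pairs$g1[i, l], pairs$g2[i, l], p[l], model))
    }
    out[i] <- s
  }
  out
}

write_labelled_matrix <- function(m, path, label = "label") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- label
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
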