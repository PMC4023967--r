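#' Clinical input groupings
#'
#' The five functional domains plus their union: subject characteristics
#' (age, BMI, sex), clinical examination (fall history, medications,
#' vision, hearing), clinical balance performance (BBS, TUG, ABC),
#' cognitive performance (TMT B-A, GDS, SLUMS) and muscle strength
#' (ankle plantarflexion, knee extension, hip abduction), giving 3-16
#' candidate inputs per network.
#'
#' @return named list of feature-name vectors.
#' @export
input_groupings <- function() {
  g <- list(
    subject_characteristics = c("age", "sex", "bmi"),
    clinical_examination = c("fall_history", "n_medications",
                             "visual_acuity", "hearing_impaired"),
    clinical_balance = c("bbs", "tug", "abc"),
    cognitive_performance = c("tmt_b_minus_a", "gds", "slums"),
    muscle_strength = c("strength_ankle_pf", "strength_knee_ext",
                        "strength_hip_abd"))
  c(g, list(all = unname(unlist(g))))
}

#' Select a grouping's feature matrix from a cohort
#'
#' @param grouping grouping name, one of `names(input_groupings())`.
#' @param cohort cohort data.frame.
#' @return numeric matrix with the grouping's columns in canonical order.
#' @export
select_inputs <- function(grouping, cohort) {
  gs <- input_groupings()
  if (!grouping %in% names(gs))
    stop("unknown grouping '", grouping, "'; valid groupings: ",
         paste(names(gs), collapse = ", "))
  cols <- gs[[grouping]]
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  as.matrix(cohort[, cols, drop = FALSE])
}

#' Cross-validation fold plan
#'
#' Randomly partitions the subjects into `k` disjoint test sets (the
#' train/test rotation: each network trains on the complement and is
#' tested on one set, so every subject is tested exactly once).  An
#' `independent` mode drawing `k` unrelated test sets is available for
#' sensitivity analysis.
#'
#' @param subject_ids character/integer vector of ids.
#' @param k number of folds (default 4).
#' @param seed integer seed.
#' @param mode `"partition"` (default) or `"independent"`.
#' @return object of class `fold_plan`: list with `test` (list of k id
#'   vectors), `mode` and `seed`.
#' @export
make_folds <- function(subject_ids, k = 4, seed = NULL, mode = c("partition", "independent")) {
  mode <- match.arg(mode)
  n <- length(subject_ids)
  if (n %% k != 0L)
    stop("number of subjects (", n, ") is not divisible into ", k,
         " equal test sets")
  ts <- n %/% k
  test <- with_seed(seed, {
    if (mode == "partition") {
      perm <- sample(subject_ids)
      split(perm, rep(seq_len(k), each = ts))
    } else {
      lapply(seq_len(k), function(i) sample(subject_ids, ts))
    }
  })
  structure(list(test = unname(test), k = k, mode = mode, seed = seed,
                 subject_ids = subject_ids),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Fold plan: ", x$k, " folds of ", length(x$test[[1L]]),
      " test subjects (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Product-moment correlation between observed and predicted values;
#' constant inputs yield `NA` with a warning rather than a silent `NaN`,
#' so degenerate folds are visible downstream.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 3L) stop("need at least 3 pairs")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    warning("correlation undefined: constant vector")
    return(NA_real_)
  }
  stats::cor(y_true, y_pred)
}

#' Run one network configuration across all folds
#'
#' For each fold the network is fitted on the training subjects only
#' (input and target normalization are part of the fit, so test rows
#' never touch the normalizer), test-set predictions are denormalized to
#' real units, and per-output Pearson correlations and mean absolute
#' errors are computed.  A training failure flags the fold and the run
#' continues.
#'
#' @param cohort cohort data.frame.
#' @param grouping input grouping name.
#' @param hidden hidden-layer size.
#' @param goal normalized MSE goal.
#' @param folds a [make_folds()] plan over `cohort$subject_id`.
#' @param seed integer seed for weight initialization (one stream per
#'   fold, derived deterministically).
#' @param max_epochs epoch cap (default 500).
#' @return data.frame with one row per fold (correlations, MAEs in
#'   cm/cm^2, epochs, stop reason); the pooled test-set predictions are
#'   attached as attribute `predictions`, and an attribute
#'   `normalizer_audit` records that every fold's input normalizer ranges
#'   were reproduced from the training rows alone.
#' @export
run_config <- function(cohort, grouping, hidden, goal, folds, seed = NULL,
                       max_epochs = 500) {
  stopifnot(inherits(folds, "fold_plan"))
  X <- select_inputs(grouping, cohort)
  Y <- as.matrix(cohort[, cohort_outcomes()])
  ids <- cohort$subject_id
  fold_seeds <- derive_seeds(seed, folds$k)
  rows <- vector("list", folds$k)
  preds <- vector("list", folds$k)
  audit_ok <- TRUE
  for (i in seq_len(folds$k)) {
    test_idx <- which(ids %in% folds$test[[i]])
    train_idx <- setdiff(seq_along(ids), test_idx)
    res <- tryCatch({
      fit <- lmnet(X[train_idx, , drop = FALSE], Y[train_idx, , drop = FALSE],
                   hidden = hidden, goal = goal, max_epochs = max_epochs,
                   seed = fold_seeds[i])
      audit_ok <- audit_ok &&
        identical(unname(fit$x_norm$min),
                  unname(apply(X[train_idx, , drop = FALSE], 2L, min))) &&
        identical(unname(fit$x_norm$max),
                  unname(apply(X[train_idx, , drop = FALSE], 2L, max)))
      yp <- predict(fit, X[test_idx, , drop = FALSE])
      yt <- Y[test_idx, , drop = FALSE]
      r <- vapply(1:3, function(k)
        tryCatch(suppressWarnings(pearson_r(yt[, k], yp[, k])),
                 error = function(e) NA_real_), numeric(1))
      mae <- colMeans(abs(yt - yp))
      preds[[i]] <- data.frame(subject_id = ids[test_idx], fold = i,
                               observed = I(yt), predicted = I(yp))
      data.frame(grouping = grouping, hidden = hidden, goal = goal, fold = i,
                 r_com_bos = r[1L], r_comv_bos = r[2L], r_bos_area = r[3L],
                 mae_com_bos = mae[1L], mae_comv_bos = mae[2L],
                 mae_bos_area = mae[3L],
                 epochs = fit$trace$epochs_used,
                 stop_reason = fit$trace$stop_reason, failed = FALSE)
    }, error = function(e) {
      data.frame(grouping = grouping, hidden = hidden, goal = goal, fold = i,
                 r_com_bos = NA_real_, r_comv_bos = NA_real_,
                 r_bos_area = NA_real_, mae_com_bos = NA_real_,
                 mae_comv_bos = NA_real_, mae_bos_area = NA_real_,
                 epochs = NA_integer_, stop_reason = conditionMessage(e),
                 failed = TRUE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- do.call(rbind, preds)
  attr(out, "normalizer_audit") <- audit_ok
  out
}

## expand one master seed into a reproducible stream of sub-seeds
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Run the full configuration grid
#'
#' Full factorial enumeration of input groupings x hidden sizes x error
#' goals (the study grid is 6 x 4 x 3 = 72 configurations), each run over
#' the same fold rotation with per-configuration seeds derived from one
#' master seed.  Per-configuration failures are recorded, never abort the
#' grid.
#'
#' @param cohort cohort data.frame.
#' @param groupings character vector of grouping names.
#' @param hidden integer vector of hidden sizes.
#' @param goals numeric vector of MSE goals.
#' @param folds a [make_folds()] plan; when `NULL`, a 4-fold plan is
#'   derived from `seed`.
#' @param seed master seed.
#' @param max_epochs epoch cap.
#' @return data.frame of class `grid_result`, one row per configuration
#'   and fold.
#' @export
run_grid <- function(cohort, groupings = names(input_groupings()),
                     hidden = c(5, 10, 20, 30), goals = c(0.1, 0.01, 0.001),
                     folds = NULL, seed = NULL, max_epochs = 500) {
  grid <- expand.grid(grouping = groupings, hidden = hidden, goal = goals,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid) + 1L)
  if (is.null(folds))
    folds <- make_folds(cohort$subject_id, k = 4,
                        seed = if (is.null(seed)) NULL else seeds[[nrow(grid) + 1L]])
  rows <- lapply(seq_len(nrow(grid)), function(i)
    run_config(cohort, grid$grouping[i], grid$hidden[i], grid$goal[i],
               folds, seed = seeds[[i]], max_epochs = max_epochs))
  out <- do.call(rbind, lapply(rows, function(r) { attributes(r)$predictions <- NULL; r }))
  rownames(out) <- NULL
  class(out) <- c("grid_result", "data.frame")
  attr(out, "folds") <- folds
  out
}

#' Aggregate fold-level results per configuration
#'
#' Mean and SD of the per-output correlations and the mean MAE across
#' folds, one row per (grouping, hidden, goal).  Undefined fold
#' correlations are excluded from the means and counted.
#'
#' @param results a [run_grid()] result (or any data.frame of its shape).
#' @return data.frame with per-configuration aggregates.
#' @export
aggregate_grid <- function(results) {
  key <- interaction(results$grouping, results$hidden, results$goal,
                     drop = TRUE)
  parts <- split(as.data.frame(results), key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(
      grouping = d$grouping[1L], hidden = d$hidden[1L], goal = d$goal[1L],
      mean_r_com_bos = mean(d$r_com_bos, na.rm = TRUE),
      sd_r_com_bos = stats::sd(d$r_com_bos, na.rm = TRUE),
      mean_r_comv_bos = mean(d$r_comv_bos, na.rm = TRUE),
      sd_r_comv_bos = stats::sd(d$r_comv_bos, na.rm = TRUE),
      mean_r_bos_area = mean(d$r_bos_area, na.rm = TRUE),
      sd_r_bos_area = stats::sd(d$r_bos_area, na.rm = TRUE),
      mean_mae_com_bos = mean(d$mae_com_bos, na.rm = TRUE),
      mean_mae_comv_bos = mean(d$mae_comv_bos, na.rm = TRUE),
      mean_mae_bos_area = mean(d$mae_bos_area, na.rm = TRUE),
      mean_epochs = mean(d$epochs, na.rm = TRUE),
      n_capped = sum(d$stop_reason == "max_epochs", na.rm = TRUE),
      n_undefined_r = sum(is.na(d$r_com_bos) | is.na(d$r_comv_bos) |
                            is.na(d$r_bos_area)))
  }))
  rownames(out) <- NULL
  out
}

#' Summarize a grid run
#'
#' Produces the standard report tables: the best configuration per
#' grouping (argmax of the mean correlation over the three outputs), the
#' epochs-to-goal distribution by hidden size, and (when a cohort is
#' supplied) the input-importance ranking of an all-inputs network
#' refitted per fold and averaged.
#'
#' @param results a [run_grid()] result.
#' @param cohort optional cohort for the importance table.
#' @param seed seed for the importance refits.
#' @return list of class `grid_summary` with `best`, `epochs_by_hidden`,
#'   `aggregates` and optionally `importance`.
#' @export
summarize_grid <- function(results, cohort = NULL, seed = NULL) {
  if (nrow(results) == 0L) stop("empty grid result")
  agg <- aggregate_grid(results)
  agg$mean_r <- rowMeans(agg[, c("mean_r_com_bos", "mean_r_comv_bos",
                                 "mean_r_bos_area")])
  best <- do.call(rbind, lapply(split(agg, agg$grouping), function(d)
    d[which.max(d$mean_r), ]))
  rownames(best) <- NULL
  epochs <- do.call(rbind, lapply(split(as.data.frame(results), results$hidden),
    function(d) data.frame(hidden = d$hidden[1L],
                           median_epochs = stats::median(d$epochs, na.rm = TRUE),
                           mean_epochs = mean(d$epochs, na.rm = TRUE),
                           n_capped = sum(d$stop_reason == "max_epochs",
                                          na.rm = TRUE),
                           n_runs = nrow(d))))
  rownames(epochs) <- NULL
  imp <- NULL
  if (!is.null(cohort)) {
    ball <- agg[agg$grouping == "all", , drop = FALSE]
    if (nrow(ball)) {
      b <- ball[which.max(ball$mean_r), ]
      X <- select_inputs("all", cohort)
      Y <- as.matrix(cohort[, cohort_outcomes()])
      seeds <- derive_seeds(seed, 4L)
      scores <- sapply(seq_len(4L), function(i) {
        fit <- lmnet(X, Y, hidden = b$hidden, goal = b$goal,
                     seed = seeds[[i]])
        sc <- colSums(abs(fit$W1))
        sc / sum(sc)
      })
      msc <- rowMeans(scores)
      ord <- order(-msc)
      imp <- data.frame(input = colnames(X)[ord], score = msc[ord],
                        rank = seq_along(msc), row.names = NULL)
    }
  }
  structure(list(best = best, epochs_by_hidden = epochs, aggregates = agg,
                 importance = imp),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat("Best configuration per input grouping (mean (SD) fold correlation):\n")
  b <- x$best
  fmt <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  print(data.frame(grouping = b$grouping, hidden = b$hidden, goal = b$goal,
                   com_bos = fmt(b$mean_r_com_bos, b$sd_r_com_bos),
                   comv_bos = fmt(b$mean_r_comv_bos, b$sd_r_comv_bos),
                   bos_area = fmt(b$mean_r_bos_area, b$sd_r_bos_area)),
        row.names = FALSE)
  cat("\nEpochs to goal by hidden size:\n")
  print(x$epochs_by_hidden, row.names = FALSE)
  if (!is.null(x$importance)) {
    cat("\nInput importance (all-inputs network, normalized |W1| column sums):\n")
    print(utils::head(x$importance, 8L), row.names = FALSE)
  }
  invisible(x)
}

#' Write grid report files
#'
#' Writes `grid_results.csv` (one row per configuration and fold),
#' `summary_best.csv`, `epochs_by_hidden.csv` and, when available,
#' `importance.csv` into a directory.
#'
#' @param results a [run_grid()] result.
#' @param summary a [summarize_grid()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_report <- function(results, summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(results),
                   file.path(dir, "grid_results.csv"), row.names = FALSE)
  utils::write.csv(summary$best, file.path(dir, "summary_best.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$epochs_by_hidden,
                   file.path(dir, "epochs_by_hidden.csv"), row.names = FALSE)
  if (!is.null(summary$importance))
    utils::write.csv(summary$importance, file.path(dir, "importance.csv"),
                     row.names = FALSE)
  invisible(dir)
}
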