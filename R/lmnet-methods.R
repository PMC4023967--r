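#' @export
print.lmnet <- function(x, ...) {
  p <- ncol(x$W1); h <- nrow(x$W1); o <- nrow(x$W2)
  cat("Three-layer feed-forward network (tansig/purelin), LM-trained\n")
  cat("  architecture: ", p, " inputs -> ", h, " hidden -> ", o,
      " outputs (", h * (p + 1) + o * (h + 1), " parameters)\n", sep = "")
  cat("  training:     ", x$trace$epochs_used, " epochs, stop: ",
      x$trace$stop_reason, ", final normalized MSE ",
      format(tail_mse(x), digits = 4), " (goal ", x$config$goal, ")\n",
      sep = "")
  invisible(x)
}

tail_mse <- function(x) x$trace$mse[length(x$trace$mse)]

#' @export
summary.lmnet <- function(object, ...) {
  res <- object$residuals
  tn <- object$target_names %||% paste0("y", seq_len(ncol(res)))
  tab <- data.frame(target = tn,
                    rmse = apply(res, 2L, function(r) sqrt(mean(r^2))),
                    mae = apply(res, 2L, function(r) mean(abs(r))),
                    row.names = NULL)
  structure(list(model = object, fit_table = tab,
                 importance = input_importance(object)),
            class = "summary.lmnet")
}

#' @export
print.summary.lmnet <- function(x, ...) {
  print(x$model)
  cat("\nTraining-set error (real units):\n")
  print(x$fit_table, digits = 4)
  cat("\nInput ranking by hidden-layer weight magnitude:\n")
  print(utils::head(x$importance, 10L), digits = 3)
  invisible(x)
}

#' @export
coef.lmnet <- function(object, ...) {
  v <- c(as.numeric(object$W1), object$b1,
         as.numeric(object$W2), object$b2)
  h <- nrow(object$W1); p <- ncol(object$W1); o <- nrow(object$W2)
  names(v) <- c(paste0("W1[", rep(seq_len(h), p), ",", rep(seq_len(p), each = h), "]"),
                paste0("b1[", seq_len(h), "]"),
                paste0("W2[", rep(seq_len(o), h), ",", rep(seq_len(h), each = o), "]"),
                paste0("b2[", seq_len(o), "]"))
  v
}

#' Predict balance measures for new subjects
#'
#' Applies the stored input normalization, the forward pass and the
#' inverse target normalization, returning predictions in real-world
#' units (cm for the distance measures, cm^2 for BoS area when fitted to
#' those targets).
#'
#' @param object an [lmnet()] fit.
#' @param newdata matrix or data.frame of predictors; when the model was
#'   fitted with named columns the same columns must be present (matched
#'   by name).
#' @param ... unused.
#' @return matrix of predictions, one column per target.
#' @export
predict.lmnet <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  X <- newdata
  if (is.data.frame(X)) {
    if (!is.null(object$feature_names)) {
      missing_cols <- setdiff(object$feature_names, names(X))
      if (length(missing_cols))
        stop("newdata is missing column(s): ",
             paste(missing_cols, collapse = ", "))
      X <- X[, object$feature_names, drop = FALSE]
    }
    X <- as.matrix(X)
  }
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    missing_cols <- setdiff(object$feature_names, colnames(X))
    if (length(missing_cols))
      stop("newdata is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  }
  Yn <- lmnet_forward(object, minmax_apply(object$x_norm, X))
  Y <- minmax_invert(object$y_norm, Yn)
  colnames(Y) <- object$target_names
  Y
}

#' @export
residuals.lmnet <- function(object, ...) object$residuals

#' @export
fitted.lmnet <- function(object, ...) object$fitted.values

#' Diagnostic plots for a fitted network
#'
#' Observed versus fitted values per target, plus the training MSE trace
#' on a log scale.
#'
#' @param x an [lmnet()] fit.
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lmnet <- function(x, y, ...) {
  o <- nrow(x$W2)
  obs <- x$fitted.values + x$residuals
  old <- graphics::par(mfrow = c(1, o + 1L))
  on.exit(graphics::par(old))
  tn <- x$target_names %||% paste0("y", seq_len(o))
  for (k in seq_len(o)) {
    graphics::plot(obs[, k], x$fitted.values[, k],
                   xlab = paste("observed", tn[k]),
                   ylab = paste("fitted", tn[k]), ...)
    graphics::abline(0, 1, lty = 2)
  }
  graphics::plot(seq_along(x$trace$mse) - 1L, x$trace$mse, type = "l",
                 log = "y", xlab = "epoch", ylab = "normalized MSE")
  graphics::abline(h = x$config$goal, lty = 3)
  invisible(x)
}

#' Serialize a fitted network to JSON
#'
#' Writes weights, biases, normalization parameters, configuration and
#' training trace with full floating-point precision, so that
#' `read_lmnet(write_lmnet(m, f))` reproduces the model bit for bit.
#'
#' @param model an [lmnet()] fit.
#' @param path file path.
#' @return `read_lmnet` returns an `lmnet` object; `write_lmnet` returns
#'   `path` invisibly.
#' @export
write_lmnet <- function(model, path) {
  stopifnot(inherits(model, "lmnet"))
  obj <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              x_min = model$x_norm$min, x_max = model$x_norm$max,
              y_min = model$y_norm$min, y_max = model$y_norm$max,
              feature_names = model$feature_names,
              target_names = model$target_names,
              config = model$config, trace = model$trace)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_lmnet
#' @export
read_lmnet <- function(path) {
  obj <- jsonlite::fromJSON(path)
  x_norm <- structure(list(min = as.numeric(obj$x_min),
                           max = as.numeric(obj$x_max)), class = "minmax")
  y_norm <- structure(list(min = as.numeric(obj$y_min),
                           max = as.numeric(obj$y_max)), class = "minmax")
  structure(list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
                 W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2),
                 x_norm = x_norm, y_norm = y_norm,
                 feature_names = obj$feature_names,
                 target_names = obj$target_names,
                 config = obj$config,
                 trace = list(mse = as.numeric(obj$trace$mse),
                              epochs_used = as.integer(obj$trace$epochs_used),
                              stop_reason = obj$trace$stop_reason,
                              mu_final = obj$trace$mu_final),
                 fitted.values = NULL, residuals = NULL,
                 call = NULL), class = "lmnet")
}
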