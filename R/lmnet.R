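#' Three-layer feed-forward network trained by Levenberg-Marquardt
#'
#' Fits a regression network with one hidden layer of hyperbolic-tangent
#' (tansig) units and a pure linear output layer,
#' \deqn{\hat y = W_2 \tanh(W_1 x + b_1) + b_2,}
#' trained by the Levenberg-Marquardt algorithm on min-max-normalized
#' inputs and targets.  Each epoch solves the damped Gauss-Newton system
#' \eqn{(J^\top J + \mu I)\,\delta = -J^\top e}; a step is accepted only
#' if it lowers the mean squared error (then \eqn{\mu} is decreased),
#' otherwise \eqn{\mu} is increased and the step retried.  Training stops
#' when the normalized MSE reaches `goal`, at `max_epochs`, or when
#' \eqn{\mu} overflows `mu_max`.
#'
#' The MSE goal is defined on the \[-1, 1\] normalized targets (mean over
#' samples and output dimensions of squared error), the scale on which
#' goals such as 0.1, 0.01 and 0.001 are meaningful.
#'
#' @param x predictors: numeric matrix, one row per subject; or a formula.
#' @param y numeric matrix of targets (one column per output).
#' @param hidden number of hidden units (study values: 5, 10, 20, 30).
#' @param goal normalized MSE at which training stops (study values: 0.1,
#'   0.01, 0.001).
#' @param max_epochs epoch cap (default 500).
#' @param seed optional integer seed for the weight initialization; the
#'   global RNG state is left untouched.
#' @param mu0,mu_up,mu_down,mu_max Levenberg-Marquardt damping schedule:
#'   initial \eqn{\mu}, factor applied on a rejected step, divisor applied
#'   on an accepted step, and overflow bound.
#' @param init `"nguyen-widrow"` (scaled layer initialization, the
#'   customary default for tansig layers) or `"uniform"`.
#' @param ... unused.
#' @return an object of class `lmnet`: weights and biases (`W1`, `b1`,
#'   `W2`, `b2`), the input/target normalizers, the training trace
#'   (per-epoch normalized MSE, `epochs_used`, `stop_reason`, `mu_final`),
#'   fitted values and residuals in real units.
#' @seealso [predict.lmnet()], [input_importance()], [write_lmnet()]
#' @examples
#' set.seed(1)
#' x <- matrix(runif(120, -1, 1), 60, 2)
#' y <- cbind(x[, 1] - 2 * x[, 2] + 1)
#' fit <- lmnet(x, y, hidden = 5, goal = 1e-8, seed = 2)
#' fit
#' @export
lmnet <- function(x, ...) UseMethod("lmnet")

#' @rdname lmnet
#' @export
lmnet.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- lmnet.default(X, as.matrix(y), ...)
  fit$call <- match.call()
  fit
}

#' @rdname lmnet
#' @export
lmnet.default <- function(x, y, hidden = 20, goal = 0.001, max_epochs = 500,
                          seed = NULL, mu0 = 1e-3, mu_up = 10, mu_down = 10,
                          mu_max = 1e10, init = c("nguyen-widrow", "uniform"),
                          ...) {
  init <- match.arg(init)
  X <- as.matrix(x); Y <- as.matrix(y)
  if (!is.numeric(X) || !is.numeric(Y)) stop("x and y must be numeric")
  if (nrow(X) != nrow(Y)) stop("x and y must have the same number of rows")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite training data")
  if (hidden < 1L || max_epochs < 1L || goal <= 0)
    stop("invalid network configuration")
  n <- nrow(X); p <- ncol(X); o <- ncol(Y)
  n_par <- hidden * (p + 1L) + o * (hidden + 1L)
  if (n * o < n_par / 5)
    warning("few samples (", n, ") for ", n_par, " parameters; ",
            "the network will interpolate rather than generalize")

  x_norm <- minmax_fit(X)
  y_norm <- minmax_fit(Y)
  Xn <- minmax_apply(x_norm, X)
  Yn <- minmax_apply(y_norm, Y)

  th <- with_seed(seed, init_weights(p, hidden, o, init))
  W1 <- th$W1; b1 <- th$b1; W2 <- th$W2; b2 <- th$b2

  fwd <- function() {
    A <- tanh(pmin(pmax(W1 %*% t(Xn) + b1, -40), 40))   # hidden x n
    list(A = A, Yhat = t(W2 %*% A + b2))                # n x o
  }
  mse_of <- function(E) mean(E^2)

  f <- fwd()
  E <- f$Yhat - Yn
  mse <- mse_of(E)
  trace_mse <- mse
  mu <- mu0
  stop_reason <- "max_epochs"
  epochs <- 0L

  while (epochs < max_epochs) {
    if (mse <= goal) { stop_reason <- "goal"; break }
    J <- lmnet_jacobian_parts(W1, b1, W2, b2, Xn, f$A)
    e_vec <- as.numeric(E)                 # column-major: outputs stacked
    g <- crossprod(J, e_vec)
    H <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(solve(H + diag(mu, ncol(H)), -g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- unflatten(as.numeric(step), p, hidden, o)
        W1c <- W1 + cand$W1; b1c <- b1 + cand$b1
        W2c <- W2 + cand$W2; b2c <- b2 + cand$b2
        Ac <- tanh(pmin(pmax(W1c %*% t(Xn) + b1c, -40), 40))
        Yc <- t(W2c %*% Ac + b2c)
        msec <- mse_of(Yc - Yn)
      } else msec <- Inf
      if (is.finite(msec) && msec < mse) {
        W1 <- W1c; b1 <- b1c; W2 <- W2c; b2 <- b2c
        f <- list(A = Ac, Yhat = Yc)
        E <- Yc - Yn
        mse <- msec
        mu <- mu / mu_down
        accepted <- TRUE
      } else {
        mu <- mu * mu_up
        if (mu > mu_max) break
      }
    }
    if (!accepted) { stop_reason <- "mu_overflow"; break }
    epochs <- epochs + 1L
    trace_mse <- c(trace_mse, mse)
    if (mse <= goal) { stop_reason <- "goal"; break }
  }
  if (stop_reason == "max_epochs" && mse <= goal) stop_reason <- "goal"

  fitted_real <- minmax_invert(y_norm, f$Yhat)
  colnames(fitted_real) <- colnames(Y)
  model <- structure(list(
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    x_norm = x_norm, y_norm = y_norm,
    feature_names = colnames(X), target_names = colnames(Y),
    config = list(hidden = hidden, goal = goal, max_epochs = max_epochs,
                  seed = seed, mu0 = mu0, mu_up = mu_up, mu_down = mu_down,
                  mu_max = mu_max, init = init),
    trace = list(mse = trace_mse, epochs_used = epochs,
                 stop_reason = stop_reason, mu_final = mu),
    fitted.values = fitted_real,
    residuals = Y - fitted_real,
    call = match.call()), class = "lmnet")
  model
}

## Nguyen-Widrow-style scaled initialization for a tansig hidden layer on
## [-1,1] inputs; output layer small uniform.
init_weights <- function(p, h, o, init) {
  if (init == "uniform") {
    W1 <- matrix(stats::runif(h * p, -0.5, 0.5), h, p)
    b1 <- stats::runif(h, -0.5, 0.5)
  } else {
    beta <- 0.7 * h^(1 / p)
    W1 <- matrix(stats::runif(h * p, -1, 1), h, p)
    nr <- sqrt(rowSums(W1^2))
    W1 <- W1 * (beta / pmax(nr, 1e-12))
    b1 <- if (h == 1L) 0 else beta * seq(-1, 1, length.out = h) * sign(W1[, 1L])
  }
  W2 <- matrix(stats::runif(o * h, -0.5, 0.5), o, h)
  b2 <- stats::runif(o, -0.5, 0.5)
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

## residual Jacobian: rows ordered like as.numeric(E) for an n x o error
## matrix (output k blocks of n samples); columns ordered
## [vec(W1), b1, vec(W2), b2].
lmnet_jacobian_parts <- function(W1, b1, W2, b2, Xn, A = NULL) {
  h <- nrow(W1); p <- ncol(W1); o <- nrow(W2); n <- nrow(Xn)
  if (is.null(A)) A <- tanh(pmin(pmax(W1 %*% t(Xn) + b1, -40), 40))
  S <- 1 - A^2                                   # h x n
  At <- t(A)                                     # n x h
  J <- matrix(0, n * o, h * (p + 1L) + o * (h + 1L))
  iW1 <- seq_len(h * p)
  ib1 <- h * p + seq_len(h)
  iW2 <- h * (p + 1L) + seq_len(o * h)
  ib2 <- h * (p + 1L) + o * h + seq_len(o)
  for (k in seq_len(o)) {
    rows <- (k - 1L) * n + seq_len(n)
    D <- t(S * W2[k, ])                          # n x h
    ## d e / d W1[j,m] = W2[k,j] (1-a_j^2) x_m ; vec(W1) index (m-1)h + j
    J[rows, iW1] <- D[, rep(seq_len(h), p)] * Xn[, rep(seq_len(p), each = h)]
    J[rows, ib1] <- D
    J[rows, iW2[seq(k, o * h, by = o)]] <- At    # vec(W2) index (j-1)o + k
    J[rows, ib2[k]] <- 1
  }
  J
}

unflatten <- function(v, p, h, o) {
  iW1 <- seq_len(h * p)
  ib1 <- h * p + seq_len(h)
  iW2 <- h * (p + 1L) + seq_len(o * h)
  ib2 <- h * (p + 1L) + o * h + seq_len(o)
  list(W1 = matrix(v[iW1], h, p), b1 = v[ib1],
       W2 = matrix(v[iW2], o, h), b2 = v[ib2])
}

#' Residual Jacobian of a network
#'
#' Analytic Jacobian of the normalized prediction errors with respect to
#' all weights and biases, one row per (sample, output) pair and one
#' column per parameter, in the order `[vec(W1), b1, vec(W2), b2]`.
#' Exposed mainly for verification against finite differences.
#'
#' @param model an [lmnet()] fit.
#' @param x raw input matrix.
#' @return Jacobian matrix, `(n * n_outputs) x n_parameters`.
#' @export
lmnet_jacobian <- function(model, x) {
  stopifnot(inherits(model, "lmnet"))
  Xn <- minmax_apply(model$x_norm, as.matrix(x))
  lmnet_jacobian_parts(model$W1, model$b1, model$W2, model$b2, Xn)
}

#' Forward pass on normalized inputs
#'
#' Evaluates the network on already-normalized inputs, returning
#' normalized outputs; [predict.lmnet()] wraps this with the affine
#' (de)normalization.
#'
#' @param model an [lmnet()] fit.
#' @param xn matrix of normalized inputs (rows = samples).
#' @return matrix of normalized outputs.
#' @export
lmnet_forward <- function(model, xn) {
  xn <- as.matrix(xn)
  if (ncol(xn) != ncol(model$W1)) stop("input has ", ncol(xn),
                                       " columns, network expects ",
                                       ncol(model$W1))
  t(model$W2 %*% tanh(pmin(pmax(model$W1 %*% t(xn) + model$b1, -40), 40)) +
      model$b2)
}

#' Rank inputs by hidden-layer weight magnitude
#'
#' Scores each input as the sum over hidden units of the absolute
#' hidden-layer weight attached to it, the customary first look at which
#' clinical measures a trained network leans on.  Ties keep input order.
#'
#' @param model an [lmnet()] fit.
#' @return data.frame with `input`, `score` and `rank`, sorted by
#'   decreasing score.
#' @export
input_importance <- function(model) {
  stopifnot(inherits(model, "lmnet"))
  sc <- colSums(abs(model$W1))
  nm <- model$feature_names %||% paste0("x", seq_along(sc))
  ord <- order(-sc)
  data.frame(input = nm[ord], score = unname(sc[ord]),
             rank = seq_along(sc), row.names = NULL)
}

## run expr under a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
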