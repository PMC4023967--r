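#' Marginal calibration table for the synthetic elderly cohort
#'
#' One row per variable: the 16 clinical features (five functional
#' domains) and the three gait balance-control outcomes, with the marginal
#' family used to emulate each instrument and the published cohort mean
#' and SD it is calibrated to.  Bounded integer-valued instruments (BBS,
#' GDS, SLUMS) use a discretized Beta whose raw parameters are
#' moment-matched so that the *rounded* variable hits the target mean and
#' SD; counts use a negative binomial; positive skewed measures use a
#' Gamma; binary traits use a Bernoulli with the published prevalence
#' (22/56 male, 14/56 hearing-impaired).
#'
#' @return data.frame with columns `name`, `family`, `mean`, `sd`, `lo`,
#'   `hi`, `integer`.
#' @export
cohort_marginals <- function() {
  m <- function(name, family, mean, sd, lo = -Inf, hi = Inf, integer = FALSE)
    data.frame(name = name, family = family, mean = mean, sd = sd,
               lo = lo, hi = hi, integer = integer)
  rbind(
    m("age",              "normal",    76.1,  6.5, 50, 110),
    m("sex",              "bernoulli", 22/56, sqrt(22/56 * 34/56), 0, 1, TRUE),
    m("bmi",              "normal",    27.4,  6.1, 12, 70),
    m("fall_history",     "nbinom",    0.95,  1.35, 0, Inf, TRUE),
    m("n_medications",    "nbinom",    3.8,   3.2,  0, Inf, TRUE),
    m("visual_acuity",    "gamma",     36.6, 11.7,  0, Inf),
    m("hearing_impaired", "bernoulli", 14/56, sqrt(14/56 * 42/56), 0, 1, TRUE),
    m("bbs",              "beta_int",  53.4,  3.8,  0, 56, TRUE),
    m("tug",              "normal",    9.0,   2.0,  2, 60),
    m("abc",              "beta",      85.7, 13.6,  0, 100),
    m("tmt_b_minus_a",    "gamma",     63.2, 63.0,  0, Inf),
    m("gds",              "beta_int",  1.6,   1.9,  0, 15, TRUE),
    m("slums",            "beta_int",  26.4,  3.3,  0, 30, TRUE),
    m("strength_ankle_pf", "gamma",    3.1,   2.3,  0, Inf),
    m("strength_knee_ext", "gamma",    3.8,   2.7,  0, Inf),
    m("strength_hip_abd",  "gamma",    1.9,   1.6,  0, Inf),
    m("com_bos",          "normal",    3.8,   1.1,  0, Inf),
    m("comv_bos",         "normal",   19.3,   3.5,  0, Inf),
    m("bos_area",         "normal",  436,    88,    0, Inf)
  )
}

#' Names of the clinical feature and outcome columns
#' @return character vectors.
#' @export
cohort_features <- function() cohort_marginals()$name[1:16]

#' @rdname cohort_features
#' @export
cohort_outcomes <- function() c("com_bos", "comv_bos", "bos_area")

#' Default latent-factor loadings
#'
#' Three latent factors — overall balance ability, lower-limb strength and
#' cognition — drive both the clinical features and the balance outcomes
#' on the Gaussian-score scale, creating a learnable (and, for the
#' outcomes, nonlinear) clinical-to-biomechanical mapping.  Signs follow
#' clinical direction: better balance ability raises BBS/ABC and lowers
#' TUG and fall counts; a larger Snellen denominator (worse vision) goes
#' with worse balance.  The rows are unit-variance scores, so each row's
#' squared norm is the variance explained by the latents.
#'
#' @return 19 x 3 matrix, rows named by variable, columns
#'   `balance`, `strength`, `cognition`.
#' @export
default_loadings <- function() {
  v <- rbind(
    age              = c(-0.45, -0.25, -0.25),
    sex              = c( 0.00,  0.30,  0.00),
    bmi              = c(-0.20, -0.15,  0.00),
    fall_history     = c(-0.50,  0.00,  0.00),
    n_medications    = c(-0.30,  0.00, -0.15),
    visual_acuity    = c(-0.40,  0.00,  0.00),
    hearing_impaired = c( 0.00,  0.00, -0.30),
    bbs              = c( 0.70,  0.20,  0.00),
    tug              = c(-0.60, -0.30,  0.00),
    abc              = c( 0.65,  0.15,  0.00),
    tmt_b_minus_a    = c(-0.15,  0.00, -0.60),
    gds              = c(-0.25,  0.00, -0.40),
    slums            = c( 0.00,  0.00,  0.65),
    strength_ankle_pf = c(0.15,  0.70,  0.00),
    strength_knee_ext = c(0.15,  0.72,  0.00),
    strength_hip_abd  = c(0.20,  0.68,  0.00),
    com_bos          = c( 0.62,  0.40,  0.15),
    comv_bos         = c( 0.55,  0.50,  0.25),
    bos_area         = c( 0.45,  0.60,  0.20)
  )
  colnames(v) <- c("balance", "strength", "cognition")
  v
}

## moment-match a Beta on [0, K] so that round(K * X) has the target
## mean/sd; deterministic Nelder-Mead over raw (mean, sd)
fit_discrete_beta <- function(mean, sd, K) {
  target <- c(mean, sd)
  moments <- function(a, b) {
    k <- 0:K
    up <- pmin((k + 0.5) / K, 1)
    lo <- pmax((k - 0.5) / K, 0)
    p <- stats::pbeta(up, a, b) - stats::pbeta(lo, a, b)
    mu <- sum(k * p)
    c(mu, sqrt(max(sum((k - mu)^2 * p), 0)))
  }
  ab_of <- function(th) {
    m <- stats::plogis(th[1L]); s <- exp(th[2L])
    v <- s^2
    if (v >= m * (1 - m)) return(NULL)
    r <- m * (1 - m) / v - 1
    c(m * r, (1 - m) * r)
  }
  obj <- function(th) {
    ab <- ab_of(th)
    if (is.null(ab)) return(1e6)
    mm <- moments(ab[1L], ab[2L])
    sum(((mm - target) / target)^2)
  }
  th0 <- c(stats::qlogis(mean / K), log(sd / K))
  fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  ab <- ab_of(fit$par)
  if (is.null(ab) || fit$value > 1e-6)
    stop("cannot match a discretized Beta to mean ", mean, ", sd ", sd,
         " on [0, ", K, "]")
  ab
}

## per-family parameters used by the quantile transform
prepare_marginal <- function(row) {
  with(row, switch(family,
    normal = list(q = function(u) stats::qnorm(u, mean, sd)),
    gamma = {
      shape <- (mean / sd)^2; rate <- mean / sd^2
      list(q = function(u) stats::qgamma(u, shape = shape, rate = rate))
    },
    beta = {
      K <- hi - lo
      m <- (mean - lo) / K; v <- (sd / K)^2
      if (v >= m * (1 - m))
        stop("infeasible Beta for ", name, ": sd too large for the range")
      r <- m * (1 - m) / v - 1
      a <- m * r; b <- (1 - m) * r
      force(lo); force(K)
      list(q = function(u) lo + K * stats::qbeta(u, a, b))
    },
    beta_int = {
      K <- hi - lo
      ab <- fit_discrete_beta(mean - lo, sd, K)
      list(q = function(u) lo + round(K * stats::qbeta(u, ab[1L], ab[2L])))
    },
    nbinom = {
      if (sd^2 <= mean)
        stop("negative binomial for ", name, " needs sd^2 > mean")
      size <- mean^2 / (sd^2 - mean)
      list(q = function(u) stats::qnbinom(u, size = size, mu = mean))
    },
    bernoulli = list(q = function(u) as.numeric(u > 1 - mean)),
    stop("unknown marginal family: ", family)))
}

#' Synthetic cohort configuration
#'
#' Bundles everything [generate_cohort()] needs: cohort size, marginal
#' calibration, latent-factor loadings, Gaussian-score noise, the
#' nonlinearity of the latent-to-outcome link, and the seed.  By default
#' the score noise SD of each variable is `sqrt(1 - ||loadings||^2)`, so
#' every Gaussian score has unit variance and the marginals are hit
#' exactly; overriding `noise_sd` (e.g. to 0) trades that off explicitly.
#'
#' @param n_subjects cohort size (>= 2).
#' @param marginals calibration table, see [cohort_marginals()].
#' @param loadings numeric matrix, rows matching `marginals$name`,
#'   columns = latent factors; row norms must be <= 1.
#' @param noise_sd optional named numeric vector of Gaussian-score noise
#'   SDs (default `sqrt(1 - rowSums(loadings^2))`).
#' @param nonlinear logical; pass the outcomes' latent score through a
#'   scaled tanh (standardized to unit variance) so the clinical-to-
#'   balance map is nonlinear (default TRUE).
#' @param nonlin_scale scale of the tanh link; smaller is more strongly
#'   saturating (default 1).
#' @param seed integer seed.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 56, marginals = cohort_marginals(),
                          loadings = default_loadings(), noise_sd = NULL,
                          nonlinear = TRUE, nonlin_scale = 1, seed = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (any(marginals$sd < 0)) stop("marginal SDs must be non-negative")
  loadings <- as.matrix(loadings)
  if (!all(marginals$name %in% rownames(loadings)))
    stop("loadings must have a row for every variable")
  loadings <- loadings[marginals$name, , drop = FALSE]
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  r2 <- rowSums(loadings^2)
  if (is.null(noise_sd)) {
    if (any(r2 > 1 + 1e-12))
      stop("row norms of loadings exceed 1; the implied dependence ",
           "structure is not positive semi-definite")
    noise_sd <- sqrt(pmax(1 - r2, 0))
    names(noise_sd) <- marginals$name
  } else {
    full <- sqrt(pmax(1 - r2, 0)); names(full) <- marginals$name
    full[names(noise_sd)] <- noise_sd
    noise_sd <- full
    if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  }
  structure(list(n_subjects = as.integer(n_subjects), marginals = marginals,
                 loadings = loadings, noise_sd = noise_sd,
                 nonlinear = nonlinear, nonlin_scale = nonlin_scale,
                 seed = seed),
            class = "cohort_params")
}

## SD of tanh(U / s0) for U ~ N(0, sig); exact by quadrature
tanh_link_sd <- function(sig, s0) {
  if (sig < 1e-12) return(0)
  v <- stats::integrate(function(x) tanh(sig * x / s0)^2 * stats::dnorm(x),
                        -Inf, Inf, rel.tol = 1e-12)$value
  sqrt(v)
}

#' Generate a synthetic elderly cohort
#'
#' Draws latent factors per subject, builds unit-variance Gaussian scores
#' for every variable from the loadings plus independent score noise
#' (outcome scores optionally passed through a standardized tanh link),
#' and maps each score to its calibrated marginal by the probability
#' integral transform.  Marginal means and SDs therefore converge to the
#' configured values as the cohort grows, while the shared latents make
#' the outcomes learnable from the clinical features.
#'
#' @param params a [cohort_params()] object.
#' @return data.frame of class `gait_cohort`: `subject_id`, the 16
#'   features, and the three outcomes (cm, cm, cm^2); the generating
#'   parameters are attached as attribute `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    n <- params$n_subjects
    mg <- params$marginals
    f <- matrix(stats::rnorm(n * ncol(params$loadings)), n)
    out <- list(subject_id = sprintf("S%04d", seq_len(n)))
    for (i in seq_len(nrow(mg))) {
      row <- mg[i, ]
      lam <- params$loadings[row$name, ]
      ns <- params$noise_sd[[row$name]]
      sig <- sqrt(sum(lam^2))
      u <- as.numeric(f %*% lam)
      if (params$nonlinear && row$name %in% cohort_outcomes() && sig > 0) {
        u <- tanh(u / params$nonlin_scale) /
          tanh_link_sd(sig, params$nonlin_scale) * sig
      }
      g <- u + stats::rnorm(n, sd = ns)
      s_tot <- sqrt(sig^2 + ns^2)
      x <- if (s_tot < 1e-12) rep(row$mean, n)
           else prepare_marginal(row)$q(stats::pnorm(g / s_tot))
      out[[row$name]] <- pmin(pmax(x, row$lo), row$hi)
    }
    out <- as.data.frame(out)
    ## physical coherence: the displacement along any ray cannot be
    ## shorter than the minimum distance to the boundary
    out$comv_bos <- pmax(out$comv_bos, out$com_bos * 1.02)
    structure(out, params = params, class = c("gait_cohort", "data.frame"))
  })
}

cohort_header <- function() c("subject_id", cohort_features(), cohort_outcomes())

#' Write / read a cohort CSV
#'
#' One row per subject with the documented 20-column header
#' (`subject_id`, 16 features, 3 outcomes).  Numeric values are written
#' with 17 significant digits so that `read_cohort(write_cohort(x))`
#' reproduces the numeric matrix bit for bit; schema violations name the
#' offending columns.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  hd <- cohort_header()
  missing_cols <- setdiff(hd, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- cohort[, hd]
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hd <- cohort_header()
  missing_cols <- setdiff(hd, names(df))
  extra <- setdiff(names(df), hd)
  if (length(missing_cols))
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (length(extra))
    stop("cohort file has unexpected column(s): ",
         paste(extra, collapse = ", "))
  df <- df[, hd]
  for (nm in hd[-1L]) df[[nm]] <- as.numeric(df[[nm]])
  class(df) <- c("gait_cohort", "data.frame")
  df
}
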