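#' Trial-generation parameters
#'
#' Defaults emulate self-paced elderly gait as captured in a motion
#' laboratory: 60 Hz sampling, a 0.55 s step time, six heel strikes, and
#' footprint templates (rectangle with a rounded toe) scaled from body
#' height by the standard anthropometric foot-length ratio of 0.152.
#' Small white noise is added to the CoM trajectory and to each foot
#' placement; the trajectory consumer is expected to low-pass filter.
#'
#' @param sampling_rate Hz (default 60, the usual marker rate).
#' @param step_time seconds per step; rounded to a whole number of frames.
#' @param n_events number of heel strikes to generate (>= 4).
#' @param noise_sd white positional noise on the CoM, metres (default
#'   0.3 mm, typical optical marker noise; the derived velocity direction,
#'   and with it the dynamic balance measure, is the quantity most
#'   sensitive to this).
#' @param placement_noise jitter of each foot placement, metres.
#' @param body_height metres; when `NULL`, 1.74 for males and 1.61 for
#'   females.
#' @param foot_length_ratio foot length as a fraction of body height.
#' @param foot_width_ratio foot width as a fraction of foot length.
#' @param toe_points vertices on the toe arc (0 gives a plain rectangle).
#' @param double_support seconds the trailing foot stays grounded after a
#'   heel strike.
#' @return list of parameters.
#' @export
trial_params <- function(sampling_rate = 60, step_time = 0.55, n_events = 6,
                         noise_sd = 3e-4, placement_noise = 0.002,
                         body_height = NULL, foot_length_ratio = 0.152,
                         foot_width_ratio = 0.40, toe_points = 5,
                         double_support = 0.12) {
  if (n_events < 4L) stop("n_events must be at least 4")
  as.list(environment())
}

#' Footprint template
#'
#' Ground-plane outline of one foot: a rectangle with a rounded toe, heel
#' at the local origin, pointing along +x.
#'
#' @param length,width foot dimensions (m).
#' @param toe_points number of arc vertices (0 = rectangle).
#' @return counter-clockwise vertex matrix (m).
#' @export
footprint_template <- function(length, width, toe_points = 5) {
  r <- width / 2
  if (toe_points < 1L) {
    verts <- rbind(c(0, -r), c(length, -r), c(length, r), c(0, r))
  } else {
    ang <- seq(-pi / 2, pi / 2, length.out = toe_points + 2L)
    arc <- cbind(length - r + r * cos(ang), r * sin(ang))
    verts <- rbind(c(0, -r), arc, c(0, r))
  }
  verts
}

translate_poly <- function(poly, dx, dy) cbind(poly[, 1L] + dx, poly[, 2L] + dy)

## double-support configuration: trailing heel at (0, -w/2), leading heel
## at (s, +w/2); returns the hull of both footprints
double_support_hull <- function(foot, s, w) {
  convex_hull(rbind(translate_poly(foot, 0, -w / 2),
                    translate_poly(foot, s, +w / 2)))
}

## measures of a candidate static configuration (CoM at (cx, cy))
config_measures <- function(foot, s, w, cx, cy) {
  hull <- double_support_hull(foot, s, w)
  cb <- com_bos_distance(c(cx, cy), hull)
  cv <- comv_bos_displacement(c(cx, cy), c(1, 0), hull)
  list(area = polygon_area(hull), com_bos = cb$distance,
       inside = cb$inside, comv_bos = cv$displacement,
       defined = cv$defined)
}

## solve step length/width and the CoM offset so the double-support
## configuration reproduces the requested balance outcome
calibrate_step_geometry <- function(outcome, foot) {
  tgt <- c(outcome$com_bos, outcome$comv_bos, outcome$bos_area)
  if (any(!is.finite(tgt)) || any(tgt <= 0))
    stop("balance outcome must be positive and finite")
  ## the double-support hull can never be smaller than one footprint, so a
  ## small-area target implies a smaller foot: scale the template so the
  ## hull retains room to close on the target
  A_f <- polygon_area(foot)
  if (tgt[3L] < 1.35 * A_f)
    foot <- foot * sqrt(tgt[3L] / (1.35 * A_f))
  L <- max(foot[, 1L]); W <- diff(range(foot[, 2L]))
  obj <- function(th) {
    s <- exp(th[1L]); w <- exp(th[2L]); cx <- th[3L]; cy <- th[4L]
    if (s > 2 || s < 0.01 || w > 0.8 || w < 0.002) return(1e6)
    m <- config_measures(foot, s, w, cx, cy)
    if (!m$inside || !m$defined) return(1e6)
    ((m$com_bos - tgt[1L]) / tgt[1L])^2 +
      ((m$comv_bos - tgt[2L]) / tgt[2L])^2 +
      ((m$area - tgt[3L]) / tgt[3L])^2
  }
  starts <- lapply(c(0.10, 0.04, 0.16, 0.02), function(w0) {
    s0 <- min(max((tgt[3L] / 1e4 - L * W - L * w0) / W, 0.02), 1.2)
    c(log(s0), log(w0), s0 + L - tgt[2L] / 100, 0)
  })
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-8) break
  }
  if (best$value > 1e-8)   # polish from the best start
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-14))
  if (best$value > 1e-4)
    stop("infeasible balance outcome for the footprint geometry ",
         "(com_bos=", tgt[1L], " cm, comv_bos=", tgt[2L], " cm, bos_area=",
         tgt[3L], " cm^2): best relative misfit ",
         format(sqrt(best$value), digits = 3))
  list(s = exp(best$par[1L]), w = exp(best$par[2L]),
       cx = best$par[3L], cy = best$par[4L], foot = foot,
       misfit = sqrt(best$value))
}

#' Generate a synthetic gait trial matching a balance outcome
#'
#' Builds a forward-progressing CoM trajectory with lateral sway and
#' alternating foot placements whose double-support geometry at every
#' heel strike reproduces the requested balance-control outcome: step
#' length, step width and the CoM offset within the base of support are
#' solved numerically against the same geometric definitions used for
#' evaluation, then the periodic trajectory is threaded through those
#' configurations (lateral sway extremal — hence laterally stationary —
#' at heel strike).  White measurement noise is added to the CoM path and
#' to each foot placement, so a round trip through [evaluate_trial()]
#' recovers the outcome to within a few percent rather than exactly.
#'
#' @param subject one cohort row (used for sex-based stature defaults);
#'   may be `NULL` when `body_height` is given in `params`.
#' @param outcome named list/vector with `com_bos` (cm), `comv_bos` (cm)
#'   and `bos_area` (cm^2).
#' @param params a [trial_params()] list.
#' @param seed integer seed for the measurement noise.
#' @return a [gait_trial()].
#' @export
generate_trial <- function(subject, outcome, params = trial_params(),
                           seed = NULL) {
  outcome <- as.list(outcome)
  bh <- params$body_height
  if (is.null(bh))
    bh <- if (!is.null(subject$sex) && subject$sex >= 0.5) 1.74 else 1.61
  L <- params$foot_length_ratio * bh
  W <- params$foot_width_ratio * L
  foot <- footprint_template(L, W, params$toe_points)
  cal <- calibrate_step_geometry(outcome, foot)
  foot <- cal$foot    # possibly rescaled for small-area outcomes

  fs <- params$sampling_rate
  fps <- as.integer(max(round(params$step_time * fs), 4L))  # frames per step
  T_step <- fps / fs
  K <- params$n_events + 1L                      # feet 0..K placed
  n <- K * fps + round(0.3 * fs)
  tt <- (seq_len(n) - 1L) / fs

  with_seed(seed, {
    ## foot placements: foot k heel at (k s, side_k w/2), odd k = left (+y)
    ks <- -1L:K
    side <- ifelse(ks %% 2L == 0L, -1, 1)
    px <- ks * cal$s + stats::rnorm(length(ks), sd = params$placement_noise)
    py <- side * cal$w / 2 + stats::rnorm(length(ks), sd = params$placement_noise)

    v <- cal$s / T_step
    com <- cbind(
      v * tt + cal$cx - cal$s,
      cal$cy * cos(pi * tt / T_step - pi),
      0.55 * bh + 0.015 * cos(2 * pi * tt / T_step)
    ) + matrix(stats::rnorm(3L * n, sd = params$noise_sd), n)

    foot_series <- function(parity) {
      idx <- which(ks %% 2L == parity)           # this foot's placements
      outlines <- vector("list", n)
      contact <- logical(n)
      for (f in seq_len(n)) {
        t <- tt[f]
        placed <- idx[ks[idx] * T_step <= t + 1e-9]
        k_cur <- if (length(placed)) placed[length(placed)] else idx[1L]
        k_next <- idx[match(k_cur, idx) + 1L]
        t_off <- (ks[k_cur] + 1L) * T_step + params$double_support
        in_stance <- t <= t_off + 1e-9 || is.na(k_next)
        if (in_stance) {
          outlines[[f]] <- translate_poly(foot, px[k_cur], py[k_cur])
          contact[f] <- ks[k_cur] * T_step <= t + 1e-9
        } else {
          t_on <- ks[k_next] * T_step
          a <- min(max((t - t_off) / (t_on - t_off), 0), 1)
          outlines[[f]] <- translate_poly(foot,
                                          (1 - a) * px[k_cur] + a * px[k_next],
                                          (1 - a) * py[k_cur] + a * py[k_next])
          contact[f] <- FALSE
        }
      }
      list(outlines = outlines, contact = contact)
    }
    left <- foot_series(1L)
    right <- foot_series(0L)

    ev_k <- seq_len(params$n_events)
    events <- data.frame(frame = ev_k * fps + 1L,
                         side = ifelse(ev_k %% 2L == 1L, "L", "R"))
    gait_trial(sampling_rate = fs, com_position = com,
               left_foot = left, right_foot = right, events = events)
  })
}
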