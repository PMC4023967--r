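#' Gait trial container
#'
#' A gait trial holds everything needed to evaluate balance control at
#' heel strikes: the centre-of-mass trajectory, a per-frame ground-plane
#' outline and contact flag for each foot, and the heel-strike event list.
#' All positions are in metres; frame indices are 1-based.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param com_position n x 3 matrix of CoM positions (x forward, y lateral,
#'   z vertical), metres.
#' @param left_foot,right_foot lists with elements `outlines` (a list of
#'   n vertex matrices, metres) and `contact` (logical length n).
#' @param events data.frame with columns `frame` (integer, strictly
#'   increasing) and `side` (`"L"` or `"R"`), the heel strikes.
#' @param com_velocity optional n x 2 matrix of horizontal CoM velocities
#'   (m/s); when absent it is derived by central differences.
#' @return an object of class `gait_trial`.
#' @export
gait_trial <- function(sampling_rate, com_position, left_foot, right_foot,
                       events, com_velocity = NULL) {
  com_position <- as.matrix(com_position)
  n <- nrow(com_position)
  if (ncol(com_position) != 3L) stop("com_position must be n x 3")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  for (ft in list(left_foot, right_foot)) {
    if (!is.list(ft) || is.null(ft$outlines) || is.null(ft$contact))
      stop("each foot needs `outlines` and `contact`")
    if (length(ft$outlines) != n || length(ft$contact) != n)
      stop("foot data must cover all ", n, " frames")
  }
  events <- as.data.frame(events)
  if (!all(c("frame", "side") %in% names(events)))
    stop("events needs columns `frame` and `side`")
  if (nrow(events) > 0L) {
    if (is.unsorted(events$frame, strictly = TRUE))
      stop("event frames must be strictly increasing")
    if (any(events$frame < 1L | events$frame > n))
      stop("event frame outside the trial")
    for (i in seq_len(nrow(events))) {
      fr <- events$frame[i]
      if (!left_foot$contact[fr] && !right_foot$contact[fr])
        stop("no foot in contact at heel-strike frame ", fr)
    }
  }
  if (!is.null(com_velocity)) {
    com_velocity <- as.matrix(com_velocity)
    if (nrow(com_velocity) != n || ncol(com_velocity) != 2L)
      stop("com_velocity must be n x 2")
  }
  structure(list(sampling_rate = sampling_rate,
                 com_position = com_position,
                 com_velocity = com_velocity,
                 left_foot = left_foot, right_foot = right_foot,
                 events = events),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  n <- nrow(x$com_position)
  cat("Gait trial: ", n, " frames @ ", x$sampling_rate, " Hz (",
      round(n / x$sampling_rate, 2), " s), ", nrow(x$events),
      " heel strikes\n", sep = "")
  invisible(x)
}

#' Base of support at a frame
#'
#' Single support yields the in-contact foot's outline polygon; double
#' support yields the convex hull of both outlines' vertices, covering the
#' region between the feet.
#'
#' @param trial a [gait_trial()].
#' @param frame 1-based frame index.
#' @return BoS polygon (counter-clockwise vertex matrix, metres).
#' @export
build_bos <- function(trial, frame) {
  stopifnot(inherits(trial, "gait_trial"))
  n <- nrow(trial$com_position)
  if (frame < 1L || frame > n)
    stop("frame ", frame, " outside trial of ", n, " frames")
  lc <- trial$left_foot$contact[frame]
  rc <- trial$right_foot$contact[frame]
  if (!lc && !rc)
    stop("no foot in contact at frame ", frame, " (flight phase)")
  if (lc && rc) {
    convex_hull(rbind(trial$left_foot$outlines[[frame]],
                      trial$right_foot$outlines[[frame]]))
  } else if (lc) {
    as_polygon(trial$left_foot$outlines[[frame]])
  } else {
    as_polygon(trial$right_foot$outlines[[frame]])
  }
}

## central-difference velocity (one-sided at the ends), m/s
central_velocity <- function(pos, fs) {
  n <- nrow(pos)
  v <- matrix(NA_real_, n, ncol(pos))
  if (n >= 3L)
    v[2:(n - 1L), ] <- (pos[3:n, , drop = FALSE] -
                          pos[1:(n - 2L), , drop = FALSE]) * (fs / 2)
  v[1L, ] <- (pos[2L, ] - pos[1L, ]) * fs
  v[n, ] <- (pos[n, ] - pos[n - 1L, ]) * fs
  v
}

#' Evaluate balance control over a gait trial
#'
#' Computes the three balance-control measures at every heel-strike event:
#' CoM-BoS distance (static balance), CoM displacement along the velocity
#' vector to the BoS boundary (dynamic balance), and BoS area.  The CoM
#' trajectory is low-pass filtered first (8 Hz fourth-order zero-phase
#' Butterworth by default); velocity is taken from the trial when present,
#' otherwise derived from the filtered positions by central differences.
#' The trial summary is the arithmetic mean over events with defined
#' values.
#'
#' @param trial a [gait_trial()].
#' @param filter_on logical; apply the trajectory filter (default TRUE).
#' @param cutoff,order filter parameters, see [lowpass_filter()].
#' @param velocity_eps speed threshold below which the dynamic measure is
#'   undefined (m/s).
#' @return list with `events` (one row per heel strike: frame, side,
#'   com_bos and comv_bos in cm, bos_area in cm^2, com_inside,
#'   comv_defined), `summary` (named means over defined events) and
#'   `n_undefined` (count of events with undefined comv_bos).
#' @export
evaluate_trial <- function(trial, filter_on = TRUE, cutoff = 8, order = 4,
                           velocity_eps = 1e-4) {
  stopifnot(inherits(trial, "gait_trial"))
  if (nrow(trial$events) < 1L) stop("trial has no heel-strike events")
  fs <- trial$sampling_rate
  pos <- trial$com_position[, 1:2, drop = FALSE]
  if (filter_on) pos <- lowpass_filter(pos, fs, cutoff, order)
  vel <- trial$com_velocity
  if (is.null(vel)) vel <- central_velocity(pos, fs)

  ev <- trial$events
  out <- data.frame(frame = ev$frame, side = ev$side,
                    com_bos = NA_real_, comv_bos = NA_real_,
                    bos_area = NA_real_, com_inside = NA,
                    comv_defined = NA)
  for (i in seq_len(nrow(ev))) {
    fr <- ev$frame[i]
    bos <- build_bos(trial, fr)
    cb <- com_bos_distance(pos[fr, ], bos)
    cv <- comv_bos_displacement(pos[fr, ], vel[fr, ], bos,
                                velocity_eps = velocity_eps)
    out$com_bos[i] <- cb$distance
    out$com_inside[i] <- cb$inside
    out$comv_bos[i] <- cv$displacement
    out$comv_defined[i] <- cv$defined
    out$bos_area[i] <- polygon_area(bos)
  }
  summ <- c(com_bos = mean(out$com_bos),
            comv_bos = mean(out$comv_bos[out$comv_defined]),
            bos_area = mean(out$bos_area))
  list(events = out, summary = summ,
       n_undefined = sum(!out$comv_defined))
}

#' Write / read a gait trial as JSON
#'
#' The on-disk schema mirrors the in-memory container: `sampling_rate`,
#' `com_position` (n x 3, metres), optional `com_velocity`, per-foot
#' `outlines` (list of vertex arrays) and `contact` flags, and `events`
#' with 1-based `frame` and `side`.
#'
#' @param trial a [gait_trial()].
#' @param path file path.
#' @return `read_trial` returns a [gait_trial()]; `write_trial` returns
#'   `path` invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  obj <- list(sampling_rate = trial$sampling_rate,
              com_position = trial$com_position,
              com_velocity = trial$com_velocity,
              left_foot = trial$left_foot,
              right_foot = trial$right_foot,
              events = trial$events)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  fix_foot <- function(ft) {
    ol <- ft$outlines
    if (is.array(ol) && length(dim(ol)) == 3L) {
      ol <- lapply(seq_len(dim(ol)[1L]), function(i) ol[i, , ])
    } else {
      ol <- lapply(ol, as.matrix)
    }
    list(outlines = ol, contact = as.logical(ft$contact))
  }
  gait_trial(sampling_rate = obj$sampling_rate,
             com_position = as.matrix(obj$com_position),
             left_foot = fix_foot(obj$left_foot),
             right_foot = fix_foot(obj$right_foot),
             events = as.data.frame(obj$events),
             com_velocity = if (!is.null(obj$com_velocity))
               as.matrix(obj$com_velocity))
}
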