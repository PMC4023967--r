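# Independent brute-force oracles used to verify the geometry and
# training code.  These deliberately avoid the package's own primitives.

# random convex polygon: points on a circle are always in convex position
random_convex_polygon <- function(nv = 8, radius = 0.15) {
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  cbind(radius * cos(ang), radius * sin(ang))
}

# random simple star-shaped polygon: noisy radii, angular gaps kept below
# pi so the closing chord cannot cut across the interior
random_star_polygon <- function(nv = 8, radius = 0.15) {
  repeat {
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    if (max(diff(c(ang, ang[1L] + 2 * pi))) < pi) break
  }
  r <- radius * (0.6 + 0.4 * stats::runif(nv))
  cbind(r * cos(ang), r * sin(ang))
}

# minimum distance to the boundary by dense sampling of every edge
dense_boundary_dist <- function(p, poly, n_samples = 1e5) {
  nv <- nrow(poly)
  nxt <- c(2:nv, 1L)
  el <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2))
  per_edge <- pmax(2L, round(n_samples * el / sum(el)))
  d2 <- Inf
  for (i in seq_len(nv)) {
    t <- seq(0, 1, length.out = per_edge[i])
    sx <- poly[i, 1L] + t * (poly[nxt[i], 1L] - poly[i, 1L])
    sy <- poly[i, 2L] + t * (poly[nxt[i], 2L] - poly[i, 2L])
    d2 <- min(d2, min((sx - p[1L])^2 + (sy - p[2L])^2))
  }
  sqrt(d2)
}

# crossing-number point-in-polygon, written independently
oracle_inside <- function(p, poly) {
  nv <- nrow(poly)
  j <- nv
  inside <- FALSE
  for (i in seq_len(nv)) {
    if ((poly[i, 2L] > p[2L]) != (poly[j, 2L] > p[2L]) &&
        p[1L] < (poly[j, 1L] - poly[i, 1L]) * (p[2L] - poly[i, 2L]) /
          (poly[j, 2L] - poly[i, 2L]) + poly[i, 1L])
      inside <- !inside
    j <- i
  }
  inside
}

# march along the ray until the inside/outside state flips
ray_march_displacement <- function(org, dir, poly, step = 1e-5, tmax = 2) {
  dir <- dir / sqrt(sum(dir^2))
  t <- seq(step, tmax, by = step)
  px <- org[1L] + t * dir[1L]
  py <- org[2L] + t * dir[2L]
  state0 <- oracle_inside(org, poly)
  nv <- nrow(poly)
  j <- nv
  inside <- rep(FALSE, length(t))
  crossings <- integer(length(t))
  for (i in seq_len(nv)) {
    yi <- poly[i, 2L]; yj <- poly[j, 2L]
    sel <- (yi > py) != (yj > py)
    xin <- (poly[j, 1L] - poly[i, 1L]) * (py - yi) / (yj - yi) + poly[i, 1L]
    crossings <- crossings + as.integer(sel & px < xin)
    j <- i
  }
  inside <- crossings %% 2L == 1L
  flip <- which(inside != state0)
  if (!length(flip)) return(NA_real_)
  t[flip[1L]]
}

# fan triangulation area of a convex polygon (cross products from v1)
fan_area <- function(poly) {
  a <- 0
  for (i in 2:(nrow(poly) - 1L)) {
    v1 <- poly[i, ] - poly[1L, ]
    v2 <- poly[i + 1L, ] - poly[1L, ]
    a <- a + (v1[1L] * v2[2L] - v1[2L] * v2[1L]) / 2
  }
  abs(a)
}

# O(n^3) convex hull: an ordered pair (i, j) is a hull edge iff every
# other point lies strictly to its left; returns hull area via shoelace
brute_hull_area <- function(pts) {
  n <- nrow(pts)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- pts[j, ] - pts[i, ]
    cr <- d[1L] * (pts[, 2L] - pts[i, 2L]) - d[2L] * (pts[, 1L] - pts[i, 1L])
    others <- setdiff(seq_len(n), c(i, j))
    if (all(cr[others] > 1e-12)) edges[[length(edges) + 1L]] <- c(i, j)
  }
  em <- do.call(rbind, edges)
  ord <- em[1L, 1L]
  nxt <- em[1L, 2L]
  while (nxt != ord[1L]) {
    ord <- c(ord, nxt)
    nxt <- em[em[, 1L] == nxt, 2L][1L]
  }
  hull <- pts[ord, , drop = FALSE]
  x <- hull[, 1L]; y <- hull[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# least-squares MSE on min-max normalized data via normal equations
ols_normalized_mse <- function(X, Y) {
  sc <- function(M) {
    lo <- apply(M, 2L, min); hi <- apply(M, 2L, max)
    sweep(sweep(M, 2L, (lo + hi) / 2), 2L, (hi - lo) / 2, "/")
  }
  Xn <- cbind(1, sc(X)); Yn <- sc(Y)
  B <- solve(crossprod(Xn), crossprod(Xn, Yn))
  mean((Xn %*% B - Yn)^2)
}

# finite-difference Jacobian of normalized predictions w.r.t. parameters
fd_jacobian <- function(model, x, eps = 1e-6) {
  xn <- gaitbalance::minmax_apply(model$x_norm, as.matrix(x))
  get_par <- function(m) c(as.numeric(m$W1), m$b1, as.numeric(m$W2), m$b2)
  set_par <- function(m, v) {
    h <- nrow(m$W1); p <- ncol(m$W1); o <- nrow(m$W2)
    m$W1 <- matrix(v[seq_len(h * p)], h, p)
    m$b1 <- v[h * p + seq_len(h)]
    m$W2 <- matrix(v[h * (p + 1L) + seq_len(o * h)], o, h)
    m$b2 <- v[h * (p + 1L) + o * h + seq_len(o)]
    m
  }
  th <- get_par(model)
  J <- matrix(NA_real_, nrow(xn) * nrow(model$W2), length(th))
  for (j in seq_along(th)) {
    up <- th; up[j] <- up[j] + eps
    dn <- th; dn[j] <- dn[j] - eps
    yu <- gaitbalance::lmnet_forward(set_par(model, up), xn)
    yd <- gaitbalance::lmnet_forward(set_par(model, dn), xn)
    J[, j] <- as.numeric(yu - yd) / (2 * eps)
  }
  J
}

# a fixed "teacher" network of the package architecture, plus data from it
make_teacher <- function(p = 8, h = 10, o = 3, seed = 100) {
  set.seed(seed)
  list(W1 = matrix(stats::rnorm(h * p, sd = 0.8), h, p),
       b1 = stats::rnorm(h, sd = 0.3),
       W2 = matrix(stats::rnorm(o * h, sd = 0.8), o, h),
       b2 = stats::rnorm(o, sd = 0.3))
}

teacher_outputs <- function(tch, X) {
  t(tch$W2 %*% tanh(tch$W1 %*% t(X) + tch$b1) + tch$b2)
}

# minimal hand-built trial: two static feet, one heel strike
static_trial <- function(left_poly, right_poly, com, vel_frames = 20,
                         fs = 60, v = c(1, 0)) {
  n <- vel_frames
  com_pos <- cbind(com[1L] + (seq_len(n) - n / 2) * v[1L] / fs,
                   com[2L] + (seq_len(n) - n / 2) * v[2L] / fs,
                   rep(0.9, n))
  mk <- function(poly) list(outlines = rep(list(poly), n),
                            contact = rep(TRUE, n))
  gaitbalance::gait_trial(fs, com_pos, mk(left_poly), mk(right_poly),
                          data.frame(frame = n %/% 2L, side = "L"))
}
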