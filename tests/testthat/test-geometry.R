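test_that("analytic square cases are exact", {
  sq <- rbind(c(-0.1, -0.1), c(0.1, -0.1), c(0.1, 0.1), c(-0.1, 0.1))
  cb <- com_bos_distance(c(0, 0), sq)
  expect_equal(cb$distance, 10, tolerance = 1e-12)
  expect_true(cb$inside)
  expect_equal(comv_bos_displacement(c(0, 0), c(1, 0), sq)$displacement,
               10, tolerance = 1e-10)
  expect_equal(comv_bos_displacement(c(0, 0), c(1, 1), sq)$displacement,
               10 * sqrt(2), tolerance = 1e-10)
  ## point on an edge
  expect_equal(com_bos_distance(c(0.1, 0), sq)$distance, 0)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1e4)
  expect_equal(polygon_area(rbind(c(0, 0), c(3, 0), c(0, 4))), 6e4)
})

test_that("com_bos_distance matches a dense boundary-sampling oracle", {
  set.seed(42)
  for (i in 1:200) {
    poly <- random_star_polygon(sample(4:10, 1))
    p <- stats::runif(2, -0.2, 0.2)
    d <- com_bos_distance(p, poly)$distance
    d_oracle <- dense_boundary_dist(p, poly, 2e4) * 100
    expect_lt(abs(d - d_oracle), 1e-3)
  }
})

test_that("comv_bos matches a ray-marching oracle and dominates com_bos", {
  set.seed(7)
  n_checked <- 0L
  while (n_checked < 120L) {
    poly <- random_star_polygon(sample(4:9, 1))
    p <- stats::runif(2, -0.08, 0.08)
    if (!oracle_inside(p, poly)) next
    th <- stats::runif(1, 0, 2 * pi)
    v <- c(cos(th), sin(th))
    cv <- comv_bos_displacement(p, v, poly)
    expect_true(cv$defined)
    t_oracle <- ray_march_displacement(p, v, poly, step = 1e-5)
    expect_lt(abs(cv$displacement - t_oracle * 100), 1e-2 + 1e-3)
    expect_gte(cv$displacement + 1e-9,
               com_bos_distance(p, poly)$distance)
    n_checked <- n_checked + 1L
  }
})

test_that("distances are invariant under rigid motion", {
  set.seed(11)
  for (i in 1:50) {
    poly <- random_star_polygon(8)
    p <- stats::runif(2, -0.05, 0.05)
    d0 <- com_bos_distance(p, poly)$distance
    th <- stats::runif(1, 0, 2 * pi); tr <- stats::runif(2, -3, 3)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    polyR <- sweep(poly %*% t(R), 2L, tr, "+")
    pR <- as.numeric(R %*% p + tr)
    d1 <- com_bos_distance(pR, polyR)$distance
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("polygon_area agrees with fan triangulation on random 8-gons", {
  set.seed(3)
  for (i in 1:100) {
    poly <- random_convex_polygon(8)
    expect_equal(polygon_area(poly), fan_area(poly) * 1e4,
                 tolerance = 1e-6)
  }
})

test_that("degenerate and invalid polygons are rejected", {
  expect_error(as_polygon(rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(as_polygon(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(as_polygon(bowtie), "self-intersecting")
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("velocity below threshold flags the dynamic measure undefined", {
  sq <- rbind(c(-0.1, -0.1), c(0.1, -0.1), c(0.1, 0.1), c(-0.1, 0.1))
  r <- comv_bos_displacement(c(0, 0), c(1e-6, 0), sq)
  expect_false(r$defined)
  expect_identical(r$reason, "zero_velocity")
  r2 <- comv_bos_displacement(c(0.5, 0), c(1, 0), sq)
  expect_false(r2$defined)
  expect_identical(r2$reason, "no_intersection")
  ## outside but re-entering is defined
  expect_equal(comv_bos_displacement(c(0.5, 0), c(-1, 0), sq)$displacement,
               40, tolerance = 1e-9)
})

test_that("double-support hull matches the brute-force hull oracle", {
  sq1 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sq2 <- sweep(sq1, 2L, c(0.4, 1.3), "+")   # stepped forward and laterally
  pts <- rbind(sq1, sq2)                    # 6-vertex hull, no collinearity
  hull <- convex_hull(pts)
  expect_equal(polygon_area(hull), brute_hull_area(pts) * 1e4,
               tolerance = 1e-9)
  ## hull contains every vertex of both footprints
  for (i in seq_len(nrow(pts)))
    expect_true(com_bos_distance(pts[i, ], hull)$inside)
  ## hull monotonicity: double-support area >= each single-foot area
  expect_gte(polygon_area(hull), polygon_area(sq1))
  expect_gte(polygon_area(hull), polygon_area(sq2))
})

test_that("build_bos handles single support, double support and flight", {
  foot_l <- rbind(c(0, 0.05), c(0.25, 0.05), c(0.25, 0.15), c(0, 0.15))
  foot_r <- rbind(c(0.3, -0.15), c(0.55, -0.15), c(0.55, -0.05), c(0.3, -0.05))
  tr <- static_trial(foot_l, foot_r, c(0.25, 0))
  expect_equal(polygon_area(build_bos(tr, 10)),
               brute_hull_area(rbind(foot_l, foot_r)) * 1e4,
               tolerance = 1e-9)
  tr$right_foot$contact[10] <- FALSE
  expect_equal(polygon_area(build_bos(tr, 10)), 0.25 * 0.10 * 1e4,
               tolerance = 1e-9)
  tr$left_foot$contact[10] <- FALSE
  expect_error(build_bos(tr, 10), "flight")
  expect_error(build_bos(tr, 999), "outside trial")
})

test_that("evaluate_trial on a known static configuration", {
  sq <- rbind(c(-0.1, -0.1), c(0.1, -0.1), c(0.1, 0.1), c(-0.1, 0.1))
  ## both "feet" the same square so the hull is the square itself
  tr <- static_trial(sq, sq, c(0, 0), v = c(0.5, 0))
  ev <- evaluate_trial(tr, filter_on = FALSE)
  expect_equal(unname(ev$summary["com_bos"]), 10, tolerance = 1e-6)
  expect_equal(unname(ev$summary["comv_bos"]), 10, tolerance = 1e-6)
  expect_equal(unname(ev$summary["bos_area"]), 400, tolerance = 1e-9)
  expect_identical(ev$n_undefined, 0L)
})

test_that("filtering an already-smooth trial changes measures by <1%", {
  sq <- rbind(c(-0.2, -0.2), c(0.2, -0.2), c(0.2, 0.2), c(-0.2, 0.2))
  n <- 120; fs <- 60
  t <- (seq_len(n) - 1) / fs
  com <- cbind(0.05 * sin(2 * pi * 1.5 * t), 0.03 * cos(2 * pi * 1 * t), 0.9)
  mk <- function(poly) list(outlines = rep(list(poly), n),
                            contact = rep(TRUE, n))
  tr <- gait_trial(fs, com, mk(sq), mk(sq),
                   data.frame(frame = c(40L, 80L), side = c("L", "R")))
  e0 <- evaluate_trial(tr, filter_on = FALSE)
  e1 <- evaluate_trial(tr, filter_on = TRUE)
  expect_equal(e1$summary, e0$summary, tolerance = 0.01)
})
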