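test_that("cohort generation is seed-deterministic and schema-complete", {
  p <- cohort_params(n_subjects = 56, seed = 10)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  expect_identical(dim(c1), c(56L, 20L))
  expect_identical(names(c1), c("subject_id", cohort_features(),
                                cohort_outcomes()))
  c3 <- generate_cohort(cohort_params(n_subjects = 56, seed = 11))
  expect_false(identical(c1$age, c3$age))
})

test_that("instrument ranges and granularity are respected", {
  ch <- generate_cohort(cohort_params(n_subjects = 500, seed = 2))
  expect_true(all(ch$bbs >= 0 & ch$bbs <= 56 & ch$bbs == round(ch$bbs)))
  expect_true(all(ch$gds >= 0 & ch$gds <= 15 & ch$gds == round(ch$gds)))
  expect_true(all(ch$slums >= 0 & ch$slums <= 30 & ch$slums == round(ch$slums)))
  expect_true(all(ch$abc >= 0 & ch$abc <= 100))
  expect_true(all(ch$fall_history >= 0 &
                    ch$fall_history == round(ch$fall_history)))
  expect_true(all(ch$n_medications >= 0 &
                    ch$n_medications == round(ch$n_medications)))
  expect_true(all(ch$sex %in% c(0, 1) & ch$hearing_impaired %in% c(0, 1)))
  expect_true(all(ch$com_bos > 0 & ch$comv_bos > 0 & ch$bos_area > 0))
  expect_true(all(ch$comv_bos >= ch$com_bos))
})

test_that("a 56-subject cohort lands near the published demographics", {
  ch <- generate_cohort(cohort_params(n_subjects = 56, seed = 1))
  ## tolerance = 3 standard errors at n = 56
  expect_lt(abs(mean(ch$age) - 76.1), 3 * 6.5 / sqrt(56))
  expect_lt(abs(mean(ch$bos_area) - 436), 3 * 88 / sqrt(56))
})

test_that("degenerate noise-free, loading-free cohort is constant at the means", {
  p <- cohort_params(n_subjects = 5, loadings = default_loadings() * 0,
                     noise_sd = setNames(rep(0, 19), cohort_marginals()$name),
                     seed = 3)
  ch <- generate_cohort(p)
  mg <- cohort_marginals()
  for (v in c("age", "bmi", "tug", "com_bos", "comv_bos", "bos_area"))
    expect_equal(ch[[v]], rep(mg$mean[mg$name == v], 5), tolerance = 1e-12)
  expect_identical(length(unique(ch$bbs)), 1L)
})

test_that("large-sample marginals converge to the configured calibration", {
  n <- 20000
  ch <- generate_cohort(cohort_params(n_subjects = n, seed = 7))
  mg <- cohort_marginals()
  for (i in seq_len(nrow(mg))) {
    x <- ch[[mg$name[i]]]
    se <- mg$sd[i] / sqrt(n)
    ## 4 SE sampling band plus a 0.5% systematic allowance for
    ## discreteness of the integer-valued instruments
    expect_lt(abs(mean(x) - mg$mean[i]), 4 * se + 0.005 * abs(mg$mean[i]),
              label = paste("mean of", mg$name[i]))
    expect_lt(abs(stats::sd(x) - mg$sd[i]), 0.03 * mg$sd[i] + 4 * se,
              label = paste("sd of", mg$name[i]))
  }
  ## law-of-large-numbers check on TUG specifically
  expect_lt(abs(mean(ch$tug) - 9.0), 3 * 2.0 / sqrt(n))
})

test_that("latent loadings induce clinical-outcome dependence", {
  ch <- generate_cohort(cohort_params(n_subjects = 2000, seed = 5))
  expect_gt(stats::cor(ch$bbs, ch$com_bos), 0.2)
  expect_gt(stats::cor(ch$strength_hip_abd, ch$bos_area), 0.2)
  expect_lt(stats::cor(ch$tug, ch$com_bos), -0.2)
  ch0 <- generate_cohort(cohort_params(n_subjects = 2000,
                                       loadings = default_loadings() * 0,
                                       seed = 5))
  expect_lt(abs(stats::cor(ch0$bbs, ch0$com_bos)), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_params(n_subjects = 1), "n_subjects")
  bad <- default_loadings(); bad["bbs", ] <- c(2, 2, 2)
  expect_error(cohort_params(loadings = bad), "positive semi-definite")
  expect_error(cohort_params(loadings = default_loadings()[1:5, ]),
               "every variable")
})

test_that("cohort CSV round-trips bit for bit and validates its schema", {
  ch <- generate_cohort(cohort_params(n_subjects = 56, seed = 1))
  path <- tempfile(fileext = ".csv")
  write_cohort(ch, path)
  raw <- utils::read.csv(path)
  expect_identical(nrow(raw), 56L)
  expect_identical(ncol(raw), 20L)   # id + 16 features + 3 outcomes
  back <- read_cohort(path)
  for (nm in c(cohort_features(), cohort_outcomes()))
    expect_identical(back[[nm]], as.numeric(ch[[nm]]),
                     info = paste("column", nm))
  ## missing feature column
  trunc <- utils::read.csv(path)[, -9]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(trunc, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "bbs")
  ## extra column
  extra <- utils::read.csv(path); extra$stray <- 1
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(extra, p3, row.names = FALSE)
  expect_error(read_cohort(p3), "stray")
})
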