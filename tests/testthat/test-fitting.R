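test_that("foot-point projection matches a dense grid-search oracle", {
  withr::local_seed(11)
  n_cases <- 100L
  for (i in seq_len(n_cases)) {
    if (i %% 2 == 0) {
      params <- plm_params(A = 10^stats::runif(1, -8, -5),
                           gamma = stats::runif(1, 2, 5))
    } else {
      params <- im_params(A = stats::runif(1, 50, 300),
                          tau = stats::runif(1, 40, 80),
                          C = stats::runif(1, -1, 0.95))
    }
    t_obs <- stats::runif(1, 20, 80)
    R_obs <- risk(params, t_obs) + stats::rnorm(1, 0, 1)
    if (R_obs <= 0) R_obs <- 0.1
    datum <- tibble::tibble(age = t_obs, rate = R_obs)
    got <- project_point(datum, params)
    want <- grid_project(params, t_obs, R_obs,
                         lower = max(1, t_obs - 30),
                         upper = t_obs + 30, step = 1e-3)
    # refine the oracle around its coarse optimum
    want <- grid_project(params, t_obs, R_obs, want - 2e-3, want + 2e-3,
                         step = 1e-5)
    expect_equal(got$t_proj, want, tolerance = 1e-4)
    # the orthogonality diagnostic is small relative to the local scale
    expect_lt(abs(got$resid), 1e-6 * (1 + sqrt(got$dist2)))
  }
})

test_that("projection degenerate cases behave as hand computation", {
  p <- plm_params(2, 3)
  # datum exactly on the curve projects to itself with zero distance
  datum <- tibble::tibble(age = 4, rate = risk(p, 4))
  got <- project_point(datum, p)
  expect_equal(got$t_proj, 4, tolerance = 1e-8)
  expect_equal(got$dist2, 0, tolerance = 1e-12)
  # constant curve (gamma = 0): vertical projection
  pc <- plm_params(5, 0)
  got2 <- project_point(tibble::tibble(age = 37, rate = 8), pc)
  expect_equal(got2$t_proj, 37, tolerance = 1e-10)
  expect_equal(got2$dist2, 9, tolerance = 1e-10)
})

test_that("orthogonal RMS is zero on-curve and hand-computable off-curve", {
  p <- im_params(109.54, 76.78, -0.49)
  d <- noiseless_series(p)
  expect_equal(odr_rms(d, p)$RMS, 0, tolerance = 1e-9)
  # constant curve one unit above two data points: RMS = 1
  pc <- plm_params(3, 0)
  d2 <- tibble::tibble(age = c(10, 20), rate = c(2, 2))
  expect_equal(odr_rms(d2, pc)$RMS, 1, tolerance = 1e-10)
})

test_that("full fits recover generating parameters from noiseless data", {
  d <- noiseless_series(plm_params(1e-7, 4.5))
  f <- fit_full(d, "plm")
  expect_equal(f$params$A, 1e-7, tolerance = 1e-6)
  expect_equal(f$params$gamma, 4.5, tolerance = 1e-6)
  expect_lt(f$RMS, 1e-6)
  expect_true(f$converged)

  p_im <- im_params(222.32, 64.10, 0.94)
  d2 <- noiseless_series(p_im, ages = 12:85)
  f2 <- fit_full(d2, "im")
  expect_equal(f2$params$A, p_im$A, tolerance = 1e-4)
  expect_equal(f2$params$tau, p_im$tau, tolerance = 1e-4)
  expect_equal(f2$params$C, p_im$C, tolerance = 1e-4)
  expect_lt(f2$RMS, 1e-5)

  d3 <- noiseless_series(im_params(0.5, variant = "im1"), ages = 10:85)
  f3 <- fit_full(d3, "im1")
  expect_equal(f3$params$A, 0.5, tolerance = 1e-6)
})

test_that("noisy power-law fits recover the exponent across seeds", {
  # colon-like generator; 20 seeds at the default noise scale
  hits <- 0L
  for (s in 1:20) {
    d <- generate_incidence_like("colon-plm", seed = s)
    f <- fit_full(d, "plm")
    hits <- hits + (abs(f$params$gamma - 4.60) < 0.15)
  }
  expect_gte(hits, 19L)
})

test_that("restricted fits reproduce the parameter action exactly", {
  # power law: transform noiseless data by the scaling symmetry
  p <- plm_params(5.78e-7, 4.60)
  d <- noiseless_series(p, ages = 12:85)
  base <- fit_full(d, "plm")
  eps <- 0.9
  td <- transform_data(d, "plm-scaling", base$params, eps)
  fr <- fit_restricted(td, base, eps)
  expect_equal(fr$params$A,
               parameter_action("plm-scaling", base$params, eps)$A,
               tolerance = 1e-6)
  expect_lt(fr$RMS, 1e-6)
  # eps = 0 recovers the baseline parameter
  fr0 <- fit_restricted(d, base, 0)
  expect_equal(fr0$params$A, base$params$A, tolerance = 1e-6)

  # immunological model: fitted C matches the linear action
  p_im <- im_params(109.54, 76.78, -0.49)
  d2 <- noiseless_series(p_im)
  base2 <- fit_full(d2, "im")
  eps2 <- 0.4
  td2 <- transform_data(d2, "im", base2$params, eps2)
  fr2 <- fit_restricted(td2, base2, eps2)
  expect_equal(fr2$params$C,
               parameter_action("im", base2$params, eps2)$C,
               tolerance = 1e-5)
})

test_that("fit objects expose tidy, glance and plot methods", {
  d <- generate_incidence_like("cml-im", seed = 3)
  f <- fit_full(d, "im")
  td <- tidy(f)
  expect_setequal(td$term, c("A", "tau", "C", "alpha"))
  expect_false(td$free[td$term == "alpha"])
  g <- glance(f)
  expect_equal(g$RMS, sqrt(g$SS / g$m))
  expect_s3_class(autoplot(f), "ggplot")
})
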