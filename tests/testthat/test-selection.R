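test_that("data transformation preserves rates, order and round-trips", {
  p <- plm_params(5.78e-7, 4.60)
  d <- noiseless_series(p, ages = 12:85)
  expect_equal(transform_data(d, "plm-scaling", p, 0), d,
               ignore_attr = TRUE)
  td <- transform_data(d, "plm-scaling", p, log(2))
  expect_equal(td$age, d$age * 2)
  expect_equal(max(td$age), 170)
  expect_identical(td$rate, d$rate)
  back <- transform_data(td, "plm-scaling", p, -log(2))
  expect_equal(back$age, d$age, tolerance = 1e-10)
  # out-of-domain transformation names the limiting point
  pim <- im_params(109.54, 76.78, -0.49)
  d2 <- noiseless_series(pim)
  expect_error(transform_data(d2, "im", pim, 5), "maximal admissible")
})

test_that("default grids span the age-doubling scales", {
  g <- default_epsilon_grid("plm-scaling", plm_params(1, 4), t_max = 85)
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 2 * log(2))
  expect_length(g, 20L)
  g2 <- default_epsilon_grid("im", im_params(0.96, 32.55, 1.03),
                             t_max = 85, n_points = 2L)
  expect_equal(g2, c(0, 0.5547927162196287), tolerance = 1e-12)
})

test_that("self-symmetric noiseless profiles are exactly invariant", {
  d <- noiseless_series(plm_params(5.78e-7, 4.60), ages = 12:85)
  pr <- symmetry_profile(d, "plm")
  expect_equal(pr$profile$eps[1], 0)
  # RMS at eps = 0 equals the full fit's RMS exactly
  expect_identical(pr$profile$RMS[1], pr$baseline$RMS)
  expect_lt(max(pr$profile$RMS), 1e-6)

  d2 <- noiseless_series(im_params(109.54, 76.78, -0.49))
  pr2 <- symmetry_profile(d2, "im")
  expect_lt(max(pr2$profile$RMS), 1e-5)
})

test_that("mismatched symmetry on noiseless data stays bounded away from zero", {
  # data from the immunological model, profiled under the power law
  d <- noiseless_series(im_params(109.54, 76.78, -0.49))
  pr <- symmetry_profile(d, "plm")
  upper_half <- pr$profile$RMS[pr$profile$eps >= max(pr$profile$eps) / 2]
  expect_true(all(upper_half > 0.5))
  # and the converse direction
  d2 <- noiseless_series(plm_params(5.78e-7, 4.60), ages = 12:85)
  pr2 <- symmetry_profile(d2, "im")
  upper_half2 <- pr2$profile$RMS[pr2$profile$eps >=
                                   max(pr2$profile$eps) / 2]
  expect_true(all(upper_half2 > 0.05))
})

test_that("verdicts implement the invariance threshold", {
  mk_profile <- function(rms, rms0 = rms[1]) {
    structure(list(model = "plm", symmetry = "plm-scaling",
                   label = "toy",
                   profile = tibble::tibble(
                     eps = seq(0, 1, length.out = length(rms)),
                     RMS = rms, par = 1, converged = TRUE),
                   baseline = structure(list(RMS = rms0,
                                             converged = TRUE),
                                        class = "odr_fit")),
              class = "symmetry_profile")
  }
  # all-zero profile is invariant at any tolerance
  v0 <- select_model(mk_profile(rep(0, 10)), tol = 1e-6)
  expect_equal(v0$verdict, "invariant")
  # doubling profile is distorted at tol = 0.25
  v1 <- select_model(mk_profile(seq(1, 2, length.out = 10)))
  expect_equal(v1$verdict, "distorted")
  # near-zero baseline is protected by the floor
  v2 <- select_model(mk_profile(c(0, 1e-9, 2e-9)))
  expect_equal(v2$verdict, "invariant")
  # all-distorted sets carry the negative-information flag
  v3 <- select_model(list(mk_profile(seq(1, 2, length.out = 5)),
                          mk_profile(seq(1, 3, length.out = 5))))
  expect_true(attr(v3, "all_rejected"))
  v4 <- select_model(list(mk_profile(rep(1, 5)),
                          mk_profile(seq(1, 3, length.out = 5))))
  expect_false(attr(v4, "all_rejected"))
  expect_equal(v4$verdict, c("invariant", "distorted"))
  # failed baseline yields no-fit
  bad <- mk_profile(rep(1, 5))
  bad$baseline$converged <- FALSE
  expect_equal(select_model(bad)$verdict, "no-fit")
})

test_that("profile objects tidy, glance and plot", {
  d <- generate_incidence_like("cml-im", seed = 5)
  pr <- symmetry_profile(d, "im", n_points = 5L)
  td <- tidy(pr)
  expect_true(all(c("eps", "RMS", "model", "symmetry") %in% names(td)))
  g <- glance(pr)
  expect_equal(g$rms0, pr$baseline$RMS)
  expect_s3_class(autoplot(pr), "ggplot")
  expect_s3_class(plot_profiles(list(pr)), "ggplot")
})
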