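test_that("group laws hold for all four symmetries", {
  for (case in sym_cases()) {
    cap <- sym_eps_cap(case)
    eps_pairs <- withr::with_seed(42, matrix(stats::runif(20, -cap, cap),
                                             ncol = 2))
    # identity element
    id <- transform_point(case$sym, case$params, 0, case$t, case$t * 0 + 1)
    expect_equal(id$t, case$t, tolerance = 1e-12)
    for (i in seq_len(nrow(eps_pairs))) {
      e1 <- eps_pairs[i, 1]
      e2 <- eps_pairs[i, 2]
      # additivity: Gamma_e1 o Gamma_e2 = Gamma_{e1+e2}
      p12 <- transform_point(case$sym, case$params, e1,
                             transform_point(case$sym, case$params, e2,
                                             case$t, 1)$t, 1)
      psum <- transform_point(case$sym, case$params, e1 + e2, case$t, 1)
      expect_equal(p12$t, psum$t, tolerance = 1e-10)
      # inverse: round trip recovers the input
      back <- inverse_transform(case$sym, case$params, e1,
                                transform_point(case$sym, case$params,
                                                e1, case$t, 1)$t, 1)
      expect_equal(back$t, case$t, tolerance = 1e-10)
    }
  }
})

test_that("rates are never moved and transformed ages are monotone in eps", {
  for (case in sym_cases()) {
    cap <- sym_eps_cap(case)
    eps_seq <- seq(-cap, cap, length.out = 11)
    R <- risk(case$params, case$t)
    tr <- sapply(eps_seq, function(e) {
      out <- transform_point(case$sym, case$params, e, case$t, R)
      expect_identical(out$R, R)
      out$t
    })
    # t-hat strictly monotone in eps at every point (direction may
    # differ between symmetries)
    for (i in seq_along(case$t)) {
      expect_true(all(diff(tr[i, ]) > 0) || all(diff(tr[i, ]) < 0))
    }
  }
})

test_that("point transforms and parameter actions map curves to curves", {
  ages <- seq(20, 85, length.out = 200)
  for (case in sym_cases()) {
    cap <- sym_eps_cap(case)
    for (eps in c(-0.8, 0.6, 1) * cap) {
      R <- risk(case$params, ages)
      moved <- transform_point(case$sym, case$params, eps, ages, R)
      acted <- parameter_action(case$sym, case$params, eps)
      expect_equal(moved$R, risk(acted, moved$t), tolerance = 1e-9)
    }
  }
})

test_that("parameter actions move exactly the family parameter", {
  # scaling: A e^{-gamma eps} with gamma preserved
  p <- parameter_action("plm-scaling", plm_params(1.53e-7, 4.43), log(2))
  expect_equal(p$A, 1.53e-7 * 0.04639136158215779, tolerance = 1e-13)
  expect_equal(p$gamma, 4.43)
  # eps = 0 is the identity on parameters
  expect_equal(parameter_action("im", im_params(222.32, 64.10, 0.94), 0),
               im_params(222.32, 64.10, 0.94))
  # immunological action is linear in eps with slope -alpha e^{alpha tau}
  pc <- im_params(222.32, 64.10, 0.94)
  eps <- c(0.1, 0.2, 0.4)
  Cs <- vapply(eps, function(e) parameter_action("im", pc, e)$C,
               numeric(1))
  slope <- -pc$alpha * exp(pc$alpha * pc$tau)
  expect_equal(Cs, 0.94 + slope * eps, tolerance = 1e-12)
  # A, tau, alpha untouched
  expect_equal(parameter_action("im", pc, 0.3)[c("A", "tau", "alpha")],
               pc[c("A", "tau", "alpha")])
})

test_that("transformation scales reproduce the age-doubling values", {
  expect_equal(round(transformation_scale("plm-scaling",
                                          plm_params(1, 4), 2), 2), 0.69)
  # frozen 40-digit evaluations for the three reference pivot ages
  expect_equal(transformation_scale("im", im_params(109.54, 76.78, -0.49),
                                    2, 85), 0.7673905897957366,
               tolerance = 1e-13)
  expect_equal(transformation_scale("im", im_params(222.32, 64.10, 0.94),
                                    2, 85), 0.6504460468077724,
               tolerance = 1e-13)
  expect_equal(transformation_scale("im", im_params(0.96, 32.55, 1.03),
                                    2, 85), 0.5547927162196287,
               tolerance = 1e-13)
  # n = 1 is degenerate for every symmetry
  for (case in sym_cases()) {
    expect_equal(transformation_scale(case$sym, case$params, 1, 60), 0)
  }
  # the scale is the functional inverse of the age map: t -> n t
  for (case in sym_cases()) {
    es <- transformation_scale(case$sym, case$params, 2, 85)
    expect_equal(transform_point(case$sym, case$params, es, 85, 1)$t,
                 170, tolerance = 1e-8)
  }
  # scaling symmetry maps age 85 to 170 at eps = log(2)
  expect_equal(transform_point("plm-scaling", plm_params(1, 4.43),
                               log(2), 85, 1)$t, 170)
})

test_that("immunological transform errors outside its validity domain", {
  p <- im_params(109.54, 76.78, -0.49)
  eps_max <- expm1(exp(-p$alpha * (85 - p$tau))) /
    (p$alpha * exp(p$alpha * p$tau))
  expect_error(transform_point("im", p, eps_max * 1.01, 85, 1),
               "maximal admissible eps")
  expect_silent(transform_point("im", p, eps_max * 0.99, 85, 1))
})

test_that("closed-form tangents agree with differentiated transforms", {
  t <- c(30, 60, 80)
  # finite differences of the point transforms are the independent check
  for (case in sym_cases()) {
    tf <- tangent_fields(case$sym, case$params)
    fd <- tangent_fields(case$sym, case$params, method = "fd")
    expect_equal(tf$xi(t, 1), fd$xi(t, 1), tolerance = 1e-6)
    expect_equal(tf$eta(t, 1), rep(0, 3))
  }
  expect_equal(tangent_fields("plm-scaling",
                              plm_params(1, 4))$xi(t, 0), t)
  expect_equal(tangent_fields("im1-translation",
                              im_params(1, variant = "im1"))$xi(t, 0),
               rep(1, 3))
})

test_that("linearized symmetry condition vanishes for matched pairs only", {
  grid <- expand.grid(t = seq(25, 80, length.out = 8),
                      R = c(0.5, 2, 10, 50))
  for (case in sym_cases()) {
    tf <- tangent_fields(case$sym, case$params)
    om <- function(t, R) ode_rhs(case$params, t, R)
    res <- linearized_residual(grid, om, tf$xi, tf$eta)
    scale <- 1 + abs(om(grid$t, grid$R))
    expect_lt(max(abs(res$residual) / scale), 1e-6)
  }
  # perturbed tangent fails at generic points
  p <- plm_params(5.78e-7, 4.60)
  om <- function(t, R) ode_rhs(p, t, R)
  res_bad <- linearized_residual(grid, om,
                                 xi = function(t, R) t + 0.1,
                                 eta = function(t, R) rep(0, length(t)))
  expect_gt(max(abs(res_bad$residual)), 1e-3)
  # mismatched pair: scaling tangents against the immunological ODE
  p_im <- im_params(222.32, 64.10, 0.94)
  om_im <- function(t, R) ode_rhs(p_im, t, R)
  res_mix <- linearized_residual(grid, om_im,
                                 xi = function(t, R) t,
                                 eta = function(t, R) rep(0, length(t)))
  expect_gt(max(abs(res_mix$residual)), 1e-3)
})

test_that("reduced characteristic separates trivial from moving symmetries", {
  grid <- expand.grid(t = c(30, 50, 75), R = c(1, 20, 200))
  for (case in sym_cases()) {
    tf <- tangent_fields(case$sym, case$params)
    om <- function(t, R) ode_rhs(case$params, t, R)
    q <- reduced_characteristic(grid, om, tf$xi, tf$eta)
    expect_true(all(abs(q$Qbar) > 1e-8))
  }
  # eta = omega * xi is trivial by construction
  p <- plm_params(1, 3)
  om <- function(t, R) ode_rhs(p, t, R)
  q0 <- reduced_characteristic(grid, om,
                               xi = function(t, R) rep(1, length(t)),
                               eta = om)
  expect_equal(q0$Qbar, rep(0, nrow(grid)))
  # scaling symmetry of the power law: Qbar = -gamma R
  qp <- reduced_characteristic(grid, om, xi = function(t, R) t,
                               eta = function(t, R) rep(0, length(t)))
  expect_equal(qp$Qbar, -3 * grid$R)
})

test_that("flow exponentiation reproduces the closed-form transforms", {
  withr::local_seed(7)
  for (case in sym_cases()) {
    cap <- sym_eps_cap(case)
    eps_set <- stats::runif(5, -cap, cap)
    t0 <- sample(case$t, 3)
    for (eps in eps_set) {
      flow <- exponentiate_flow(case$sym, case$params, eps, t0,
                                rep(1, 3))
      closed <- transform_point(case$sym, case$params, eps, t0,
                                rep(1, 3))
      expect_equal(flow$t, closed$t, tolerance = 1e-6)
      expect_equal(flow$R, closed$R, tolerance = 1e-6)
    }
    # eps = 0 is the identity
    expect_equal(exponentiate_flow(case$sym, case$params, 0, 50, 2),
                 tibble::tibble(t = 50, R = 2))
  }
})
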