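#' Symmetry transformations of the candidate models
#'
#' Each candidate model admits a one-parameter Lie group of point
#' transformations \eqn{\Gamma_\epsilon} mapping solution curves of the
#' family to solution curves of the same family. All four implemented
#' symmetries are *t*-directional (they move only the age coordinate):
#' \describe{
#'   \item{`"plm-scaling"`}{\eqn{(t, R) \mapsto (t e^\epsilon, R)};
#'     moves the PLM scale \eqn{A} while preserving \eqn{\gamma}.}
#'   \item{`"im"`}{\eqn{t \mapsto \tau - \log(\log(w(t) - \alpha
#'     e^{\alpha\tau}\epsilon))/\alpha} with
#'     \eqn{w(t) = \exp(e^{-\alpha (t-\tau)})}; moves the IET shift
#'     \eqn{C} while preserving \eqn{(A, \tau, \alpha)}. Defined only
#'     while \eqn{w(t) - \alpha e^{\alpha\tau}\epsilon > 1}.}
#'   \item{`"im2"`}{\eqn{w \mapsto e^\epsilon (w - 1) + 1} on the same
#'     \eqn{w} coordinate; a symmetry of the full IM family and of the
#'     \eqn{C = 1} sub-model, moving the scale \eqn{A}.}
#'   \item{`"im1-translation"`}{\eqn{(t, R) \mapsto (t + \epsilon, R)};
#'     a symmetry of all three immunological variants.}
#' }
#'
#' @param id One of `"plm-scaling"`, `"im"`, `"im2"`, `"im1-translation"`.
#' @return A `symmetry` object.
#' @examples
#' transform_point(symmetry("plm-scaling"), plm_params(1, 4.43),
#'                 eps = log(2), t = 85, R = 1)
#' @export
symmetry <- function(id = c("plm-scaling", "im", "im2", "im1-translation")) {
  id <- match.arg(id)
  model <- switch(id,
                  "plm-scaling" = "plm",
                  "im" = "im",
                  "im2" = "im2",
                  "im1-translation" = "im1")
  structure(list(id = id, model = model), class = "symmetry")
}

#' @export
print.symmetry <- function(x, ...) {
  cat("<symmetry: ", x$id, "> (t-directional, acts on '", x$model,
      "' family)\n", sep = "")
  invisible(x)
}

.as_symmetry <- function(sym) {
  if (inherits(sym, "symmetry")) sym else symmetry(sym)
}

# checks the params object matches what the symmetry's formulas need
.sym_check_params <- function(sym, params) {
  if (sym$id == "plm-scaling") {
    if (!inherits(params, "plm_params")) {
      stop("symmetry 'plm-scaling' needs plm_params", call. = FALSE)
    }
  } else {
    if (!inherits(params, "im_params")) {
      stop("symmetry '", sym$id, "' needs im_params", call. = FALSE)
    }
    if (sym$id %in% c("im", "im2") && params$variant == "im1") {
      stop("symmetry '", sym$id, "' is not defined for the pure ",
           "exponential variant", call. = FALSE)
    }
    if (sym$id == "im" && params$variant == "im2") {
      stop("symmetry 'im' moves C and does not preserve the C = 1 ",
           "sub-model; use symmetry 'im2'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Apply a symmetry transformation to points
#'
#' Maps points \eqn{(t, R)} to \eqn{(\hat t(\epsilon), R)}. The rate
#' coordinate is unchanged for all four symmetries. For the `"im"`
#' symmetry the transform is only defined while
#' \eqn{\exp(e^{-\alpha(t-\tau)}) - \alpha e^{\alpha\tau} \epsilon > 1};
#' violations raise an error naming the maximal admissible
#' \eqn{\epsilon} for the offending point (no silent clipping).
#'
#' @param sym A [symmetry()] object or its id string.
#' @param params Model parameters supplying \eqn{(\alpha, \tau)} where the
#'   transform needs them.
#' @param eps Transformation parameter (scalar).
#' @param t,R Point coordinates (vectorised).
#' @return A tibble with columns `t` and `R`.
#' @export
transform_point <- function(sym, params, eps, t, R) {
  sym <- .as_symmetry(sym)
  .sym_check_params(sym, params)
  stopifnot(is.numeric(eps), length(eps) == 1L, is.finite(eps))
  t_new <- switch(
    sym$id,
    "plm-scaling" = t * exp(eps),
    "im1-translation" = t + eps,
    "im" = {
      al <- params$alpha
      tau <- params$tau
      v <- exp(-al * (t - tau))
      # w - 1 computed as expm1(v) for stability at large ages
      arg1 <- expm1(v) - al * exp(al * tau) * eps # = w - a*eps - 1
      if (any(arg1 <= 0)) {
        i <- which(arg1 <= 0)[1L]
        eps_max <- expm1(v[i]) / (al * exp(al * tau))
        stop(sprintf(paste0("symmetry 'im' undefined at point t = %.6g ",
                            "for eps = %.6g (maximal admissible eps = ",
                            "%.6g)"), t[i], eps, eps_max), call. = FALSE)
      }
      tau - log(log1p(arg1)) / al
    },
    "im2" = {
      al <- params$alpha
      tau <- params$tau
      v <- exp(-al * (t - tau))
      tau - log(log1p(exp(eps) * expm1(v))) / al
    })
  tibble::tibble(t = t_new, R = R)
}

#' Apply the inverse symmetry transformation
#'
#' Equal to [transform_point()] at `-eps` (the group inverse
#' \eqn{\Gamma_\epsilon^{-1} = \Gamma_{-\epsilon}}).
#'
#' @inheritParams transform_point
#' @export
inverse_transform <- function(sym, params, eps, t, R) {
  transform_point(sym, params, -eps, t, R)
}

#' Action of a symmetry on model parameters
#'
#' Every implemented symmetry moves exactly the parameter(s) indexing
#' the solution-curve family it acts on, so that transforming each point
#' of a curve reproduces the curve with the acted-on parameters:
#' \itemize{
#'   \item `"plm-scaling"`: \eqn{A(\epsilon) = A e^{-\gamma\epsilon}},
#'     \eqn{\gamma} preserved;
#'   \item `"im"`: \eqn{C(\epsilon) = C - \alpha e^{\alpha\tau}\epsilon},
#'     \eqn{(A, \tau, \alpha)} preserved (linear in \eqn{\epsilon});
#'   \item `"im2"`: \eqn{A(\epsilon) = A e^{\epsilon}},
#'     \eqn{C(\epsilon) = 1 + e^{\epsilon}(C - 1)} (so \eqn{C = 1} is
#'     preserved);
#'   \item `"im1-translation"`: \eqn{\tau(\epsilon) = \tau + \epsilon}
#'     for the IM/IM-II families and \eqn{A(\epsilon) = A
#'     e^{-\alpha\epsilon}} for the pure exponential.
#' }
#'
#' @inheritParams transform_point
#' @return A `model_params` object of the same class.
#' @export
parameter_action <- function(sym, params, eps) {
  sym <- .as_symmetry(sym)
  .sym_check_params(sym, params)
  stopifnot(is.numeric(eps), length(eps) == 1L, is.finite(eps))
  switch(
    sym$id,
    "plm-scaling" = plm_params(A = params$A * exp(-params$gamma * eps),
                               gamma = params$gamma),
    "im" = im_params(A = params$A, tau = params$tau,
                     C = params$C - params$alpha *
                       exp(params$alpha * params$tau) * eps,
                     alpha = params$alpha, variant = "im"),
    "im2" = {
      if (params$variant == "im2") {
        im_params(A = params$A * exp(eps), tau = params$tau,
                  alpha = params$alpha, variant = "im2")
      } else {
        im_params(A = params$A * exp(eps), tau = params$tau,
                  C = 1 + exp(eps) * (params$C - 1),
                  alpha = params$alpha, variant = "im")
      }
    },
    "im1-translation" = {
      if (params$variant == "im1") {
        im_params(A = params$A * exp(-params$alpha * eps),
                  alpha = params$alpha, variant = "im1")
      } else {
        im_params(A = params$A, tau = params$tau + eps, C = params$C,
                  alpha = params$alpha, variant = params$variant)
      }
    })
}

#' Transformation scale for an age-multiplication factor
#'
#' The transformation parameter \eqn{\epsilon_{scale}} that maps a
#' reference age `t` to `n * t` under the given symmetry. For the PLM
#' scaling symmetry this is \eqn{\log(n)}, independent of the parameters
#' and of the reference age; for the IM symmetry it is
#' \deqn{\epsilon_{scale} = \frac{\exp(e^{-\alpha(t-\tau)}) -
#'   \exp(e^{-\alpha(nt-\tau)})}{\alpha e^{\alpha\tau}},}
#' which depends on \eqn{(\alpha, \tau)} and on `t`.
#'
#' @inheritParams transform_point
#' @param n Age-multiplication factor (`n = 1` gives 0).
#' @param t Reference age in years (ignored by `"plm-scaling"`).
#' @return The scalar \eqn{\epsilon_{scale}}.
#' @examples
#' transformation_scale("plm-scaling", plm_params(1, 4), n = 2) # log(2)
#' transformation_scale("im", im_params(109.54, 76.78, -0.49),
#'                      n = 2, t = 85)
#' @export
transformation_scale <- function(sym, params, n, t = NULL) {
  sym <- .as_symmetry(sym)
  .sym_check_params(sym, params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (sym$id != "plm-scaling") {
    stopifnot(is.numeric(t), length(t) == 1L, t > 0)
  }
  al <- params$alpha
  tau <- params$tau
  switch(
    sym$id,
    "plm-scaling" = log(n),
    "im1-translation" = (n - 1) * t,
    "im" = {
      v1 <- exp(-al * (t - tau))
      v2 <- exp(-al * (n * t - tau))
      (exp(v1) - exp(v2)) / (al * exp(al * tau))
    },
    "im2" = {
      v1 <- exp(-al * (t - tau))
      v2 <- exp(-al * (n * t - tau))
      log(expm1(v2) / expm1(v1)) # negative for n > 1: im2 moves ages down
    })
}

#' Tangent fields (infinitesimal generator) of a symmetry
#'
#' Returns the tangents \eqn{(\xi(t, R), \eta(t, R))} of the generator
#' \eqn{X = \xi \partial_t + \eta \partial_R}, i.e. the
#' \eqn{\epsilon}-derivatives of the point transforms at
#' \eqn{\epsilon = 0}. All are coded in closed form (with
#' \eqn{v = e^{-\alpha (t - \tau)}}):
#' \itemize{
#'   \item scaling: \eqn{\xi = t};
#'   \item immunological: \eqn{\xi = e^{\alpha\tau} / (v e^{v})};
#'   \item C = 1 sub-model: \eqn{\xi = -(e^{v} - 1)/(\alpha v e^{v})};
#'   \item translation: \eqn{\xi = 1}.
#' }
#' All four symmetries are t-directional, so \eqn{\eta \equiv 0}. A
#' central finite difference of [transform_point()] (`method = "fd"`,
#' step `1e-6 * max(1, eps_ref)`) is retained as an independent
#' cross-check of the closed forms.
#'
#' @inheritParams transform_point
#' @param method `"analytic"` (default) or `"fd"`.
#' @param eps_ref Reference transformation scale sizing the
#'   finite-difference step.
#' @return A list with vectorised functions `xi(t, R)` and `eta(t, R)`.
#' @export
tangent_fields <- function(sym, params, method = c("analytic", "fd"),
                           eps_ref = 1) {
  sym <- .as_symmetry(sym)
  method <- match.arg(method)
  .sym_check_params(sym, params)
  eta <- function(t, R) rep(0, length(t))
  if (method == "fd") {
    h <- 1e-6 * max(1, abs(eps_ref))
    force(params)
    xi <- function(t, R) {
      (transform_point(sym, params, h, t, R)$t -
         transform_point(sym, params, -h, t, R)$t) / (2 * h)
    }
    return(list(xi = xi, eta = eta))
  }
  al <- params$alpha
  tau <- params$tau
  xi <- switch(
    sym$id,
    "plm-scaling" = function(t, R) t,
    "im1-translation" = function(t, R) rep(1, length(t)),
    "im" = function(t, R) {
      v <- exp(-al * (t - tau))
      exp(al * tau) / (v * exp(v))
    },
    "im2" = function(t, R) {
      v <- exp(-al * (t - tau))
      -expm1(v) / (al * v * exp(v))
    })
  list(xi = xi, eta = eta)
}

#' Residual of the linearized symmetry condition
#'
#' For tangents \eqn{(\xi, \eta)} to generate a symmetry of
#' \eqn{dR/dt = \omega(t, R)} they must satisfy
#' \deqn{\eta_t + (\eta_R - \xi_t)\omega - \xi_R \omega^2 - \xi \omega_t
#'   - \eta \omega_R = 0.}
#' This verifier evaluates the left-hand side on a grid of points; it is
#' numerically zero for each implemented (symmetry, family-ODE) pair and
#' detectably nonzero for mismatched or perturbed tangents. Partial
#' derivatives are taken by central differences of the supplied
#' functions.
#'
#' @param grid A data frame with columns `t` and `R`.
#' @param omega Function `omega(t, R)` (see [ode_rhs()]).
#' @param xi,eta Tangent functions `(t, R) -> numeric` (see
#'   [tangent_fields()]).
#' @param step Relative finite-difference step.
#' @return The input grid with a `residual` column added.
#' @export
linearized_residual <- function(grid, omega, xi, eta, step = 1e-6) {
  stopifnot(is.data.frame(grid), all(c("t", "R") %in% names(grid)))
  t <- grid$t
  R <- grid$R
  ht <- step * pmax(1, abs(t))
  hR <- step * pmax(1, abs(R))
  d_t <- function(f) (f(t + ht, R) - f(t - ht, R)) / (2 * ht)
  d_R <- function(f) (f(t, R + hR) - f(t, R - hR)) / (2 * hR)
  om <- omega(t, R)
  res <- d_t(eta) + (d_R(eta) - d_t(xi)) * om - d_R(xi) * om^2 -
    xi(t, R) * d_t(omega) - eta(t, R) * d_R(omega)
  dplyr::mutate(tibble::as_tibble(grid), residual = res)
}

#' Reduced characteristic of a symmetry
#'
#' \eqn{\bar Q(t, R) = \eta(t, R) - \omega(t, R)\,\xi(t, R)}. A symmetry
#' is *trivial* (moves no point of any solution curve) iff
#' \eqn{\bar Q \equiv 0}; only non-trivial symmetries are useful for
#' model selection.
#'
#' @inheritParams linearized_residual
#' @return The input grid with a `Qbar` column added.
#' @export
reduced_characteristic <- function(grid, omega, xi, eta) {
  stopifnot(is.data.frame(grid), all(c("t", "R") %in% names(grid)))
  dplyr::mutate(tibble::as_tibble(grid),
                Qbar = eta(t, R) - omega(t, R) * xi(t, R))
}

#' Generate a symmetry by exponentiating its infinitesimal generator
#'
#' Integrates the flow \eqn{dt/ds = \xi(t, R)}, \eqn{dR/ds = \eta(t, R)}
#' from \eqn{s = 0} to \eqn{s = \epsilon}, recovering the global
#' transformation from the generator. The flow is integrated numerically
#' (via \pkg{deSolve}) rather than summing the exponential-map series,
#' whose truncations diverge for the stiff immunological tangent; the
#' result agrees with the closed-form [transform_point()] to high
#' accuracy, which ties the infinitesimal picture to the closed-form
#' group actions.
#'
#' @inheritParams transform_point
#' @param rtol,atol Integration tolerances.
#' @return A tibble with columns `t` and `R`.
#' @export
exponentiate_flow <- function(sym, params, eps, t, R, rtol = 1e-12,
                              atol = 1e-12) {
  sym <- .as_symmetry(sym)
  .sym_check_params(sym, params)
  tf <- tangent_fields(sym, params, eps_ref = eps)
  out_t <- numeric(length(t))
  out_R <- numeric(length(t))
  for (i in seq_along(t)) {
    if (eps == 0) {
      out_t[i] <- t[i]
      out_R[i] <- R[i]
      next
    }
    sol <- deSolve::ode(
      y = c(t = t[i], R = R[i]),
      times = c(0, eps),
      func = function(s, y, parms) {
        list(c(tf$xi(y[1L], y[2L]), tf$eta(y[1L], y[2L])))
      },
      parms = NULL, rtol = rtol, atol = atol)
    if (anyNA(sol[nrow(sol), ])) {
      stop("flow left the validity domain before s = ", eps,
           call. = FALSE)
    }
    out_t[i] <- sol[nrow(sol), "t"]
    out_R[i] <- sol[nrow(sol), "R"]
  }
  tibble::tibble(t = out_t, R = out_R)
}
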