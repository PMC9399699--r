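#' Power law model parameters
#'
#' The power law model (PLM) describes cancer incidence driven by the
#' accumulation of driver mutations: \eqn{R(t) = A t^\gamma}, where
#' \eqn{\gamma} is one less than the number of driver mutations required
#' for incidence and \eqn{A} (units \eqn{\mathrm{years}^{-\gamma}}) sets
#' the scale.
#'
#' @param A Scaling coefficient, must be positive.
#' @param gamma Exponent (dimensionless); one less than the number of
#'   driver mutations.
#' @return An object of class `c("plm_params", "model_params")`.
#' @examples
#' p <- plm_params(A = 1.53e-7, gamma = 4.43)
#' risk(p, 50)
#' @export
plm_params <- function(A, gamma) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (A <= 0) stop("'A' must be positive", call. = FALSE)
  structure(list(A = unname(A), gamma = unname(gamma)),
            class = c("plm_params", "model_params"))
}

#' Immunological model parameters
#'
#' The immunological model (IM) describes incidence limited by
#' immunosenescence: potentially cancerous cell clones arise at a constant
#' rate and undergo a stochastic birth-death process; a clone progresses
#' to incidence only if it crosses an immune escape threshold (IET) that
#' declines exponentially with age at the rate of T-cell production
#' decline, \eqn{\alpha = 0.044\,\mathrm{yr}^{-1}}. The resulting risk
#' curve is
#' \deqn{R(t) = \frac{A}{\exp(e^{-\alpha (t - \tau)}) - C},}
#' where \eqn{\tau} (years) is the pivot age and \eqn{C} shifts the IET
#' (values of \eqn{C} below one correspond to a higher threshold, i.e.
#' more immune protection). Two nested sub-models are supported:
#' `variant = "im2"` fixes \eqn{C = 1} (two free parameters), and
#' `variant = "im1"` is the pure exponential \eqn{R(t) = A e^{\alpha t}}
#' obtained for an unbiased birth-death walk (one free parameter).
#'
#' @param A Scale parameter, positive.
#' @param tau Pivot age in years (unused by variant `"im1"`).
#' @param C IET-shift parameter (dimensionless). Forced to 1 for
#'   `variant = "im2"`; unused by `"im1"`.
#' @param alpha T-cell production decline rate per year; fixed to 0.044
#'   by default.
#' @param variant One of `"im"`, `"im2"`, `"im1"`.
#' @return An object of class `c("im_params", "model_params")`.
#' @examples
#' p <- im_params(A = 109.54, tau = 76.78, C = -0.49)
#' risk(p, c(40, 60, 85))
#' @export
im_params <- function(A, tau = NULL, C = NULL, alpha = 0.044,
                      variant = c("im", "im2", "im1")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (A <= 0) stop("'A' must be positive", call. = FALSE)
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (variant == "im2") C <- 1
  if (variant == "im1") {
    tau <- NA_real_
    C <- NA_real_
  } else {
    stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
    stopifnot(is.numeric(C), length(C) == 1L, is.finite(C))
  }
  structure(list(A = unname(A), tau = unname(tau), C = unname(C),
                 alpha = unname(alpha), variant = variant),
            class = c("im_params", "model_params"))
}

#' Mechanistic parameters of the immunological model
#'
#' Parameters of the underlying cell-level picture: clones originate at
#' rate `r`, grow as a birth-death walk with per-cell birth rate `b` and
#' death rate `d` (the immune-controlled regime requires `d > b`), and
#' progress to incidence upon crossing the immune escape threshold
#' \eqn{K(t) = K_0 e^{-\alpha t} + K_1}.
#'
#' @param r Clone origination rate (per year).
#' @param b,d Per-cell birth and death rates; `d > b > 0` required.
#' @param K0,K1 IET coefficients (cells); `K0 > 0` so the pivot age is
#'   defined.
#' @return An object of class `"mechanistic_params"` with derived fields
#'   `A0 = r (d - b) / b`, `B0 = K0 log(d/b)`, `B1 = K1 log(d/b)`.
#' @seealso [im_from_mechanism()]
#' @export
mechanistic_params <- function(r, b, d, K0, K1) {
  stopifnot(is.numeric(r), r > 0, is.numeric(b), is.numeric(d),
            is.numeric(K0), is.numeric(K1))
  if (!(d > b && b > 0)) {
    stop("invalid regime: need d > b > 0", call. = FALSE)
  }
  if (K0 <= 0) stop("'K0' must be positive", call. = FALSE)
  structure(list(r = r, b = b, d = d, K0 = K0, K1 = K1,
                 A0 = r * (d - b) / b,
                 B0 = K0 * log(d / b),
                 B1 = K1 * log(d / b)),
            class = "mechanistic_params")
}

#' Construct model parameters from a model id
#'
#' @param model One of `"plm"`, `"im"`, `"im2"`, `"im1"`.
#' @param ... Passed to [plm_params()] or [im_params()].
#' @return A `model_params` object.
#' @export
model_params <- function(model = c("plm", "im", "im2", "im1"), ...) {
  model <- match.arg(model)
  if (model == "plm") plm_params(...) else im_params(..., variant = model)
}

#' @export
print.model_params <- function(x, ...) {
  id <- if (inherits(x, "plm_params")) "plm" else x$variant
  vals <- unlist(x[vapply(x, is.numeric, logical(1))])
  vals <- vals[is.finite(vals)]
  cat("<model_params: ", id, ">\n", sep = "")
  cat(paste0("  ", names(vals), " = ", signif(vals, 6), collapse = "\n"), "\n")
  invisible(x)
}

.model_id <- function(params) {
  if (inherits(params, "plm_params")) "plm" else params$variant
}

# inner exponent of the double exponential; overflow-guarded upstream
.im_v <- function(params, t) exp(-params$alpha * (t - params$tau))

#' Evaluate a risk curve
#'
#' Computes the incidence rate \eqn{R(t)} for the given model parameters.
#' The power law is evaluated in the log domain, and the double
#' exponential of the immunological model raises an explicit overflow
#' error when the inner exponent exceeds the double-precision range
#' (ages far below the pivot age) rather than returning infinity.
#'
#' @param params A `model_params` object.
#' @param t Ages in years (vectorised).
#' @return Numeric vector of rates.
#' @export
risk <- function(params, t) UseMethod("risk")

#' @rdname risk
#' @export
risk.plm_params <- function(params, t) {
  if (any(t < 0)) stop("domain error: age must be non-negative", call. = FALSE)
  if (any(t == 0) && params$gamma < 0) {
    stop("domain error: t = 0 with negative exponent", call. = FALSE)
  }
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(log(params$A) + params$gamma * log(t[pos]))
  out[!pos] <- if (params$gamma == 0) params$A else 0
  out
}

#' @rdname risk
#' @export
risk.im_params <- function(params, t) {
  if (params$variant == "im1") {
    z <- params$alpha * t
    if (any(z > 709)) stop("overflow in exponential risk", call. = FALSE)
    return(params$A * exp(z))
  }
  u <- -params$alpha * (t - params$tau)
  if (any(u > log(709))) {
    stop("overflow in double exponential: age too far below pivot age",
         call. = FALSE)
  }
  params$A / (exp(exp(u)) - params$C)
}

#' Analytic derivative of a risk curve
#'
#' @inheritParams risk
#' @return Numeric vector `dR/dt`.
#' @keywords internal
risk_deriv <- function(params, t) UseMethod("risk_deriv")

#' @export
risk_deriv.plm_params <- function(params, t) {
  params$gamma * risk(params, t) / t
}

#' @export
risk_deriv.im_params <- function(params, t) {
  al <- params$alpha
  if (params$variant == "im1") return(al * params$A * exp(al * t))
  v <- .im_v(params, t)
  w <- exp(v)
  params$A * al * v * w / (w - params$C)^2
}

#' Reparameterize the mechanistic picture as an immunological model
#'
#' Maps cell-level parameters (origination rate, birth/death rates, IET
#' coefficients) to the phenomenological parameters \eqn{(A, \tau, C)}:
#' \eqn{\tau = \log(B_0)/\alpha}, \eqn{A = A_0 e^{-B_1}},
#' \eqn{C = e^{-B_1}} with \eqn{B_i = K_i \log(d/b)}. Setting
#' \eqn{K_1 = 0} gives \eqn{C = 1}, the two-parameter sub-model;
#' \eqn{K_1 > 0} gives \eqn{C < 1} (extra protection at late ages).
#'
#' @param mp A [mechanistic_params()] object.
#' @param alpha IET decline rate per year.
#' @return An [im_params()] object evaluating identically to the
#'   mechanistic form \eqn{R(t) = A_0 / (\exp(B_0 e^{-\alpha t} + B_1) - 1)}.
#' @export
im_from_mechanism <- function(mp, alpha = 0.044) {
  stopifnot(inherits(mp, "mechanistic_params"))
  im_params(A = mp$A0 * exp(-mp$B1),
            tau = log(mp$B0) / alpha,
            C = exp(-mp$B1),
            alpha = alpha,
            variant = "im")
}

#' Risk in the raw mechanistic parameterization
#'
#' Direct evaluation of \eqn{R(t) = A_0/(\exp(B_0 e^{-\alpha t} + B_1) - 1)},
#' used to cross-check [im_from_mechanism()].
#'
#' @inheritParams im_from_mechanism
#' @param t Ages in years.
#' @export
mechanistic_risk <- function(mp, t, alpha = 0.044) {
  stopifnot(inherits(mp, "mechanistic_params"))
  mp$A0 / (exp(mp$B0 * exp(-alpha * t) + mp$B1) - 1)
}

#' Absorption probability of the birth-death walk
#'
#' Probability that a clone starting from one cell reaches the immune
#' escape threshold `K` before extinction, for a random walk with birth
#' rate `b` and death rate `d` (gambler's ruin with absorbing states at
#' 0 and `K`):
#' \deqn{p = \frac{b^{K-1}(d-b)}{d^K - b^K} = \frac{x - 1}{x^K - 1}, \quad x = d/b.}
#' The unbiased case `b = d` is handled by the analytic limit `1/K`.
#'
#' @param b,d Birth and death rates, positive.
#' @param K Threshold (integer number of cells, at least 1).
#' @return Probability in `(0, 1]`; decreasing in `K` when `d > b`.
#' @examples
#' absorption_probability(1, 2, 5) # 1/31
#' absorption_probability(2, 2, 10) # 1/10
#' @export
absorption_probability <- function(b, d, K) {
  stopifnot(is.numeric(b), b > 0, is.numeric(d), d > 0, is.numeric(K))
  if (length(K) != 1L || K < 1 || abs(K - round(K)) > 1e-8) {
    stop("'K' must be an integer >= 1", call. = FALSE)
  }
  K <- round(K)
  if (b == d) return(1 / K)
  x <- d / b
  # (x - 1) / (x^K - 1), stable near x = 1
  num <- x - 1
  num / expm1(K * log1p(num))
}

#' Right-hand side of the family-characterising ODE
#'
#' Each candidate family, with its symmetry-moved parameter eliminated,
#' satisfies a single first-order ODE \eqn{dR/dt = \omega(t, R)}. These
#' are the forms the symmetry verifiers (linearized symmetry condition,
#' reduced characteristic) act on:
#' \itemize{
#'   \item PLM (A eliminated, \eqn{\gamma} fixed): \eqn{\omega = \gamma R / t};
#'   \item IM (C eliminated; A, \eqn{\tau}, \eqn{\alpha} fixed):
#'     \eqn{\omega = (\alpha/A) R^2 v e^{v}} with \eqn{v = e^{-\alpha(t-\tau)}};
#'   \item IM-II (A eliminated, C = 1):
#'     \eqn{\omega = \alpha R v e^{v} / (e^{v} - 1)};
#'   \item IM-I (A eliminated): \eqn{\omega = \alpha R}.
#' }
#' Each form is verified against the analytic derivative of the
#' corresponding risk curve in the test-suite.
#'
#' @param params A `model_params` object; the `variant`/class selects the
#'   family.
#' @param t,R Coordinates (vectorised, equal length or length 1).
#' @return The slope \eqn{\omega(t, R)}.
#' @export
ode_rhs <- function(params, t, R) UseMethod("ode_rhs")

#' @export
ode_rhs.plm_params <- function(params, t, R) {
  if (any(t <= 0)) stop("domain error: need t > 0", call. = FALSE)
  params$gamma * R / t
}

#' @export
ode_rhs.im_params <- function(params, t, R) {
  al <- params$alpha
  if (params$variant == "im1") return(al * R)
  v <- .im_v(params, t)
  w <- exp(v)
  if (params$variant == "im2") {
    al * R * v * w / expm1(v)
  } else {
    (al / params$A) * R^2 * v * w
  }
}
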