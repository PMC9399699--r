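#' @title Orthogonal distance regression onto risk curves
#' @description Internal machinery: per-datum foot-point projection and
#'   the SS/RMS objective. The projection finds, for each datum
#'   \eqn{(\tilde t_i, \tilde R_i)}, the local minimiser nearest the
#'   start guess of the squared Euclidean distance
#'   \eqn{(\tilde t - t)^2 + (\tilde R - R(t))^2} in the (age, rate)
#'   plane, by bracketing a sign change of the distance derivative from
#'   the start and bisecting. All data points are processed as one
#'   vectorised sweep. The axes are deliberately not standardised: the
#'   distance mixes years and rate units exactly as the RMS statistic
#'   defines it.
#' @name odr-internals
#' @keywords internal
NULL

# age interval on which the curve is finite and positive
.curve_domain <- function(params) {
  if (inherits(params, "plm_params")) {
    return(c(1e-9, 1e7))
  }
  al <- params$alpha
  if (params$variant == "im1") return(c(-700 / al, 700 / al))
  tau <- params$tau
  lo <- tau - log(709) / al # double-exponential overflow guard
  hi <- if (params$C > 1) {
    tau - log(log(params$C)) / al - 1e-9 # pole where exp(v) = C
  } else {
    tau + 1e7
  }
  c(lo, hi)
}

# Vectorised foot-point projection of all data points onto one curve.
# Returns t_proj, dist2, resid (orthogonality diagnostic), converged.
# The bracketing/bisection itself lives in src/odr.cpp.
.project_mat <- function(params, t_obs, R_obs, start = t_obs,
                         n_expand = 60L, n_bisect = 52L) {
  dom <- .curve_domain(params)
  model_code <- if (inherits(params, "plm_params")) {
    0L
  } else if (params$variant == "im1") {
    2L
  } else {
    1L
  }
  par <- unlist(params[vapply(params, is.numeric, logical(1))])
  .cpp_project(model_code, par, t_obs, R_obs,
               rep_len(as.numeric(start), length(t_obs)),
               dom[1L], dom[2L], n_expand, n_bisect)
}

.project_vec <- function(params, t_obs, R_obs, start = t_obs) {
  pr <- .project_mat(params, t_obs, R_obs, start)
  tibble::tibble(t_proj = unname(pr[, "t_proj"]),
                 dist2 = unname(pr[, "dist2"]),
                 resid = unname(pr[, "resid"]),
                 converged = unname(pr[, "converged"]) > 0)
}

#' Project a data point onto a risk curve
#'
#' Finds the foot point: the local minimiser, nearest to `start`, of the
#' squared distance between the datum and the curve in the (age, rate)
#' plane. The orthogonality diagnostic
#' \eqn{(\tilde t - t^*) + R'(t^*) (\tilde R - R(t^*))} is reported; the
#' minimiser is found by local minimisation, not by solving the
#' orthogonality equation, so the diagnostic is small but not exactly
#' zero.
#'
#' @param data A data frame with columns `age` and `rate` (one row per
#'   datum).
#' @param params Model parameters for the curve.
#' @param start Start ages for the local search; defaults to the
#'   observed ages.
#' @return A tibble with one row per datum: `t_proj`, `dist2`, `resid`,
#'   `converged`. Non-convergence is flagged, never raised.
#' @export
project_point <- function(data, params, start = data$age) {
  stopifnot(is.data.frame(data), all(c("age", "rate") %in% names(data)))
  .project_vec(params, data$age, data$rate, start = start)
}

# sum of squared orthogonal distances; large finite penalty when the
# curve is invalid over the data range so optimisers can recover
.odr_ss <- function(params, data) {
  pr <- try(.project_mat(params, data$age, data$rate), silent = TRUE)
  if (inherits(pr, "try-error") || any(!is.finite(pr[, "dist2"]))) {
    return(list(SS = 1e12, projections = NULL))
  }
  list(SS = sum(pr[, "dist2"]),
       projections = tibble::tibble(
         t_proj = unname(pr[, "t_proj"]), dist2 = unname(pr[, "dist2"]),
         resid = unname(pr[, "resid"]),
         converged = unname(pr[, "converged"]) > 0))
}

# objective-only variant for optimiser inner loops (no tibble overhead)
.odr_ss_val <- function(params, age, rate) {
  pr <- try(.project_mat(params, age, rate), silent = TRUE)
  if (inherits(pr, "try-error")) return(1e12)
  ss <- sum(pr[, "dist2"])
  if (!is.finite(ss)) 1e12 else ss
}

# nlminb termination short of the evaluation/iteration limits counts as
# converged; flat near-zero objectives report "false convergence"
.nlminb_ok <- function(opt) {
  opt$convergence == 0L || !grepl("limit reached", opt$message)
}

.new_fit <- function(params, data, eps = 0, converged = TRUE,
                     n_starts = 1L, free = character()) {
  sc <- .odr_ss(params, data)
  m <- nrow(data)
  structure(
    list(params = params, model = .model_id(params), data = data,
         projections = sc$projections, SS = sc$SS,
         RMS = sqrt(sc$SS / m), m = m, eps = eps,
         converged = converged &&
           !is.null(sc$projections) && all(sc$projections$converged),
         n_starts = n_starts, free = free,
         label = .series_label(data)),
    class = "odr_fit")
}

#' Orthogonal-distance RMS of data against a (transformed) curve
#'
#' Computes \eqn{RMS(\epsilon) = \sqrt{SS(\epsilon)/m}} where
#' \eqn{SS(\epsilon)} sums squared Euclidean distances in the (age,
#' rate) plane between the data and their foot points on the curve. If a
#' symmetry and \eqn{\epsilon} are supplied, the curve is first
#' inversely transformed via the parameter action at \eqn{-\epsilon}
#' (the selection loop's "transform back" step); with `eps = 0` this is
#' the plain ODR distance to the curve itself.
#'
#' @param data A data frame with columns `age` and `rate` (the
#'   *original* observations).
#' @param params Parameters of the curve fitted to transformed data.
#' @param sym Optional symmetry used for the inverse transformation.
#' @param eps Transformation parameter context.
#' @return A list with elements `RMS`, `SS`, `params` (after any inverse
#'   action), `projections` and `flagged` (`TRUE` when any projection
#'   failed to converge).
#' @export
odr_rms <- function(data, params, sym = NULL, eps = 0) {
  .check_series(data)
  if (!is.null(sym) && eps != 0) {
    params <- parameter_action(sym, params, -eps)
  }
  sc <- .odr_ss(params, data)
  flagged <- is.null(sc$projections) || !all(sc$projections$converged)
  list(RMS = sqrt(sc$SS / nrow(data)), SS = sc$SS, params = params,
       projections = sc$projections, flagged = flagged)
}

# deterministic data-driven start guesses ------------------------------

.start_plm <- function(data) {
  fit <- stats::lm(log(rate) ~ log(age), data = data)
  c(logA = unname(stats::coef(fit)[1L]),
    gamma = unname(stats::coef(fit)[2L]))
}

# profile a coarse pivot-age grid; for fixed tau the reciprocal rate is
# linear in w = exp(exp(-alpha (t - tau))), giving (A, C) by least squares
.start_im <- function(data, alpha, fix_C1 = FALSE) {
  taus <- seq(min(data$age), max(data$age) + 45, length.out = 25L)
  best <- NULL
  for (tau in taus) {
    w <- exp(exp(-alpha * (data$age - tau)))
    if (any(!is.finite(w))) next
    cand <- if (fix_C1) {
      a <- sum((w - 1) * (1 / data$rate)) / sum((w - 1)^2)
      if (!is.finite(a) || a <= 0) next
      c(A = 1 / a, tau = tau, C = 1)
    } else {
      cf <- stats::coef(stats::lm(I(1 / rate) ~ w, data = data))
      if (!is.finite(cf[2L]) || cf[2L] <= 0) next
      c(A = unname(1 / cf[2L]), tau = tau, C = unname(-cf[1L] / cf[2L]))
    }
    p <- try(im_params(A = cand[["A"]], tau = cand[["tau"]],
                       C = cand[["C"]], alpha = alpha), silent = TRUE)
    if (inherits(p, "try-error")) next
    pred <- try(risk(p, data$age), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred))) next
    sse <- sum((data$rate - pred)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = cand, sse = sse)
  }
  if (is.null(best)) {
    best <- list(par = c(A = max(data$rate), tau = stats::median(data$age),
                         C = 0.9))
  }
  best$par
}

#' Full orthogonal-distance fit of a candidate model
#'
#' Minimises the sum of squared orthogonal distances \eqn{SS(0)} over
#' the model's free parameters: \eqn{(A, \gamma)} for the power law and
#' \eqn{(A, \tau, C)} for the immunological model with
#' \eqn{\alpha = 0.044\,\mathrm{yr}^{-1}} held fixed (variants `"im2"`
#' and `"im1"` free \eqn{(A, \tau)} and \eqn{A} respectively). Start
#' guesses are deterministic and data-driven: log-log least squares for
#' the power law, and a coarse pivot-age profile with a reciprocal-rate
#' linear solve for the immunological family. The scale parameter is
#' optimised on the log scale.
#'
#' @param data A filtered data frame with columns `age` and `rate`.
#' @param model One of `"plm"`, `"im"`, `"im2"`, `"im1"`.
#' @param alpha Immune decline rate, fixed during fitting.
#' @param control Passed to [stats::optim()] (Nelder-Mead); defaults use
#'   relative tolerance 1e-10 and at most 1e4 evaluations.
#' @return An object of class `"odr_fit"` with fields `params`,
#'   `projections`, `SS`, `RMS`, `converged`, `n_starts`.
#' @examples
#' d <- generate_series(plm_params(1.53e-7, 4.43), ages = 25:85,
#'                      sigma_R = 0, sigma_t = 0)
#' fit <- fit_full(d, "plm")
#' glance(fit)
#' @export
fit_full <- function(data, model = c("plm", "im", "im2", "im1"),
                     alpha = 0.044,
                     control = list(reltol = 1e-10, maxit = 1e4)) {
  model <- match.arg(model)
  .check_series(data)
  if (model == "plm") {
    st <- .start_plm(data)
    obj <- function(th) {
      .odr_ss_val(plm_params(A = exp(th[1L]), gamma = th[2L]),
                  data$age, data$rate)
    }
    opt <- stats::optim(st, obj, method = "Nelder-Mead", control = control)
    params <- plm_params(A = exp(opt$par[1L]), gamma = opt$par[2L])
    return(.new_fit(params, data, converged = opt$convergence == 0L,
                    n_starts = 1L, free = c("A", "gamma")))
  }
  if (model == "im1") {
    obj <- function(la) {
      .odr_ss_val(im_params(A = exp(la), alpha = alpha, variant = "im1"),
                  data$age, data$rate)
    }
    la0 <- mean(log(data$rate) - alpha * data$age)
    opt <- stats::nlminb(la0, obj, control = list(rel.tol = 1e-10,
                                                  eval.max = 1e4,
                                                  iter.max = 1e4))
    params <- im_params(A = exp(opt$par), alpha = alpha, variant = "im1")
    return(.new_fit(params, data, converged = .nlminb_ok(opt),
                    n_starts = 1L, free = "A"))
  }
  fix_C1 <- model == "im2"
  st <- .start_im(data, alpha, fix_C1 = fix_C1)
  mk <- function(th) {
    if (fix_C1) {
      im_params(A = exp(th[1L]), tau = th[2L], alpha = alpha,
                variant = "im2")
    } else {
      im_params(A = exp(th[1L]), tau = th[2L], C = th[3L], alpha = alpha)
    }
  }
  th0 <- if (fix_C1) c(log(st[["A"]]), st[["tau"]]) else
    c(log(st[["A"]]), st[["tau"]], st[["C"]])
  obj <- function(th) {
    p <- try(mk(th), silent = TRUE)
    if (inherits(p, "try-error")) return(1e12)
    .odr_ss_val(p, data$age, data$rate)
  }
  opt <- stats::optim(th0, obj, method = "Nelder-Mead", control = control)
  # one restart from the optimum polishes Nelder-Mead stalls
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = control)
  if (opt2$value < opt$value) opt <- opt2
  params <- mk(opt$par)
  .new_fit(params, data, converged = opt$convergence == 0L, n_starts = 1L,
           free = if (fix_C1) c("A", "tau") else c("A", "tau", "C"))
}

#' Restricted fit to symmetry-transformed data
#'
#' Refits only the parameter moved by the model's symmetry, holding the
#' rest at the baseline fit: the power law frees \eqn{A} (single start
#' \eqn{\tilde A e^{-\tilde\gamma \epsilon}}, \eqn{\gamma} frozen); the
#' immunological model frees \eqn{C} from 10 linearly spaced starts on
#' \eqn{[-5, 1]} with \eqn{(A, \tau)} frozen and \eqn{\alpha} fixed.
#' Among multi-starts the lowest-SS local solution wins (ties broken by
#' first index).
#'
#' @param data The (typically symmetry-transformed) data frame with
#'   columns `age` and `rate`.
#' @param baseline An `"odr_fit"` from [fit_full()] on the original
#'   data.
#' @param eps Transformation parameter the data were transformed with.
#' @param c_starts Start interval and count for the immunological
#'   restricted fit.
#' @return An `"odr_fit"`; start failures are flagged, not raised.
#' @export
fit_restricted <- function(data, baseline, eps,
                           c_starts = list(lower = -5, upper = 1,
                                           n = 10L)) {
  stopifnot(inherits(baseline, "odr_fit"))
  .check_series(data)
  bp <- baseline$params
  ctl <- list(rel.tol = 1e-10, eval.max = 1e4, iter.max = 1e4)
  if (baseline$model == "plm") {
    obj <- function(la) {
      .odr_ss_val(plm_params(A = exp(la), gamma = bp$gamma),
                  data$age, data$rate)
    }
    la0 <- log(bp$A) - bp$gamma * eps
    opt <- stats::nlminb(la0, obj, control = ctl)
    params <- plm_params(A = exp(opt$par), gamma = bp$gamma)
    return(.new_fit(params, data, eps = eps,
                    converged = .nlminb_ok(opt), n_starts = 1L,
                    free = "A"))
  }
  if (baseline$model != "im") {
    stop("restricted fitting is defined for models 'plm' and 'im'",
         call. = FALSE)
  }
  obj <- function(C) {
    p <- try(im_params(A = bp$A, tau = bp$tau, C = C, alpha = bp$alpha),
             silent = TRUE)
    if (inherits(p, "try-error")) return(1e12)
    .odr_ss_val(p, data$age, data$rate)
  }
  starts <- seq(c_starts$lower, c_starts$upper, length.out = c_starts$n)
  best <- NULL
  ok <- FALSE
  for (i in seq_along(starts)) {
    opt <- try(stats::nlminb(starts[i], obj, control = ctl),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    ok <- ok || .nlminb_ok(opt)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) {
    return(.new_fit(im_params(A = bp$A, tau = bp$tau, C = bp$C,
                              alpha = bp$alpha),
                    data, eps = eps, converged = FALSE,
                    n_starts = c_starts$n, free = "C"))
  }
  params <- im_params(A = bp$A, tau = bp$tau, C = best$par,
                      alpha = bp$alpha)
  .new_fit(params, data, eps = eps, converged = ok,
           n_starts = c_starts$n, free = "C")
}

# ---- broom-style and plotting methods --------------------------------

#' @export
print.odr_fit <- function(x, ...) {
  cat("<odr_fit: ", x$model, " on '", x$label, "'>\n", sep = "")
  cat("  m = ", x$m, ", RMS = ", signif(x$RMS, 6),
      ", converged = ", x$converged, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Tidy an orthogonal-distance fit
#'
#' @param x An `"odr_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`,
#'   `estimate`, `free`).
#' @method tidy odr_fit
#' @export
tidy.odr_fit <- function(x, ...) {
  p <- x$params
  terms <- names(p)[vapply(p, is.numeric, logical(1))]
  vals <- unlist(p[terms])
  keep <- is.finite(vals)
  tibble::tibble(term = terms[keep], estimate = unname(vals[keep]),
                 free = terms[keep] %in% x$free)
}

#' Summarise an orthogonal-distance fit
#'
#' @inheritParams tidy.odr_fit
#' @return A one-row tibble: `model`, `label`, `m`, `SS`, `RMS`, `eps`,
#'   `converged`, `n_starts`.
#' @method glance odr_fit
#' @export
glance.odr_fit <- function(x, ...) {
  tibble::tibble(model = x$model, label = x$label, m = x$m, SS = x$SS,
                 RMS = x$RMS, eps = x$eps, converged = x$converged,
                 n_starts = x$n_starts)
}

#' Plot an orthogonal-distance fit
#'
#' Data points with the fitted risk curve overlaid.
#'
#' @param object An `"odr_fit"`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odr_fit
#' @export
autoplot.odr_fit <- function(object, n_curve = 200L, ...) {
  d <- object$data
  tt <- seq(min(d$age), max(d$age), length.out = n_curve)
  curve <- tibble::tibble(age = tt, rate = risk(object$params, tt))
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$rate)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = curve, colour = "#4040a0") +
    ggplot2::labs(
      x = "age (years)", y = "incidence rate",
      title = sprintf("%s fit to %s (RMS = %.3g)", object$model,
                      object$label, object$RMS)) +
    ggplot2::theme_minimal()
}
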