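#' Transform an incidence series by a symmetry
#'
#' Applies the point transformation to every datum. All implemented
#' symmetries are t-directional, so rates are unchanged and the age
#' order is preserved. Any point outside the symmetry's validity domain
#' raises an error naming the limiting datum and the maximal feasible
#' \eqn{\epsilon} (no silent clipping, which would corrupt RMS
#' profiles).
#'
#' @param data A data frame with columns `age` and `rate`.
#' @param sym A [symmetry()] or its id.
#' @param params Model parameters supplying \eqn{(\alpha, \tau)} where
#'   needed.
#' @param eps Transformation parameter.
#' @return A tibble with transformed `age` and unchanged `rate`.
#' @export
transform_data <- function(data, sym, params, eps) {
  .check_series(data, allow_zero = TRUE)
  tp <- transform_point(sym, params, eps, data$age, data$rate)
  out <- tibble::tibble(age = tp$t, rate = tp$R)
  attr(out, "label") <- attr(data, "label")
  out
}

#' Default transformation-parameter grid for a profile
#'
#' The power-law scaling symmetry is profiled on
#' \eqn{[0, 2\log 2]} (twice the age-doubling scale); the
#' parameter-dependent symmetries on \eqn{[0, \epsilon_{scale}]} where
#' \eqn{\epsilon_{scale}} doubles the maximum observed age. 20 evenly
#' spaced points including both endpoints by default.
#'
#' @inheritParams transform_data
#' @param t_max Maximum age of the dataset (years).
#' @param n_points Number of grid points (>= 2).
#' @return Numeric vector starting at 0.
#' @export
default_epsilon_grid <- function(sym, params, t_max, n_points = 20L) {
  sym <- .as_symmetry(sym)
  stopifnot(n_points >= 2L)
  end <- if (sym$id == "plm-scaling") {
    2 * log(2)
  } else {
    transformation_scale(sym, params, n = 2, t = t_max)
  }
  seq(0, end, length.out = n_points)
}

.own_symmetry <- function(model) {
  switch(model,
         plm = "plm-scaling",
         im = "im",
         im2 = "im2",
         im1 = "im1-translation",
         stop("unknown model id: ", model, call. = FALSE))
}

#' RMS(\eqn{\epsilon}) profile of a model under its symmetry
#'
#' Runs the four-step selection loop over a grid of transformation
#' parameters: (1) transform the data by the candidate's symmetry at
#' \eqn{\epsilon}; (2) refit only the symmetry-moved parameter to the
#' transformed data ([fit_restricted()], starting from the baseline
#' optimum); (3) transform the fitted curve back via the parameter
#' action at \eqn{-\epsilon}; (4) score the inversely transformed curve
#' against the *original* data by orthogonal-distance RMS. If the
#' symmetry is manifest in the data the profile stays at its
#' \eqn{\epsilon = 0} level; otherwise transformation introduces
#' systematic errors and the profile rises.
#'
#' The baseline full fit is computed once and reused for every
#' \eqn{\epsilon}; the grid point at \eqn{\epsilon = 0} reports the
#' baseline RMS itself. Per-\eqn{\epsilon} domain violations truncate
#' the profile with a warning rather than aborting it.
#'
#' @param data A filtered data frame with columns `age` and `rate`.
#' @param model Candidate model id (`"plm"`, `"im"`, `"im2"`, `"im1"`).
#' @param sym Symmetry to profile with; defaults to the model's own.
#' @param baseline Optional precomputed [fit_full()] result.
#' @param eps_grid Optional explicit grid (must start at 0).
#' @param n_points Grid resolution when `eps_grid` is `NULL`.
#' @param alpha Immune decline rate for immunological fits.
#' @return A `"symmetry_profile"` object: a list with the per-
#'   \eqn{\epsilon} tibble `profile` (columns `eps`, `RMS`, `par`,
#'   `converged`), the `baseline` fit, and ids.
#' @examples
#' d <- generate_series(plm_params(5.78e-7, 4.6), ages = 12:85,
#'                      sigma_R = 0, sigma_t = 0)
#' pr <- symmetry_profile(d, "plm", n_points = 5)
#' tidy(pr)
#' @export
symmetry_profile <- function(data, model = c("plm", "im", "im2", "im1"),
                             sym = NULL, baseline = NULL, eps_grid = NULL,
                             n_points = 20L, alpha = 0.044) {
  model <- match.arg(model)
  .check_series(data)
  sym <- .as_symmetry(sym %||% .own_symmetry(model))
  if (is.null(baseline)) baseline <- fit_full(data, model, alpha = alpha)
  if (is.null(eps_grid)) {
    eps_grid <- default_epsilon_grid(sym, baseline$params, max(data$age),
                                     n_points)
  }
  if (abs(eps_grid[1L]) > 1e-15) {
    stop("the epsilon grid must start at 0", call. = FALSE)
  }
  free_par <- if (model == "plm") "A" else "C"
  rows <- vector("list", length(eps_grid))
  for (j in seq_along(eps_grid)) {
    eps <- eps_grid[j]
    if (eps == 0) {
      rows[[j]] <- tibble::tibble(
        eps = 0, RMS = baseline$RMS,
        par = baseline$params[[free_par]],
        converged = baseline$converged)
      next
    }
    step <- try({
      td <- transform_data(data, sym, baseline$params, eps)
      fr <- fit_restricted(td, baseline, eps)
      sc <- odr_rms(data, fr$params, sym = sym, eps = eps)
      tibble::tibble(eps = eps, RMS = sc$RMS,
                     par = fr$params[[free_par]],
                     converged = fr$converged && !sc$flagged)
    }, silent = TRUE)
    if (inherits(step, "try-error")) {
      warning("profile truncated at eps = ", signif(eps, 4), ": ",
              attr(step, "condition")$message, call. = FALSE)
      rows[[j]] <- tibble::tibble(eps = eps, RMS = NA_real_,
                                  par = NA_real_, converged = FALSE)
    } else {
      rows[[j]] <- step
    }
  }
  structure(
    list(model = model, symmetry = sym$id, label = .series_label(data),
         profile = dplyr::bind_rows(rows), baseline = baseline),
    class = "symmetry_profile")
}

#' @export
print.symmetry_profile <- function(x, ...) {
  cat("<symmetry_profile: ", x$model, " / ", x$symmetry, " on '",
      x$label, "'>\n", sep = "")
  cat("  RMS(0) = ", signif(x$baseline$RMS, 4), ", max RMS = ",
      signif(max(x$profile$RMS, na.rm = TRUE), 4), " over ",
      nrow(x$profile), " grid points\n", sep = "")
  invisible(x)
}

#' @rdname symmetry_profile
#' @param x A `"symmetry_profile"`.
#' @param ... Unused.
#' @method tidy symmetry_profile
#' @export
tidy.symmetry_profile <- function(x, ...) {
  dplyr::mutate(x$profile, model = x$model, symmetry = x$symmetry,
                label = x$label)
}

#' @rdname symmetry_profile
#' @method glance symmetry_profile
#' @export
glance.symmetry_profile <- function(x, ...) {
  tibble::tibble(model = x$model, symmetry = x$symmetry,
                 label = x$label, rms0 = x$baseline$RMS,
                 rms_max = max(x$profile$RMS, na.rm = TRUE),
                 n_eps = nrow(x$profile),
                 n_failed = sum(!x$profile$converged))
}

#' Plot an RMS profile
#'
#' RMS(\eqn{\epsilon}) against the transformation parameter, with the
#' baseline RMS(0) as a dashed reference line: a flat profile indicates
#' the symmetry (and hence the model's mechanism) is manifest in the
#' data; a rising one indicates distortion.
#'
#' @param object A `"symmetry_profile"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot symmetry_profile
#' @export
autoplot.symmetry_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$eps, .data$RMS)) +
    ggplot2::geom_hline(yintercept = object$baseline$RMS,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "#4040a0") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(
      x = expression(epsilon), y = expression(RMS(epsilon)),
      title = sprintf("%s under %s on %s", object$model,
                      object$symmetry, object$label)) +
    ggplot2::theme_minimal()
}

#' Compare RMS profiles of several candidates in one figure
#'
#' @param profiles A list of `"symmetry_profile"` objects.
#' @return A ggplot object with one panel per profile.
#' @export
plot_profiles <- function(profiles) {
  if (inherits(profiles, "symmetry_profile")) profiles <- list(profiles)
  df <- dplyr::bind_rows(lapply(profiles, tidy))
  ggplot2::ggplot(df, ggplot2::aes(.data$eps, .data$RMS)) +
    ggplot2::geom_line(colour = "#4040a0") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ model + label, scales = "free") +
    ggplot2::labs(x = expression(epsilon), y = expression(RMS(epsilon))) +
    ggplot2::theme_minimal()
}

#' Symmetry-based model selection verdicts
#'
#' A candidate is selected ("invariant") when its fit to transformed
#' data, scored against the original data, stays at the baseline level
#' across the whole transformation grid:
#' \eqn{\max_\epsilon RMS(\epsilon) \le (1 + tol) \cdot
#' \max(RMS(0), floor)}. Otherwise it is "distorted"; a candidate whose
#' baseline fit failed is "no-fit". When every candidate is distorted
#' the result carries the attribute `all_rejected = TRUE` — valuable
#' negative information indicating that none of the candidate
#' mechanisms underlies the data.
#'
#' The invariance threshold is a package choice (the criterion itself is
#' qualitative): `tol` allows the mild wiggle a manifest symmetry shows
#' on noisy data, and `floor` keeps near-zero baselines (noiseless data)
#' from turning numerical jitter into a rejection. Always inspect the
#' raw profiles alongside the verdicts.
#'
#' @param profiles A `"symmetry_profile"` or list of them (one per
#'   candidate model).
#' @param tol Relative invariance tolerance.
#' @param floor Absolute RMS floor.
#' @return A tibble with one row per candidate: `model`, `symmetry`,
#'   `label`, `rms0`, `rms_max`, `verdict`; attribute `all_rejected`.
#' @export
select_model <- function(profiles, tol = 0.25, floor = 0.05) {
  if (inherits(profiles, "symmetry_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    g <- glance(p)
    verdict <- if (!p$baseline$converged) {
      "no-fit"
    } else if (g$rms_max <= (1 + tol) * max(g$rms0, floor)) {
      "invariant"
    } else {
      "distorted"
    }
    dplyr::mutate(g[c("model", "symmetry", "label", "rms0", "rms_max")],
                  verdict = verdict)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "all_rejected") <- all(out$verdict != "invariant")
  out
}
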