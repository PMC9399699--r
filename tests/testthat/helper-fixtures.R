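# shared fixtures: parameter sets, noiseless series, small oracles

ref_plm <- function(dataset = "colon") cancer_params(dataset, "plm")
ref_im <- function(dataset = "myeloma") cancer_params(dataset, "im")

noiseless_series <- function(params, ages = 25:85) {
  generate_series(params, ages = ages, sigma_R = 0, sigma_t = 0)
}

# all four (symmetry id, params) pairs on generic in-range settings
sym_cases <- function() {
  list(
    list(sym = "plm-scaling", params = plm_params(5.78e-7, 4.60),
         t = c(20, 45, 70, 85)),
    list(sym = "im", params = im_params(222.32, 64.10, 0.94),
         t = c(20, 45, 70, 85)),
    list(sym = "im2", params = im_params(150, 70, variant = "im2"),
         t = c(20, 45, 70, 85)),
    list(sym = "im1-translation",
         params = im_params(0.5, alpha = 0.044, variant = "im1"),
         t = c(20, 45, 70, 85)))
}

# admissible eps magnitude for group-law sampling per symmetry
sym_eps_cap <- function(case) {
  if (case$sym == "im") {
    # keep eps + delta within the validity bound at the largest age
    p <- case$params
    tmax <- max(case$t)
    0.3 * expm1(exp(-p$alpha * (tmax - p$tau))) /
      (p$alpha * exp(p$alpha * p$tau))
  } else {
    0.5
  }
}

# Monte-Carlo absorption frequency of a birth-death walk from 1 cell
mc_absorption <- function(b, d, K, n_walks, seed = 1) {
  withr::with_seed(seed, {
    state <- rep(1L, n_walks)
    p_birth <- b / (b + d)
    active <- rep(TRUE, n_walks)
    while (any(active)) {
      n <- sum(active)
      up <- stats::runif(n) < p_birth
      state[active] <- state[active] + ifelse(up, 1L, -1L)
      active <- state > 0L & state < K
    }
    mean(state >= K)
  })
}

# dense grid-search oracle for the foot-point projection
grid_project <- function(params, t_obs, R_obs, lower, upper,
                         step = 1e-5) {
  tt <- seq(lower, upper, by = step)
  dist2 <- (t_obs - tt)^2 + (R_obs - risk(params, tt))^2
  tt[which.min(dist2)]
}
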