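#' Network model parameters
#'
#' Builds and validates the full parameter set of the multi-module attractor
#' network. Each of the `n_modules` modules is a reduced two-variable
#' winner-take-all circuit: two option-selective populations whose NMDA gating
#' variables integrate input through an effective f-I transfer curve, coupled
#' by recurrent excitation (`w_same`) and lateral inhibition (`w_diff`).
#' Modules share the sensory input but receive independent Ornstein-Uhlenbeck
#' background-noise currents; the coupling fraction `ic` interpolates between
#' fully independent modules (0) and a uniform all-to-all network (1).
#'
#' Defaults for the synaptic and f-I constants are the standard reduced
#' two-variable attractor-model values; the vote threshold is 15 Hz with a
#' 5 Hz counting window above it, and the background noise has a 10 ms
#' correlation time.
#'
#' @param n_modules Number of modules N (>= 1).
#' @param ic Inter-module coupling fraction in \[0, 1\].
#' @param tau_nmda NMDA channel closure time constant (s).
#' @param gamma NMDA opening-rate constant (dimensionless).
#' @param w_same Intra-pair recurrent excitatory weight (nA), >= 0.
#' @param w_diff Cross-population inhibitory weight (nA), <= 0.
#' @param fi_a f-I gain (Hz/nA).
#' @param fi_b f-I threshold (Hz).
#' @param fi_d f-I curvature (s).
#' @param i0 Constant background current (nA).
#' @param ou_tau Background-noise correlation time (s).
#' @param ou_var Background-noise stationary variance (nA^2).
#' @param lambda_thr Vote threshold on the firing rate (Hz).
#' @param delta_lambda Width of the counting window above the threshold (Hz).
#' @param dt Euler-Maruyama integration step (s).
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params(n_modules = 10, ic = 0.5)
#' transfer_rate(0.5, p)
#' @export
model_params <- function(n_modules = 100L, ic = 0, tau_nmda = 0.100,
                         gamma = 0.641, w_same = 0.2609, w_diff = -0.0497,
                         fi_a = 270, fi_b = 108, fi_d = 0.154, i0 = 0.3255,
                         ou_tau = 0.010, ou_var = 0.02^2, lambda_thr = 15,
                         delta_lambda = 5, dt = 5e-4) {
  p <- list(
    n_modules = as.integer(n_modules), ic = ic, tau_nmda = tau_nmda,
    gamma = gamma, w_same = w_same, w_diff = w_diff, fi_a = fi_a,
    fi_b = fi_b, fi_d = fi_d, i0 = i0, ou_tau = ou_tau, ou_var = ou_var,
    lambda_thr = lambda_thr, delta_lambda = delta_lambda, dt = dt
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  stopifnot(
    "n_modules must be >= 1" = p$n_modules >= 1L,
    "ic must lie in [0, 1]" = is.finite(p$ic) && p$ic >= 0 && p$ic <= 1,
    "tau_nmda must be > 0" = p$tau_nmda > 0,
    "ou_tau must be > 0" = p$ou_tau > 0,
    "dt must be > 0" = p$dt > 0,
    "ou_var must be >= 0" = p$ou_var >= 0,
    "delta_lambda must be > 0" = p$delta_lambda > 0,
    "w_same must be >= 0" = p$w_same >= 0,
    "w_diff must be <= 0" = p$w_diff <= 0,
    "gamma must be > 0" = p$gamma > 0
  )
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all model parameters must be numeric")
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1)))) {
    stop("all model parameters must be finite")
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$n_modules, "modules, IC =", x$ic, "\n")
  cat("  vote threshold", x$lambda_thr, "Hz (+", x$delta_lambda, "Hz window),",
      "dt =", x$dt * 1e3, "ms\n")
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of a `model_params` object with the named fields replaced
#' and the invariants re-checked.
#'
#' @param params A `model_params` object.
#' @param ... Named fields to replace, e.g. `ic = 0.5`.
#' @return A `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  params$n_modules <- as.integer(params$n_modules)
  validate_model_params(params)
  structure(params, class = "model_params")
}

#' Luminance-to-current transform
#'
#' The sensory stage maps patch luminance L (cd/m^2) linearly onto synaptic
#' input current, I = g (L + b). The gain `g` and bias `b` are the two
#' behavioral parameters recovered in the first fitting stage.
#'
#' @param g Input gain (nA m^2/cd).
#' @param b Input bias (cd/m^2).
#' @return An object of class `luminance_transform`.
#' @export
luminance_transform <- function(g = 3e-3, b = -30) {
  stopifnot(is.finite(g), is.finite(b))
  structure(list(g = g, b = b), class = "luminance_transform")
}

#' Sigmoid confidence map
#'
#' Binary (high/low) confidence reports are sampled from a sigmoid probability
#' of the trial's dispersion estimate x: with `input_kind = "fmc"` (fraction of
#' modules counted just above the vote threshold, larger means tighter
#' dispersion) the probability of a high report is
#' `1 / (1 + exp(-(x - center_c) / slope_a))`; with `input_kind = "sigma_dv"`
#' the sign is flipped so that larger dispersion means lower confidence.
#'
#' @param slope_a Sigmoid scale, same units as the input statistic; non-zero.
#' @param center_c Sigmoid midpoint, same units as the input statistic.
#' @param input_kind Which statistic feeds the sigmoid, `"fmc"` or
#'   `"sigma_dv"`.
#' @return An object of class `confidence_map`.
#' @export
confidence_map <- function(slope_a = 0.03, center_c = 0.24,
                           input_kind = c("fmc", "sigma_dv")) {
  input_kind <- match.arg(input_kind)
  stopifnot("slope_a must be non-zero" = is.finite(slope_a) && slope_a != 0,
            is.finite(center_c))
  structure(list(slope_a = slope_a, center_c = center_c,
                 input_kind = input_kind),
            class = "confidence_map")
}

#' Probability of a high-confidence report
#'
#' @param x Dispersion estimate(s), in the units of `map$input_kind`.
#' @param map A [confidence_map()].
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
confidence_prob <- function(x, map) {
  stopifnot(inherits(map, "confidence_map"))
  z <- (x - map$center_c) / map$slope_a
  if (map$input_kind == "sigma_dv") z <- -z
  stats::plogis(z)
}
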