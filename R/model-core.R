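#' Effective f-I transfer function
#'
#' Maps total synaptic current onto a population firing rate through the
#' effective input-output relation of the reduced attractor model,
#' `phi(I) = (aI - b) / (1 - exp(-d (aI - b)))`. The removable singularity at
#' `aI = b` is evaluated by its series limit `1/d`, keeping the curve
#' continuous and monotone.
#'
#' @param i_syn Synaptic current (nA); vectorized.
#' @param params A [model_params()] object supplying `fi_a`, `fi_b`, `fi_d`.
#' @return Firing rate(s) in Hz, non-negative.
#' @examples
#' p <- model_params()
#' transfer_rate(p$fi_b / p$fi_a, p)  # exactly 1 / fi_d
#' @export
transfer_rate <- function(i_syn, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(i_syn))) stop("non-finite synaptic current")
  x <- params$fi_a * i_syn - params$fi_b
  u <- params$fi_d * x
  out <- numeric(length(x))
  small <- abs(u) < 1e-4
  out[small] <- (1 + u[small] / 2 + u[small]^2 / 12) / params$fi_d
  big <- !small & u < -700
  out[big] <- 0
  rest <- !small & !big
  out[rest] <- x[rest] / (1 - exp(-u[rest]))
  out
}

#' Inter-module coupling tensor
#'
#' Synaptic weight from population j of module l onto population i of module
#' k: `W[k, i, l, j] = w_ij * ((1 - IC) * delta_kl + IC / N)`, where `w_ij` is
#' `w_same` for i = j and `w_diff` otherwise. The IC/N normalization conserves
#' the total recurrent drive `sum_l W[k, i, l, j] = w_ij` for every coupling
#' fraction, which is what leaves first-order behavior (accuracy, RT)
#' unchanged as modules are interconnected.
#'
#' @param params A [model_params()] object.
#' @return A numeric array of dimension `(N, 2, N, 2)`, in nA.
#' @export
build_coupling <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n <- params$n_modules
  w <- matrix(c(params$w_same, params$w_diff, params$w_diff, params$w_same), 2)
  W <- array(0, dim = c(n, 2, n, 2))
  mix <- diag(n) * (1 - params$ic) + params$ic / n
  for (i in 1:2) {
    for (j in 1:2) {
      W[, i, , j] <- w[i, j] * mix
    }
  }
  W
}

#' One Ornstein-Uhlenbeck noise update
#'
#' Advances the background-noise current by `dt` using the exact
#' discretization of the O-U process with correlation time `ou_tau` and
#' stationary variance `ou_var`:
#' `eta' = eta * exp(-dt/tau) + sqrt(ou_var * (1 - exp(-2 dt/tau))) * xi`.
#' Draws come from R's RNG, so `set.seed()` makes the update reproducible.
#'
#' @param eta Current noise value(s) (nA); any shape.
#' @param params A [model_params()] object.
#' @param dt Time step (s); defaults to `params$dt`.
#' @return Updated noise current(s), same shape as `eta`.
#' @export
ou_step <- function(eta, params, dt = params$dt) {
  stopifnot(inherits(params, "model_params"), dt > 0)
  decay <- exp(-dt / params$ou_tau)
  sd <- sqrt(params$ou_var * (1 - decay^2))
  eta * decay + sd * stats::rnorm(length(eta))
}

#' Initial network state
#'
#' All gating variables, rates and noise currents start at zero; the
#' pre-stimulus epoch lets the network settle into its spontaneous state
#' under background input alone.
#'
#' @param params A [model_params()] object.
#' @return An object of class `network_state` with fields `s`, `r`, `eta`
#'   (each an `N x 2` matrix, columns = options A, B) and elapsed time `t`.
#' @export
network_state <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n <- params$n_modules
  z <- matrix(0, n, 2, dimnames = list(NULL, c("A", "B")))
  structure(list(s = z, r = z, eta = z, t = 0), class = "network_state")
}

#' One Euler-Maruyama network step (reference implementation)
#'
#' Advances the full network by one step `dt`: the noise is updated first
#' (exact O-U discretization), then currents and rates are recomputed, and
#' finally the gating variables are advanced and clamped to \[0, 1\]. This is
#' the plain-R reference used for testing; batch simulation goes through the
#' compiled integrator, which implements the identical scheme.
#'
#' @param state A `network_state`.
#' @param i_ext External current, `N x 2` matrix or length-2 vector (nA).
#' @param params A [model_params()] object.
#' @return The advanced `network_state`.
#' @export
step_network <- function(state, i_ext, params) {
  stopifnot(inherits(state, "network_state"), inherits(params, "model_params"))
  n <- params$n_modules
  if (is.null(dim(i_ext))) i_ext <- matrix(i_ext, n, 2, byrow = TRUE)
  eta <- ou_step(state$eta, params)
  sbar <- colMeans(state$s)
  mix <- (1 - params$ic) * state$s +
    params$ic * matrix(sbar, n, 2, byrow = TRUE)
  i_rec <- cbind(params$w_same * mix[, 1] + params$w_diff * mix[, 2],
                 params$w_same * mix[, 2] + params$w_diff * mix[, 1])
  i_tot <- i_rec + params$i0 + i_ext + eta
  r <- matrix(transfer_rate(as.vector(i_tot), params), n, 2)
  if (any(!is.finite(r))) {
    stop("non-finite firing rate in module ",
         which(!is.finite(rowSums(r)))[1])
  }
  s <- state$s + params$dt *
    (-state$s / params$tau_nmda + params$gamma * (1 - state$s) * r)
  s <- pmin(pmax(s, 0), 1)
  dimnames(s) <- dimnames(r) <- dimnames(state$s)
  structure(list(s = s, r = r, eta = eta, t = state$t + params$dt),
            class = "network_state")
}
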