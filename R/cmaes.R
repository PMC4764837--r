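#' Covariance matrix adaptation evolution strategy
#'
#' A compact (mu/mu_w, lambda)-CMA-ES minimizer with cumulative step-size
#' adaptation and rank-one plus rank-mu covariance updates, for the small
#' (2-parameter) noisy objectives of the behavioral fits. Box constraints
#' are enforced by repairing candidates onto the box before evaluation.
#'
#' @param fn Objective function of a numeric vector, returning a scalar.
#' @param x0 Start point (defaults to the box midpoint).
#' @param sigma0 Initial step size (defaults to 30% of the box width).
#' @param lower,upper Box constraints (numeric vectors).
#' @param popsize Offspring per generation (lambda); default
#'   `4 + floor(3 log n)`.
#' @param max_iter Generations to run.
#' @param tol_sigma Stop early once the step size falls below this fraction
#'   of `sigma0`.
#' @return An object of class `cma_fit`: `par`, `value`, the evaluation
#'   `trace` (tibble: `iter`, `eval`, `value`, one column per parameter) and
#'   counters. Use [tidy()] / [glance()] for summaries.
#' @examples
#' fit <- cma_es(function(x) sum(x^2), lower = c(-5, -5), upper = c(5, 5),
#'               max_iter = 60)
#' fit$par
#' @export
cma_es <- function(fn, x0 = NULL, sigma0 = NULL, lower, upper,
                   popsize = NULL, max_iter = 100, tol_sigma = 1e-8) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(upper > lower))
  if (is.null(x0)) x0 <- (lower + upper) / 2
  if (is.null(sigma0)) sigma0 <- 0.3 * max(upper - lower)
  f0 <- fn(pmin(pmax(x0, lower), upper))
  if (!is.finite(f0)) stop("objective is not finite at the start point")

  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  best_par <- x0
  best_val <- f0
  n_eval <- 1L
  trace <- vector("list", max_iter)

  for (iter in seq_len(max_iter)) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    Xr <- pmin(pmax(X, lower), upper)
    vals <- apply(Xr, 2, fn)
    n_eval <- n_eval + lambda
    ord <- order(vals)
    if (vals[ord[1]] < best_val) {
      best_val <- vals[ord[1]]
      best_par <- Xr[, ord[1]]
    }
    pars <- stats::setNames(as.data.frame(t(Xr)), paste0("x", seq_len(n)))
    trace[[iter]] <- dplyr::bind_cols(
      tibble::tibble(iter = iter,
                     eval = n_eval - lambda + seq_len(lambda) - 1L,
                     value = vals),
      pars)

    sel <- ord[seq_len(mu)]
    y_w <- drop((Y[, sel, drop = FALSE] %*% w))
    xmean <- xmean + sigma * y_w
    c_inv_half <- B %*% ((1 / D) * t(B))
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mu_eff) * drop(c_inv_half %*% y_w)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * iter)) / chi_n < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * y_w
    Ys <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ys %*% (w * t(Ys))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))
    if (sigma < tol_sigma * sigma0) break
  }

  trace <- dplyr::bind_rows(trace)
  structure(list(par = best_par, value = best_val, trace = trace,
                 n_eval = n_eval, n_iter = max(trace$iter), sigma = sigma),
            class = "cma_fit")
}

#' @export
print.cma_fit <- function(x, ...) {
  cat("<cma_fit> best value", signif(x$value, 6), "after", x$n_eval,
      "evaluations\n  par:", signif(x$par, 6), "\n")
  invisible(x)
}

#' @rdname cma_es
#' @param x A `cma_fit`.
#' @param ... Unused.
#' @export
tidy.cma_fit <- function(x, ...) {
  tibble::tibble(term = paste0("x", seq_along(x$par)), estimate = x$par)
}

#' @rdname cma_es
#' @export
glance.cma_fit <- function(x, ...) {
  tibble::tibble(value = x$value, n_eval = x$n_eval, n_iter = x$n_iter,
                 sigma_final = x$sigma)
}

#' Run one fitting stage with CMA-ES
#'
#' Thin driver around [cma_es()]: checks that the objective is finite at the
#' box midpoint and returns the optimizer result with its evaluation trace.
#' For noisy simulation objectives pass an `objective` that fixes its own
#' seed (common random numbers), which makes the merit a deterministic
#' function of the parameters.
#'
#' @param objective Function of a parameter vector returning a scalar merit.
#' @param lower,upper Box bounds.
#' @param ... Passed to [cma_es()] (`popsize`, `max_iter`, ...).
#' @return A `cma_fit`.
#' @export
fit_stage <- function(objective, lower, upper, ...) {
  cma_es(objective, lower = lower, upper = upper, ...)
}

#' Two-stage behavioral fit
#'
#' Stage 1 recovers the luminance transform (g, b) by minimizing the
#' decision-kernel plus performance merit ([decision_merit()]); stage 2
#' freezes (g, b), simulates a pool of trials once, and recovers the
#' confidence sigmoid (a, c) by minimizing the 4-way Pearson statistic
#' ([confidence_merit()]). Both stages use common random numbers.
#'
#' @param target A `behavioral_dataset` (the subject to fit).
#' @param params A [model_params()] object.
#' @param cfg A [merit_config()].
#' @param lower,upper Bounds on `c(g, b)` for stage 1.
#' @param seed Base seed for the whole fit.
#' @param popsize,max_iter CMA-ES settings.
#' @param refine Settings for an optional second, zoomed-in CMA-ES pass, as
#'   a list with `n_sim` (larger simulation count per evaluation), `span`
#'   (half-width of the shrunken box around the first-pass optimum, as a
#'   fraction of the original box width, default 0.15), `popsize` and
#'   `max_iter`. The merit surface is shallow along the near-equivalence
#'   manifold `g (L + b) ~ const`, so the coarse pass localizes cheaply and
#'   the refinement pass buys the merit precision that separates manifold
#'   points. `NULL` skips refinement.
#' @return A list of class `consensus_fit` with elements `transform` (the
#'   fitted [luminance_transform()]), `cma` (the last-pass `cma_fit`) and
#'   the merit components at the optimum.
#' @export
fit_decision_stage <- function(target, params, cfg,
                               lower = c(2e-4, -150), upper = c(8e-3, 150),
                               seed = 1L, popsize = 6L, max_iter = 20L,
                               refine = NULL) {
  ts <- target_summary(target)
  crn_seed <- seed + 1000L
  make_obj <- function(cfg_i) {
    function(x) {
      as.numeric(decision_merit(x[1], x[2], target, cfg_i, params,
                                seed = crn_seed, target_stats = ts))
    }
  }
  set.seed(seed)
  cma <- fit_stage(make_obj(cfg), lower = lower, upper = upper,
                   popsize = popsize, max_iter = max_iter)
  if (!is.null(refine)) {
    span <- (refine$span %||% 0.15) * (upper - lower)
    lo2 <- pmax(lower, cma$par - span)
    hi2 <- pmin(upper, cma$par + span)
    cfg2 <- cfg
    cfg2$n_sim <- as.integer(refine$n_sim %||% (4L * cfg$n_sim))
    set.seed(seed + 1L)
    cma <- fit_stage(make_obj(cfg2), lower = lo2, upper = hi2,
                     x0 = cma$par, popsize = refine$popsize %||% 4L,
                     max_iter = refine$max_iter %||% 6L)
    cfg <- cfg2
  }
  best <- decision_merit(cma$par[1], cma$par[2], target, cfg, params,
                         seed = crn_seed, target_stats = ts)
  structure(list(stage = "decision",
                 transform = luminance_transform(g = cma$par[1],
                                                 b = cma$par[2]),
                 cma = cma, merit = as.numeric(best),
                 components = attr(best, "components")),
            class = "consensus_fit")
}

#' @rdname fit_decision_stage
#' @param transform The stage-1 fitted [luminance_transform()].
#' @param n_pool Model trials simulated once for the confidence pool.
#' @param input_kind Statistic feeding the sigmoid, `"fmc"` or `"sigma_dv"`.
#' @param lower2,upper2 Bounds on `c(a, c)`.
#' @return For `fit_confidence_stage()`: a `consensus_fit` with `conf_map`
#'   (the fitted [confidence_map()]), the `cma_fit`, and the simulated pool.
#' @export
fit_confidence_stage <- function(target, params, cfg, transform,
                                 n_pool = 2000L, input_kind = "fmc",
                                 lower2 = c(0.005, 0.02),
                                 upper2 = c(0.3, 0.8),
                                 seed = 1L, popsize = 6L, max_iter = 25L) {
  tc <- confidence_table(target$trials)
  set.seed(seed + 2000L)
  mt <- sample(target$trials$mean_target[!is.na(target$trials$choice)],
               n_pool, replace = TRUE)
  pool <- simulate_trials(params, transform, n_pool, mean_target = mt,
                          frame_sd = cfg$frame_sd, frame_ms = cfg$frame_ms,
                          duration = cfg$deadline, n_bars = 1L,
                          onset = cfg$wait, target_patch = "A")
  pool <- pool[!pool$undecided, ]
  crn_seed <- seed + 3000L
  obj <- function(x) {
    as.numeric(confidence_merit(x[1], x[2], target, pool,
                                input_kind = input_kind, seed = crn_seed,
                                target_counts = tc))
  }
  set.seed(seed)
  cma <- fit_stage(obj, lower = lower2, upper = upper2, popsize = popsize,
                   max_iter = max_iter)
  structure(list(stage = "confidence",
                 conf_map = confidence_map(slope_a = cma$par[1],
                                           center_c = cma$par[2],
                                           input_kind = input_kind),
                 cma = cma, merit = cma$value, pool = pool),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat("<consensus_fit> stage:", x$stage, "| merit", signif(x$merit, 5), "\n")
  if (x$stage == "decision") {
    cat("  g =", signif(x$transform$g, 5), "nA m2/cd, b =",
        signif(x$transform$b, 5), "cd/m2\n")
  } else {
    cat("  a =", signif(x$conf_map$slope_a, 5), ", c =",
        signif(x$conf_map$center_c, 5), "(", x$conf_map$input_kind, ")\n")
  }
  invisible(x)
}

#' @rdname fit_decision_stage
#' @param x A `consensus_fit`.
#' @param ... Unused.
#' @export
tidy.consensus_fit <- function(x, ...) {
  if (x$stage == "decision") {
    tibble::tibble(term = c("g", "b"),
                   estimate = c(x$transform$g, x$transform$b))
  } else {
    tibble::tibble(term = c("slope_a", "center_c"),
                   estimate = c(x$conf_map$slope_a, x$conf_map$center_c))
  }
}

#' @rdname fit_decision_stage
#' @export
glance.consensus_fit <- function(x, ...) {
  tibble::tibble(stage = x$stage, merit = x$merit, n_eval = x$cma$n_eval,
                 n_iter = x$cma$n_iter)
}
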