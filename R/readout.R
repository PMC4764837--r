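#' Detect module votes from a rate trace
#'
#' A module commits irrevocably to the first option whose population rate
#' reaches the vote threshold; if both populations cross within the same
#' step the higher rate wins, with ties going to option A.
#'
#' @param trace A tidy rate trace: tibble with columns `time`, `module`,
#'   `option` (`"A"`/`"B"`) and `rate` (Hz), as returned by
#'   [simulate_trial()].
#' @param lambda_thr Vote threshold (Hz).
#' @return A tibble with one row per voting module: `module`, `option`,
#'   `vote_time`. Modules that never reach the threshold are absent.
#' @export
detect_votes <- function(trace, lambda_thr = 15) {
  stopifnot(nrow(trace) > 0,
            all(c("time", "module", "option", "rate") %in% names(trace)))
  wide <- tidyr::pivot_wider(trace, id_cols = c("time", "module"),
                             names_from = "option", values_from = "rate")
  wide <- dplyr::arrange(wide, .data$module, .data$time)
  first_cross <- function(g) {
    hit <- which(g$A >= lambda_thr | g$B >= lambda_thr)
    if (length(hit) == 0L) return(NULL)
    k <- hit[1]
    opt <- if (g$A[k] >= lambda_thr && g$B[k] >= lambda_thr) {
      if (g$A[k] >= g$B[k]) "A" else "B"
    } else if (g$A[k] >= lambda_thr) "A" else "B"
    tibble::tibble(module = g$module[1], option = opt, vote_time = g$time[k])
  }
  out <- dplyr::group_split(wide, .data$module)
  dplyr::bind_rows(purrr::map(out, first_cross))
}

#' Majority decision from module votes
#'
#' The network commits at the earliest time one option has accumulated a
#' strict majority (more than N/2) of votes.
#'
#' @param votes A tibble of votes (`option`, `vote_time`), e.g. from
#'   [detect_votes()].
#' @param n_modules Total number of modules N.
#' @return A one-row tibble with `choice` (`"A"`, `"B"`, or `NA` if no strict
#'   majority is ever reached) and `rt` (s, `NA` when undecided).
#' @export
global_decision <- function(votes, n_modules) {
  stopifnot(n_modules >= 1)
  if (nrow(votes) == 0L) {
    return(tibble::tibble(choice = NA_character_, rt = NA_real_))
  }
  v <- dplyr::arrange(votes, .data$vote_time)
  cum_a <- cumsum(v$option == "A")
  cum_b <- cumsum(v$option == "B")
  hit <- which(2 * cum_a > n_modules | 2 * cum_b > n_modules)
  if (length(hit) == 0L) {
    return(tibble::tibble(choice = NA_character_, rt = NA_real_))
  }
  k <- hit[1]
  tibble::tibble(choice = if (2 * cum_a[k] > n_modules) "A" else "B",
                 rt = v$vote_time[k])
}

#' Inter-module dispersion of the chosen option
#'
#' The latent confidence signal: the standard deviation, across modules, of
#' the chosen-option population rates sampled at the decision time
#' (population SD, i.e. divide-by-N). Low dispersion means the modules agree
#' and signals high confidence.
#'
#' @param rates `N x 2` matrix of firing rates at decision (columns A, B).
#' @param choice `"A"` or `"B"`.
#' @return Dispersion in Hz (0, with a warning, for a single module).
#' @export
sigma_dv <- function(rates, choice) {
  stopifnot(!is.na(choice), choice %in% c("A", "B"))
  x <- rates[, if (choice == "A") 1L else 2L]
  if (length(x) == 1L) {
    warning("sigma_dv of a single module is 0 by convention")
    return(0)
  }
  sqrt(mean((x - mean(x))^2))
}

#' Fraction of modules counted just above threshold
#'
#' Neural proxy of the inter-module dispersion: because the median
#' chosen-option rate sits at the vote threshold at decision time, the
#' fraction of modules whose chosen-option rate lies in the half-open window
#' `[lambda, lambda + delta_lambda)` counts a fixed percentile band and is
#' inversely related to the dispersion. High FMC signals high confidence.
#'
#' @param rates `N x 2` matrix of firing rates at decision (columns A, B).
#' @param choice `"A"` or `"B"`.
#' @param lambda_thr Vote threshold (Hz).
#' @param delta_lambda Window width (Hz).
#' @return Fraction in \[0, 1\].
#' @export
fmc <- function(rates, choice, lambda_thr = 15, delta_lambda = 5) {
  stopifnot(!is.na(choice), choice %in% c("A", "B"), delta_lambda > 0)
  x <- rates[, if (choice == "A") 1L else 2L]
  mean(x >= lambda_thr & x < lambda_thr + delta_lambda)
}

#' Sample binary confidence reports
#'
#' Draws `"high"`/`"low"` reports from the sigmoid probability of the
#' dispersion estimate (see [confidence_map()]). Uses R's RNG.
#'
#' @param x Dispersion estimate(s): FMC fractions or sigma_dv values,
#'   matching `map$input_kind`.
#' @param map A [confidence_map()].
#' @return Character vector of `"high"`/`"low"` (NA where `x` is NA).
#' @export
confidence_sample <- function(x, map) {
  p <- confidence_prob(x, map)
  out <- ifelse(stats::runif(length(x)) < p, "high", "low")
  out[is.na(x)] <- NA_character_
  out
}
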