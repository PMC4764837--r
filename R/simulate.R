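#' Simulate one trial with a dense rate trace
#'
#' Integrates the network from rest through the pre-stimulus epoch and the
#' stimulus, consulting the vote/majority readout every step, and returns
#' both the recorded trace and the trial summary. The network spends
#' `stim$onset` seconds with background input only before stimulus onset;
#' decisions taken before onset are flagged early.
#'
#' @param params A [model_params()] object.
#' @param stim A [generate_flicker()] stimulus.
#' @param transform A [luminance_transform()].
#' @param max_t Maximum simulated time (s); default runs to stimulus offset.
#' @param stop_rule `"majority"` (free response: stop at a strict majority)
#'   or `"offset"` (forced choice at stimulus offset from latched votes,
#'   ties to the higher mean rate).
#' @param record_stride Record every `record_stride`-th step in the trace.
#' @return A list of class `sim_trial` with `trace` (tibble: `time`,
#'   `module`, `option`, `rate`, `s`) and `result` (one-row tibble: `choice`,
#'   `rt`, `early`, `undecided`, `n_votes_a`, `n_votes_b`, `sigma_dv`, `fmc`,
#'   `median_chosen`), plus `rates_at_decision` (`N x 2`) and `votes`.
#' @examples
#' p <- model_params(n_modules = 10)
#' stim <- generate_flicker(mean_target = 60, duration = 2)
#' set.seed(1)
#' tr <- simulate_trial(p, stim, luminance_transform())
#' tr$result
#' @export
simulate_trial <- function(params, stim, transform,
                           max_t = stim$onset + stim$duration,
                           stop_rule = c("majority", "offset"),
                           record_stride = 2L) {
  stopifnot(inherits(params, "model_params"), inherits(stim, "stimulus"),
            max_t > stim$onset)
  stop_rule <- match.arg(stop_rule)
  cur <- stimulus_currents(stim, transform)
  seed <- floor(stats::runif(1) * 2^31)
  raw <- .sim_trials_cpp(unclass(params), list(cur), stim$frame_ms / 1000,
                         stim$onset, max_t, stop_rule, seed,
                         as.integer(record_stride))
  n <- params$n_modules
  n_rec <- length(raw$trace_times)
  trace <- tibble::tibble(
    time = rep(raw$trace_times, each = 2 * n),
    module = rep(rep(seq_len(n), each = 2), times = n_rec),
    option = rep(c("A", "B"), times = n * n_rec),
    rate = as.vector(raw$trace_rates),
    s = as.vector(raw$trace_s)
  )
  res <- summarize_raw(raw, params, stim$target_patch)
  votes <- tibble::tibble(
    module = seq_len(n),
    option = c(NA, "A", "B")[raw$vote_opt[1, ] + 1L],
    vote_time = raw$vote_time[1, ]
  )
  structure(list(trace = trace,
                 result = res,
                 rates_at_decision = cbind(A = raw$rates_a[1, ],
                                           B = raw$rates_b[1, ]),
                 votes = votes[!is.na(votes$option), ]),
            class = "sim_trial")
}

#' Simulate a batch of trials under one stimulus condition
#'
#' Generates `n_trials` independent flicker stimuli (optionally with a pulse),
#' integrates each through the compiled network core, and summarizes every
#' trial through the vote/majority readout. This is the workhorse behind the
#' experiment drivers and the fitting pipeline.
#'
#' @param params A [model_params()] object.
#' @param transform A [luminance_transform()].
#' @param n_trials Number of trials.
#' @param mean_target,mean_distractor,frame_sd,frame_ms,duration,n_bars,onset
#'   Stimulus settings, see [generate_flicker()]. `mean_target` may be a
#'   vector of length `n_trials` (per-trial target means).
#' @param target_patch `"A"`, `"B"`, or `"random"` (coin-flip per trial).
#' @param pulse Optional pulse, a list with `patch`, `amplitude`, `start`,
#'   `width` passed to [apply_pulse()].
#' @param stop_rule `"majority"` or `"offset"` (see [simulate_trial()]).
#' @param max_t Maximum simulated time (s).
#' @param conf_map Optional [confidence_map()]; when given, binary confidence
#'   reports are sampled per decided trial.
#' @param stimuli Optional list of pre-built `stimulus` objects (overrides
#'   generation; length `n_trials`).
#' @param keep_stimuli,keep_rates Keep the per-trial stimuli / decision-time
#'   rate matrices as attributes `"stimuli"` / `"rates"` of the result.
#' @return A tibble with one row per trial: `trial`, `choice`, `rt`, `early`,
#'   `undecided`, `correct`, `n_votes_a`, `n_votes_b`, `vote_time_chosen`
#'   (mean vote time of modules voting with the decision), `sigma_dv`, `fmc`,
#'   `median_chosen`, and `confidence` when `conf_map` is given.
#' @examples
#' p <- model_params(n_modules = 20)
#' set.seed(7)
#' res <- simulate_trials(p, luminance_transform(), n_trials = 5,
#'                        mean_target = 60, duration = 2)
#' mean(res$correct, na.rm = TRUE)
#' @export
simulate_trials <- function(params, transform, n_trials,
                            mean_target = 55, mean_distractor = 50,
                            frame_sd = 5, frame_ms = 40, duration = 3,
                            n_bars = 1L, onset = 0.2, target_patch = "A",
                            pulse = NULL, stop_rule = c("majority", "offset"),
                            max_t = onset + duration, conf_map = NULL,
                            stimuli = NULL, keep_stimuli = FALSE,
                            keep_rates = FALSE) {
  stopifnot(inherits(params, "model_params"), n_trials >= 1)
  stop_rule <- match.arg(stop_rule)
  if (is.null(stimuli)) {
    mt <- rep_len(mean_target, n_trials)
    tp <- if (identical(target_patch, "random")) {
      sample(c("A", "B"), n_trials, replace = TRUE)
    } else rep_len(target_patch, n_trials)
    stimuli <- purrr::map(seq_len(n_trials), function(i) {
      s <- generate_flicker(mean_target = mt[i],
                            mean_distractor = mean_distractor,
                            frame_sd = frame_sd, frame_ms = frame_ms,
                            duration = duration, n_bars = n_bars,
                            target_patch = tp[i], onset = onset)
      if (!is.null(pulse)) {
        s <- apply_pulse(s, pulse$patch, pulse$amplitude,
                         pulse$start %||% 0, pulse$width %||% 0.04)
      }
      s
    })
  } else {
    stopifnot(length(stimuli) == n_trials)
  }
  currents <- purrr::map(stimuli, stimulus_currents, transform = transform)
  seeds <- floor(stats::runif(n_trials) * 2^31)
  raw <- .sim_trials_cpp(unclass(params), currents,
                         stimuli[[1]]$frame_ms / 1000, stimuli[[1]]$onset,
                         max_t, stop_rule, seeds, 0L)
  tp_vec <- vapply(stimuli, function(s) s$target_patch, character(1))
  out <- summarize_raw(raw, params, tp_vec)
  out$trial <- seq_len(n_trials)
  out <- dplyr::relocate(out, "trial")
  if (!is.null(conf_map)) {
    x <- if (conf_map$input_kind == "fmc") out$fmc else out$sigma_dv
    out$confidence <- confidence_sample(x, conf_map)
  }
  if (keep_stimuli) attr(out, "stimuli") <- stimuli
  if (keep_rates) {
    attr(out, "rates") <- list(A = raw$rates_a, B = raw$rates_b)
  }
  out
}

# Vectorized trial summaries from the compiled core's raw output.
summarize_raw <- function(raw, params, target_patch) {
  n_tr <- length(raw$choice)
  n <- params$n_modules
  ch <- c(NA, "A", "B")[raw$choice + 1L]
  decided <- !is.na(ch)
  chosen <- raw$rates_a
  swap <- which(raw$choice == 2L)
  chosen[swap, ] <- raw$rates_b[swap, , drop = FALSE]
  mu <- rowMeans(chosen)
  sig <- sqrt(rowMeans((chosen - mu)^2))
  fm <- rowMeans(chosen >= params$lambda_thr &
                   chosen < params$lambda_thr + params$delta_lambda)
  med <- apply(chosen, 1, stats::median)
  sig[!decided] <- NA_real_
  fm[!decided] <- NA_real_
  med[!decided] <- NA_real_
  vmask <- raw$vote_opt == matrix(raw$choice, n_tr, n)
  vmask[!decided, ] <- FALSE
  n_ch_votes <- rowSums(vmask)
  vt <- raw$vote_time
  vt[!vmask | is.na(vt)] <- 0
  vtc <- ifelse(n_ch_votes > 0, rowSums(vt) / n_ch_votes, NA_real_)
  tibble::tibble(
    choice = ch,
    rt = raw$rt,
    early = as.logical(raw$early),
    undecided = !decided,
    correct = ifelse(decided, ch == rep_len(target_patch, n_tr), NA),
    n_votes_a = rowSums(raw$vote_opt == 1L),
    n_votes_b = rowSums(raw$vote_opt == 2L),
    vote_time_chosen = vtc,
    sigma_dv = sig,
    fmc = fm,
    median_chosen = med
  )
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("<sim_trial>\n")
  print(x$result)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
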