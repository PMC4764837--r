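# Shared fixtures: small networks and quick stimuli keep the unit tests fast;
# the acceptance suite uses the full 100-module defaults.

small_params <- function(...) {
  model_params(n_modules = 10L, ...)
}

default_transform <- function() luminance_transform()

quick_stim <- function(mean_target = 58, duration = 1.5, ...) {
  generate_flicker(mean_target = mean_target, duration = duration, ...)
}

# Minimal hand-built behavioral dataset: luminance array plus a trials
# tibble, bypassing the simulator so kernel logic can be tested against
# known inputs.
manual_dataset <- function(lum, choice, confidence, rt, mean_patch,
                           frame_ms = 40, onset = 0, deadline = NULL) {
  n <- length(choice)
  trials <- tibble::tibble(
    trial = seq_len(n), choice = choice, confidence = confidence, rt = rt,
    correct = choice == "A", early = FALSE, undecided = is.na(choice),
    mean_target = mean_patch[, 1]
  )
  consensusconf:::new_behavioral_dataset(
    trials, lum, mean_patch, frame_ms, onset,
    deadline %||% (dim(lum)[2] * frame_ms / 1000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
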