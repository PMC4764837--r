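#' Generate a flickering-luminance stimulus
#'
#' Two patches (A = target side by default, B = distractor) flicker: every
#' frame (40 ms by default) each patch's luminance is redrawn independently
#' from a Gaussian around its nominal mean and held constant until the next
#' frame. In the simulation-protocol mode each patch carries a single
#' luminance trace (`n_bars = 1`, frame SD 5 cd/m^2); in the behavioral mode
#' each patch is made of 4 bars drawn independently (frame SD 10 cd/m^2) and
#' the network integrates the patch mean while kernels are computed per bar.
#'
#' @param mean_target Nominal target-patch mean luminance (cd/m^2).
#' @param mean_distractor Nominal distractor mean luminance (cd/m^2).
#' @param frame_sd Per-frame, per-bar luminance SD (cd/m^2), >= 0.
#' @param frame_ms Frame duration (ms).
#' @param duration Maximum stimulus duration (s).
#' @param n_bars Bars per patch (1 = protocol mode, 4 = behavioral mode).
#' @param target_patch Which patch carries the target mean, `"A"` or `"B"`.
#' @param onset Stimulus onset time from trial start (s).
#' @return An object of class `stimulus`: luminance array `lum` of dimension
#'   `(frames, 2 patches, n_bars)` plus the generating settings.
#' @examples
#' stim <- generate_flicker(mean_target = 55, duration = 1)
#' dim(stim$lum)  # 25 frames x 2 patches x 1 bar
#' @export
generate_flicker <- function(mean_target = 55, mean_distractor = 50,
                             frame_sd = 5, frame_ms = 40, duration = 3,
                             n_bars = 1L, target_patch = "A", onset = 0.2) {
  if (frame_sd < 0) stop("frame_sd must be >= 0")
  stopifnot(duration > 0, frame_ms > 0, n_bars >= 1L,
            target_patch %in% c("A", "B"))
  n_frames <- as.integer(ceiling(duration / (frame_ms / 1000) - 1e-9))
  means <- if (target_patch == "A") c(mean_target, mean_distractor) else
    c(mean_distractor, mean_target)
  lum <- array(stats::rnorm(n_frames * 2 * n_bars, sd = frame_sd),
               dim = c(n_frames, 2, n_bars))
  lum <- lum + rep(means, each = n_frames)
  new_stimulus(lum, frame_ms, onset, duration, mean_target, mean_distractor,
               frame_sd, target_patch)
}

new_stimulus <- function(lum, frame_ms, onset, duration, mean_target,
                         mean_distractor, frame_sd, target_patch) {
  structure(list(lum = lum, frame_ms = frame_ms, onset = onset,
                 duration = duration, mean_target = mean_target,
                 mean_distractor = mean_distractor, frame_sd = frame_sd,
                 target_patch = target_patch),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat("<stimulus>", dim(x$lum)[1], "frames x 2 patches x", dim(x$lum)[3],
      "bar(s),", x$frame_ms, "ms frames\n")
  cat("  target", x$target_patch, "at", x$mean_target, "cd/m2, distractor at",
      x$mean_distractor, "cd/m2, frame SD", x$frame_sd, "cd/m2\n")
  invisible(x)
}

#' Tidy view of a stimulus
#'
#' @param x A `stimulus`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time` (s, from trial start),
#'   `patch`, `bar`, `lum` (cd/m^2).
#' @export
as_tibble.stimulus <- function(x, ...) {
  d <- dim(x$lum)
  tibble::tibble(
    frame = rep(seq_len(d[1]), times = 2 * d[3]),
    time = x$onset + (rep(seq_len(d[1]), times = 2 * d[3]) - 1) *
      x$frame_ms / 1000,
    patch = rep(rep(c("A", "B"), each = d[1]), times = d[3]),
    bar = rep(seq_len(d[3]), each = 2 * d[1]),
    lum = as.vector(x$lum)
  )
}

#' Add a luminance pulse to one patch
#'
#' Adds a signed luminance offset to every bar of one patch over the window
#' `[start, start + width)` measured from stimulus onset. The two pulse
#' protocols of the asymmetry experiment are `apply_pulse(stim, "A", +1, 0,
#' 0.04)` (SP1) and `apply_pulse(stim, "B", -1, 0, 0.04)` (SP2).
#'
#' @param stim A `stimulus`.
#' @param patch `"A"` or `"B"`.
#' @param amplitude Signed offset (cd/m^2).
#' @param start Pulse start, seconds from stimulus onset.
#' @param width Pulse width (s), > 0.
#' @return The modified `stimulus`.
#' @export
apply_pulse <- function(stim, patch, amplitude, start = 0, width = 0.04) {
  stopifnot(inherits(stim, "stimulus"), patch %in% c("A", "B"), width > 0)
  frame_s <- stim$frame_ms / 1000
  n_frames <- dim(stim$lum)[1]
  if (start < 0 || start + width > n_frames * frame_s + 1e-9) {
    stop("pulse window [", start, ", ", start + width,
         ") lies outside the stimulus window")
  }
  f0 <- floor(start / frame_s + 1e-9) + 1
  f1 <- ceiling((start + width) / frame_s - 1e-9)
  p <- if (patch == "A") 1L else 2L
  stim$lum[f0:f1, p, ] <- stim$lum[f0:f1, p, ] + amplitude
  stim
}

#' Transform luminance to input current
#'
#' Affine sensory stage `I = g * (L + b)`; order-preserving for `g > 0`.
#'
#' @param L Luminance(s) (cd/m^2).
#' @param transform A [luminance_transform()].
#' @return Current(s) in nA.
#' @export
luminance_to_current <- function(L, transform) {
  stopifnot(inherits(transform, "luminance_transform"))
  transform$g * (L + transform$b)
}

#' Per-frame input currents of a stimulus
#'
#' Averages bars within each patch (the network integrates the patch mean)
#' and applies the luminance transform, giving the piecewise-constant
#' external current delivered on the frame grid.
#'
#' @param stim A `stimulus`.
#' @param transform A [luminance_transform()].
#' @return A `frames x 2` matrix of currents (nA), columns = patches A, B.
#' @export
stimulus_currents <- function(stim, transform) {
  stopifnot(inherits(stim, "stimulus"))
  d <- dim(stim$lum)
  pm <- if (d[3] == 1L) stim$lum[, , 1] else apply(stim$lum, c(1, 2), mean)
  matrix(luminance_to_current(pm, transform), d[1], 2)
}

#' Write / read a stimulus as CSV plus a JSON sidecar
#'
#' The CSV holds one row per (frame, patch, bar); the sidecar records the
#' generating settings so a fit can be replayed on fixed stimuli.
#'
#' @param stim A `stimulus`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `write_stimulus()` returns `path` invisibly; `read_stimulus()`
#'   returns the reconstructed `stimulus`.
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus"))
  utils::write.csv(as_tibble.stimulus(stim), path, row.names = FALSE)
  meta <- stim[setdiff(names(stim), "lum")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @param path CSV path previously written by `write_stimulus()`.
#' @export
read_stimulus <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_frames <- max(tab$frame)
  n_bars <- max(tab$bar)
  lum <- array(NA_real_, dim = c(n_frames, 2, n_bars))
  lum[cbind(tab$frame, ifelse(tab$patch == "A", 1L, 2L), tab$bar)] <- tab$lum
  new_stimulus(lum, meta$frame_ms, meta$onset, meta$duration,
               meta$mean_target, meta$mean_distractor, meta$frame_sd,
               meta$target_patch)
}
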