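#' Pool luminance fluctuations by choice and confidence
#'
#' Reverse-correlation preprocessing: every decided trial contributes the
#' fluctuation traces (presented luminance minus the patch's nominal
#' generating mean) of its selected and non-selected patches, split by the
#' reported confidence into the four groups `s_high`, `s_low`, `n_high`,
#' `n_low`. Traces are aligned to stimulus onset; a frame contributes to a
#' trial only while the response has not yet occurred.
#'
#' @param dataset A `behavioral_dataset`, see [generate_synthetic_subject()].
#' @param rule Frame-inclusion rule: `"frame_start"` (the frame the response
#'   lands in still contributes, default) or `"frame_end"` (frame must end at
#'   or before the response). The default matters here: decisions concentrate
#'   shortly after onset, and the stricter rule would discard most trials.
#' @param baseline Fluctuation baseline: `"nominal"` (the generating mean,
#'   default) or `"empirical"` (the patch's observed trial mean).
#' @return An object of class `fluctuation_groups`: per group a
#'   `(trial x bar) x frame` fluctuation matrix (cd/m^2, NA after the
#'   response) plus row trial indices, the frame time grid (s from onset),
#'   and the number of excluded (undecided or unrated) trials.
#' @export
pool_fluctuations <- function(dataset, rule = c("frame_start", "frame_end"),
                              baseline = c("nominal", "empirical")) {
  stopifnot(inherits(dataset, "behavioral_dataset"))
  rule <- match.arg(rule)
  baseline <- match.arg(baseline)
  tr <- dataset$trials
  stopifnot(all(c("choice", "confidence", "rt") %in% names(tr)))
  ok <- !is.na(tr$choice) & !is.na(tr$confidence) & !is.na(tr$rt)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " undecided or unrated trial(s) excluded from pooling")
  }
  if (!any(ok)) stop("no usable trials to pool")

  lum <- dataset$lum  # (trial, frame, patch, bar)
  d <- dim(lum)
  n_frames <- d[2]; n_bars <- d[4]
  frame_s <- dataset$frame_ms / 1000
  keep <- which(ok)

  # fluctuations against the per-trial, per-patch baseline
  base <- if (baseline == "nominal") {
    dataset$mean_patch  # (trial, patch)
  } else {
    apply(lum, c(1, 3), mean)
  }

  sel <- ifelse(tr$choice == "A", 1L, 2L)
  rt_on <- tr$rt - dataset$onset
  n_incl <- if (rule == "frame_end") {
    pmin(n_frames, floor(rt_on / frame_s + 1e-9))
  } else {
    pmin(n_frames, ceiling(rt_on / frame_s - 1e-9))
  }

  grab <- function(rows, patch_of) {
    if (length(rows) == 0L) {
      return(list(fluc = matrix(NA_real_, 0, n_frames),
                  trial = integer(0)))
    }
    # rows stacked trial-major, bars within trial
    m <- matrix(NA_real_, length(rows) * n_bars, n_frames)
    trial_of <- integer(length(rows) * n_bars)
    for (i in seq_along(rows)) {
      t_i <- rows[i]
      p_i <- patch_of[i]
      ni <- n_incl[t_i]
      idx <- (i - 1L) * n_bars + seq_len(n_bars)
      trial_of[idx] <- t_i
      if (ni >= 1L) {
        block <- t(matrix(lum[t_i, seq_len(ni), p_i, ], ni, n_bars))
        m[idx, seq_len(ni)] <- block - base[t_i, p_i]
      }
    }
    list(fluc = m, trial = trial_of)
  }

  hi <- keep[tr$confidence[keep] == "high"]
  lo <- keep[tr$confidence[keep] == "low"]
  groups <- list(
    s_high = grab(hi, sel[hi]),
    s_low = grab(lo, sel[lo]),
    n_high = grab(hi, 3L - sel[hi]),
    n_low = grab(lo, 3L - sel[lo])
  )
  structure(c(groups,
              list(time = (seq_len(n_frames) - 1L) * frame_s,
                   n_excluded = n_excluded)),
            class = "fluctuation_groups")
}

group_mean <- function(g) {
  list(mean = colMeans(g$fluc, na.rm = TRUE),
       count = colSums(!is.na(g$fluc)))
}

#' Decision kernels
#'
#' The decision kernel is the mean fluctuation conditioned on choice alone
#' (both confidence levels pooled): `d_s(t)` averages the selected-patch
#' fluctuations over trials and bars, `d_n(t)` the non-selected ones. In the
#' model, fluctuations for and against carry comparable weight, so the two
#' kernels mirror each other.
#'
#' @param groups A [pool_fluctuations()] result.
#' @return A tibble with `time` (s from onset), `d_s`, `d_n` (cd/m^2, `NA`
#'   where no trial contributes), and contributing counts `n_s`, `n_n`.
#' @export
decision_kernels <- function(groups) {
  stopifnot(inherits(groups, "fluctuation_groups"))
  s <- group_mean(list(fluc = rbind(groups$s_high$fluc, groups$s_low$fluc)))
  n <- group_mean(list(fluc = rbind(groups$n_high$fluc, groups$n_low$fluc)))
  if (all(s$count == 0)) stop("empty fluctuation groups")
  tibble::tibble(time = groups$time,
                 d_s = ifelse(s$count > 0, s$mean, NA_real_),
                 d_n = ifelse(n$count > 0, n$mean, NA_real_),
                 n_s = s$count, n_n = n$count)
}

#' Confidence kernels
#'
#' The confidence kernel is the high-minus-low difference of the mean
#' fluctuations per patch: `c_s(t) = mean(s_high) - mean(s_low)` and
#' `c_n(t) = mean(n_high) - mean(n_low)`. Its hallmark is asymmetry:
#' fluctuations of the selected patch drive confidence, fluctuations of the
#' non-selected patch barely do.
#'
#' @param groups A [pool_fluctuations()] result.
#' @return A tibble with `time`, `c_s`, `c_n` and the per-level counts.
#' @export
confidence_kernels <- function(groups) {
  stopifnot(inherits(groups, "fluctuation_groups"))
  if (nrow(groups$s_high$fluc) == 0L) stop("no high-confidence trials")
  if (nrow(groups$s_low$fluc) == 0L) stop("no low-confidence trials")
  sh <- group_mean(groups$s_high); sl <- group_mean(groups$s_low)
  nh <- group_mean(groups$n_high); nl <- group_mean(groups$n_low)
  both_s <- sh$count > 0 & sl$count > 0
  both_n <- nh$count > 0 & nl$count > 0
  tibble::tibble(time = groups$time,
                 c_s = ifelse(both_s, sh$mean - sl$mean, NA_real_),
                 c_n = ifelse(both_n, nh$mean - nl$mean, NA_real_),
                 n_high = sh$count, n_low = sl$count)
}

#' Decision and confidence kernels with bootstrap errors
#'
#' One-call kernel analysis: pools fluctuations, computes the decision and
#' confidence kernels, and (optionally) trial-level bootstrap standard
#' errors.
#'
#' @inheritParams pool_fluctuations
#' @param n_boot Bootstrap replicates (0 skips the bootstrap).
#' @return A tibble of class `kernel_set`: `time`, `d_s`, `d_n`, `c_s`,
#'   `c_n`, `count` (selected-patch trials contributing per time), and, with
#'   `n_boot > 0`, `se_d_s`, `se_d_n`, `se_c_s`, `se_c_n`.
#' @examples
#' \donttest{
#' p <- model_params(n_modules = 20)
#' set.seed(2)
#' ds <- generate_synthetic_subject(p, luminance_transform(),
#'                                  confidence_map(), n_trials = 100)
#' compute_kernels(ds)
#' }
#' @export
compute_kernels <- function(dataset, n_boot = 0, rule = "frame_start",
                            baseline = "nominal") {
  groups <- pool_fluctuations(dataset, rule = rule, baseline = baseline)
  dk <- decision_kernels(groups)
  ck <- confidence_kernels(groups)
  out <- tibble::tibble(time = dk$time, d_s = dk$d_s, d_n = dk$d_n,
                        c_s = ck$c_s, c_n = ck$c_n, count = dk$n_s)
  if (n_boot > 0) {
    se <- kernel_bootstrap(groups, n_boot)
    out <- dplyr::bind_cols(out, se)
  }
  class(out) <- c("kernel_set", class(out))
  out
}

# Trial-level bootstrap of all four kernels. Bars within a trial are
# resampled together (the trial is the exchangeable unit).
kernel_bootstrap <- function(groups, n_boot) {
  per_trial <- function(g) {
    ids <- unique(g$trial)
    m <- rowsum(ifelse(is.na(g$fluc), 0, g$fluc), g$trial) /
      pmax(rowsum((!is.na(g$fluc)) + 0, g$trial), 1)
    cnt <- rowsum((!is.na(g$fluc)) + 0, g$trial) > 0
    m[!cnt] <- NA
    list(m = m, ids = ids)
  }
  gs <- lapply(groups[c("s_high", "s_low", "n_high", "n_low")], per_trial)
  boot_mean <- function(m, idx) colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
  n_frames <- length(groups$time)
  acc <- replicate(n_boot, {
    idx <- lapply(gs, function(g) sample.int(nrow(g$m), replace = TRUE))
    sh <- boot_mean(gs$s_high$m, idx$s_high)
    sl <- boot_mean(gs$s_low$m, idx$s_low)
    nh <- boot_mean(gs$n_high$m, idx$n_high)
    nl <- boot_mean(gs$n_low$m, idx$n_low)
    ws <- nrow(gs$s_high$m); wl <- nrow(gs$s_low$m)
    c((ws * sh + wl * sl) / (ws + wl), (ws * nh + wl * nl) / (ws + wl),
      sh - sl, nh - nl)
  })
  dim(acc) <- c(n_frames, 4, n_boot)
  se <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE)
  tibble::tibble(se_d_s = se[, 1], se_d_n = se[, 2],
                 se_c_s = se[, 3], se_c_n = se[, 4])
}

#' Plot a kernel set
#'
#' @param object A `kernel_set` from [compute_kernels()].
#' @param ... Unused.
#' @return A ggplot: decision and confidence kernels against time from
#'   stimulus onset, with bootstrap ribbons when available.
#' @export
autoplot.kernel_set <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "time", "d_s", "d_n", "c_s", "c_n"),
    -"time", names_to = "kernel", values_to = "value")
  long$panel <- ifelse(long$kernel %in% c("d_s", "d_n"),
                       "decision", "confidence")
  long$patch <- ifelse(long$kernel %in% c("d_s", "c_s"),
                       "selected", "non-selected")
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                           color = .data$patch)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = "mean fluctuation (cd/m²)")
  if ("se_d_s" %in% names(object)) {
    ribbon <- tidyr::pivot_longer(
      dplyr::select(object, "time", dplyr::starts_with("se_")),
      -"time", names_to = "kernel", values_to = "se")
    ribbon$kernel <- sub("^se_", "", ribbon$kernel)
    long <- dplyr::left_join(long, ribbon, by = c("time", "kernel"))
    gg <- gg + ggplot2::geom_ribbon(
      data = long,
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se, fill = .data$patch),
      alpha = 0.2, color = NA)
  }
  gg
}
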