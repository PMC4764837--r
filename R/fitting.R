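#' Pearson chi-squared statistic against model proportions
#'
#' `sum_i (O_i - n p_i)^2 / (n p_i)` with `n = sum(O)`: the goodness-of-fit
#' statistic that the observed counts come from the multinomial with
#' proportions `p`. Used in both fitting stages (hits/misses, and the 4-way
#' confidence-by-correctness table).
#'
#' @param observed Non-negative integer counts.
#' @param p Model proportions, summing to 1.
#' @return The statistic (numeric scalar).
#' @examples
#' pearson_chi2(c(60, 40), c(0.5, 0.5))  # 4
#' @export
pearson_chi2 <- function(observed, p) {
  stopifnot(length(observed) == length(p), all(observed >= 0), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) stop("model proportions must sum to 1")
  n <- sum(observed)
  expected <- n * p
  if (any(expected == 0)) {
    stop("zero expected count; pool the affected categories before testing")
  }
  sum((observed - expected)^2 / expected)
}

#' Merit-function configuration
#'
#' Bundles the weights, penalties and simulation settings of the behavioral
#' merit functions. The kernel least-squares and Pearson terms carry unit
#' weights by default, which puts them on the same order of magnitude at the
#' self-fit point. Early and undecided trials are penalized linearly; the
#' default coefficient (0.1 per trial) keeps the penalties on the same
#' order as the fitted terms at the self-fit point at desk-scale `n_sim`,
#' while the rate itself is matched by the multinomial term.
#'
#' @param w_lsq Weight of the decision-kernel least-squares term.
#' @param w_chi2 Weight of the Pearson chi-squared term.
#' @param pen_early Penalty per early-decision trial (decision before onset).
#' @param pen_undecided Penalty per trial with no decision in the window.
#' @param n_sim Simulated trials per merit evaluation.
#' @param deadline Forced-decision window after stimulus onset (s).
#' @param wait Pre-stimulus wait (s).
#' @param frame_sd Model-side per-patch frame SD (cd/m^2); 5 by default, the
#'   SD of a 4-bar patch mean when bars have SD 10.
#' @param frame_ms Frame duration (ms).
#' @return A list of class `merit_config`.
#' @export
merit_config <- function(w_lsq = 1, w_chi2 = 1, pen_early = 0.1,
                         pen_undecided = 0.1, n_sim = 1000, deadline = 1,
                         wait = 1, frame_sd = 5, frame_ms = 40) {
  stopifnot(w_lsq >= 0, w_chi2 >= 0, pen_early >= 0, pen_undecided >= 0,
            n_sim >= 1, deadline > 0, wait >= 0)
  structure(list(w_lsq = w_lsq, w_chi2 = w_chi2, pen_early = pen_early,
                 pen_undecided = pen_undecided, n_sim = as.integer(n_sim),
                 deadline = deadline, wait = wait, frame_sd = frame_sd,
                 frame_ms = frame_ms),
            class = "merit_config")
}

#' Generate a synthetic behavioral subject
#'
#' Runs the full model forward to produce a behavioral dataset with the
#' statistics of the flicker brightness task: per trial a 4-bar, 10 cd/m^2
#' frame-SD stimulus on each patch (target side randomized, target mean drawn
#' from a truncated Gaussian), a forced-decision window after a pre-stimulus
#' wait, binary confidence sampled from the FMC sigmoid, and the full per-bar
#' luminance traces needed for kernel analysis. This stands in for human data
#' when exercising the fitting pipeline.
#'
#' @param params A [model_params()] object.
#' @param transform The generating [luminance_transform()] (the "true" g, b).
#' @param conf_map The generating [confidence_map()] (the "true" a, c).
#' @param n_trials Number of trials.
#' @param mean_target_range Truncation bounds of the target-mean distribution
#'   (cd/m^2); the underlying Gaussian has mean 55 and SD 5.
#' @param mean_distractor Distractor mean (cd/m^2).
#' @param frame_sd Per-bar frame SD (cd/m^2).
#' @param n_bars Bars per patch.
#' @param wait Pre-stimulus wait (s).
#' @param deadline Forced-decision window (s).
#' @param frame_ms Frame duration (ms).
#' @return An object of class `behavioral_dataset`: `trials` (tibble with
#'   `choice`, `correct`, `confidence`, `rt`, `early`, `undecided`,
#'   `mean_target`, `target_patch`, `sigma_dv`, `fmc`), the luminance array
#'   `lum` (trial x frame x patch x bar), the nominal per-patch means
#'   `mean_patch`, and the timing settings.
#' @export
generate_synthetic_subject <- function(params, transform, conf_map,
                                       n_trials,
                                       mean_target_range = c(51, 70),
                                       mean_distractor = 50, frame_sd = 10,
                                       n_bars = 4L, wait = 1, deadline = 1,
                                       frame_ms = 40) {
  stopifnot(n_trials >= 1, inherits(conf_map, "confidence_map"))
  mt <- rtrunc_norm(n_trials, 55, 5, mean_target_range[1],
                    mean_target_range[2])
  res <- simulate_trials(params, transform, n_trials, mean_target = mt,
                         mean_distractor = mean_distractor,
                         frame_sd = frame_sd, frame_ms = frame_ms,
                         duration = deadline, n_bars = n_bars, onset = wait,
                         target_patch = "random", conf_map = conf_map,
                         keep_stimuli = TRUE)
  stimuli <- attr(res, "stimuli")
  n_frames <- dim(stimuli[[1]]$lum)[1]
  lum <- array(NA_real_, dim = c(n_trials, n_frames, 2, n_bars))
  mean_patch <- matrix(NA_real_, n_trials, 2)
  for (i in seq_len(n_trials)) {
    lum[i, , , ] <- stimuli[[i]]$lum
    mean_patch[i, ] <- if (stimuli[[i]]$target_patch == "A") {
      c(mt[i], mean_distractor)
    } else c(mean_distractor, mt[i])
  }
  trials <- dplyr::mutate(res, mean_target = mt,
                          target_patch = vapply(stimuli, function(s)
                            s$target_patch, character(1)))
  new_behavioral_dataset(trials, lum, mean_patch, frame_ms, wait, deadline)
}

new_behavioral_dataset <- function(trials, lum, mean_patch, frame_ms, onset,
                                   deadline) {
  structure(list(trials = trials, lum = lum, mean_patch = mean_patch,
                 frame_ms = frame_ms, onset = onset, deadline = deadline),
            class = "behavioral_dataset")
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  tr <- x$trials
  dec <- !is.na(tr$choice)
  cat("<behavioral_dataset>", nrow(tr), "trials,",
      sum(dec), "decided,", sum(tr$confidence == "high", na.rm = TRUE),
      "high-confidence\n")
  cat("  accuracy", round(mean(tr$correct[dec]), 3), "| mean RT",
      round(mean(tr$rt[dec] - x$onset, na.rm = TRUE), 3), "s from onset\n")
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Four-way confidence-by-correctness counts
#'
#' Counts of high-hit, high-miss, low-hit, low-miss over decided, rated
#' trials — the fitting target of the confidence stage.
#'
#' @param trials A trials tibble with `correct` and `confidence`.
#' @return Named integer vector `c(high_hit, high_miss, low_hit, low_miss)`.
#' @export
confidence_table <- function(trials) {
  ok <- !is.na(trials$correct) & !is.na(trials$confidence)
  t <- trials[ok, ]
  c(high_hit = sum(t$confidence == "high" & t$correct),
    high_miss = sum(t$confidence == "high" & !t$correct),
    low_hit = sum(t$confidence == "low" & t$correct),
    low_miss = sum(t$confidence == "low" & !t$correct))
}

# Two-sample Pearson statistic: both count vectors treated as draws from
# one pooled multinomial (cells empty in both samples are dropped).
chi2_two_sample <- function(o1, o2) {
  keep <- (o1 + o2) > 0
  o1 <- o1[keep]; o2 <- o2[keep]
  p <- (o1 + o2) / sum(o1 + o2)
  e1 <- sum(o1) * p
  e2 <- sum(o2) * p
  sum((o1 - e1)^2 / e1) + sum((o2 - e2)^2 / e2)
}

# Precomputed target-side quantities shared by every merit evaluation.
target_summary <- function(target) {
  stopifnot(inherits(target, "behavioral_dataset"))
  tr <- target$trials
  dec <- !is.na(tr$choice)
  groups <- pool_fluctuations_choice_only(target)
  dk <- decision_kernels(groups)
  list(dk = dk,
       counts_hmu = c(hits = sum(tr$correct[dec]),
                      misses = sum(!tr$correct[dec]),
                      undecided = sum(!dec)),
       conf_counts = if (!all(is.na(tr$confidence)))
         confidence_table(tr) else NULL,
       mean_targets = tr$mean_target[dec],
       n_decided = sum(dec))
}

# Choice-conditioned pooling that ignores confidence labels (decision
# kernels only need choice).
pool_fluctuations_choice_only <- function(dataset) {
  ds <- dataset
  ds$trials$confidence <- ifelse(is.na(ds$trials$choice), NA, "high")
  suppressMessages(pool_fluctuations(ds))
}

#' Stage-1 merit: decision kernels and performance
#'
#' Simulates `cfg$n_sim` trials at candidate gain/bias `(g, b)` with
#' target-matched stimulus statistics (target means resampled from the
#' dataset, distractor at 50 cd/m^2, per-patch flicker, forced decision
#' within the deadline) and scores the candidate by
#' `w_lsq * sum_t [(Dhat_S - D_S)^2 + (Dhat_N - D_N)^2]
#'  + w_chi2 * chi2(hits, misses, undecided) + pen_early * N_e
#'  + pen_undecided * N_d`.
#' The kernel term is count-weighted on the target's frame grid (absent
#' model frames count as zero influence); the Pearson term treats the
#' subject's (hit, miss, undecided) counts as one multinomial.
#' Undecided-only simulations yield a finite, penalty-dominated merit.
#'
#' @param g,b Candidate input gain (nA m^2/cd) and bias (cd/m^2).
#' @param target A `behavioral_dataset` (the subject).
#' @param cfg A [merit_config()].
#' @param params A [model_params()] object.
#' @param seed Seed applied before simulating; pass the same value across
#'   evaluations for common random numbers.
#' @param target_stats Optional precomputed target summary (internal reuse).
#' @return The merit (scalar) with attribute `"components"` holding the four
#'   logged terms.
#' @export
decision_merit <- function(g, b, target, cfg, params, seed = NULL,
                           target_stats = NULL) {
  stopifnot(inherits(cfg, "merit_config"))
  if (is.null(target_stats)) target_stats <- target_summary(target)
  if (!is.null(seed)) set.seed(seed)
  tf <- luminance_transform(g = g, b = b)
  mt <- sample(target_stats$mean_targets, cfg$n_sim, replace = TRUE)
  sim <- simulate_trials(params, tf, cfg$n_sim, mean_target = mt,
                         frame_sd = cfg$frame_sd, frame_ms = cfg$frame_ms,
                         duration = cfg$deadline, n_bars = 1L,
                         onset = cfg$wait, target_patch = "A",
                         keep_stimuli = TRUE)
  n_e <- sum(sim$early)
  n_d <- sum(sim$undecided)
  lsq <- 0
  chi2 <- 0
  if (any(!sim$undecided)) {
    mdl <- as_model_dataset(sim, cfg)
    mdk <- tryCatch(decision_kernels(pool_fluctuations_choice_only(mdl)),
                    error = function(e) NULL)
    tdk <- target_stats$dk
    # compare on the target's own frame grid; a frame the candidate model
    # never reaches contributes its full squared target kernel (an absent
    # kernel is zero measured influence), so fast-deciding candidates
    # cannot shrink the sum by emptying the overlap
    use <- which(tdk$n_s > 0)
    use <- use[use <= if (is.null(mdk)) 0L else nrow(mdk)]
    if (length(use)) {
      md_s <- ifelse(mdk$n_s[use] > 0, mdk$d_s[use], 0)
      md_n <- ifelse(mdk$n_n[use] > 0, mdk$d_n[use], 0)
      # frames weighted by the target's contributing-trial counts (mean
      # weight 1): late frames are estimated from the few slow responses
      # and would otherwise drown the informative early frames in noise
      w <- tdk$n_s[use] / mean(tdk$n_s[use])
      lsq <- sum(w * ((md_s - tdk$d_s[use])^2 + (md_n - tdk$d_n[use])^2))
    }
    # the subject's non-decision rate is behavioral data too: two-sample
    # Pearson statistic that subject and simulation (hit, miss, undecided)
    # counts come from one multinomial. The two-sample form keeps the
    # statistic's sampling noise bounded even when a category (typically
    # 'undecided') is rare, and pulls candidates toward the subject's
    # non-decision rate instead of rewarding them for zeroing it.
    counts_sim <- c(sum(sim$correct & !sim$undecided, na.rm = TRUE),
                    sum(!sim$correct & !sim$undecided, na.rm = TRUE), n_d)
    chi2 <- chi2_two_sample(target_stats$counts_hmu, counts_sim)
  }
  merit <- cfg$w_lsq * lsq + cfg$w_chi2 * chi2 +
    cfg$pen_early * n_e + cfg$pen_undecided * n_d
  attr(merit, "components") <- c(lsq = cfg$w_lsq * lsq,
                                 chi2 = cfg$w_chi2 * chi2,
                                 early = cfg$pen_early * n_e,
                                 undecided = cfg$pen_undecided * n_d)
  merit
}

# Wrap a simulate_trials() result (with kept stimuli) as a behavioral
# dataset so the kernel machinery applies to model-side simulations.
as_model_dataset <- function(sim, cfg) {
  stimuli <- attr(sim, "stimuli")
  n_trials <- nrow(sim)
  n_frames <- dim(stimuli[[1]]$lum)[1]
  n_bars <- dim(stimuli[[1]]$lum)[3]
  lum <- array(NA_real_, dim = c(n_trials, n_frames, 2, n_bars))
  mean_patch <- matrix(NA_real_, n_trials, 2)
  for (i in seq_len(n_trials)) {
    lum[i, , , ] <- stimuli[[i]]$lum
    mean_patch[i, ] <- if (stimuli[[i]]$target_patch == "A") {
      c(stimuli[[i]]$mean_target, stimuli[[i]]$mean_distractor)
    } else c(stimuli[[i]]$mean_distractor, stimuli[[i]]$mean_target)
  }
  trials <- sim
  if (!"confidence" %in% names(trials)) trials$confidence <- NA_character_
  new_behavioral_dataset(trials, lum, mean_patch, cfg$frame_ms, cfg$wait,
                         cfg$deadline)
}

#' Stage-2 merit: confidence-conditioned performance
#'
#' Samples binary confidence reports for a pool of already-simulated model
#' trials from the candidate sigmoid `(a, c)` and returns the Pearson
#' chi-squared statistic between the subject's and the model's 4-way
#' confidence-by-correctness table.
#'
#' @param a,c Candidate sigmoid scale and midpoint.
#' @param target A `behavioral_dataset` with confidence reports.
#' @param sim_pool A decided-trials tibble with `fmc` (or `sigma_dv`) and
#'   `correct`: the stage-1 model simulation at the fitted (g, b).
#' @param input_kind `"fmc"` or `"sigma_dv"`.
#' @param seed Seed applied before sampling (common random numbers).
#' @param target_counts Optional precomputed [confidence_table()] counts.
#' @return The chi-squared merit with attribute `"counts"` (the model's
#'   4-way counts).
#' @export
confidence_merit <- function(a, c, target, sim_pool,
                             input_kind = "fmc", seed = NULL,
                             target_counts = NULL) {
  if (is.null(target_counts)) target_counts <- confidence_table(target$trials)
  if (!is.null(seed)) set.seed(seed)
  map <- confidence_map(slope_a = a, center_c = c, input_kind = input_kind)
  x <- if (input_kind == "fmc") sim_pool$fmc else sim_pool$sigma_dv
  conf <- confidence_sample(x, map)
  counts <- c(high_hit = sum(conf == "high" & sim_pool$correct),
              high_miss = sum(conf == "high" & !sim_pool$correct),
              low_hit = sum(conf == "low" & sim_pool$correct),
              low_miss = sum(conf == "low" & !sim_pool$correct))
  n <- sum(counts)
  p <- pmax(counts / n, 0.5 / n)
  p <- p / sum(p)
  out <- pearson_chi2(target_counts, p)
  attr(out, "counts") <- counts
  out
}
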