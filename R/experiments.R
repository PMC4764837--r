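#' Coupling-by-discriminability sweep
#'
#' Simulates free-response trials over a grid of inter-module couplings and
#' discriminabilities and summarizes each cell: accuracy, mean RT (with the
#' correct/error split — this task yields slow errors), mean dispersion and
#' mean FMC, with trial-bootstrap confidence intervals. The headline
#' contrasts: coupling leaves accuracy and RT unchanged, while the
#' dispersion-discriminability correlation is strong at low coupling and
#' vanishes at full coupling.
#'
#' @param params A [model_params()] object (the `ic` field is overridden by
#'   the grid).
#' @param transform A [luminance_transform()].
#' @param ics Coupling values to sweep.
#' @param discriminabilities Target-minus-distractor mean luminances
#'   (cd/m^2).
#' @param n_trials Trials per (ic, discriminability) cell.
#' @param duration Maximum stimulus duration (s).
#' @param n_boot Bootstrap replicates for the cell CIs.
#' @param keep_trials Attach the trial-level tibble as attribute `"trials"`
#'   (needed for trial-level correlations).
#' @return A tibble with one row per cell: `ic`, `d`, `n`, `accuracy`,
#'   `rt_mean`, `rt_correct`, `rt_error`, `sigma_mean`, `fmc_mean`,
#'   `p_undecided` and bootstrap 95% CI bounds for accuracy, RT, sigma and
#'   FMC.
#' @examples
#' \donttest{
#' p <- model_params(n_modules = 20)
#' set.seed(1)
#' run_ic_sweep(p, luminance_transform(), n_trials = 50,
#'              discriminabilities = c(2, 8))
#' }
#' @export
run_ic_sweep <- function(params, transform = luminance_transform(),
                         ics = c(0, 1), discriminabilities = c(1, 2, 4, 8, 16),
                         n_trials = 2000, duration = 3, n_boot = 200,
                         keep_trials = TRUE) {
  grid <- tidyr::expand_grid(ic = ics, d = discriminabilities)
  all_trials <- purrr::pmap(grid, function(ic, d) {
    res <- simulate_trials(update_params(params, ic = ic), transform,
                           n_trials, mean_target = 50 + d, duration = duration)
    dplyr::mutate(res, ic = ic, d = d)
  })
  trials <- dplyr::bind_rows(all_trials)
  summ <- dplyr::bind_rows(purrr::map(all_trials, summarize_cell,
                                      n_boot = n_boot))
  if (keep_trials) attr(summ, "trials") <- trials
  summ
}

summarize_cell <- function(res, n_boot = 200) {
  dec <- !res$undecided
  cell_stats <- function(r) {
    dec_r <- !r$undecided
    c(accuracy = mean(r$correct[dec_r]),
      rt_mean = mean(r$rt[dec_r]),
      sigma_mean = mean(r$sigma_dv[dec_r]),
      fmc_mean = mean(r$fmc[dec_r]))
  }
  boot <- replicate(n_boot, cell_stats(res[sample.int(nrow(res),
                                                      replace = TRUE), ]))
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  base <- cell_stats(res)
  tibble::tibble(
    ic = res$ic[1], d = res$d[1], n = nrow(res),
    accuracy = base["accuracy"], rt_mean = base["rt_mean"],
    rt_correct = mean(res$rt[dec & res$correct]),
    rt_error = mean(res$rt[dec & !res$correct]),
    n_error = sum(dec & !res$correct),
    sigma_mean = base["sigma_mean"], fmc_mean = base["fmc_mean"],
    p_undecided = mean(res$undecided),
    accuracy_lo = ci[1, "accuracy"], accuracy_hi = ci[2, "accuracy"],
    rt_lo = ci[1, "rt_mean"], rt_hi = ci[2, "rt_mean"],
    sigma_lo = ci[1, "sigma_mean"], sigma_hi = ci[2, "sigma_mean"],
    fmc_lo = ci[1, "fmc_mean"], fmc_hi = ci[2, "fmc_mean"]
  )
}

#' Pulse-asymmetry experiment
#'
#' Runs the two stimulation protocols at zero nominal discriminability:
#' SP1 adds +`amplitude` cd/m^2 to patch A during the first 40 ms of
#' stimulation, SP2 adds -`amplitude` to patch B. Both favor option A
#' equally through the input difference, but SP1 briefly raises and SP2
#' lowers the total input, which asymmetrically shifts vote times, network
#' RT, dispersion and FMC.
#'
#' @param params A [model_params()] object.
#' @param transform A [luminance_transform()].
#' @param n_trials Trials per protocol.
#' @param amplitude Pulse amplitude (cd/m^2).
#' @param duration Maximum stimulus duration (s).
#' @return A tibble with one row per protocol (accuracy = P(choose A), mean
#'   RT, mean vote time of modules voting with the decision, mean sigma_dv,
#'   mean FMC, and normal-theory 95% CIs), with attribute `"tests"`: a
#'   tibble of two-sample Welch tests for the four SP1-vs-SP2 contrasts.
#' @export
run_sp_asymmetry <- function(params, transform = luminance_transform(),
                             n_trials = 10000, amplitude = 1, duration = 3) {
  run_one <- function(sp) {
    pulse <- if (sp == "SP1") {
      list(patch = "A", amplitude = amplitude, start = 0, width = 0.04)
    } else {
      list(patch = "B", amplitude = -amplitude, start = 0, width = 0.04)
    }
    res <- simulate_trials(params, transform, n_trials, mean_target = 50,
                           duration = duration, pulse = pulse)
    dplyr::mutate(res, sp = sp)
  }
  sp1 <- run_one("SP1")
  sp2 <- run_one("SP2")
  summ <- function(r) {
    dec <- !r$undecided
    ci <- function(x) 1.96 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    tibble::tibble(
      sp = r$sp[1], n = nrow(r), p_choose_a = mean(r$choice[dec] == "A"),
      p_choose_a_ci = 1.96 * sqrt(.25 / sum(dec)),
      rt_mean = mean(r$rt[dec]), rt_ci = ci(r$rt[dec]),
      vote_time_mean = mean(r$vote_time_chosen[dec], na.rm = TRUE),
      sigma_mean = mean(r$sigma_dv[dec]), sigma_ci = ci(r$sigma_dv[dec]),
      fmc_mean = mean(r$fmc[dec]), fmc_ci = ci(r$fmc[dec]),
      p_undecided = mean(r$undecided)
    )
  }
  out <- dplyr::bind_rows(summ(sp1), summ(sp2))
  welch <- function(x1, x2, alternative) {
    t <- stats::t.test(x1, x2, alternative = alternative)
    tibble::tibble(estimate = mean(x1, na.rm = TRUE) - mean(x2, na.rm = TRUE),
                   p_value = t$p.value)
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(welch(sp1$rt, sp2$rt, "less"), contrast = "rt_sp1_lt_sp2"),
    dplyr::mutate(welch(sp1$vote_time_chosen, sp2$vote_time_chosen, "less"),
                  contrast = "vote_time_sp1_lt_sp2"),
    dplyr::mutate(welch(sp1$sigma_dv, sp2$sigma_dv, "less"),
                  contrast = "sigma_sp1_lt_sp2"),
    dplyr::mutate(welch(sp1$fmc, sp2$fmc, "greater"),
                  contrast = "fmc_sp1_gt_sp2")
  )
  attr(out, "tests") <- dplyr::relocate(tests, "contrast")
  attr(out, "trials") <- dplyr::bind_rows(sp1, sp2)
  out
}

#' Fixed-delay (interrogation) experiment
#'
#' Presents the stimulus for a fixed duration and forces the decision at
#' stimulus offset from the latched votes (ties to the higher mean rate).
#' Confidence is sampled at offset from the dispersion sigmoid. Away from
#' the majority moment the median rate no longer sits at the vote threshold,
#' so the percentile count (FMC) stops proxying the dispersion; the driver
#' therefore reads sigma_dv directly by default. The longer the stimulus,
#' the more modules settle into a common attractor, the tighter the
#' dispersion, and the higher the mean confidence.
#'
#' @param params A [model_params()] object.
#' @param transform A [luminance_transform()].
#' @param conf_map A [confidence_map()].
#' @param durations Stimulus durations to test (s).
#' @param n_trials Trials per duration.
#' @param mean_target Target mean (cd/m^2).
#' @return A tibble per duration: `duration`, `n`, `accuracy`,
#'   `p_high`, `fmc_mean`, `sigma_mean`, with attribute `"trend"`: the
#'   Cochran-Armitage trend test of high-confidence rate against duration.
#' @export
run_fixed_delay <- function(params, transform = luminance_transform(),
                            conf_map = confidence_map(slope_a = 0.4,
                                                      center_c = 6.3,
                                                      input_kind = "sigma_dv"),
                            durations = c(0.2, 0.4, 0.8), n_trials = 500,
                            mean_target = 53) {
  cells <- purrr::map(durations, function(dur) {
    res <- simulate_trials(params, transform, n_trials,
                           mean_target = mean_target, duration = dur,
                           stop_rule = "offset", max_t = 0.2 + dur,
                           conf_map = conf_map)
    dplyr::mutate(res, duration = dur)
  })
  out <- dplyr::bind_rows(purrr::map(cells, function(r) {
    tibble::tibble(duration = r$duration[1], n = nrow(r),
                   accuracy = mean(r$correct),
                   p_high = mean(r$confidence == "high"),
                   fmc_mean = mean(r$fmc), sigma_mean = mean(r$sigma_dv))
  }))
  if (length(durations) > 1L) {
    trials <- dplyr::bind_rows(cells)
    x <- tapply(trials$confidence == "high", trials$duration, sum)
    n <- tapply(trials$confidence, trials$duration, length)
    # the trend statistic is undefined when the pooled rate is 0 or 1
    attr(out, "trend") <- if (sum(x) > 0 && sum(x) < sum(n)) {
      # prop.trend.test warns through anova.lm when the fit is exact
      tt <- suppressWarnings(stats::prop.trend.test(x = x, n = n))
      tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      tibble::tibble(statistic = NA_real_, p_value = NA_real_)
    }
  }
  out
}

#' Write an experiment result with its reproducibility sidecar
#'
#' Writes the summary tibble as CSV plus a JSON sidecar holding the
#' parameter set, seed and any attached test tables, so a run can be
#' reproduced from its outputs alone.
#'
#' @param x A result tibble from one of the `run_*()` drivers.
#' @param path Output CSV path (sidecar at `<path>.json`).
#' @param params The [model_params()] used.
#' @param seed The seed used.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_run <- function(x, path, params = NULL, seed = NULL, extra = list()) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  side <- c(list(params = if (!is.null(params)) unclass(params),
                 seed = seed,
                 tests = if (!is.null(attr(x, "tests")))
                   as.data.frame(attr(x, "tests"))),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Psychometric / chronometric sweep plot
#'
#' @param sweep A [run_ic_sweep()] result.
#' @param what `"accuracy"`, `"rt_mean"`, `"sigma_mean"` or `"fmc_mean"`.
#' @return A ggplot of the chosen summary against discriminability, colored
#'   by coupling.
#' @export
plot_ic_sweep <- function(sweep, what = "accuracy") {
  stopifnot(what %in% c("accuracy", "rt_mean", "sigma_mean", "fmc_mean"))
  lohi <- c(accuracy = "accuracy", rt_mean = "rt", sigma_mean = "sigma",
            fmc_mean = "fmc")[[what]]
  ggplot2::ggplot(sweep, ggplot2::aes(.data$d, .data[[what]],
                                      color = factor(.data$ic),
                                      group = factor(.data$ic))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[paste0(lohi, "_lo")]],
                                        ymax = .data[[paste0(lohi, "_hi")]]),
                           width = 0.1) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "discriminability (cd/m²)", y = what,
                  color = "IC")
}
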