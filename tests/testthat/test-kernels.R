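# Hand-built datasets with known fluctuations exercise the pooling and
# kernel arithmetic independently of the simulator.

flat_dataset <- function(n_trials = 8, n_frames = 5, n_bars = 2, fluc = NULL,
                         choice = NULL, confidence = NULL, rt = NULL) {
  lum <- array(50, dim = c(n_trials, n_frames, 2, n_bars))
  if (!is.null(fluc)) lum <- lum + fluc
  manual_dataset(
    lum,
    choice %||% rep(c("A", "B"), length.out = n_trials),
    confidence %||% rep(c("high", "low"), length.out = n_trials),
    rt %||% rep(n_frames * 0.04, n_trials),
    mean_patch = matrix(50, n_trials, 2))
}

test_that("frame inclusion follows the response-time rule", {
  # RT = 0.20 s with 40 ms frames: exactly 5 frames contribute
  ds <- flat_dataset(n_trials = 4, n_frames = 8, rt = rep(0.20, 4))
  g <- pool_fluctuations(ds)
  counts <- colSums(!is.na(g$s_high$fluc))
  expect_equal(unname(counts), c(rep(4, 5), 0, 0, 0))  # 2 trials x 2 bars
  # frame_start rule admits the frame the response lands in
  g2 <- pool_fluctuations(ds, rule = "frame_start")
  expect_equal(unname(colSums(!is.na(g2$s_high$fluc))),
               c(rep(4, 5), 0, 0, 0))
  ds3 <- flat_dataset(n_trials = 4, n_frames = 8, rt = rep(0.21, 4))
  expect_equal(unname(colSums(!is.na(
    pool_fluctuations(ds3, rule = "frame_end")$s_high$fluc)))[6], 0)
  expect_equal(unname(colSums(!is.na(
    pool_fluctuations(ds3)$s_high$fluc)))[6], 4)
})

test_that("selected and non-selected traces land in the right groups", {
  n <- 4
  fluc <- array(0, dim = c(n, 3, 2, 1))
  fluc[, , 1, ] <- 1   # patch A fluctuations +1
  fluc[, , 2, ] <- -2  # patch B fluctuations -2
  ds <- flat_dataset(n_trials = n, n_frames = 3, n_bars = 1, fluc = fluc,
                     choice = c("A", "A", "B", "B"),
                     confidence = c("high", "low", "high", "low"),
                     rt = rep(0.12, n))
  g <- pool_fluctuations(ds)
  expect_equal(unique(as.vector(g$s_high$fluc)), c(1, -2))
  expect_equal(g$s_high$fluc[1, ], rep(1, 3))   # A-chooser, patch A
  expect_equal(g$s_high$fluc[2, ], rep(-2, 3))  # B-chooser, patch B
  expect_equal(g$n_high$fluc[1, ], rep(-2, 3))
  # zero-noise stimulus: all fluctuations identically zero
  dz <- flat_dataset()
  gz <- pool_fluctuations(dz)
  expect_true(all(gz$s_high$fluc[!is.na(gz$s_high$fluc)] == 0))
})

test_that("undecided or unrated trials are excluded with a message", {
  ds <- flat_dataset(n_trials = 6,
                     choice = c("A", NA, "B", "A", "B", "A"),
                     confidence = c("high", "high", NA, "low", "high", "low"),
                     rt = c(0.2, NA, 0.2, 0.2, 0.2, 0.2))
  expect_message(g <- pool_fluctuations(ds), "2 undecided or unrated")
  expect_identical(g$n_excluded, 2L)
})

test_that("decision kernels are group means with the pooling identity", {
  set.seed(61)
  n <- 40
  fluc <- array(rnorm(n * 6 * 2 * 2), dim = c(n, 6, 2, 2))
  ds <- flat_dataset(n_trials = n, n_frames = 6, n_bars = 2, fluc = fluc,
                     rt = rep(0.24, n))
  g <- pool_fluctuations(ds)
  dk <- decision_kernels(g)
  ck <- confidence_kernels(g)
  # pooling identity: count-weighted high/low means give the decision kernel
  sh <- colMeans(g$s_high$fluc, na.rm = TRUE)
  sl <- colMeans(g$s_low$fluc, na.rm = TRUE)
  wh <- colSums(!is.na(g$s_high$fluc))
  wl <- colSums(!is.na(g$s_low$fluc))
  expect_equal(dk$d_s, (wh * sh + wl * sl) / (wh + wl))
  expect_equal(ck$c_s, sh - sl)
  # single trial, single bar: the kernel is that trial's own trace
  f1 <- array(0, dim = c(1, 4, 2, 1))
  f1[1, , 1, 1] <- c(1, -1, 2, 0.5)
  d1 <- flat_dataset(n_trials = 1, n_frames = 4, n_bars = 1, fluc = f1,
                     choice = "A", confidence = "high", rt = 0.16)
  g1 <- pool_fluctuations(d1)
  expect_equal(decision_kernels(g1)$d_s, c(1, -1, 2, 0.5))
  expect_error(confidence_kernels(g1), "low")
})

test_that("null data give flat kernels and duplication leaves them fixed", {
  set.seed(62)
  n <- 400
  fluc <- array(rnorm(n * 5 * 2 * 2, sd = 5), dim = c(n, 5, 2, 2))
  ds <- flat_dataset(n_trials = n, n_frames = 5, n_bars = 2, fluc = fluc,
                     choice = sample(c("A", "B"), n, TRUE),
                     confidence = sample(c("high", "low"), n, TRUE),
                     rt = rep(0.2, n))
  ks <- compute_kernels(ds)
  se_null <- 5 / sqrt(n * 2)  # per-time SE of a mean of n x 2 bars
  expect_true(all(abs(ks$d_s) < 4 * se_null))
  expect_true(all(abs(ks$d_n) < 4 * se_null))
  expect_true(all(abs(ks$c_s) < 8 * se_null))
  # duplicating every trial leaves the kernels unchanged
  ds2 <- ds
  ds2$lum <- ds$lum[rep(seq_len(n), 2), , , , drop = FALSE]
  ds2$mean_patch <- ds$mean_patch[rep(seq_len(n), 2), ]
  ds2$trials <- dplyr::bind_rows(ds$trials, ds$trials)
  ks2 <- compute_kernels(ds2)
  expect_equal(ks2$d_s, ks$d_s)
  expect_equal(ks2$c_n, ks$c_n)
})

test_that("bootstrap standard errors shrink as 1/sqrt(n) on null data", {
  set.seed(63)
  make_null <- function(n) {
    fluc <- array(rnorm(n * 4 * 2), dim = c(n, 4, 2, 1))
    flat_dataset(n_trials = n, n_frames = 4, n_bars = 1, fluc = fluc,
                 choice = sample(c("A", "B"), n, TRUE),
                 confidence = sample(c("high", "low"), n, TRUE),
                 rt = rep(0.16, n))
  }
  k_small <- compute_kernels(make_null(100), n_boot = 200)
  k_big <- compute_kernels(make_null(400), n_boot = 200)
  ratio <- mean(k_small$se_d_s) / mean(k_big$se_d_s)
  expect_equal(ratio, 2, tolerance = 0.25)
})
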