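test_that("Pearson chi-squared follows the multinomial formula", {
  expect_equal(pearson_chi2(c(50, 50), c(0.5, 0.5)), 0)
  expect_equal(pearson_chi2(c(60, 40), c(0.5, 0.5)), 4)
  # doubling all counts with fixed proportions doubles the statistic
  o <- c(12, 30, 8)
  p <- c(0.2, 0.5, 0.3)
  expect_equal(pearson_chi2(2 * o, p), 2 * pearson_chi2(o, p))
  expect_error(pearson_chi2(c(10, 0), c(1, 0)), "pool")
  expect_error(pearson_chi2(c(10, 10), c(0.6, 0.6)), "sum to 1")
})

test_that("chi-squared matches the stats implementation on random tables", {
  set.seed(71)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    o <- rmultinom(1, sample(50:500, 1), rep(1 / k, k))[, 1]
    p <- as.vector(rmultinom(1, 1000, rep(1 / k, k))) + 1
    p <- p / sum(p)
    want <- suppressWarnings(
      unname(stats::chisq.test(o, p = p)$statistic))
    expect_equal(pearson_chi2(o, p), want, tolerance = 1e-10)
  }
})

test_that("CMA-ES finds the optimum of smooth test functions", {
  set.seed(72)
  sphere <- cma_es(function(x) sum((x - c(1, -2))^2),
                   lower = c(-5, -5), upper = c(5, 5), max_iter = 80)
  expect_lt(sqrt(sum((sphere$par - c(1, -2))^2)), 1e-3)
  expect_lt(sphere$value, 1e-6)
  # optimum on the box boundary is found by repair
  edge <- cma_es(function(x) sum(x^2), lower = c(1, 1), upper = c(3, 3),
                 max_iter = 60)
  expect_equal(edge$par, c(1, 1), tolerance = 1e-3)
  expect_error(cma_es(function(x) NaN, lower = -1, upper = 1),
               "not finite")
  # tidy/glance accessors
  td <- tidy(sphere)
  expect_identical(td$term, c("x1", "x2"))
  expect_identical(nrow(glance(sphere)), 1L)
})

test_that("synthetic subjects behave like subjects", {
  p <- small_params()
  tf <- default_transform()
  cm <- confidence_map()
  set.seed(73)
  easy <- generate_synthetic_subject(p, tf, cm, n_trials = 120,
                                     mean_target_range = c(62, 70),
                                     wait = 0.3)
  set.seed(73)
  hard <- generate_synthetic_subject(p, tf, cm, n_trials = 120,
                                     mean_target_range = c(50.5, 53),
                                     wait = 0.3)
  acc <- function(d) mean(d$trials$correct, na.rm = TRUE)
  expect_gt(acc(easy), acc(hard))
  # counts decompose over the 4-way table
  tab <- confidence_table(easy$trials)
  expect_identical(sum(tab),
                   sum(!is.na(easy$trials$choice) &
                         !is.na(easy$trials$confidence)))
  # determinism under the seed
  set.seed(74)
  a <- generate_synthetic_subject(p, tf, cm, n_trials = 20, wait = 0.3)
  set.seed(74)
  b <- generate_synthetic_subject(p, tf, cm, n_trials = 20, wait = 0.3)
  expect_identical(a$trials, b$trials)
  expect_identical(a$lum, b$lum)
})

test_that("decision merit decomposes and ranks parameters sensibly", {
  p <- small_params()
  tf <- default_transform()
  cm <- confidence_map()
  cfg <- merit_config(n_sim = 60, wait = 0.3)
  set.seed(75)
  target <- generate_synthetic_subject(p, tf, cm, n_trials = 150,
                                       wait = 0.3)
  m_true <- decision_merit(tf$g, tf$b, target, cfg, p, seed = 7)
  comp <- attr(m_true, "components")
  expect_equal(as.numeric(m_true), sum(comp))
  expect_named(comp, c("lsq", "chi2", "early", "undecided"))
  # a blind network (g = 0) fits far worse than the truth
  m_blind <- decision_merit(0, tf$b, target, cfg, p, seed = 7)
  expect_gt(as.numeric(m_blind), as.numeric(m_true))
  # undecided penalty is linear with its coefficient
  cfg <- merit_config(n_sim = 60, wait = 0.3, pen_undecided = 1)
  m_blind <- decision_merit(0, tf$b, target, cfg, p, seed = 7)
  cfg2 <- merit_config(n_sim = 60, wait = 0.3, pen_undecided = 5)
  m_pen <- decision_merit(0, tf$b, target, cfg2, p, seed = 7)
  c1 <- attr(m_blind, "components")
  c2 <- attr(m_pen, "components")
  expect_equal(c2[["undecided"]], 5 * c1[["undecided"]])
  if (c1[["undecided"]] > 0) expect_gt(as.numeric(m_pen),
                                       as.numeric(m_blind))
})

test_that("confidence merit equals the chi-squared of its own counts", {
  p <- small_params()
  tf <- default_transform()
  cm <- confidence_map()
  set.seed(76)
  target <- generate_synthetic_subject(p, tf, cm, n_trials = 200,
                                       wait = 0.3)
  pool <- target$trials[!target$trials$undecided, ]
  m <- confidence_merit(cm$slope_a, cm$center_c, target, pool, seed = 9)
  counts <- attr(m, "counts")
  n <- sum(counts)
  pr <- pmax(counts / n, 0.5 / n)
  pr <- pr / sum(pr)
  expect_equal(as.numeric(m),
               pearson_chi2(confidence_table(target$trials), pr))
  # a degenerate all-low sigmoid fits much worse
  m_bad <- confidence_merit(cm$slope_a, 5, target, pool, seed = 9)
  expect_gt(as.numeric(m_bad), as.numeric(m))
})
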