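simple_trace <- function(rates_a, rates_b, dt = 0.01) {
  n_t <- nrow(rates_a); n_m <- ncol(rates_a)
  grid <- expand.grid(option = c("A", "B"), module = seq_len(n_m),
                      t = seq_len(n_t))
  tibble::tibble(
    time = grid$t * dt,
    module = grid$module,
    option = as.character(grid$option),
    rate = ifelse(grid$option == "A",
                  rates_a[cbind(grid$t, grid$module)],
                  rates_b[cbind(grid$t, grid$module)])
  )
}

test_that("votes latch at the first threshold crossing with the stated ties", {
  # module 1: A crosses at step 3; module 2: never crosses;
  # module 3: both cross at step 2, B higher; module 4: both cross, equal
  ra <- cbind(c(5, 10, 16, 30), c(5, 6, 7, 8), c(5, 16, 20, 20),
              c(5, 17, 20, 20))
  rb <- cbind(c(5, 5, 5, 5), c(5, 6, 7, 8), c(5, 18, 10, 10),
              c(5, 17, 10, 10))
  votes <- detect_votes(simple_trace(ra, rb), lambda_thr = 15)
  expect_identical(nrow(votes), 3L)
  expect_identical(votes$option[votes$module == 1], "A")
  expect_equal(votes$vote_time[votes$module == 1], 0.03)
  expect_false(2 %in% votes$module)
  expect_identical(votes$option[votes$module == 3], "B")
  expect_identical(votes$option[votes$module == 4], "A")  # tie goes to A
})

test_that("strict majority rule picks the earliest winning vote", {
  # N = 100: the 51st A vote lands at 0.8 s
  v <- tibble::tibble(option = rep(c("A", "B"), c(51, 30)),
                      vote_time = c(seq(0.3, 0.8, length.out = 51),
                                    seq(0.2, 0.9, length.out = 30)))
  gd <- global_decision(v, 100)
  expect_identical(gd$choice, "A")
  expect_equal(gd$rt, 0.8)
  # N = 2 split 1-1 can never reach a strict majority
  v2 <- tibble::tibble(option = c("A", "B"), vote_time = c(0.1, 0.2))
  expect_identical(global_decision(v2, 2)$choice, NA_character_)
  # N = 3, votes A 0.3, B 0.4, A 0.5 -> A at 0.5
  v3 <- tibble::tibble(option = c("A", "B", "A"),
                       vote_time = c(0.3, 0.4, 0.5))
  gd3 <- global_decision(v3, 3)
  expect_identical(gd3$choice, "A")
  expect_equal(gd3$rt, 0.5)
})

test_that("majority rule agrees with a brute-force scan on random vote sets", {
  brute <- function(votes, n) {
    ts <- sort(unique(votes$vote_time))
    for (t in ts) {
      na <- sum(votes$option == "A" & votes$vote_time <= t)
      nb <- sum(votes$option == "B" & votes$vote_time <= t)
      if (na > n / 2) return(list(choice = "A", rt = t))
      if (nb > n / 2) return(list(choice = "B", rt = t))
    }
    list(choice = NA_character_, rt = NA_real_)
  }
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:9, 1)
    k <- sample.int(n, 1)
    votes <- tibble::tibble(option = sample(c("A", "B"), k, replace = TRUE),
                            vote_time = round(runif(k), 2))
    got <- global_decision(votes, n)
    want <- brute(votes, n)
    expect_identical(got$choice, want$choice)
    expect_equal(got$rt, want$rt)
  }
})

test_that("dispersion and FMC follow their stated conventions", {
  rates <- cbind(A = c(10, 20), B = c(1, 1))
  expect_equal(sigma_dv(rates, "A"), 5)  # population SD
  expect_equal(sigma_dv(cbind(A = rep(7, 5), B = rep(1, 5)), "A"), 0)
  expect_warning(s1 <- sigma_dv(matrix(c(10, 2), 1), "A"), "single module")
  expect_equal(s1, 0)
  # half-open window [lambda, lambda + delta)
  r4 <- cbind(A = c(14.9, 15.0, 19.99, 20.0), B = rep(0, 4))
  expect_equal(fmc(r4, "A", 15, 5), 0.5)
  expect_equal(fmc(cbind(A = c(15, 16, 19.9), B = rep(0, 3)), "A", 15, 5), 1)
})

test_that("confidence sigmoid has the right midpoint, limits and rates", {
  m <- confidence_map(slope_a = 0.05, center_c = 0.3, input_kind = "fmc")
  expect_equal(confidence_prob(0.3, m), 0.5)
  # steep slope approaches a step
  ms <- confidence_map(slope_a = 1e-9, center_c = 0.3)
  expect_equal(confidence_prob(0.31, ms), 1)
  expect_equal(confidence_prob(0.29, ms), 0)
  # sigma_dv input flips the direction: larger dispersion, lower confidence
  md <- confidence_map(slope_a = 1, center_c = 5, input_kind = "sigma_dv")
  expect_gt(confidence_prob(3, md), confidence_prob(7, md))
  # empirical high-rate matches p(x) within a binomial 99% CI
  set.seed(41)
  x <- 0.27
  p_true <- confidence_prob(x, m)
  draws <- confidence_sample(rep(x, 1e4), m)
  ci <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / 1e4)
  expect_lt(abs(mean(draws == "high") - p_true), ci * 1.2)
})

test_that("trace-based readout agrees with the compiled core's votes", {
  p <- small_params()
  set.seed(51)
  stim <- quick_stim(mean_target = 62, duration = 1.5)
  tr <- simulate_trial(p, stim, default_transform(), record_stride = 1L)
  votes_r <- detect_votes(tr$trace, p$lambda_thr)
  merged <- dplyr::inner_join(votes_r, tr$votes, by = "module",
                              suffix = c("_r", "_cpp"))
  expect_identical(merged$option_r, merged$option_cpp)
  expect_equal(merged$vote_time_r, merged$vote_time_cpp, tolerance = 1e-12)
  # the R-side majority rule reproduces the compiled decision
  gd <- global_decision(votes_r, p$n_modules)
  expect_identical(gd$choice, tr$result$choice)
  if (!is.na(gd$choice)) expect_equal(gd$rt, tr$result$rt)
})
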