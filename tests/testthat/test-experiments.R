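test_that("the combinatorial guessing formula matches exhaustive enumeration", {
  # printed single-item baselines: 50% with two stripes, 33% with three
  expect_equal(guess_probability(2, 1), 0.5)
  expect_equal(guess_probability(3, 1), 1 / 3)
  # two items, two stripes: 2^2 assignments x 2 readout choices, 2 successes
  expect_equal(guess_probability(2, 2), 0.25)
  for (n in 1:4) {
    for (N in 1:3) {
      expect_equal(guess_probability(n, N), enumerate_gating_success(n, N),
                   info = sprintf("n=%d N=%d", n, N))
    }
  }
})

test_that("the error-mixture fit recovers known guess mass and precision", {
  set.seed(42)
  gen <- function(n, w, sd) {
    guess <- runif(n) < w
    e <- numeric(n)
    e[guess] <- runif(sum(guess), -180, 180)
    e[!guess] <- rnorm(sum(!guess), 0, sd)
    e[e > 180] <- e[e > 180] - 360
    e[e <= -180] <- e[e <= -180] + 360
    e
  }
  for (w in c(0.2, 0.6)) {
    fit <- fit_error_mixture(gen(4000, w, 15))
    expect_lt(abs(fit$guess_weight - w), 0.06)
    expect_lt(abs(fit$sd_deg - 15), 2)
  }
  # pure point mass: guess weight near zero
  fit0 <- fit_error_mixture(rnorm(2000, 0, 8))
  expect_lt(fit0$guess_weight, 0.05)
  # pure guessing: guess weight near one
  fit1 <- fit_error_mixture(runif(2000, -179.999, 180))
  expect_gt(fit1$guess_weight, 0.9)
})

test_that("training is deterministic given the seed", {
  cfg <- run_config(model = "chunk", set_size = 2, epochs = 3,
                    trials_per_epoch = 15, eval_episodes = 5)
  a <- train_network(cfg, 7)
  b <- train_network(cfg, 7)
  expect_identical(a$epoch_log, b$epoch_log)
  expect_identical(a$net$go_in, b$net$go_in)
  expect_identical(a$net$w_direct, b$net$w_direct)
  eva <- evaluate_network(a, 10, seed = 5)
  evb <- evaluate_network(b, 10, seed = 5)
  expect_identical(eva, evb)
})

test_that("with zero learning rates recall performance stays at chance", {
  p <- pbwm_params(lrate_go = 0, lrate_nogo = 0, lrate_out = 0, alpha_v = 0)
  cfg <- run_config(model = "no_chunk", set_size = 2, epochs = 6,
                    trials_per_epoch = 99, eval_episodes = 200, params = p)
  fit <- train_network(cfg, 11)
  ev <- evaluate_network(fit, 400, seed = 2)
  # mean absolute error of a guesser is 90 degrees
  expect_gt(mean(ev$abs_err), 75)
  # and the error histogram is consistent with uniform guessing
  counts <- graphics::hist(ev$error_deg, breaks = seq(-180, 180, by = 45),
                           plot = FALSE)$counts
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("analysis helpers aggregate logs correctly", {
  log <- data.frame(error_deg = c(0, 10, -170, 20),
                    abs_err = c(0, 10, 170, 20),
                    non_response = c(FALSE, FALSE, TRUE, FALSE),
                    n_out_gated = c(1, 2, 0, 1),
                    lag = c(1, 2, 2, 1),
                    ocv = c(10, 10, 50, 50),
                    max_load = TRUE,
                    n_occupied = c(2, 2, 1, 2),
                    all_occupied = c(TRUE, TRUE, FALSE, TRUE),
                    occ.1 = c(1, 1, 1, 1), occ.2 = c(1, 1, 0, 1))
  su <- stripe_usage(log)
  expect_equal(su$all_occupied_rate, 0.75)
  expect_equal(su$empty_stripe_rate, 0.25)
  expect_equal(unname(su$per_stripe), c(1, 0.75))
  rc <- recency_curve(log)
  expect_equal(rc$mean_abs_err[rc$lag == 1], 10)
  expect_equal(rc$mean_abs_err[rc$lag == 2], 90)
  ob <- ocv_binned_error(log, breaks = c(0, 30, 60))
  expect_equal(ob$mean_abs_err[ob$ocv_mid == 15], 5)
  expect_equal(ob$mean_abs_err[ob$ocv_mid == 45], 95)
})
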