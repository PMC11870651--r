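test_that("reward is linear in error with a sign change at the closeness threshold", {
  expect_equal(compute_reward(1, 1), 1)
  expect_equal(compute_reward(pi, 0), 1 - 180 / 45)
  # exactly at the 45-degree threshold the reward crosses zero
  expect_equal(compute_reward(45 * pi / 180, 0), 0)
  expect_lt(compute_reward(46 * pi / 180, 0), 0)
  expect_gt(compute_reward(44 * pi / 180, 0), 0)
})

test_that("the Rescorla-Wagner critic converges to the mean reward", {
  expect_equal(rpe(0.5, 0.5)$delta, 0)
  expect_equal(rpe(1, 0)$delta, 1)
  V <- 0
  for (i in 1:500) V <- rpe(0.7, V, alpha_v = 0.05)$V
  expect_equal(V, 0.7, tolerance = 1e-4)
  # under iid rewards the estimate lands within 0.05 of the expectation
  set.seed(5)
  V <- 0
  r <- rbinom(500, 1, 0.3)
  for (i in seq_along(r)) V <- rpe(r[i], V, alpha_v = 0.05)$V
  expect_lt(abs(V - 0.3), 0.05)
})

test_that("dopamine gains scale bursts and dips independently", {
  expect_equal(da_modulate(0), 0)
  expect_equal(da_modulate(0.5, burst_gain = 0.6, dip_gain = 1.2), 0.3)
  expect_equal(da_modulate(-0.5, burst_gain = 0.6, dip_gain = 1.2), -0.6)
})

test_that("striatal plasticity respects the sign contract on every synapse", {
  set.seed(31)
  for (k in 1:30) {
    go <- matrix(runif(12, 0.2, 0.8), 4, 3)
    nogo <- matrix(runif(12, 0.2, 0.8), 4, 3)
    tags <- matrix(runif(12) * rbinom(12, 1, 0.5), 4, 3)
    eff <- runif(1, -2, 2)
    upd <- update_striatal(go, nogo, tags, eff)
    dgo <- upd$go - go; dnogo <- upd$nogo - nogo
    tagged <- tags > 0
    if (eff > 0) {
      expect_true(all(dgo[tagged] > 0))
      expect_true(all(dnogo[tagged] < 0))
    } else if (eff < 0) {
      expect_true(all(dgo[tagged] < 0))
      expect_true(all(dnogo[tagged] > 0))
    }
    expect_true(all(dgo[!tagged] == 0))
    expect_true(all(dnogo[!tagged] == 0))
    expect_true(all(upd$go >= 0 & upd$go <= 1))
    expect_true(all(upd$nogo >= 0 & upd$nogo <= 1))
  }
})

test_that("weights stay inside [0, 1] even under extreme updates", {
  go <- matrix(0.99, 2, 2); nogo <- matrix(0.01, 2, 2)
  tags <- matrix(1, 2, 2)
  upd <- update_striatal(go, nogo, tags, eff_delta = 100)
  expect_true(all(upd$go == 1))
  expect_true(all(upd$nogo == 0))
  upd2 <- update_striatal(go, nogo, tags, eff_delta = -100)
  expect_true(all(upd2$go == 0))
  expect_true(all(upd2$nogo == 1))
})

test_that("gating-policy metric is the rectified normalized contrast", {
  go <- matrix(0, 6, 2); nogo <- matrix(0, 6, 2)
  ori <- 1:4
  # equal Go and NoGo sums give zero
  go[ori, 1] <- 0.5; nogo[ori, 1] <- 0.5
  # Go 3 vs NoGo 1 gives (3-1)/(3+1) = 0.5
  go[ori, 2] <- 0.75; nogo[ori, 2] <- 0.25
  expect_equal(gating_policy_metric(go, nogo, ori), c(0, 0.5))
  # more NoGo than Go rectifies to zero
  go[ori, 1] <- 0.1; nogo[ori, 1] <- 0.9
  expect_equal(gating_policy_metric(go, nogo, ori)[1], 0)
  # all-zero weights define alpha as zero rather than 0/0
  expect_equal(gating_policy_metric(matrix(0, 6, 1), matrix(0, 6, 1), ori), 0)
  # range is always [0, 1]
  set.seed(13)
  for (k in 1:20) {
    g <- matrix(runif(12), 6, 2); n <- matrix(runif(12), 6, 2)
    a <- gating_policy_metric(g, n, ori)
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("tags decay multiplicatively and clear to zero", {
  tags <- matrix(c(1, 0.5, 0, 2), 2, 2)
  expect_equal(decay_tags(tags, 0.9), tags * 0.9)
  expect_equal(decay_tags(tags, 0), tags * 0)
})
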