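test_that("net excitation averages sender activity times weight across projections", {
  # all-zero senders drive nothing
  pr <- projection(matrix(1, 3, 2))
  expect_equal(net_excitation(c(0, 0, 0), pr), c(0, 0))
  # saturated senders through unit weights give exactly 1 (the rule is a mean)
  expect_equal(net_excitation(c(1, 1, 1), pr), c(1, 1))
  # hand-evaluated mean: (1*0.2 + 0.5*0.8) / 2 = 0.3
  w <- matrix(c(0.2, 0.8), 2, 1)
  expect_equal(net_excitation(c(1, 0.5), projection(w)), 0.3)
  # two converging projections combine as a rel_scale-weighted average
  p1 <- projection(matrix(1, 2, 1), rel_scale = 1)
  p2 <- projection(matrix(1, 2, 1), rel_scale = 0.5)
  ge <- net_excitation(list(c(1, 1), c(0, 0)), list(p1, p2))
  expect_equal(ge, 1 / 1.5)
  expect_error(net_excitation(c(1, 0.5, 0.2), projection(w)), "sender activities")
})

test_that("membrane potential steps toward and stays at the conductance-weighted equilibrium", {
  up <- unit_params()
  # at the equilibrium the derivative vanishes
  veq <- vm_equilibrium(ge = 0.4, gi = 0.2, up)
  expect_equal(step_membrane(veq, 0.4, 0.2, up), veq)
  # leak-only dynamics converge to the leak reversal
  vm <- 0.9
  for (i in 1:800) vm <- step_membrane(vm, 0, 0, up)
  expect_equal(vm, up$E_l, tolerance = 1e-6)
  # one hand-evaluated Euler step
  vm0 <- 0.35; ge <- 0.25; gi <- 0.1; dt <- 0.3
  expected <- vm0 + dt * (ge * 1 * (1 - vm0) + gi * 1 * (0.25 - vm0) +
                            0.1 * (0.3 - vm0))
  expect_equal(step_membrane(vm0, ge, gi, up, dt = dt), expected)
})

test_that("membrane potential is bounded by the reversal potentials for any inputs", {
  up <- unit_params()
  set.seed(11)
  for (k in 1:50) {
    vm <- runif(1, up$E_i, up$E_e)
    ge <- runif(1, 0, 1); gi <- runif(1, 0, 2)
    for (i in 1:200) vm <- step_membrane(vm, ge, gi, up)
    expect_gte(vm, min(up$E_i, up$E_l) - 1e-9)
    expect_lte(vm, up$E_e + 1e-9)
  }
})

test_that("rate activation is thresholded, saturating, and monotone", {
  up <- unit_params()
  gt <- ge_theta(gi = 0.2, up)
  # exactly at threshold conductance the rate is zero
  expect_equal(unit_activation(gt, 0.2, up), 0)
  expect_equal(unit_activation(gt * 0.5, 0.2, up), 0)
  # algebraically forced half-activation point: gamma * (ge - ge_theta) = 1
  expect_equal(unit_activation(gt + 1 / up$gamma, 0.2, up), 0.5)
  # saturation toward (but below) 1
  expect_lt(unit_activation(1e6, 0.2, up), 1)
  expect_gt(unit_activation(1e6, 0.2, up), 0.999)
  # monotone nondecreasing in ge, nonincreasing in gi
  ges <- seq(0, 1, by = 0.02)
  ys <- unit_activation(ges, 0.2, up)
  expect_true(all(diff(ys) >= 0))
  gis <- seq(0, 1, by = 0.02)
  ys2 <- unit_activation(0.4, gis, up)
  expect_true(all(diff(ys2) <= 0))
})

test_that("FFFB inhibition is zero for silent layers and scale-monotone", {
  ip <- inhib_params(Gi = 1.8, ff_gain = 1, fb_gain = 0.5, ff_floor = 0.01)
  expect_equal(fffb_inhibition(rep(0, 10), rep(0, 10), ip), 0)
  # hand-evaluated: gi = Gi * (ff_gain*(mean(net) - floor) + fb_gain*mean(act))
  gi <- fffb_inhibition(rep(0.2, 10), rep(0.5, 10), ip)
  expect_equal(gi, 1.8 * (1 * (0.2 - 0.01) + 0.5 * 0.5))
  # doubling net input never decreases gi
  set.seed(4)
  for (k in 1:20) {
    x <- runif(8); y <- runif(8)
    expect_gte(fffb_inhibition(2 * x, y, ip), fffb_inhibition(x, y, ip))
    expect_gte(fffb_inhibition(x, 2 * y, ip), fffb_inhibition(x, y, ip))
  }
})

test_that("settle reaches a fixed point and is idempotent", {
  # silent inputs settle to silence
  K <- ring_kernel()
  pr <- projection(K)
  out0 <- settle(list(rep(0, 20)), list(pr))
  expect_equal(out0$y, rep(0, 20))
  expect_true(out0$converged)
  # a clamped bump drives a settled bump with the peak unit clearly active
  bump <- encode_color(pi)
  out <- settle(list(bump), list(pr), inhib = inhib_params(Gi = 2),
                n_cycles = 100)
  expect_true(out$converged)
  expect_gt(max(out$y), 0.5)
  expect_equal(which.max(out$y), which.max(bump))
  # re-settling from the fixed point changes nothing beyond tolerance:
  # run again with more cycles and compare
  out2 <- settle(list(bump), list(pr), inhib = inhib_params(Gi = 2),
                 n_cycles = 200)
  expect_equal(out$y, out2$y, tolerance = 1e-3)
})
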