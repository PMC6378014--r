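# Cytokine pools, macrophage polarization and onset detection.

test_that("cytokine decay is exactly geometric without sources", {
  ip <- inflammation_params()
  f <- cytokine_field(pro = 100, anti = 50, decay = 0.1)
  f1 <- secrete_cytokines(f, n_super = 0, p_a = 0, m1 = 0, m2 = 0, ip)
  expect_equal(f1$pro, 90)
  expect_equal(f1$anti, 45)
  for (i in 1:20) f1 <- secrete_cytokines(f1, 0, 0, 0, 0, ip)
  expect_equal(f1$pro, 100 * 0.9^21, tolerance = 1e-12)
  expect_true(f1$pro >= 0 && f1$anti >= 0)
})

test_that("a constant source reaches the closed-form fixed point S/decay", {
  # source S = s_adipo * p_a * n_super per step; geometric series limit
  ip <- inflammation_params(s_adipo = 2, decay = 0.2)
  S <- 2 * 0.5 * 30
  f <- cytokine_field(decay = 0.2)
  for (i in 1:400)
    f <- secrete_cytokines(f, n_super = 30, p_a = 0.5, m1 = 0, m2 = 0, ip)
  expect_equal(f$pro, S / 0.2, tolerance = 1e-6)
  expect_error(inflammation_params(s_adipo = -1), "non-negative")
})

test_that("no sources means the pro pool stays at zero", {
  ip <- inflammation_params()
  f <- cytokine_field()
  for (i in 1:10) f <- secrete_cytokines(f, 0, 0, 0, 0, ip)
  expect_equal(f$pro, 0)
  expect_equal(f$anti, 0)
})

test_that("polarization conserves macrophage count and respects signals", {
  ip <- inflammation_params()
  states <- rep.int(0L, 200)
  # no cytokines: the baseline switch probability is negligible
  set.seed(1)
  f0 <- cytokine_field()
  for (i in 1:100) states <- polarize_macrophages(states, f0, ip)
  expect_equal(sum(states != 0L), 0L)
  expect_length(states, 200)
  # saturating pro signal: every M0 switches to M1 in one step
  f_hi <- cytokine_field(pro = 1e12)
  states <- polarize_macrophages(rep.int(0L, 200), f_hi, ip)
  expect_true(mean(states == 1L) > 0.99)
  expect_length(states, 200)
})

test_that("M1 occupancy matches the two-state Markov stationary law", {
  # constant pro field: M0 <-> M1 with switch probability p and reversion r
  # has stationary M1 fraction p / (p + r); simulate and compare
  ip <- inflammation_params(gain = 1, bias = -4, revert = 0.02)
  f <- cytokine_field(pro = 10^2.5 - 1)       # switch prob = 0.5(1+tanh(-1.5))
  p_switch <- 0.5 * (1 + tanh(1 * 2.5 - 4))
  expected <- p_switch / (p_switch + 0.02)
  states <- rep.int(0L, 500)
  set.seed(33)
  frac <- numeric(3000)
  for (i in seq_along(frac)) {
    states <- polarize_macrophages(states, f, ip)
    frac[i] <- mean(states == 1L)
  }
  expect_lt(abs(mean(frac[-(1:500)]) - expected), 0.02)
})

test_that("onset detection finds the first sustained window", {
  expect_equal(detect_onset(rep(0, 100), 0.5, 30),
               list(time = 99L, event = 0L))
  expect_equal(detect_onset(rep(1, 100), 0.5, 30),
               list(time = 0L, event = 1L))
  s <- c(0, 0, 0.6, 0.6, 0.4, 0.6, 0.6, 0.6)
  expect_equal(detect_onset(s, 0.5, 3), list(time = 5L, event = 1L))
  expect_error(detect_onset(numeric(0)), "empty")
  expect_error(detect_onset(rep(0.1, 10), threshold = 1.5), "threshold")
})

test_that("onset detection agrees with a brute-force window scan", {
  brute <- function(x, thr, per) {
    n <- length(x)
    if (n >= per) {
      for (d in 0:(n - per)) {
        if (all(x[(d + 1):(d + per)] >= thr)) return(list(time = d, event = 1L))
      }
    }
    list(time = n - 1L, event = 0L)
  }
  set.seed(99)
  for (i in 1:50) {
    x <- runif(sample(5:60, 1))
    thr <- runif(1, 0.2, 0.8)
    per <- sample(1:10, 1)
    got <- detect_onset(x, thr, per)
    want <- brute(x, thr, per)
    expect_equal(got$time, as.integer(want$time))
    expect_equal(got$event, want$event)
  }
})

test_that("positive M1 feedback raises the inflammatory steady state", {
  # with a marginal adipocyte source, the M1 secretion term pushes the pro
  # pool over the switch midpoint; without it the M1 pool stays low
  run_case <- function(s_m1) {
    ip <- inflammation_params(s_m1 = s_m1)
    f <- cytokine_field()
    states <- rep.int(0L, 100)
    set.seed(17)
    for (i in 1:8000) {
      f <- secrete_cytokines(f, n_super = 2000, p_a = 0.88,
                             m1 = sum(states == 1L), m2 = sum(states == 2L), ip)
      states <- polarize_macrophages(states, f, ip)
    }
    mean(states == 1L)
  }
  expect_gt(run_case(20), run_case(0) + 0.2)
})
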