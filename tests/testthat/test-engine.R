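# Engine: diet scheduling, the step loop, replicate management,
# reproducibility.

test_that("weekly on/off mask applies surplus on the right days", {
  p <- diet_protocol(1004, days_on_per_week = 6, duration_days = 100)
  e <- effective_energy(p, 1:100)
  # repeating 7-day mask, day 7 of each block off
  expect_equal(which(e == 0), seq(7, 100, by = 7))
  expect_equal(sum(e > 0), 86)
  p7 <- diet_protocol(1506, 7, 42)
  expect_true(all(effective_energy(p7, 1:42) == 1506))
  expect_error(diet_protocol(100, 0, 10), "days_on_per_week")
})

test_that("the realized on-day count is recorded in the trajectory", {
  tr <- run_simulation(tremblay_subject(), diet_protocol(1004, 6, 14),
                       fast_control(), seed = 1)
  expect_equal(attr(tr, "on_days"), 12L)
})

test_that("a zero-duration run returns only the initial record", {
  tr <- run_simulation(diaz_subject(), diet_protocol(1506, 7, 0),
                       fast_control(), seed = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$bw_kg, 73.7)
  expect_equal(tr$day, 0)
})

test_that("runs are bit-identical for the same seed and differ across seeds", {
  p <- diet_protocol(1506, 7, 10)
  a <- run_simulation(diaz_subject(), p, fast_control(), seed = 42)
  b <- run_simulation(diaz_subject(), p, fast_control(), seed = 42)
  expect_identical(a, b)
  c <- run_simulation(diaz_subject(), p, fast_control(), seed = 43)
  expect_false(identical(a$v_total_ul, c$v_total_ul))
})

test_that("trajectories start at the subject weight and record daily", {
  tr <- run_simulation(diaz_subject(), diet_protocol(1506, 7, 15),
                       fast_control(), seed = 3)
  expect_equal(nrow(tr), 16L)
  expect_equal(tr$day, 0:15)
  expect_equal(tr$bw_kg[1], 73.7)
  # cell count never decreases (no adipocyte death in the model)
  expect_true(all(diff(tr$n_cells) >= 0))
  # internal consistency of the recorded population columns
  expect_equal(tr$v_mean_ul, tr$v_total_ul / tr$n_cells, tolerance = 1e-12)
  # macrophage counts always partition the pool
  nm <- fast_control()$inflammation$n_macrophages
  expect_true(all(tr$m0 + tr$m1 + tr$m2 == nm))
})

test_that("replicate summaries average the individual trajectories", {
  fit <- adiposim(diaz_subject(), diet_protocol(1506, 7, 8),
                  replicates = 3, seed = 5, control = fast_control())
  expect_length(fit$trajectories, 3)
  bw <- sapply(fit$trajectories, `[[`, "bw_kg")
  expect_equal(fit$summary$bw_mean, rowMeans(bw), tolerance = 1e-12)
  expect_equal(fit$summary$bw_sd, apply(bw, 1, sd), tolerance = 1e-12)
  expect_true(all(fit$summary$bw_sd >= 0))
  # replicates = 1: the summary is the single trajectory
  f1 <- adiposim(diaz_subject(), diet_protocol(1506, 7, 5),
                 replicates = 1, seed = 5, control = fast_control())
  expect_equal(f1$summary$bw_mean, f1$trajectories[[1]]$bw_kg)
  expect_equal(f1$summary$bw_sd, rep(0, 6))
})

test_that("weight trajectories are ordered by surplus energy", {
  subj <- lean_subject()
  fits <- lapply(c(500, 1500), function(E) {
    adiposim(subj, diet_protocol(E, 7, 60), replicates = 3, seed = 7,
             control = fast_control())
  })
  lo <- fits[[1]]$summary$bw_mean
  hi <- fits[[2]]$summary$bw_mean
  expect_true(all(hi[-(1:7)] >= lo[-(1:7)]))
})

test_that("fit object methods work", {
  fit <- adiposim(diaz_subject(), diet_protocol(1506, 7, 6),
                  replicates = 2, seed = 1, control = fast_control())
  expect_output(print(fit), "Adipose-tissue simulation")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.adiposim")
  expect_output(print(sm), "weight gain")
  cf <- coef(fit)
  expect_equal(unname(cf["k1"]), 4)
  expect_equal(unname(cf["v0"]), 8.181e-6)
  fit2 <- simulate(fit, nsim = 2)
  expect_s3_class(fit2, "adiposim")
  expect_equal(fit2$seed, fit$seed + fit$replicates)
  ot <- onset_table(fit)
  expect_equal(nrow(ot), 2)
  expect_true(all(ot$event_flag %in% 0:1))
})
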