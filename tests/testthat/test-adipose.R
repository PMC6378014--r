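# Stochastic adipocyte dynamics: swelling factor/probability, adipogenesis
# probability, population initialisation, volume updates and recruitment.

test_that("swelling factor is the relative distance from critical volume", {
  vc <- sphere_volume(120)
  expect_equal(swelling_factor(vc, vc), 0)
  expect_equal(swelling_factor(2 * vc, vc), -1)
  # a cell at the first study subject's initial size
  expect_equal(swelling_factor(sphere_volume(96.96), vc), 0.472485888,
               tolerance = 1e-8)
})

test_that("swelling probability matches the tanh switch and is monotone", {
  expect_equal(swelling_probability(0), 0.98201379, tolerance = 1e-8)
  expect_equal(swelling_probability(-1), 0.01798621, tolerance = 1e-8)
  expect_equal(swelling_probability(c(-5, 0, 7), k1 = 0, k2 = 0),
               rep(0.5, 3))
  theta <- seq(-3, 3, by = 0.05)
  p <- swelling_probability(theta)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))  # increasing in theta = decreasing in volume
})

test_that("adipogenesis probability is zero at zeta 0 and saturates", {
  # exact zero by oddness of tanh at the default k6 = -1
  expect_equal(adipogenesis_probability(0), 0)
  expect_equal(adipogenesis_probability(1), 0.8804617278, tolerance = 1e-8)
  expect_equal(adipogenesis_probability(0.2), 0.380797078, tolerance = 1e-8)
  z <- seq(0, 1, by = 0.02)
  p <- adipogenesis_probability(z)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  # stays a probability when parameters leave the default regime
  expect_true(all(adipogenesis_probability(z, k5 = 50, k6 = 5) <= 1))
  expect_true(all(adipogenesis_probability(z, k5 = 1, k6 = -30) >= 0))
  expect_error(adipogenesis_probability(1.5), "zeta")
})

test_that("probability functions stay within [0,1] over parameter grids", {
  set.seed(7)
  for (i in 1:200) {
    ps <- swelling_probability(runif(1, -10, 10), k1 = runif(1, 0, 20),
                               k2 = runif(1, -10, 10))
    pa <- adipogenesis_probability(runif(1), k5 = runif(1, 0, 20),
                                   k6 = runif(1, -10, 10))
    expect_true(ps >= 0 && ps <= 1)
    expect_true(pa >= 0 && pa <= 1)
  }
})

test_that("initial population matches the subject's anthropometry", {
  gp <- growth_params(gender = "male")
  set.seed(5)
  pop <- init_population(diaz_subject(), gp, sim_volume = 1)
  n0 <- length(pop$volumes)
  expect_equal(n0, 2095)  # 1 uL / sphere_volume(96.96 um)
  d <- sphere_diameter(pop$volumes)
  expect_equal(mean(d), adipocyte_diameter(bmi(diaz_subject()), "male"),
               tolerance = 0.02)
  expect_true(all(pop$volumes >= gp$v0))
  # doubling the simulated volume doubles the cell count (+/- rounding)
  set.seed(5)
  pop2 <- init_population(diaz_subject(), gp, sim_volume = 2)
  expect_lte(abs(length(pop2$volumes) - 2L * n0), 1L)
  expect_warning(init_population(diaz_subject(), gp, sim_volume = 1e-3),
                 "cells")
})

test_that("volume update is inert with zero energy and zero noise", {
  gp <- noiseless_growth()
  set.seed(2)
  pop <- init_population(diaz_subject(), gp, 1)
  v_before <- pop$volumes
  set.seed(3)
  pop <- update_volumes(pop, E = 0, gp)
  expect_identical(pop$volumes, v_before)
})

test_that("no cell ever falls below the baseline volume", {
  gp <- growth_params(gender = "male")
  set.seed(11)
  pop <- init_population(lean_subject(), gp, 0.05)
  # adversarial energy sequence: strong negative, alternating, zero
  E_seq <- c(rep(-5000, 30), rep(c(-2000, 1500), 15), rep(0, 10),
             rep(-1e5, 10))
  for (E in E_seq) {
    pop <- update_volumes(pop, E, gp)
    expect_true(all(pop$volumes >= gp$v0))
  }
})

test_that("a cell at the floor stays there under sustained deficit", {
  gp <- noiseless_growth()
  pop <- structure(list(volumes = rep(gp$v0, 20), v0 = gp$v0, v_c = gp$v_c,
                        sim_volume = 1), class = "adipocyte_population")
  set.seed(4)
  for (i in 1:50) pop <- update_volumes(pop, -2000, gp)
  expect_identical(pop$volumes, rep(gp$v0, 20))
})

test_that("supercritical fraction counts cells above critical volume", {
  vc <- sphere_volume(120)
  pop <- structure(list(volumes = vc * c(0.5, 1.1, 1.2, 0.9), v0 = 8.181e-6,
                        v_c = vc, sim_volume = 1),
                   class = "adipocyte_population")
  expect_equal(supercritical_fraction(pop), 0.5)
  pop$volumes <- vc * c(0.1, 0.2, 0.3)
  expect_equal(supercritical_fraction(pop), 0)
  pop$volumes <- vc * c(1.1, 1.2, 1.3)
  expect_equal(supercritical_fraction(pop), 1)
})

test_that("recruitment adds round(V) cells at baseline volume", {
  gp <- growth_params(gender = "male")
  set.seed(8)
  pop <- init_population(diaz_subject(), gp, 1)
  n0 <- length(pop$volumes)
  v_tot <- sum(pop$volumes)
  pop0 <- recruit_adipocytes(pop, p_a = 0)
  expect_identical(pop0$volumes, pop$volumes)
  pop1 <- recruit_adipocytes(pop, p_a = 1)
  k <- round(v_tot)
  expect_equal(length(pop1$volumes), n0 + k)
  expect_equal(pop1$volumes[(n0 + 1):(n0 + k)], rep(gp$v0, k))
  # total volume grows by exactly the recruited baseline volumes
  expect_equal(sum(pop1$volumes), v_tot + k * gp$v0, tolerance = 1e-12)
  expect_error(recruit_adipocytes(pop, 1.5), "p_a")
})

test_that("mean volume stays bounded under sustained large surplus", {
  # the swelling probability collapses near twice the critical volume, so
  # even an extreme diet cannot push the population mean past 2 v_c
  gp <- growth_params(gender = "male")
  set.seed(9)
  tr <- run_simulation(lean_subject(), diet_protocol(3000, 7, 365),
                       fast_control(), seed = 9)
  expect_true(all(tr$v_mean_ul < 2 * gp$v_c))
})
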