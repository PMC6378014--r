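# The adipocyte population: initial size distribution, stochastic swelling
# under caloric surplus, and recruitment of new cells (adipogenesis).
#
# The population is stored as a plain numeric vector of cell volumes (uL)
# wrapped in a light list so the step loop stays vectorised.

#' Swelling factor
#'
#' Relative distance of a cell volume from the critical volume:
#' \eqn{\vartheta = 1 - v/v_c}. Positive below the critical size, zero at
#' \eqn{v = v_c}, negative above.
#'
#' @param v Cell volume(s), uL (> 0).
#' @param v_c Critical volume, uL (> 0).
#' @return Dimensionless swelling factor, same length as `v`.
#' @export
swelling_factor <- function(v, v_c) {
  stopifnot(all(v > 0), v_c > 0)
  1 - v / v_c
}

#' Swelling probability
#'
#' Probability that a cell increments its volume in one step:
#' \eqn{p_s = \frac12(1 + \tanh(k_1\vartheta + k_2))}. Strictly increasing in
#' the swelling factor, hence decreasing in cell volume: large cells are less
#' likely to swell. With the default parameters it is ~0.982 at the critical
#' volume and ~0.018 at twice the critical volume.
#'
#' @param theta Swelling factor(s), unbounded.
#' @param k1,k2 Shape parameters.
#' @return Probability in (0, 1), same length as `theta`.
#' @export
swelling_probability <- function(theta, k1 = 4, k2 = 2) {
  0.5 * (1 + tanh(k1 * theta + k2))
}

#' Adipogenesis probability
#'
#' Probability that supercritical adipocytes trigger recruitment of new cells
#' in one step: \eqn{p_a = \frac12(\tanh(k_5\zeta + k_6) + \tanh 1)} of the
#' supercritical fraction \eqn{\zeta}. With the defaults (`k6 = -1`) it is
#' exactly 0 at \eqn{\zeta = 0} (by oddness of tanh) and ~0.880 at
#' \eqn{\zeta = 1}; it is non-decreasing in \eqn{\zeta}. For non-default
#' parameters the value is clipped to [0, 1].
#'
#' @param zeta Supercritical fraction(s), in \[0, 1\].
#' @param k5,k6 Shape parameters.
#' @return Probability in \[0, 1\], same length as `zeta`.
#' @export
adipogenesis_probability <- function(zeta, k5 = 5, k6 = -1) {
  if (any(zeta < 0 | zeta > 1)) stop("'zeta' must lie in [0, 1]", call. = FALSE)
  pmin(1, pmax(0, 0.5 * (tanh(k5 * zeta + k6) + tanh(1))))
}

#' Initialise an adipocyte population
#'
#' Draws the initial cell-volume distribution for a subject. The mean initial
#' diameter is set by the diameter-BMI relation; individual diameters are
#' drawn from a normal distribution with coefficient of variation
#' `params$init_cv`, truncated to `[sphere_diameter(v0), 2*phi_c]`, then
#' converted to volumes. The cell count is
#' `N0 = round(sim_volume / sphere_volume(mean diameter))`.
#'
#' @param profile An [adipose_subject()] profile.
#' @param params A [growth_params()] object (its `v_c` should match the
#'   subject's gender).
#' @param sim_volume Simulated tissue volume in uL.
#' @return An object of class `"adipocyte_population"`: list with `volumes`
#'   (numeric vector, uL), `v0`, `v_c`, `sim_volume`.
#' @export
init_population <- function(profile, params, sim_volume = 1) {
  stopifnot(inherits(profile, "adipose_subject"),
            inherits(params, "growth_params"), sim_volume > 0)
  d_mean <- adipocyte_diameter(bmi(profile), profile$gender)
  n0 <- round(sim_volume / sphere_volume(d_mean))
  if (n0 < 1) n0 <- 1
  if (n0 < 10)
    warning("initial population has only ", n0,
            " cells; statistics will be unreliable (increase sim_volume)")
  d_lo <- sphere_diameter(params$v0)
  d_hi <- 2 * sphere_diameter(params$v_c)   # 2 * phi_c
  d <- truncated_normal(n0, mean = d_mean, sd = params$init_cv * d_mean,
                        lo = d_lo, hi = d_hi)
  volumes <- sphere_volume(d)
  volumes[volumes < params$v0] <- params$v0
  structure(list(volumes = volumes, v0 = params$v0, v_c = params$v_c,
                 sim_volume = sim_volume),
            class = "adipocyte_population")
}

# rejection-free truncated normal via inverse CDF
truncated_normal <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

#' @export
print.adipocyte_population <- function(x, ...) {
  cat(sprintf("Adipocyte population: %d cells, total %.4g uL (mean %.4g uL, %.1f%% supercritical)\n",
              length(x$volumes), sum(x$volumes), mean(x$volumes),
              100 * supercritical_fraction(x)))
  invisible(x)
}

#' Supercritical fraction
#'
#' Fraction \eqn{\zeta} of adipocytes whose volume exceeds the critical
#' volume `v_c` (these cells secrete adipokines and proinflammatory
#' cytokines).
#'
#' @param pop An [init_population()] object.
#' @param v_c Critical volume; defaults to the population's own.
#' @return A number in \[0, 1\].
#' @export
supercritical_fraction <- function(pop, v_c = pop$v_c) {
  stopifnot(inherits(pop, "adipocyte_population"), length(pop$volumes) >= 1)
  mean(pop$volumes > v_c)
}

# One swelling sub-step on a raw volume vector. e_step is the surplus energy
# allotted to this step (kcal); returns the updated vector.
# Kept free of S3 dispatch: this is the innermost loop of the engine.
swell_kernel <- function(volumes, e_step, gp, sim_volume) {
  n <- length(volumes)
  theta <- 1 - volumes / gp$v_c
  ps <- 0.5 * (1 + tanh(gp$k1 * theta + gp$k2))
  idx <- which(stats::runif(n) < ps)
  np <- length(idx)
  if (np == 0L) return(volumes)
  influx <- gp$energy_partition_scale * gp$k3 * e_step
  delta <- switch(gp$partition,
    per_capita = influx / n,
    tissue     = influx * (sum(volumes) / sim_volume) / np,
    per_cell   = influx)
  eta <- if (gp$k4 > 0) stats::rnorm(np, 0, sqrt(gp$k4) * gp$v0) else 0
  cand <- volumes[idx] + delta + eta
  ok <- cand >= gp$v0
  volumes[idx[ok]] <- cand[ok]
  volumes
}

#' Apply one swelling step to a population
#'
#' Each cell independently passes a Bernoulli draw with its swelling
#' probability; passing cells receive an energy-derived volume increment plus
#' Gaussian noise, except that an update that would take a cell below the
#' baseline volume `v0` leaves that cell unchanged (the volume floor). How
#' the energy influx is split over cells is set by `params$partition`; see
#' [growth_params()].
#'
#' @param pop An [init_population()] object.
#' @param E Surplus energy for the day, kcal/day (may be negative or zero).
#' @param params A [growth_params()] object.
#' @param steps_per_day The day's energy is divided evenly over this many
#'   steps; one call advances one step.
#' @return The updated population.
#' @export
update_volumes <- function(pop, E, params, steps_per_day = 3) {
  stopifnot(inherits(pop, "adipocyte_population"),
            inherits(params, "growth_params"), steps_per_day >= 1)
  pop$volumes <- swell_kernel(pop$volumes, E / steps_per_day, params,
                              pop$sim_volume)
  pop
}

#' Recruit new adipocytes
#'
#' With probability `p_a`, adds `round(V)` new cells (one cell per step per
#' microlitre of current tissue volume `V`), each initialised at the baseline
#' volume `v0`. The new cells enlarge the total tissue volume: they are a new
#' reservoir for further fat accumulation.
#'
#' @param pop An [init_population()] object.
#' @param p_a Adipogenesis probability for this step, in \[0, 1\].
#' @return The updated population.
#' @export
recruit_adipocytes <- function(pop, p_a) {
  stopifnot(inherits(pop, "adipocyte_population"))
  if (p_a < 0 || p_a > 1) stop("'p_a' must lie in [0, 1]", call. = FALSE)
  if (stats::runif(1) < p_a) {
    k <- round(sum(pop$volumes))
    if (k > 0) pop$volumes <- c(pop$volumes, rep.int(pop$v0, k))
  }
  pop
}
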