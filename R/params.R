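# Parameter containers: adipocyte growth kinetics, macrophage/cytokine
# kinetics, and engine-level simulation control.

#' Adipocyte growth parameters
#'
#' Kinetic constants of the stochastic swelling / recruitment model.
#' `k1`, `k2` shape the swelling probability
#' \eqn{p_s = \frac12(1+\tanh(k_1\vartheta + k_2))} of the swelling factor
#' \eqn{\vartheta = 1 - v/v_c}; `k3` (uL*day/kcal) converts daily surplus
#' energy into lipid volume; `k4` scales the per-step volume noise
#' (\eqn{\eta \sim N(0, k_4 v_0^2)}); `k5`, `k6` shape the adipogenesis
#' probability \eqn{p_a = \frac12(\tanh(k_5\zeta + k_6) + \tanh 1)} of the
#' supercritical fraction \eqn{\zeta}.
#'
#' @param k1,k2 Dimensionless swelling-probability shape parameters.
#' @param k3 Energy-to-volume conversion, uL*day/kcal.
#' @param k4 Dimensionless noise variance scale.
#' @param k5,k6 Dimensionless adipogenesis-probability shape parameters.
#' @param v0 Baseline adipocyte volume in uL (the volume floor and the volume
#'   of newly recruited cells).
#' @param v_c Critical volume in uL. If `NULL`, computed from the
#'   gender-specific critical diameter `phi_c` via [sphere_volume()].
#' @param gender Used only to derive `v_c` when `v_c` is `NULL`.
#' @param energy_partition_scale Dimensionless calibration factor multiplying
#'   the energy-derived volume influx. The default was calibrated once so the
#'   42-day, 1506 kcal/day overfeeding protocol reproduces the observed mean
#'   7.6 kg gain, and is used unchanged for every other protocol.
#' @param partition How the daily energy-derived volume influx `scale*k3*E` is
#'   split over cells. `"per_capita"` (default): each cell is offered an equal
#'   share `scale*k3*(E/steps_per_day)/N(t)` and accepts it with probability
#'   `p_s`, so total uptake is throttled by the swelling probability.
#'   `"tissue"`: the influx is scaled by current relative tissue volume and
#'   divided among the cells that pass the swelling draw (total uptake forced).
#'   `"per_cell"`: the literal per-cell increment `scale*k3*(E/steps_per_day)`
#'   for every passing cell. See the methods vignette for the trade-offs.
#' @param init_cv Coefficient of variation of the initial adipocyte diameter
#'   distribution (truncated normal on diameter).
#'
#' @return An object of class `"growth_params"` (a list).
#' @export
growth_params <- function(k1 = 4, k2 = 2, k3 = 8e-6, k4 = 2e-5, k5 = 5, k6 = -1,
                          v0 = 8.181e-6, v_c = NULL, gender = "male",
                          energy_partition_scale = 0.743,
                          partition = c("per_capita", "tissue", "per_cell"),
                          init_cv = 0.1) {
  partition <- match.arg(partition)
  if (is.null(v_c)) v_c <- sphere_volume(diameter_params(gender)$phi_c)
  stopifnot(v0 > 0, v_c > 0, k3 >= 0, k4 >= 0, init_cv >= 0,
            energy_partition_scale > 0)
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
         v0 = v0, v_c = v_c,
         energy_partition_scale = energy_partition_scale,
         partition = partition, init_cv = init_cv),
    class = "growth_params"
  )
}

#' Macrophage and cytokine parameters
#'
#' Kinetics of the lumped cytokine pools and the phenomenological macrophage
#' polarization rule. Cytokines are two well-mixed pools in arbitrary units
#' ("pro" lumping TNF-alpha, IL-6 and IL-1beta; "anti" the anti-inflammatory
#' counterpart) with per-step exponential decay. Resting (M0) macrophages
#' switch to M1 with per-step probability
#' \eqn{\frac12(1 + \tanh(a \log_{10}(1 + pro) + b))} and to M2 with the
#' analogous function of the anti pool; polarized cells revert to M0 with a
#' small constant probability.
#'
#' @param n_macrophages Macrophages per uL of simulated tissue (all start M0).
#' @param s_adipo Pro-cytokine secretion per supercritical adipocyte per step,
#'   weighted by the current adipogenesis probability (a.u.).
#' @param s_m1 Pro-cytokine secretion per M1 macrophage per step (the positive
#'   inflammation feedback; a.u.).
#' @param s_m2 Anti-cytokine secretion per M2 macrophage per step (a.u.).
#' @param decay Per-step fractional decay of both cytokine pools, in (0, 1).
#' @param gain,bias Gain `a` and bias `b` of the M0 -> M1 switch probability.
#' @param gain_anti,bias_anti Same for the M0 -> M2 switch.
#' @param revert Per-step probability that an M1 or M2 cell reverts to M0.
#'
#' @return An object of class `"inflammation_params"` (a list).
#' @export
inflammation_params <- function(n_macrophages = 100,
                                s_adipo = 1, s_m1 = 20, s_m2 = 20,
                                decay = 0.1,
                                gain = 3, bias = -16.7,
                                gain_anti = 3, bias_anti = -16.7,
                                revert = 5e-4) {
  if (s_adipo < 0 || s_m1 < 0 || s_m2 < 0)
    stop("secretion rates must be non-negative", call. = FALSE)
  if (decay <= 0 || decay >= 1)
    stop("'decay' must lie in (0, 1)", call. = FALSE)
  if (revert < 0 || revert > 1)
    stop("'revert' must lie in [0, 1]", call. = FALSE)
  stopifnot(n_macrophages >= 0)
  structure(
    list(n_macrophages = as.integer(n_macrophages),
         s_adipo = s_adipo, s_m1 = s_m1, s_m2 = s_m2, decay = decay,
         gain = gain, bias = bias, gain_anti = gain_anti,
         bias_anti = bias_anti, revert = revert),
    class = "inflammation_params"
  )
}

#' Simulation control settings
#'
#' Engine-level settings: the simulated tissue volume (the model follows a
#' small, well-mixed volume of visceral adipose tissue and scales weight
#' changes by relative volume), the number of 8-hour steps per day, and the
#' growth / inflammation parameter blocks.
#'
#' @param sim_volume Simulated tissue volume in uL (default 1).
#' @param steps_per_day Discrete steps per day; the default 3 corresponds to
#'   the 8-hour step of the model.
#' @param growth A [growth_params()] object, or `NULL` to build defaults for
#'   the subject's gender at simulation time.
#' @param inflammation An [inflammation_params()] object.
#' @param onset_threshold M1 fraction defining the inflammation-onset event.
#' @param onset_persistence_days Days the threshold must be sustained.
#'
#' @return An object of class `"sim_control"` (a list).
#' @export
sim_control <- function(sim_volume = 1, steps_per_day = 3,
                        growth = NULL, inflammation = inflammation_params(),
                        onset_threshold = 0.5, onset_persistence_days = 30) {
  stopifnot(sim_volume > 0, steps_per_day >= 1)
  if (!is.null(growth)) stopifnot(inherits(growth, "growth_params"))
  stopifnot(inherits(inflammation, "inflammation_params"))
  if (onset_threshold <= 0 || onset_threshold >= 1)
    stop("'onset_threshold' must lie in (0, 1)", call. = FALSE)
  stopifnot(onset_persistence_days >= 1)
  structure(
    list(sim_volume = sim_volume, steps_per_day = as.integer(steps_per_day),
         growth = growth, inflammation = inflammation,
         onset_threshold = onset_threshold,
         onset_persistence_days = as.integer(onset_persistence_days)),
    class = "sim_control"
  )
}
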