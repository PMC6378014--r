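# Protocol fixtures for the two published human overfeeding studies used to
# calibrate and check the model, plus unit conversions and the fit check.

#' Convert megajoules to kilocalories
#'
#' Thermochemical calorie: 1 kcal = 4.184 kJ.
#'
#' @param x Energy in MJ. Vectorised.
#' @return Energy in kcal.
#' @examples
#' mj_to_kcal(4.2)  # ~1004 kcal
#' @export
mj_to_kcal <- function(x) x * 1000 / 4.184

#' Overfeeding study fixtures
#'
#' Ready-made subject + protocol configurations for two classical controlled
#' overfeeding studies, with the published reference weights:
#'
#' * `"diaz"`: 42-day overfeeding at a surplus of 1506 kcal/day, applied
#'   every day; simulated subject a 36-year-old male, 1.75 m, 73.7 kg
#'   (BMI 24.06). Observed gain 7.6 +/- 1.6 kg (73.7 -> 81.4 kg). Note the
#'   study quotes the surplus both as 6.2 MJ/day and as 1506 kcal/day,
#'   although 6.2 MJ is 1482 kcal; the fixture uses the published kcal
#'   figure.
#' * `"tremblay"`: 100-day overfeeding at 1004 kcal/day (4.2 MJ/day) on
#'   6 days per week; simulated subject a 36-year-old male, 1.72 m, 60.3 kg
#'   (BMI 20.38). Observed final weight 68.4 kg (from 60.3 kg).
#'
#' @param name `"diaz"` or `"tremblay"`.
#' @return An object of class `"overfeeding_fixture"`: list with `name`,
#'   `subject`, `protocol` and `reference` (`initial_kg`, `final_kg`,
#'   `gain_kg`, `gain_sd_kg`, `duration_days`).
#' @export
overfeeding_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% fixture_names())
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available fixtures: ",
         paste(fixture_names(), collapse = ", "), call. = FALSE)
  fx <- switch(name,
    diaz = list(
      name = "diaz",
      subject = adipose_subject(73.7, 1.75, 36, "male"),
      protocol = diet_protocol(1506, 7, 42),
      reference = list(initial_kg = 73.7, final_kg = 81.4, gain_kg = 7.6,
                       gain_sd_kg = 1.6, duration_days = 42),
      note = "surplus published as 6.2 MJ/day and 1506 kcal/day; 6.2 MJ = 1482 kcal; the kcal figure is used"
    ),
    tremblay = list(
      name = "tremblay",
      subject = adipose_subject(60.3, 1.72, 36, "male"),
      protocol = diet_protocol(1004, 6, 100),
      reference = list(initial_kg = 60.3, final_kg = 68.4, gain_kg = 8.1,
                       gain_sd_kg = 2, duration_days = 100),
      note = "surplus 4.2 MJ/day = 1004 kcal/day, 6 days on / 1 day off"
    ))
  class(fx) <- "overfeeding_fixture"
  fx
}

#' @rdname overfeeding_fixture
#' @export
fixture_names <- function() c("diaz", "tremblay")

#' @export
print.overfeeding_fixture <- function(x, ...) {
  cat("Overfeeding fixture '", x$name, "'\n", sep = "")
  print(x$subject)
  print(x$protocol)
  cat(sprintf("  reference: %.1f -> %.1f kg over %d days (gain %.1f kg)\n",
              x$reference$initial_kg, x$reference$final_kg,
              x$reference$duration_days, x$reference$gain_kg))
  invisible(x)
}

#' Check the simulator against a fixture's published weights
#'
#' Runs the fixture protocol and compares the mean simulated weight gain and
#' final weight with the published values.
#'
#' @param fixture An [overfeeding_fixture()] or a fixture name.
#' @param replicates,seed,control Passed to [adiposim()].
#' @param tol_kg Pass tolerance on the final weight (kg).
#' @return Invisibly, a list with `fit`, `gain_mean`, `final_mean`,
#'   `reference`, `abs_error_kg`, `pass`.
#' @export
fit_check <- function(fixture, replicates = 50, seed = 1L,
                      control = sim_control(), tol_kg = 2) {
  if (is.character(fixture)) fixture <- overfeeding_fixture(fixture)
  stopifnot(inherits(fixture, "overfeeding_fixture"))
  fit <- adiposim(fixture$subject, fixture$protocol, replicates = replicates,
                  seed = seed, control = control)
  sm <- summary(fit)
  err <- abs(sm$final_mean - fixture$reference$final_kg)
  pass <- err <= tol_kg
  cat(sprintf("fixture '%s': simulated gain %.2f kg (final %.2f kg); published gain %.1f kg (final %.1f kg)\n",
              fixture$name, sm$gain_mean, sm$final_mean,
              fixture$reference$gain_kg, fixture$reference$final_kg))
  cat(sprintf("  |final - published| = %.2f kg (tolerance %.1f kg): %s\n",
              err, tol_kg, if (pass) "PASS" else "FAIL"))
  invisible(list(fit = fit, gain_mean = sm$gain_mean,
                 final_mean = sm$final_mean, reference = fixture$reference,
                 abs_error_kg = err, pass = pass))
}

#' Calibrate the energy-partition scale on the 42-day overfeeding study
#'
#' Solves for the `energy_partition_scale` at which the mean simulated
#' 42-day weight gain under the `"diaz"` fixture equals the published
#' 7.6 kg. The gain is very nearly linear in the scale, so a secant
#' iteration converges in a few steps. This calibration is performed once;
#' the resulting value is the package default in [growth_params()] and is
#' used unchanged for every other protocol.
#'
#' @param target_gain_kg Published mean gain to match (kg).
#' @param replicates,seed Replicates and base seed per evaluation.
#' @param start Starting scale value.
#' @param iterations Secant iterations.
#' @return The calibrated scale (numeric scalar), with attribute
#'   `"achieved_gain_kg"`.
#' @export
calibrate_energy_scale <- function(target_gain_kg = 7.6, replicates = 50,
                                   seed = 1L, start = 0.743, iterations = 3) {
  fx <- overfeeding_fixture("diaz")
  eval_gain <- function(scale) {
    ctrl <- sim_control(growth = growth_params(
      gender = fx$subject$gender, energy_partition_scale = scale))
    fit <- adiposim(fx$subject, fx$protocol, replicates = replicates,
                    seed = seed, control = ctrl)
    s <- fit$summary
    s$bw_mean[nrow(s)] - s$bw_mean[1]
  }
  scale <- start
  gain <- eval_gain(scale)
  for (i in seq_len(iterations)) {
    scale <- scale * target_gain_kg / gain
    gain <- eval_gain(scale)
    if (abs(gain - target_gain_kg) < 0.01) break
  }
  structure(scale, achieved_gain_kg = gain)
}
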