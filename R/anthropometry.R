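# Closed-form anthropometric relations: subject profile, the diameter-BMI
# relation for omental adipocytes, spherical volume conversions, the
# Westerterp fat-free-mass regression, and the map from simulated tissue
# volume back to body weight.

# 1 microlitre = 1e9 cubic micrometres
.UM3_PER_UL <- 1e9

#' Create a subject profile
#'
#' Anthropometric inputs of the simulated subject. Body mass index, fat mass
#' and the initial adipocyte diameter are derived from these four fields.
#'
#' @param weight_kg Initial body weight in kilograms (> 0).
#' @param height_m Height in metres (> 0).
#' @param age_y Age in years (>= 0). The fat-free-mass regression is an adult
#'   regression; paediatric profiles are out of scope.
#' @param gender `"male"` or `"female"` (case-insensitive).
#'
#' @return An object of class `"adipose_subject"`: a list with fields
#'   `weight_kg`, `height_m`, `age_y`, `gender`.
#' @examples
#' s <- adipose_subject(73.7, 1.75, 36, "male")
#' bmi(s)
#' @export
adipose_subject <- function(weight_kg, height_m, age_y, gender) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || !is.finite(weight_kg) || weight_kg <= 0)
    stop("'weight_kg' must be a single positive number", call. = FALSE)
  if (!is.numeric(height_m) || length(height_m) != 1L || !is.finite(height_m) || height_m <= 0)
    stop("'height_m' must be a single positive number", call. = FALSE)
  if (!is.numeric(age_y) || length(age_y) != 1L || !is.finite(age_y) || age_y < 0)
    stop("'age_y' must be a single non-negative number", call. = FALSE)
  gender <- match_gender(gender)
  structure(
    list(weight_kg = as.numeric(weight_kg), height_m = as.numeric(height_m),
         age_y = as.numeric(age_y), gender = gender),
    class = "adipose_subject"
  )
}

match_gender <- function(gender) {
  if (!is.character(gender) || length(gender) != 1L)
    stop("'gender' must be \"male\" or \"female\"", call. = FALSE)
  g <- tolower(gender)
  if (!g %in% c("male", "female"))
    stop("unknown gender '", gender, "'; must be \"male\" or \"female\"", call. = FALSE)
  g
}

#' @export
print.adipose_subject <- function(x, ...) {
  cat(sprintf("Subject: %s, %.1f kg, %.2f m, %g y (BMI %.2f kg/m^2)\n",
              x$gender, x$weight_kg, x$height_m, x$age_y, bmi(x)))
  invisible(x)
}

#' Diameter-BMI relation parameters
#'
#' Gender-specific parameters of the saturating-exponential relation between
#' body mass index and mean omental adipocyte diameter,
#' \eqn{\phi(BMI) = \phi_c - \lambda e^{-\delta\,BMI}}. `phi_c` is the
#' asymptotic (critical) diameter in micrometres.
#'
#' @param gender `"male"` or `"female"`.
#' @return List with `phi_c` (um), `lambda` (um), `delta_d` (m^2/kg).
#' @export
diameter_params <- function(gender) {
  switch(match_gender(gender),
    male   = list(phi_c = 120, lambda = 74.905,  delta_d = 0.049),
    female = list(phi_c = 123, lambda = 198.445, delta_d = 0.061))
}

#' Fat-free-mass regression parameters (Westerterp)
#'
#' Gender-specific coefficients of the adult fat-free-mass regression
#' \eqn{FFM = \alpha + \beta A + \gamma H + \delta BW}. `delta_ffm` is the
#' dimensionless body-weight coefficient, also used by the weight-update map
#' through the factor \eqn{1/(1-\delta)}.
#'
#' @param gender `"male"` or `"female"`.
#' @return List with `alpha` (kg), `beta` (kg/year), `gamma` (kg/m),
#'   `delta_ffm` (dimensionless, in (0,1)).
#' @export
ffm_params <- function(gender) {
  switch(match_gender(gender),
    male   = list(alpha = -18.36, beta = -0.105, gamma = 34.009, delta_ffm = 0.292),
    female = list(alpha = -12.47, beta = -0.074, gamma = 27.392, delta_ffm = 0.218))
}

#' Body mass index
#'
#' @param profile An [adipose_subject()] profile.
#' @return BMI in kg/m^2 (weight / height^2).
#' @export
bmi <- function(profile) {
  stopifnot(inherits(profile, "adipose_subject"))
  if (profile$height_m <= 0) stop("height must be positive", call. = FALSE)
  profile$weight_kg / profile$height_m^2
}

#' Mean adipocyte diameter from BMI
#'
#' Saturating-exponential diameter-BMI relation for omental (visceral)
#' adipocytes: \eqn{\phi = \phi_c - \lambda e^{-\delta\,BMI}}. Strictly
#' increasing in BMI and bounded above by the gender-specific critical
#' diameter `phi_c` (120 um male, 123 um female).
#'
#' @param bmi Body mass index in kg/m^2 (> 0). Vectorised.
#' @param gender `"male"` or `"female"`.
#' @return Diameter in micrometres.
#' @export
adipocyte_diameter <- function(bmi, gender) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("'bmi' must be positive and finite", call. = FALSE)
  p <- diameter_params(gender)
  p$phi_c - p$lambda * exp(-p$delta_d * bmi)
}

#' Sphere volume and diameter conversions
#'
#' Adipocytes are modelled as spheres. `sphere_volume()` converts a diameter
#' in micrometres to a volume in microlitres (\eqn{v = \pi d^3 / 6}, with
#' 1 uL = 1e9 um^3); `sphere_diameter()` is the exact inverse.
#'
#' @param diameter_um Diameter in micrometres (> 0). Vectorised.
#' @return Volume in microlitres.
#' @export
sphere_volume <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("'diameter_um' must be positive and finite", call. = FALSE)
  (pi / 6) * diameter_um^3 / .UM3_PER_UL
}

#' @rdname sphere_volume
#' @param volume_ul Volume in microlitres (> 0). Vectorised.
#' @return Diameter in micrometres.
#' @export
sphere_diameter <- function(volume_ul) {
  if (any(!is.finite(volume_ul)) || any(volume_ul <= 0))
    stop("'volume_ul' must be positive and finite", call. = FALSE)
  (6 * volume_ul * .UM3_PER_UL / pi)^(1 / 3)
}

#' Fat-free mass and fat mass
#'
#' `free_fat_mass()` evaluates the adult Westerterp regression
#' \eqn{FFM = \alpha + \beta A + \gamma H + \delta BW} with gender-specific
#' coefficients; `fat_mass()` returns \eqn{FM = BW - FFM}. A profile whose
#' fat mass comes out non-positive is outside the validity range of the
#' regression and raises an error (such a subject has no fat reservoir to
#' simulate).
#'
#' @param profile An [adipose_subject()] profile.
#' @return Mass in kilograms.
#' @export
free_fat_mass <- function(profile) {
  stopifnot(inherits(profile, "adipose_subject"))
  p <- ffm_params(profile$gender)
  p$alpha + p$beta * profile$age_y + p$gamma * profile$height_m +
    p$delta_ffm * profile$weight_kg
}

#' @rdname free_fat_mass
#' @export
fat_mass <- function(profile) {
  fm <- profile$weight_kg - free_fat_mass(profile)
  if (!is.finite(fm) || fm <= 0)
    stop("infeasible subject: computed fat mass is ", signif(fm, 4),
         " kg; the fat-free-mass regression is outside its validity range",
         call. = FALSE)
  fm
}

#' Body weight from relative tissue volume
#'
#' Linear map from the relative change of simulated adipose volume to body
#' weight: \eqn{BW(t) = BW(0) + [FM(0)/(1-\delta)] \, (V(t)-V_0)/V_0}, where
#' \eqn{\delta} is the body-weight coefficient of the fat-free-mass
#' regression. At `ratio = 1` the initial weight is returned exactly.
#'
#' @param ratio Relative tissue volume \eqn{V(t)/V_0} (> 0). Vectorised.
#' @param fm0 Initial fat mass in kg.
#' @param delta_ffm Dimensionless regression coefficient, in (0, 1).
#' @param bw0 Initial body weight in kg.
#' @return Body weight in kg.
#' @examples
#' body_weight_from_volume(1.364, fm0 = 14.8, delta_ffm = 0.292, bw0 = 73.7)
#' @export
body_weight_from_volume <- function(ratio, fm0, delta_ffm, bw0) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("'ratio' must be positive and finite", call. = FALSE)
  if (!is.finite(delta_ffm) || delta_ffm >= 1 || delta_ffm <= 0)
    stop("'delta_ffm' must lie in (0, 1)", call. = FALSE)
  bw0 + fm0 / (1 - delta_ffm) * (ratio - 1)
}
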