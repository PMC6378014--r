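# S3 methods for the "adiposim" fit object.

#' @export
print.adiposim <- function(x, ...) {
  s <- x$summary
  last <- nrow(s)
  cat("Adipose-tissue simulation\n")
  cat(sprintf("  subject : %s, %.1f kg, %.2f m, %g y (BMI %.2f)\n",
              x$subject$gender, x$subject$weight_kg, x$subject$height_m,
              x$subject$age_y, bmi(x$subject)))
  cat(sprintf("  protocol: %+g kcal/day, %d day(s)/week, %d days\n",
              x$protocol$excess_kcal_per_day, x$protocol$days_on_per_week,
              x$protocol$duration_days))
  cat(sprintf("  replicates: %d (base seed %d)\n", x$replicates, x$seed))
  cat(sprintf("  final weight: %.2f +/- %.2f kg (gain %+.2f kg)\n",
              s$bw_mean[last], s$bw_sd[last], s$bw_mean[last] - s$bw_mean[1]))
  cat(sprintf("  final M1 fraction: %.3f; supercritical fraction: %.3f\n",
              s$m1_frac_mean[last], s$zeta_mean[last]))
  invisible(x)
}

#' @export
summary.adiposim <- function(object, ...) {
  s <- object$summary
  last <- nrow(s)
  gains <- vapply(object$trajectories,
                  function(tr) tr$bw_kg[nrow(tr)] - tr$bw_kg[1], numeric(1))
  finals <- vapply(object$trajectories,
                   function(tr) tr$bw_kg[nrow(tr)], numeric(1))
  ot <- onset_table(object)
  out <- list(
    subject = object$subject, protocol = object$protocol,
    replicates = object$replicates,
    duration_days = object$protocol$duration_days,
    gain_mean = mean(gains), gain_sd = stats::sd(gains),
    final_mean = mean(finals), final_sd = stats::sd(finals),
    m1_frac_final = s$m1_frac_mean[last],
    zeta_final = s$zeta_mean[last],
    n_cells_final = s$n_mean[last],
    onset_events = sum(ot$event_flag),
    onset_median = if (any(ot$event_flag == 1))
      stats::median(ot$onset_day[ot$event_flag == 1]) else NA_real_
  )
  class(out) <- "summary.adiposim"
  out
}

#' @export
print.summary.adiposim <- function(x, ...) {
  cat(sprintf("Simulated %d replicates of %d days at %+g kcal/day\n",
              x$replicates, x$duration_days, x$protocol$excess_kcal_per_day))
  cat(sprintf("  weight gain : %.2f +/- %.2f kg (replicate SD)\n",
              x$gain_mean, x$gain_sd))
  cat(sprintf("  final weight: %.2f +/- %.2f kg\n", x$final_mean, x$final_sd))
  cat(sprintf("  final supercritical fraction: %.3f; cells: %.0f\n",
              x$zeta_final, x$n_cells_final))
  cat(sprintf("  final mean M1 fraction: %.3f\n", x$m1_frac_final))
  cat(sprintf("  inflammation onsets: %d/%d", x$onset_events, x$replicates))
  if (!is.na(x$onset_median))
    cat(sprintf(" (median onset day %g)", x$onset_median))
  cat("\n")
  invisible(x)
}

#' @export
coef.adiposim <- function(object, ...) {
  gp <- object$control$growth
  if (is.null(gp)) gp <- growth_params(gender = object$subject$gender)
  ip <- object$control$inflammation
  c(k1 = gp$k1, k2 = gp$k2, k3 = gp$k3, k4 = gp$k4, k5 = gp$k5, k6 = gp$k6,
    v0 = gp$v0, v_c = gp$v_c,
    energy_partition_scale = gp$energy_partition_scale,
    n_macrophages = ip$n_macrophages, s_adipo = ip$s_adipo,
    s_m1 = ip$s_m1, s_m2 = ip$s_m2, decay = ip$decay,
    gain = ip$gain, bias = ip$bias, revert = ip$revert)
}

#' Draw further replicates of a fitted simulation
#'
#' @param object An [adiposim()] object.
#' @param nsim Number of new replicates.
#' @param seed Base seed for the new replicates (defaults to continuing the
#'   original seed sequence).
#' @param ... Unused.
#' @return A new `"adiposim"` object with `nsim` replicates.
#' @export
simulate.adiposim <- function(object, nsim = object$replicates,
                              seed = object$seed + object$replicates, ...) {
  adiposim(object$subject, object$protocol, replicates = nsim,
           seed = seed, control = object$control)
}

#' Plot an adiposim fit
#'
#' @param x An [adiposim()] object.
#' @param which `"weight"` (mean body weight with a +/- 1 SD band),
#'   `"cells"` (mean cell count) or `"inflammation"` (mean M1/M2 fractions).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adiposim <- function(x, which = c("weight", "cells", "inflammation"),
                          ...) {
  which <- match.arg(which)
  s <- x$summary
  if (which == "weight") {
    graphics::plot(s$day, s$bw_mean, type = "l", xlab = "day",
                   ylab = "body weight (kg)", ...)
    graphics::polygon(c(s$day, rev(s$day)),
                      c(s$bw_mean - s$bw_sd, rev(s$bw_mean + s$bw_sd)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(s$day, s$bw_mean)
  } else if (which == "cells") {
    graphics::plot(s$day, s$n_mean, type = "l", xlab = "day",
                   ylab = "adipocytes in simulated volume", ...)
  } else {
    nm <- x$control$inflammation$n_macrophages
    graphics::plot(s$day, s$m1_mean / nm, type = "l", ylim = c(0, 1),
                   xlab = "day", ylab = "macrophage fraction", col = "red3", ...)
    graphics::lines(s$day, s$m2_mean / nm, col = "blue3")
    graphics::legend("topleft", c("M1", "M2"), lty = 1,
                     col = c("red3", "blue3"), bty = "n")
  }
  invisible(x)
}
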