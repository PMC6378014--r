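# Energy sweeps: the same subject simulated across a grid of daily surplus
# energies, with year-end macrophage summaries and Kaplan-Meier inputs.

#' Sweep over daily surplus-energy levels
#'
#' Runs [adiposim()] for each surplus level (applied every day of the week)
#' over a multi-year horizon and collects the per-level fits, year-end
#' macrophage counts and onset times for Kaplan-Meier analysis.
#'
#' @param subject An [adipose_subject()].
#' @param E_values Numeric vector of daily surplus energies, kcal/day.
#' @param duration_days Horizon in days (default 5 years).
#' @param replicates Replicates per energy level.
#' @param seed Base seed; every energy level uses the same replicate seeds so
#'   levels are paired.
#' @param control A [sim_control()].
#' @return An object of class `"adiposim_sweep"`: list with `fits` (named by
#'   energy level), `year_end` (data frame: `E_kcal_day`, `year`, `m1_mean`,
#'   `m2_mean`, `bw_mean`), `onsets` (stacked [onset_table()] rows),
#'   `E_values`, `horizon_days`.
#' @export
energy_sweep <- function(subject, E_values, duration_days = 5 * 365,
                         replicates = 50, seed = 1L,
                         control = sim_control()) {
  stopifnot(length(E_values) >= 1, duration_days >= 1)
  fits <- lapply(E_values, function(E) {
    adiposim(subject, diet_protocol(E, 7, duration_days),
             replicates = replicates, seed = seed, control = control)
  })
  names(fits) <- as.character(E_values)
  years <- seq_len(duration_days %/% 365)
  nm <- control$inflammation$n_macrophages
  year_end <- do.call(rbind, lapply(seq_along(E_values), function(i) {
    s <- fits[[i]]$summary
    idx <- match(years * 365, s$day)
    data.frame(E_kcal_day = E_values[i], year = years,
               m1_mean = s$m1_mean[idx], m2_mean = s$m2_mean[idx],
               m1_frac_mean = s$m1_frac_mean[idx], bw_mean = s$bw_mean[idx])
  }))
  onsets <- do.call(rbind, lapply(fits, onset_table))
  rownames(onsets) <- NULL
  structure(list(fits = fits, year_end = year_end, onsets = onsets,
                 E_values = E_values,
                 horizon_days = as.integer(duration_days)),
            class = "adiposim_sweep")
}

#' @export
print.adiposim_sweep <- function(x, ...) {
  cat(sprintf("Energy sweep over {%s} kcal/day, %d days, %d replicates/level\n",
              paste(x$E_values, collapse = ", "), x$horizon_days,
              x$fits[[1]]$replicates))
  last_year <- max(x$year_end$year)
  ye <- x$year_end[x$year_end$year == last_year, ]
  cat(sprintf("Year %d: ", last_year))
  cat(paste(sprintf("E=%g: BW %.1f kg, M1 %.2f", ye$E_kcal_day, ye$bw_mean,
                    ye$m1_frac_mean), collapse = "; "), "\n")
  invisible(x)
}

#' Kaplan-Meier curves of a sweep
#'
#' @param sweep An [energy_sweep()] object.
#' @return Named list of [km_curve()] objects, one per energy level.
#' @export
sweep_km <- function(sweep) {
  stopifnot(inherits(sweep, "adiposim_sweep"))
  out <- lapply(split(sweep$onsets, sweep$onsets$E_kcal_day),
                function(d) km_curve(d$onset_day, d$event_flag))
  out[order(as.numeric(names(out)))]
}

#' @export
plot.adiposim_sweep <- function(x, which = c("weight", "km"), ...) {
  which <- match.arg(which)
  if (which == "weight") {
    cols <- grDevices::hcl.colors(length(x$fits), "viridis")
    s1 <- x$fits[[1]]$summary
    rng <- range(sapply(x$fits, function(f) range(f$summary$bw_mean)))
    graphics::plot(s1$day, s1$bw_mean, type = "n", ylim = rng,
                   xlab = "day", ylab = "body weight (kg)", ...)
    for (i in seq_along(x$fits))
      graphics::lines(x$fits[[i]]$summary$day,
                      x$fits[[i]]$summary$bw_mean, col = cols[i])
    graphics::legend("topleft", legend = names(x$fits), col = cols,
                     lty = 1, bty = "n", title = "kcal/day")
  } else {
    kms <- sweep_km(x)
    cols <- grDevices::hcl.colors(length(kms), "viridis")
    graphics::plot(NA, xlim = c(0, x$horizon_days), ylim = c(0, 1),
                   xlab = "day", ylab = "fraction without onset", ...)
    for (i in seq_along(kms)) {
      k <- kms[[i]]
      graphics::lines(stats::stepfun(k$time[-1], k$survival),
                      do.points = FALSE, col = cols[i])
    }
    graphics::legend("bottomleft", legend = names(kms), col = cols,
                     lty = 1, bty = "n", title = "kcal/day")
  }
  invisible(x)
}
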