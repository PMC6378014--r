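# Cytokine pools, macrophage polarization, inflammation-onset detection and
# the Kaplan-Meier product-limit estimator over replicates.

#' Create a cytokine field
#'
#' Two well-mixed cytokine pools in arbitrary units: `pro` lumps the
#' proinflammatory species (TNF-alpha, IL-6, IL-1beta) secreted by
#' supercritical adipocytes and M1 macrophages; `anti` is the
#' anti-inflammatory pool secreted by M2 macrophages. Both decay
#' exponentially each step.
#'
#' @param pro,anti Initial concentrations (a.u., >= 0).
#' @param decay Per-step fractional decay, in (0, 1).
#' @return An object of class `"cytokine_field"`.
#' @export
cytokine_field <- function(pro = 0, anti = 0, decay = 0.1) {
  stopifnot(pro >= 0, anti >= 0, decay > 0, decay < 1)
  structure(list(pro = pro, anti = anti, decay = decay),
            class = "cytokine_field")
}

# field update kernel: decay the standing pools, then add this step's
# secretion, so a constant source S has fixed point S/decay exactly.
secrete_kernel <- function(pro, anti, decay, n_super, p_a, m1, m2, ip) {
  pro  <- (1 - decay) * pro  + ip$s_adipo * p_a * n_super + ip$s_m1 * m1
  anti <- (1 - decay) * anti + ip$s_m2 * m2
  c(pro, anti)
}

#' Secrete cytokines for one step
#'
#' Supercritical adipocytes secrete proinflammatory cytokines in proportion
#' to the current adipogenesis probability (the same signalling event that
#' recruits new cells), and M1 macrophages add a positive feedback term; M2
#' macrophages secrete into the anti-inflammatory pool. Decay is applied to
#' the standing pools, so a constant total source `S` has the exact fixed
#' point `S / decay`.
#'
#' @param field A [cytokine_field()].
#' @param n_super Number of supercritical adipocytes.
#' @param p_a Current adipogenesis probability.
#' @param m1,m2 Counts of M1 and M2 macrophages.
#' @param params An [inflammation_params()] object.
#' @return The updated field (concentrations are always >= 0).
#' @export
secrete_cytokines <- function(field, n_super, p_a, m1, m2,
                              params = inflammation_params()) {
  stopifnot(inherits(field, "cytokine_field"),
            inherits(params, "inflammation_params"),
            n_super >= 0, p_a >= 0, p_a <= 1, m1 >= 0, m2 >= 0)
  x <- secrete_kernel(field$pro, field$anti, field$decay,
                      n_super, p_a, m1, m2, params)
  field$pro <- x[1]
  field$anti <- x[2]
  field
}

# per-step switch probabilities from the field (scalars)
switch_probs <- function(pro, anti, ip) {
  p1 <- 0.5 * (1 + tanh(ip$gain * log10(1 + pro) + ip$bias))
  p2 <- 0.5 * (1 + tanh(ip$gain_anti * log10(1 + anti) + ip$bias_anti))
  c(p1, p2)
}

# macrophage state vector: integer 0 = M0, 1 = M1, 2 = M2
polarize_kernel <- function(states, p1, p2, revert) {
  m0 <- which(states == 0L)
  if (length(m0)) {
    u1 <- stats::runif(length(m0))
    to1 <- u1 < p1
    # M1 is tested first; only cells that did not switch draw for M2
    rest <- m0[!to1]
    states[m0[to1]] <- 1L
    if (length(rest)) {
      u2 <- stats::runif(length(rest))
      states[rest[u2 < p2]] <- 2L
    }
  }
  pol <- which(states != 0L)
  if (length(pol)) {
    u3 <- stats::runif(length(pol))
    states[pol[u3 < revert]] <- 0L
  }
  states
}

#' Polarize macrophages for one step
#'
#' Each resting (M0) macrophage switches to M1 with per-step probability
#' \eqn{\frac12(1 + \tanh(a\,\log_{10}(1 + pro) + b))} and, failing that, to
#' M2 with the analogous function of the anti pool (mutually exclusive
#' draws, M1 tested first). Polarized cells revert to M0 with a small
#' constant probability. The macrophage count is conserved: no cell is
#' created or destroyed here.
#'
#' @param states Integer vector of macrophage states (0 = M0, 1 = M1,
#'   2 = M2).
#' @param field A [cytokine_field()].
#' @param params An [inflammation_params()] object.
#' @return The updated state vector.
#' @export
polarize_macrophages <- function(states, field, params = inflammation_params()) {
  stopifnot(is.integer(states), all(states %in% 0:2),
            inherits(field, "cytokine_field"),
            inherits(params, "inflammation_params"))
  p <- switch_probs(field$pro, field$anti, params)
  polarize_kernel(states, p[1], p[2], params$revert)
}

#' Detect inflammation onset in an M1-fraction series
#'
#' The onset event is the first day on which the M1 fraction reaches the
#' threshold and stays at or above it for `persistence_days` consecutive
#' days. Days are indexed from 0 (the first element of the series). If no
#' such window exists the trajectory is censored at its horizon.
#'
#' @param m1_fraction Numeric vector of per-day M1 fractions (day 0 first).
#' @param threshold Onset threshold, in (0, 1).
#' @param persistence_days Number of consecutive days required (>= 1).
#' @return A list with `time` (onset day, or the last observed day if
#'   censored) and `event` (1 = onset observed, 0 = censored).
#' @export
detect_onset <- function(m1_fraction, threshold = 0.5, persistence_days = 30) {
  if (length(m1_fraction) == 0) stop("empty trajectory", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  stopifnot(persistence_days >= 1)
  above <- m1_fraction >= threshold
  n <- length(above)
  if (n >= persistence_days) {
    # run-length scan for the first window of persistence_days TRUEs
    run <- 0L
    for (d in seq_len(n)) {
      run <- if (above[d]) run + 1L else 0L
      if (run >= persistence_days)
        return(list(time = d - persistence_days, event = 1L))
    }
  }
  list(time = n - 1L, event = 0L)
}

#' Kaplan-Meier product-limit curve
#'
#' Nonparametric survival-curve estimate over replicate onset times:
#' "survival" at time t is the estimated probability that a replicate has
#' not yet triggered the inflammation-onset event by t. Standard
#' product-limit estimator with right censoring:
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over distinct event times.
#'
#' @param time Non-negative event or censoring times (days).
#' @param event 1 (or TRUE) if the onset event was observed at `time`,
#'   0 (FALSE) if censored.
#' @return An object of class `"km_curve"`: data frame with columns `time`
#'   (distinct event times, with a leading 0), `survival`, `n_risk`,
#'   `n_event`. Survival starts at 1 and is non-increasing.
#' @export
km_curve <- function(time, event) {
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  stopifnot(length(time) == length(event), length(time) >= 1)
  event <- as.integer(as.logical(event))
  et <- sort(unique(time[event == 1L]))
  surv <- numeric(length(et))
  n_risk <- integer(length(et))
  n_event <- integer(length(et))
  s <- 1
  for (i in seq_along(et)) {
    n_risk[i] <- sum(time >= et[i])
    n_event[i] <- sum(time == et[i] & event == 1L)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  out <- data.frame(time = c(0, et), survival = c(1, surv),
                    n_risk = c(length(time), n_risk),
                    n_event = c(0L, n_event))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier onset curve:", nrow(x) - 1L, "event time(s),",
      sprintf("final survival %.3f\n", x$survival[nrow(x)]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "day", ylab = "fraction without onset",
                          main = "Inflammation-free survival", ...) {
  graphics::plot(stats::stepfun(x$time[-1], x$survival), do.points = FALSE,
                 xlab = xlab, ylab = ylab, main = main, ylim = c(0, 1), ...)
  invisible(x)
}
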