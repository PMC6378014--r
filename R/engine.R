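# Time-stepped orchestration: diet scheduling, the 8-hour step loop,
# replicate management and trajectory recording.

#' Define a diet protocol
#'
#' A daily surplus-energy schedule with a repeating weekly on/off pattern:
#' the first `days_on_per_week` days of each 7-day block are "on" (surplus
#' applied), the remainder "off" (surplus 0). The protocol starts on mask
#' day 1.
#'
#' @param excess_kcal_per_day Daily surplus energy on "on" days, kcal/day.
#'   May be negative (hypocaloric diet).
#' @param days_on_per_week Integer 1-7 (default 7, surplus every day).
#' @param duration_days Protocol length in days (>= 1; 0 is allowed and runs
#'   no steps, returning only the initial record).
#' @return An object of class `"diet_protocol"`.
#' @export
diet_protocol <- function(excess_kcal_per_day, days_on_per_week = 7,
                          duration_days) {
  stopifnot(is.numeric(excess_kcal_per_day), length(excess_kcal_per_day) == 1L)
  if (!days_on_per_week %in% 1:7)
    stop("'days_on_per_week' must be an integer in 1..7", call. = FALSE)
  if (duration_days < 0) stop("'duration_days' must be >= 0", call. = FALSE)
  structure(
    list(excess_kcal_per_day = as.numeric(excess_kcal_per_day),
         days_on_per_week = as.integer(days_on_per_week),
         duration_days = as.integer(duration_days)),
    class = "diet_protocol"
  )
}

#' @export
print.diet_protocol <- function(x, ...) {
  cat(sprintf("Diet protocol: %+g kcal/day, %d day(s)/week, %d days (%d on-days)\n",
              x$excess_kcal_per_day, x$days_on_per_week, x$duration_days,
              sum(is_on_day(seq_len(x$duration_days), x$days_on_per_week))))
  invisible(x)
}

# day is 1-indexed within the protocol
is_on_day <- function(day, days_on_per_week) {
  ((day - 1L) %% 7L) < days_on_per_week
}

#' Effective surplus energy on a protocol day
#'
#' @param protocol A [diet_protocol()].
#' @param day Protocol day, 1-indexed. Vectorised.
#' @return kcal/day: the protocol surplus on "on" days, 0 on "off" days.
#' @export
effective_energy <- function(protocol, day) {
  stopifnot(inherits(protocol, "diet_protocol"), all(day >= 1))
  ifelse(is_on_day(as.integer(day), protocol$days_on_per_week),
         protocol$excess_kcal_per_day, 0)
}

#' Run a single replicate simulation
#'
#' Initialises the adipocyte population from the subject's anthropometry and
#' iterates the 8-hour step loop for the protocol duration. Each step
#' applies, in order: (1) stochastic swelling with the day's effective
#' surplus energy, (2) supercritical fraction and adipogenesis probability,
#' (3) recruitment of new adipocytes, (4) cytokine secretion and decay,
#' (5) macrophage polarization. State is recorded once per simulated day.
#'
#' @param subject An [adipose_subject()].
#' @param protocol A [diet_protocol()].
#' @param control A [sim_control()].
#' @param seed Integer seed; the run is bit-reproducible given
#'   (subject, protocol, control, seed).
#' @return A data frame of class `"adiposim_trajectory"` with one row per
#'   day (day 0 first) and columns `day`, `bw_kg`, `n_cells`, `v_total_ul`,
#'   `v_mean_ul`, `zeta`, `pro`, `anti`, `m0`, `m1`, `m2`. Attributes:
#'   `V0`, `N0`, `fm0`, `on_days` (realized count of on-days).
#' @export
run_simulation <- function(subject, protocol, control = sim_control(),
                           seed = 1L) {
  stopifnot(inherits(subject, "adipose_subject"),
            inherits(protocol, "diet_protocol"),
            inherits(control, "sim_control"))
  gp <- control$growth
  if (is.null(gp)) gp <- growth_params(gender = subject$gender)
  ip <- control$inflammation
  spd <- control$steps_per_day

  fm0 <- fat_mass(subject)
  if (fm0 <= 1)
    stop("infeasible subject: initial fat mass ", signif(fm0, 3),
         " kg is too small for the weight-update map", call. = FALSE)
  delta <- ffm_params(subject$gender)$delta_ffm
  bw0 <- subject$weight_kg

  set.seed(as.integer(seed))
  pop <- init_population(subject, gp, control$sim_volume)

  # mutable state kept as raw vectors; capacity-doubling for recruitment
  vol <- pop$volumes
  n <- length(vol)
  n0 <- n
  V0 <- sum(vol)
  states <- rep.int(0L, ip$n_macrophages)
  pro <- 0
  anti <- 0

  ndays <- protocol$duration_days
  rec <- matrix(NA_real_, nrow = ndays + 1L, ncol = 11L)
  colnames(rec) <- c("day", "bw_kg", "n_cells", "v_total_ul", "v_mean_ul",
                     "zeta", "pro", "anti", "m0", "m1", "m2")
  record <- function(day, V, zeta) {
    rec[day + 1L, ] <<- c(day,
                          body_weight_from_volume(V / V0, fm0, delta, bw0),
                          n, V, V / n, zeta, pro, anti,
                          sum(states == 0L), sum(states == 1L),
                          sum(states == 2L))
  }
  record(0L, V0, mean(vol > gp$v_c))

  on_days <- 0L
  for (day in seq_len(ndays)) {
    e_day <- if (is_on_day(day, protocol$days_on_per_week)) {
      on_days <- on_days + 1L
      protocol$excess_kcal_per_day
    } else 0
    e_step <- e_day / spd
    for (s in seq_len(spd)) {
      v <- vol[seq_len(n)]
      v <- swell_kernel(v, e_step, gp, control$sim_volume)
      vol[seq_len(n)] <- v
      n_super <- sum(v > gp$v_c)
      zeta <- n_super / n
      p_a <- min(1, max(0, 0.5 * (tanh(gp$k5 * zeta + gp$k6) + tanh(1))))
      if (stats::runif(1) < p_a) {
        k <- round(sum(v))
        if (k > 0) {
          if (n + k > length(vol))
            vol <- c(vol, numeric(max(k, length(vol))))
          vol[n + seq_len(k)] <- gp$v0
          n <- n + k
        }
      }
      x <- secrete_kernel(pro, anti, ip$decay, n_super, p_a,
                          sum(states == 1L), sum(states == 2L), ip)
      pro <- x[1]
      anti <- x[2]
      if (length(states)) {
        p <- switch_probs(pro, anti, ip)
        states <- polarize_kernel(states, p[1], p[2], ip$revert)
      }
    }
    record(day, sum(vol[seq_len(n)]), sum(vol[seq_len(n)] > gp$v_c) / n)
  }

  out <- as.data.frame(rec)
  class(out) <- c("adiposim_trajectory", "data.frame")
  attr(out, "V0") <- V0
  attr(out, "N0") <- n0
  attr(out, "fm0") <- fm0
  attr(out, "on_days") <- on_days
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate adipose-tissue growth and inflammation over replicates
#'
#' The main entry point. Runs `replicates` independent simulations of a
#' subject under a diet protocol (replicate r is seeded `seed + r`) and
#' collects per-day trajectories and summary statistics. The returned object
#' has `print`, `summary`, `plot`, `coef` and `simulate` methods.
#'
#' @param subject An [adipose_subject()].
#' @param protocol A [diet_protocol()].
#' @param replicates Number of independent replicates (default 50).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param control A [sim_control()].
#' @return An object of class `"adiposim"`: list with `trajectories` (list
#'   of per-replicate data frames), `summary` (per-day data frame with
#'   `bw_mean`, `bw_sd`, `m1_mean`, `m2_mean`, `zeta_mean`, `n_mean`),
#'   `subject`, `protocol`, `control`, `replicates`, `seed`, `call`.
#' @examples
#' \donttest{
#' fx <- overfeeding_fixture("diaz")
#' fit <- adiposim(fx$subject, fx$protocol, replicates = 5, seed = 1)
#' print(fit)
#' }
#' @export
adiposim <- function(subject, protocol, replicates = 50, seed = 1L,
                     control = sim_control()) {
  stopifnot(replicates >= 1)
  trajs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    trajs[[r]] <- run_simulation(subject, protocol, control,
                                 seed = as.integer(seed) + r)
  }
  structure(
    list(trajectories = trajs,
         summary = summarise_replicates(trajs,
                                        control$inflammation$n_macrophages),
         subject = subject, protocol = protocol, control = control,
         replicates = as.integer(replicates), seed = as.integer(seed),
         call = match.call()),
    class = "adiposim"
  )
}

summarise_replicates <- function(trajs, n_macro) {
  bw <- sapply(trajs, `[[`, "bw_kg")
  m1 <- sapply(trajs, `[[`, "m1")
  m2 <- sapply(trajs, `[[`, "m2")
  zeta <- sapply(trajs, `[[`, "zeta")
  ncells <- sapply(trajs, `[[`, "n_cells")
  if (is.null(dim(bw))) {  # duration 0: single row
    bw <- matrix(bw, nrow = 1)
    m1 <- matrix(m1, nrow = 1)
    m2 <- matrix(m2, nrow = 1)
    zeta <- matrix(zeta, nrow = 1)
    ncells <- matrix(ncells, nrow = 1)
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(
    day = trajs[[1]]$day,
    bw_mean = rowMeans(bw),
    bw_sd = apply(bw, 1, sd0),
    m1_mean = rowMeans(m1),
    m2_mean = rowMeans(m2),
    m1_frac_mean = if (n_macro > 0) rowMeans(m1) / n_macro else 0,
    zeta_mean = rowMeans(zeta),
    n_mean = rowMeans(ncells)
  )
}

#' Onset times of an adiposim fit
#'
#' Applies [detect_onset()] to every replicate's per-day M1-fraction series.
#'
#' @param fit An [adiposim()] object.
#' @param threshold,persistence_days Onset definition; default from the
#'   fit's control settings.
#' @return Data frame with columns `replicate`, `E_kcal_day`, `onset_day`,
#'   `event_flag` (1 = onset, 0 = censored at horizon).
#' @export
onset_table <- function(fit,
                        threshold = fit$control$onset_threshold,
                        persistence_days = fit$control$onset_persistence_days) {
  stopifnot(inherits(fit, "adiposim"))
  nm <- fit$control$inflammation$n_macrophages
  res <- lapply(seq_along(fit$trajectories), function(r) {
    tr <- fit$trajectories[[r]]
    on <- detect_onset(tr$m1 / nm, threshold, persistence_days)
    data.frame(replicate = r,
               E_kcal_day = fit$protocol$excess_kcal_per_day,
               onset_day = on$time, event_flag = on$event)
  })
  do.call(rbind, res)
}
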