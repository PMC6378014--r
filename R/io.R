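# Config files, run manifests and CSV outputs.

#' Read a simulation configuration file
#'
#' Reads a YAML or JSON run configuration (chosen by file extension; `.yml`,
#' `.yaml` or anything `yaml::read_yaml` accepts, else JSON). Recognised
#' keys:
#'
#' * `subject`: `weight_kg`, `height_m`, `age_y`, `gender`
#' * `protocol`: `excess_kcal_per_day`, `days_on_per_week`, `duration_days`
#' * `replicates`, `seed`
#' * `sim_volume`, `steps_per_day`, `onset_threshold`,
#'   `onset_persistence_days`
#' * `growth`: any [growth_params()] argument (including
#'   `energy_partition_scale` and `partition`)
#' * `inflammation`: any [inflammation_params()] argument
#'
#' @param path Path to the config file.
#' @return A list with `subject`, `protocol`, `control`, `replicates`,
#'   `seed`, ready for [adiposim()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  build_config(raw)
}

build_config <- function(raw) {
  if (is.null(raw$subject) || is.null(raw$protocol))
    stop("config must contain 'subject' and 'protocol' blocks", call. = FALSE)
  subject <- adipose_subject(raw$subject$weight_kg, raw$subject$height_m,
                             raw$subject$age_y, raw$subject$gender)
  protocol <- diet_protocol(
    raw$protocol$excess_kcal_per_day,
    raw$protocol$days_on_per_week %||% 7,
    raw$protocol$duration_days)
  gp_args <- as.list(raw$growth %||% list())
  gp_args$gender <- subject$gender
  growth <- do.call(growth_params, gp_args)
  ip_args <- as.list(raw$inflammation %||% list())
  inflammation <- do.call(inflammation_params, ip_args)
  control <- sim_control(
    sim_volume = raw$sim_volume %||% 1,
    steps_per_day = raw$steps_per_day %||% 3,
    growth = growth, inflammation = inflammation,
    onset_threshold = raw$onset_threshold %||% 0.5,
    onset_persistence_days = raw$onset_persistence_days %||% 30)
  list(subject = subject, protocol = protocol, control = control,
       replicates = raw$replicates %||% 50, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and replay run manifests
#'
#' `write_run_manifest()` serialises the complete configuration of a fit
#' (subject, protocol, all parameters, replicate count and base seed) as a
#' JSON manifest; `adiposim_from_manifest()` re-runs the simulation from a
#' manifest. A replayed run is bit-identical to the original.
#'
#' @param fit An [adiposim()] object.
#' @param path Manifest file path (JSON).
#' @return `write_run_manifest()` returns `path` invisibly;
#'   `adiposim_from_manifest()` returns a new `"adiposim"` object.
#' @export
write_run_manifest <- function(fit, path) {
  stopifnot(inherits(fit, "adiposim"))
  gp <- fit$control$growth
  if (is.null(gp)) gp <- growth_params(gender = fit$subject$gender)
  manifest <- list(
    package = "adiposim",
    subject = unclass(fit$subject),
    protocol = unclass(fit$protocol),
    sim_volume = fit$control$sim_volume,
    steps_per_day = fit$control$steps_per_day,
    onset_threshold = fit$control$onset_threshold,
    onset_persistence_days = fit$control$onset_persistence_days,
    growth = unclass(gp),
    inflammation = unclass(fit$control$inflammation),
    replicates = fit$replicates,
    seed = fit$seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
adiposim_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- build_config(m)
  adiposim(cfg$subject, cfg$protocol, replicates = cfg$replicates,
           seed = cfg$seed, control = cfg$control)
}

#' Write trajectories and summary tables as CSV
#'
#' Writes one `trajectory_<r>.csv` per replicate (columns `day`, `bw_kg`,
#' `n_cells`, `v_total_ul`, `v_mean_ul`, `zeta`, `pro`, `anti`, `m0`, `m1`,
#' `m2`), a `summary.csv` of per-day replicate means/SDs, an `onsets.csv`
#' table and a `manifest.json`.
#'
#' @param fit An [adiposim()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_trajectories <- function(fit, dir) {
  stopifnot(inherits(fit, "adiposim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(fit$trajectories)) {
    utils::write.csv(fit$trajectories[[r]],
                     file.path(dir, sprintf("trajectory_%03d.csv", r)),
                     row.names = FALSE)
  }
  utils::write.csv(fit$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(onset_table(fit), file.path(dir, "onsets.csv"),
                   row.names = FALSE)
  write_run_manifest(fit, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Write Kaplan-Meier tables of a sweep as CSV
#'
#' One `km_E<level>.csv` per energy level (columns `time`, `survival`,
#' `n_risk`, `n_event`) plus the stacked `onsets.csv`.
#'
#' @param sweep An [energy_sweep()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_km_tables <- function(sweep, dir) {
  stopifnot(inherits(sweep, "adiposim_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kms <- sweep_km(sweep)
  for (nm in names(kms)) {
    utils::write.csv(as.data.frame(kms[[nm]]),
                     file.path(dir, sprintf("km_E%s.csv", nm)),
                     row.names = FALSE)
  }
  utils::write.csv(sweep$onsets, file.path(dir, "onsets.csv"),
                   row.names = FALSE)
  invisible(dir)
}
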