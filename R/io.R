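# config schema version written into files and manifests
CONFIG_SCHEMA_VERSION <- 1L

config_to_list <- function(x) {
  if (inherits(x, "cohort_spec")) {
    out <- config_to_list(x$config)
    out$replicates <- x$n_replicates
    out$seed <- x$base_seed
    return(out)
  }
  stopifnot(inherits(x, "sim_config"))
  out <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    distribution = x$distribution$name,
    rates = list(alpha = x$rates$alpha, delta = x$rates$delta,
                 mu = x$rates$mu, dose_response = x$rates$dose_response,
                 misseg_sampling = x$rates$misseg_sampling,
                 division_crowding_scale = x$rates$division_crowding_scale),
    initial_population = x$initial_population,
    capacity = x$capacity,
    detection_threshold = x$detection_threshold,
    max_population = x$max_population,
    max_steps = x$max_steps,
    scenario = if (is.null(x$therapy)) "none" else x$therapy$scenario,
    seed = x$seed
  )
  if (x$distribution$name == "custom") {
    out$custom_distribution <- apply(x$distribution$content, 1L, function(r) {
      as.list(r[r > 0])
    }, simplify = FALSE)
  }
  if (!is.null(x$therapy) && x$therapy$scenario != "none") {
    out$therapy <- list(
      surgery_keep_head = x$therapy$surgery_keep_head,
      surgery_removal = x$therapy$surgery_removal,
      chemo_rounds = x$therapy$chemo_rounds,
      chemo_includes_intervention_step =
        x$therapy$chemo_includes_intervention_step,
      surgery_mode = x$therapy$surgery_mode
    )
  }
  out
}

#' Write a configuration to a YAML file
#'
#' @param config a [sim_config()] or [cohort_spec()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Load a configuration from a YAML file
#'
#' Reads a human-readable key-value config, fills in the documented defaults
#' for any omitted field (the model's standard parameters: alpha = delta =
#' 0.045, mu = 0.02, 100 initial cells, capacity 200, detection at 1000,
#' termination at 7000 cells or 300 steps), validates all invariants, and
#' returns either a single-run [sim_config()] or, when a `replicates` field
#' greater than 1 is present, a [cohort_spec()].
#'
#' @param path YAML file path.
#' @return a `sim_config` or `cohort_spec`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  known <- c("schema_version", "distribution", "custom_distribution", "rates",
             "initial_population", "capacity", "detection_threshold",
             "max_population", "max_steps", "scenario", "therapy", "seed",
             "replicates")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config_from_list(raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_from_list <- function(raw) {
  dist_name <- raw$distribution %||% "A"
  dist <- if (identical(dist_name, "custom")) {
    if (is.null(raw$custom_distribution)) {
      stop("config error: distribution \"custom\" needs a custom_distribution",
           call. = FALSE)
    }
    gene_distribution(lapply(raw$custom_distribution, unlist))
  } else {
    as_gene_distribution(dist_name)
  }
  r <- raw$rates %||% list()
  rates <- rate_params(alpha = r$alpha %||% 0.045,
                       delta = r$delta %||% 0.045,
                       mu = r$mu %||% 0.02,
                       dose_response = r$dose_response %||% "linear",
                       misseg_sampling = r$misseg_sampling %||% "copy",
                       division_crowding_scale =
                         r$division_crowding_scale %||% 1)
  scenario <- raw$scenario %||% "none"
  detection <- raw$detection_threshold %||% 1000L
  plan <- if (identical(scenario, "none")) NULL else {
    th <- raw$therapy %||% list()
    therapy_plan(scenario = scenario,
                 detection_threshold = detection,
                 surgery_keep_head = th$surgery_keep_head %||% 100L,
                 surgery_removal = th$surgery_removal %||% 900L,
                 chemo_rounds = th$chemo_rounds %||% 9L,
                 chemo_includes_intervention_step =
                   th$chemo_includes_intervention_step %||% TRUE,
                 surgery_mode = th$surgery_mode %||% "fraction")
  }
  cfg <- sim_config(distribution = dist, rates = rates,
                    initial_population = raw$initial_population %||% 100L,
                    capacity = raw$capacity %||% 200L,
                    detection_threshold = detection,
                    max_population = raw$max_population %||% 7000L,
                    max_steps = raw$max_steps %||% 300L,
                    therapy = plan,
                    seed = raw$seed %||% 1L)
  n_rep <- raw$replicates %||% 1L
  if (n_rep > 1L) cohort_spec(cfg, n_rep, cfg$seed) else cfg
}

# tiny stable content hash (FNV-1a, 32-bit) for manifests.
# arithmetic kept exact in doubles: xor touches only the low byte, and the
# multiply is split 16/16 so no intermediate exceeds 2^53.
fnv1a_hash <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * p + ((hi16 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(yaml::as.yaml(config_to_list(config)))
}

write_manifest <- function(out_dir, config, files, seeds) {
  manifest <- list(
    artifact = "karyosim",
    version = as.character(utils::packageVersion("karyosim")),
    config_hash = config_hash(config),
    seeds = seeds,
    files = files,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Export run or cohort outputs
#'
#' Writes the standard file inventory to a directory. For a single
#' trajectory: `trajectory.csv` (one row per step), `composition_long.csv`
#' (step, n_div, n_apop, n_seg, count; when recorded), `events.json` (event
#' markers and config echo). For a cohort: `replicates.csv` (one row per
#' replicate) and `summary.json` (means, standard deviations, seeds, config
#' echo). Both get a `manifest.json` listing every file with a stable config
#' hash. All tables round-trip through standard CSV readers.
#'
#' @param x a `sim_trajectory` or `sim_cohort`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
export_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  UseMethod("export_outputs")
}

#' @export
export_outputs.sim_trajectory <- function(x, out_dir) {
  files <- character(0)
  traj_cols <- c("step", "population", "mean_div", "mean_apop", "mean_seg",
                 "deaths", "divisions", "missegregations", "chemo_kills",
                 "n_genotypes")
  utils::write.csv(x$steps[, traj_cols],
                   file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  files <- c(files, "trajectory.csv")
  if (!is.null(x$composition)) {
    utils::write.csv(x$composition, file.path(out_dir, "composition_long.csv"),
                     row.names = FALSE)
    files <- c(files, "composition_long.csv")
  }
  ev <- x$events
  ev$config <- config_to_list(x$config)
  jsonlite::write_json(ev, file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  files <- c(files, "events.json")
  manifest <- write_manifest(out_dir, x$config, c(files, "manifest.json"),
                             seeds = x$config$seed)
  invisible(manifest)
}

#' @export
export_outputs.sim_cohort <- function(x, out_dir) {
  utils::write.csv(x$replicates, file.path(out_dir, "replicates.csv"),
                   row.names = FALSE)
  summ <- x$summary
  summ$config <- config_to_list(x$spec)
  summ$seeds <- x$replicates$seed
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  manifest <- write_manifest(out_dir, x$spec,
                             c("replicates.csv", "summary.json",
                               "manifest.json"),
                             seeds = x$replicates$seed)
  invisible(manifest)
}

#' Re-read exported tables
#'
#' Convenience readers for the files written by [export_outputs()]; used for
#' round-trip checks and re-plotting.
#'
#' @param out_dir directory written by [export_outputs()].
#' @return `read_trajectory()`: list of `steps`, `composition` (or `NULL`)
#'   and `events`; `read_cohort_table()`: the replicate data frame.
#' @export
read_trajectory <- function(out_dir) {
  steps <- utils::read.csv(file.path(out_dir, "trajectory.csv"))
  comp_path <- file.path(out_dir, "composition_long.csv")
  comp <- if (file.exists(comp_path)) utils::read.csv(comp_path) else NULL
  events <- jsonlite::read_json(file.path(out_dir, "events.json"),
                                simplifyVector = TRUE)
  list(steps = steps, composition = comp, events = events)
}

#' @rdname read_trajectory
#' @export
read_cohort_table <- function(out_dir) {
  utils::read.csv(file.path(out_dir, "replicates.csv"))
}
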