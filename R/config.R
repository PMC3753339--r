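#' Rate parameters of the stochastic engine
#'
#' The per-step behaviour of every cell is governed by three gene-dose rules:
#' \describe{
#'   \item{apoptosis}{only when the step-start population exceeds the carrying
#'     capacity; default linear dose `min(1, alpha * n_apop)`.}
#'   \item{division}{`min(1, delta * n_div)`; a cell with six division-gene
#'     copies divides three times as often as the diploid baseline.}
#'   \item{mis-segregation}{conditional on division; default inverse dose
#'     `min(1, 2 * mu / n_seg)`, equal to `mu` at diploidy (n_seg = 2) and 1
#'     when all segregation genes are lost.}
#' }
#'
#' @param alpha apoptosis rate per apoptosis-gene copy (default 0.045).
#' @param delta division rate per division-gene copy (default 0.045).
#' @param mu baseline (diploid) mis-segregation rate (default 0.02).
#' @param dose_response `"linear"` (default) or `"exponential"`
#'   (`1 - exp(-rate * n)`) for the apoptosis and division doses; the
#'   mis-segregation dose is always the calibrated inverse form.
#' @param misseg_sampling `"copy"` (default) or `"type"`: whether the
#'   mis-segregating chromosome is drawn uniformly over chromosome copies or
#'   over chromosome types.
#' @param division_crowding_scale multiplier applied to the division
#'   probability when the population exceeds capacity (default 1: crowding
#'   acts through death only).
#' @return an object of class `rate_params`.
#' @examples
#' rate_params()
#' @export
rate_params <- function(alpha = 0.045, delta = 0.045, mu = 0.02,
                        dose_response = c("linear", "exponential"),
                        misseg_sampling = c("copy", "type"),
                        division_crowding_scale = 1) {
  dose_response <- dose_response[1L]
  if (!dose_response %in% c("linear", "exponential")) {
    stop("unknown dose_response \"", dose_response,
         "\": must be \"linear\" or \"exponential\"", call. = FALSE)
  }
  misseg_sampling <- misseg_sampling[1L]
  if (!misseg_sampling %in% c("copy", "type")) {
    stop("unknown misseg_sampling \"", misseg_sampling,
         "\": must be \"copy\" or \"type\"", call. = FALSE)
  }
  for (nm in c("alpha", "delta", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("rate parameter '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.numeric(division_crowding_scale) || division_crowding_scale < 0 ||
      division_crowding_scale > 1) {
    stop("division_crowding_scale must be in [0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, delta = delta, mu = mu,
                 dose_response = dose_response,
                 misseg_sampling = misseg_sampling,
                 division_crowding_scale = division_crowding_scale),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("Rates: alpha=%g delta=%g mu=%g (dose %s, misseg sampling per %s)\n",
              x$alpha, x$delta, x$mu, x$dose_response, x$misseg_sampling))
  invisible(x)
}

#' Therapy plan
#'
#' Describes the single intervention of a run. Detection occurs when the
#' end-of-step population first reaches `detection_threshold`; the
#' intervention executes at the start of the following step. Surgery keeps
#' the first `surgery_keep_head` cells in list order, deletes the next
#' `surgery_removal` contiguous cells and retains any overshoot tail.
#' Chemotherapy kills every cell that attempts division during `chemo_rounds`
#' consecutive steps after detection. Combination is surgery followed by the
#' chemotherapy window.
#'
#' @param scenario one of `"none"`, `"surgery"`, `"chemotherapy"`,
#'   `"combination"`.
#' @param detection_threshold population size triggering the intervention
#'   (default 1000 cells).
#' @param surgery_keep_head cells retained at the head of the list (default 100).
#' @param surgery_removal contiguous cells removed (default 900); the head and
#'   removal segment must together equal the detection threshold.
#' @param chemo_rounds consecutive chemotherapy steps (default 9).
#' @param chemo_includes_intervention_step logical; if `TRUE` (default) the
#'   chemotherapy window starts at the intervention step itself (the step
#'   after detection), covering `chemo_rounds` steps.
#' @param surgery_mode `"fraction"` (default) removes a contiguous segment
#'   containing the fraction `surgery_removal / detection_threshold` (90
#'   percent at the defaults) of the population present at the intervention,
#'   so the residual is about a tenth of the detected tumour regardless of
#'   detection overshoot; `"fixed"` removes exactly `surgery_removal` cells.
#'   The two coincide when the intervention finds exactly
#'   `detection_threshold` cells.
#' @return an object of class `therapy_plan`.
#' @export
therapy_plan <- function(scenario = c("none", "surgery", "chemotherapy",
                                      "combination"),
                         detection_threshold = 1000L,
                         surgery_keep_head = 100L,
                         surgery_removal = 900L,
                         chemo_rounds = 9L,
                         chemo_includes_intervention_step = TRUE,
                         surgery_mode = c("fraction", "fixed")) {
  scenario <- match.arg(scenario)
  surgery_mode <- match.arg(surgery_mode)
  detection_threshold <- as.integer(detection_threshold)
  surgery_keep_head <- as.integer(surgery_keep_head)
  surgery_removal <- as.integer(surgery_removal)
  chemo_rounds <- as.integer(chemo_rounds)
  if (detection_threshold < 1L) {
    stop("detection_threshold must be positive", call. = FALSE)
  }
  if (scenario %in% c("surgery", "combination") &&
      surgery_keep_head + surgery_removal != detection_threshold) {
    stop("surgery_keep_head + surgery_removal must equal detection_threshold",
         call. = FALSE)
  }
  if (scenario %in% c("chemotherapy", "combination") && chemo_rounds < 1L) {
    stop("chemo_rounds must be >= 1", call. = FALSE)
  }
  structure(list(scenario = scenario,
                 detection_threshold = detection_threshold,
                 surgery_keep_head = surgery_keep_head,
                 surgery_removal = surgery_removal,
                 chemo_rounds = chemo_rounds,
                 chemo_includes_intervention_step =
                   isTRUE(chemo_includes_intervention_step),
                 surgery_mode = surgery_mode),
            class = "therapy_plan")
}

#' @export
print.therapy_plan <- function(x, ...) {
  cat("Therapy plan:", x$scenario)
  if (x$scenario != "none") {
    cat(sprintf(" (detect at %d cells", x$detection_threshold))
    if (x$scenario %in% c("surgery", "combination")) {
      cat(sprintf(", keep %d / remove %d", x$surgery_keep_head,
                  x$surgery_removal))
    }
    if (x$scenario %in% c("chemotherapy", "combination")) {
      cat(sprintf(", %d chemo rounds", x$chemo_rounds))
    }
    cat(")")
  }
  cat("\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles everything a single run needs. Defaults are the model's standard
#' experimental conditions: 100 diploid cells, carrying capacity 200,
#' detection at 1000 cells, termination at 7000 cells or 300 time steps,
#' rates alpha = delta = 0.045 and mu = 0.02.
#'
#' @param distribution gene distribution name or [gene_distribution()].
#' @param rates a [rate_params()] object.
#' @param initial_population starting number of diploid cells.
#' @param capacity homeostatic carrying capacity of the tissue (cells).
#' @param detection_threshold tumour detection size (cells).
#' @param max_population terminate when the population reaches this size.
#' @param max_steps terminate after this many time steps.
#' @param therapy a [therapy_plan()] or `NULL` for an untreated run.
#' @param seed integer seed for the run's random stream.
#' @param record_composition logical; keep the per-step genotype composition
#'   table (needed for marble diagrams; off by default in cohorts).
#' @param keep_tissue logical; keep the final tissue matrix in the result.
#' @return an object of class `sim_config`.
#' @examples
#' sim_config(distribution = "B", therapy = therapy_plan("surgery"))
#' @export
sim_config <- function(distribution = "A",
                       rates = rate_params(),
                       initial_population = 100L,
                       capacity = 200L,
                       detection_threshold = 1000L,
                       max_population = 7000L,
                       max_steps = 300L,
                       therapy = NULL,
                       seed = 1L,
                       record_composition = TRUE,
                       keep_tissue = TRUE) {
  dist <- as_gene_distribution(distribution)
  if (!inherits(rates, "rate_params")) stop("rates must be a rate_params object",
                                            call. = FALSE)
  initial_population <- as.integer(initial_population)
  capacity <- as.integer(capacity)
  detection_threshold <- as.integer(detection_threshold)
  max_population <- as.integer(max_population)
  max_steps <- as.integer(max_steps)
  if (!is.null(therapy) && !inherits(therapy, "therapy_plan")) {
    stop("therapy must be a therapy_plan or NULL", call. = FALSE)
  }
  if (initial_population <= 0L) {
    stop("initial_population must be positive", call. = FALSE)
  }
  if (initial_population > capacity) {
    stop("initial_population must not exceed capacity", call. = FALSE)
  }
  if (capacity >= detection_threshold) {
    stop("capacity must be below detection_threshold", call. = FALSE)
  }
  if (detection_threshold > max_population) {
    stop("detection_threshold must not exceed max_population", call. = FALSE)
  }
  if (max_steps <= 0L) stop("max_steps must be positive", call. = FALSE)
  if (!is.null(therapy) && therapy$scenario != "none" &&
      therapy$detection_threshold != detection_threshold) {
    stop("therapy plan detection_threshold (", therapy$detection_threshold,
         ") disagrees with config detection_threshold (", detection_threshold,
         ")", call. = FALSE)
  }
  structure(list(distribution = dist, rates = rates,
                 initial_population = initial_population,
                 capacity = capacity,
                 detection_threshold = detection_threshold,
                 max_population = max_population,
                 max_steps = max_steps,
                 therapy = therapy,
                 seed = as.integer(seed),
                 record_composition = isTRUE(record_composition),
                 keep_tissue = isTRUE(keep_tissue)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config\n")
  cat("  distribution:", x$distribution$name, "\n")
  cat(sprintf("  rates: alpha=%g delta=%g mu=%g (%s dose)\n", x$rates$alpha,
              x$rates$delta, x$rates$mu, x$rates$dose_response))
  cat(sprintf("  population: start %d, capacity %d, detect %d, stop at %d cells or %d steps\n",
              x$initial_population, x$capacity, x$detection_threshold,
              x$max_population, x$max_steps))
  cat("  therapy:", if (is.null(x$therapy)) "none" else x$therapy$scenario,
      "| seed:", x$seed, "\n")
  invisible(x)
}
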