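#' Tumour detection
#'
#' A tumour is detected when the population first reaches the detection
#' threshold; at most one intervention is triggered per run.
#'
#' @param population current population count.
#' @param plan a [therapy_plan()].
#' @param already_treated has an intervention already been triggered?
#' @return logical: does detection fire now?
#' @export
detect_tumour <- function(population, plan, already_treated = FALSE) {
  !already_treated && population >= plan$detection_threshold
}

# surgery on the raw cell matrix: keep the list head, delete the next
# `removal` contiguous cells, keep any overshoot tail.  In "fraction" mode
# the removed segment scales with the population actually present, so the
# residual is ~10% of the detected tumour whatever the detection overshoot.
surgery_matrix <- function(M, plan) {
  n <- nrow(M)
  removal <- if (plan$surgery_mode == "fraction") {
    as.integer(round(n * plan$surgery_removal / plan$detection_threshold))
  } else {
    plan$surgery_removal
  }
  if (n < plan$surgery_keep_head + removal) {
    stop("surgery needs at least ", plan$surgery_keep_head + removal,
         " cells (have ", n, ")", call. = FALSE)
  }
  keep <- c(seq_len(plan$surgery_keep_head),
            seq.int(plan$surgery_keep_head + removal + 1L,
                    length.out = n - plan$surgery_keep_head - removal))
  M[keep, , drop = FALSE]
}

#' Surgical resection of a tissue
#'
#' Retains the first `surgery_keep_head` cells in list order, deletes the
#' next contiguous segment (90 percent of the present population in the
#' default `"fraction"` mode, or exactly `surgery_removal` cells in `"fixed"`
#' mode), and retains any cells beyond it, preserving order. Because
#' daughters are placed adjacent to mothers, the removed segment is a
#' lineage-correlated block -- the model's abstraction of removing the tumour
#' bulk plus margin.
#'
#' @param tissue a [new_tissue()] object.
#' @param plan a [therapy_plan()].
#' @return the post-surgery `tissue`.
#' @export
apply_surgery <- function(tissue, plan) {
  stopifnot(inherits(tissue, "tissue"))
  tissue$cells <- surgery_matrix(tissue$cells, plan)
  tissue
}

#' Chemotherapy window
#'
#' The steps during which the anti-mitotic treatment is active: exactly
#' `chemo_rounds` consecutive steps beginning the step after detection.
#'
#' @param detection_step step at which the tumour was detected.
#' @param plan a [therapy_plan()].
#' @return integer vector of active step indices.
#' @export
chemo_window <- function(detection_step, plan) {
  first <- if (plan$chemo_includes_intervention_step) detection_step + 1L
           else detection_step + 2L
  seq.int(first, length.out = plan$chemo_rounds)
}

#' Relapse time of a treated run
#'
#' The number of time steps until the population first re-reaches the
#' detection threshold, measured from the end of treatment (the default):
#' the surgery step for surgery, the last chemotherapy round for
#' chemotherapy and combination. With `origin = "intervention"` the clock
#' starts at the intervention step instead (the surgery step or first chemo
#' round), counting that step as the first; the two origins coincide for
#' surgery and differ by the chemotherapy window length otherwise. `NA` if
#' the run terminated before relapsing (censored).
#'
#' @param trajectory a [run_simulation()] result from a treated run.
#' @param origin `"treatment_end"` (default) or `"intervention"`.
#' @return integer number of steps, or `NA` if censored.
#' @export
relapse_time <- function(trajectory,
                         origin = c("treatment_end", "intervention")) {
  origin <- match.arg(origin)
  e <- trajectory$events
  if (e$scenario == "none" || is.na(e$detection_step)) {
    stop("relapse_time is only defined for a treated trajectory", call. = FALSE)
  }
  if (origin == "treatment_end") trajectory_relapse_time(trajectory)
  else trajectory_relapse_time_intervention(trajectory)
}

treatment_end_step <- function(events) {
  if (!is.na(events$chemo_last)) events$chemo_last
  else events$intervention_step
}

# headline relapse clock: steps elapsed after the treatment completed
# (for surgery the treatment is instantaneous, so the surgery step counts
# as the first post-treatment step)
trajectory_relapse_time <- function(trajectory) {
  e <- trajectory$events
  if (is.na(e$relapse_step) || is.na(e$intervention_step)) return(NA_integer_)
  end <- treatment_end_step(e)
  if (!is.na(e$chemo_last)) e$relapse_step - end
  else e$relapse_step - e$intervention_step + 1L
}

trajectory_relapse_time_intervention <- function(trajectory) {
  e <- trajectory$events
  if (is.na(e$relapse_step) || is.na(e$intervention_step)) return(NA_integer_)
  e$relapse_step - e$intervention_step + 1L
}

#' Therapy outcome of a single run
#'
#' Per-replicate bookkeeping used by cohorts: detection step and size,
#' population immediately after surgery, population at the end of the
#' chemotherapy window, mean per-step chemotherapy kill fraction, relapse
#' step/time and censoring.
#'
#' @param trajectory a [run_simulation()] result.
#' @return a one-row data frame.
#' @export
therapy_outcome <- function(trajectory) {
  e <- trajectory$events
  s <- trajectory$steps
  cells_end_chemo <- NA_integer_
  chemo_kill_frac <- NA_real_
  chemo_decline_frac <- NA_real_
  if (!is.na(e$chemo_first)) {
    w <- e$chemo_first:e$chemo_last
    w <- w[w <= nrow(s)]
    if (length(w)) {
      cells_end_chemo <- s$population[max(w)]
      denom <- s$pop_start[w]
      ok <- denom > 0L
      if (any(ok)) {
        # anti-mitotic kills alone, and the total per-step population
        # decline (anti-mitotic kills + crowding deaths; there are no
        # births while the treatment is active)
        chemo_kill_frac <- mean(s$chemo_kills[w][ok] / denom[ok])
        chemo_decline_frac <-
          mean((denom[ok] - s$population[w][ok]) / denom[ok])
      }
    }
  }
  data.frame(scenario = e$scenario,
             detection_step = e$detection_step,
             cells_at_detection = e$cells_at_detection,
             cells_post_surgery = e$cells_post_surgery,
             cells_end_chemo = cells_end_chemo,
             chemo_kill_frac = chemo_kill_frac,
             chemo_decline_frac = chemo_decline_frac,
             relapse_step = e$relapse_step,
             relapse_time = trajectory_relapse_time(trajectory),
             relapse_time_from_intervention =
               trajectory_relapse_time_intervention(trajectory),
             censored = !is.na(e$detection_step) && is.na(e$relapse_step),
             detected = !is.na(e$detection_step),
             termination = e$termination,
             final_population = if (nrow(s)) s$population[nrow(s)] else 0L,
             final_step = nrow(s))
}
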