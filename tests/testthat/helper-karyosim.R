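# shared builders for the simulation tests

default_therapy_config <- function(distribution, scenario, ...) {
  sim_config(distribution = distribution,
             therapy = therapy_plan(scenario),
             record_composition = FALSE, keep_tissue = FALSE, ...)
}

# a genome with explicit per-type copy counts on a named distribution
genome_with_counts <- function(distribution, counts) {
  g <- make_initial_genome(distribution)
  g[] <- as.integer(counts)
  g
}

# minimal treated trajectory skeleton for testing event bookkeeping
fake_treated_trajectory <- function(detection_step, relapse_step,
                                    scenario = "surgery",
                                    chemo_last = NA_integer_) {
  structure(list(
    events = list(detection_step = detection_step,
                  intervention_step = detection_step + 1L,
                  cells_at_detection = 1000L,
                  cells_post_surgery = NA_integer_,
                  chemo_first = if (is.na(chemo_last)) NA_integer_
                                else detection_step + 1L,
                  chemo_last = chemo_last,
                  relapse_step = relapse_step,
                  scenario = scenario,
                  termination = "max_steps"),
    steps = data.frame()
  ), class = "sim_trajectory")
}
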