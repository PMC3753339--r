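#' Genotypic diversity
#'
#' The number of distinct genotype states present in a population (richness).
#'
#' @param composition a composition table with a `count` column (as produced
#'   per step by [run_simulation()]), or a named vector of counts.
#' @return integer count of distinct genotypes with count > 0.
#' @examples
#' genotype_diversity(data.frame(n_div = c(2, 3), n_apop = c(2, 1),
#'                               n_seg = c(2, 2), count = c(5, 2)))
#' @export
genotype_diversity <- function(composition) {
  counts <- if (is.data.frame(composition)) composition$count
            else as.numeric(composition)
  sum(counts > 0)
}

#' Shannon entropy of a genotype composition
#'
#' Exported alongside richness as a robustness check on diversity trends.
#'
#' @inheritParams genotype_diversity
#' @return Shannon entropy (nats); 0 for a monoclonal or empty population.
#' @export
genotype_entropy <- function(composition) {
  counts <- if (is.data.frame(composition)) composition$count
            else as.numeric(composition)
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Apoptosis/division gene-ratio series after an intervention
#'
#' The per-step ratio of the mean number of apoptosis genes to the mean
#' number of division genes, indexed from the intervention step (index 0).
#' The falling ratio after treatment tracks the loss of tumour suppression
#' and gain of oncogenic load in the recovering population.
#'
#' @param trajectory a treated [run_simulation()] result.
#' @param window number of steps retained, starting at the intervention step.
#' @return data frame with columns `step_rel` (0-based) and `ratio`
#'   (`NA` where the mean division count is 0).
#' @export
ratio_series <- function(trajectory, window = 25L) {
  e <- trajectory$events
  if (e$scenario == "none" || is.na(e$intervention_step)) {
    stop("ratio_series needs a treated trajectory", call. = FALSE)
  }
  s <- trajectory$steps
  idx <- seq.int(e$intervention_step, length.out = window)
  idx <- idx[idx <= nrow(s)]
  ratio <- ifelse(s$mean_div[idx] > 0, s$mean_apop[idx] / s$mean_div[idx],
                  NA_real_)
  data.frame(step_rel = idx - e$intervention_step, ratio = ratio)
}

#' Slope of the gene-ratio series
#'
#' Ordinary least-squares slope of the apoptosis/division ratio against the
#' step index over a post-intervention window (default 25 steps, intervention
#' step at index 0). Replicates whose run ends inside the window contribute
#' their available points.
#'
#' @param series a data frame from [ratio_series()] (columns `step_rel`,
#'   `ratio`), or a bare numeric vector of ratios at consecutive steps.
#' @param window number of leading points used.
#' @return the OLS slope (ratio units per time step).
#' @examples
#' ratio_slope(1 - 0.005 * (0:24))  # exactly -0.005
#' @export
ratio_slope <- function(series, window = 25L) {
  if (is.numeric(series)) {
    series <- data.frame(step_rel = seq_along(series) - 1, ratio = series)
  }
  series <- series[series$step_rel < window & !is.na(series$ratio), , drop = FALSE]
  if (nrow(series) < 2L) {
    stop("ratio_slope needs at least 2 defined points in the window",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(ratio ~ step_rel, data = series))[2L])
}

#' Unpaired two-sample t-test
#'
#' Classical equal-variance two-sided t-test used to compare cohort outcomes
#' (relapse times, ratio slopes) between gene distributions.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return list with `statistic`, `p.value` and `df`.
#' @examples
#' unpaired_ttest(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_ttest <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("degenerate samples: pooled variance is zero", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

#' Replicate cohort specification
#'
#' A cohort is `n_replicates` independent runs of one configuration;
#' replicate `i` is seeded with `base_seed + i` so the whole cohort is
#' reproducible from the base seed.
#'
#' @param config a [sim_config()] shared by all replicates.
#' @param n_replicates number of replicate runs.
#' @param base_seed integer base seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(config, n_replicates = 100L, base_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(config = config, n_replicates = n_replicates,
                 base_seed = as.integer(base_seed)),
            class = "cohort_spec")
}

#' Run a replicate cohort
#'
#' Runs the seeded replicates, collects per-replicate therapy outcomes and
#' post-intervention gene-ratio slopes, and summarises them. Deterministic
#' given the base seed.
#'
#' @param spec a [cohort_spec()] (or a [sim_config()], with `n_replicates`
#'   and `base_seed` supplied here).
#' @param n_replicates,base_seed used when `spec` is a bare config.
#' @param keep_trajectories logical: retain the individual `sim_trajectory`
#'   objects (needed for broom/marble plots; memory-heavy for large cohorts).
#' @param slope_window window length for [ratio_slope()].
#' @return an object of class `sim_cohort`: the spec, a per-replicate data
#'   frame `replicates`, a `summary` list of means and standard deviations,
#'   and optionally `trajectories`.
#' @examples
#' cfg <- sim_config(distribution = "A", max_steps = 30)
#' co <- run_cohort(cohort_spec(cfg, n_replicates = 3, base_seed = 1))
#' co$replicates$final_population
#' @export
run_cohort <- function(spec, n_replicates = 100L, base_seed = NULL,
                       keep_trajectories = FALSE, slope_window = 25L) {
  if (inherits(spec, "sim_config")) {
    spec <- cohort_spec(spec, n_replicates,
                        if (is.null(base_seed)) spec$seed else base_seed)
  }
  stopifnot(inherits(spec, "cohort_spec"))
  cfg <- spec$config
  cfg$record_composition <- FALSE
  cfg$keep_tissue <- FALSE
  rows <- vector("list", spec$n_replicates)
  trajs <- if (keep_trajectories) vector("list", spec$n_replicates) else NULL
  for (i in seq_len(spec$n_replicates)) {
    cfg$seed <- spec$base_seed + i
    tr <- run_simulation(cfg)
    row <- therapy_outcome(tr)
    row$replicate <- i
    row$seed <- cfg$seed
    row$ratio_slope <- if (row$detected) {
      sr <- ratio_series(tr, slope_window)
      if (sum(!is.na(sr$ratio)) >= 2L) ratio_slope(sr, slope_window) else NA_real_
    } else NA_real_
    rows[[i]] <- row
    if (keep_trajectories) trajs[[i]] <- tr
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  out <- structure(list(spec = spec, replicates = reps,
                        summary = summarise_replicates(reps),
                        trajectories = trajs),
                   class = "sim_cohort")
  out
}

mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
       n = length(x))
}

summarise_replicates <- function(reps) {
  list(
    n_replicates = nrow(reps),
    n_detected = sum(reps$detected),
    n_censored = sum(reps$censored),
    cells_post_surgery = mean_sd(reps$cells_post_surgery),
    cells_end_chemo = mean_sd(reps$cells_end_chemo),
    chemo_kill_frac = mean_sd(reps$chemo_kill_frac),
    chemo_decline_frac = mean_sd(reps$chemo_decline_frac),
    relapse_time = mean_sd(reps$relapse_time),
    relapse_time_from_intervention =
      mean_sd(reps$relapse_time_from_intervention),
    relapse_time_censored_as_max = {
      # censored replicates carried at their censoring time (run end)
      rt <- reps$relapse_time
      cen <- reps$censored & !is.na(reps$detection_step)
      rt[cen] <- reps$final_step[cen] - reps$detection_step[cen]
      mean_sd(rt)
    },
    ratio_slope = mean_sd(reps$ratio_slope),
    final_population = mean_sd(reps$final_population)
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort: %d replicates, distribution %s, scenario %s (base seed %d)\n",
              s$n_replicates, x$spec$config$distribution$name,
              if (is.null(x$spec$config$therapy)) "none"
              else x$spec$config$therapy$scenario,
              x$spec$base_seed))
  if (s$n_detected > 0L) {
    cat(sprintf("  detected: %d, censored: %d\n", s$n_detected, s$n_censored))
    if (!is.na(s$relapse_time$mean)) {
      cat(sprintf("  relapse time: mean %.2f (sd %.2f, n %d)\n",
                  s$relapse_time$mean, s$relapse_time$sd, s$relapse_time$n))
    }
  }
  cat(sprintf("  final population: mean %.1f\n", s$final_population$mean))
  invisible(x)
}

#' @export
summary.sim_cohort <- function(object, ...) object$summary

#' Compare two cohorts
#'
#' Unpaired equal-variance t-tests on relapse times and on post-intervention
#' gene-ratio slopes between two cohorts (e.g. gene distributions B vs C
#' under one therapy scenario).
#'
#' @param cohort_a,cohort_b [run_cohort()] results.
#' @return an object of class `cohort_comparison` with the two summaries and
#'   the t-test results.
#' @export
compare_cohorts <- function(cohort_a, cohort_b) {
  stopifnot(inherits(cohort_a, "sim_cohort"), inherits(cohort_b, "sim_cohort"))
  ra <- cohort_a$replicates; rb <- cohort_b$replicates
  tests <- list()
  if (sum(!is.na(ra$relapse_time)) >= 2L && sum(!is.na(rb$relapse_time)) >= 2L) {
    tests$relapse_time <- unpaired_ttest(ra$relapse_time, rb$relapse_time)
  }
  if (sum(!is.na(ra$ratio_slope)) >= 2L && sum(!is.na(rb$ratio_slope)) >= 2L) {
    tests$ratio_slope <- unpaired_ttest(ra$ratio_slope, rb$ratio_slope)
  }
  structure(list(summary_a = cohort_a$summary, summary_b = cohort_b$summary,
                 label_a = cohort_a$spec$config$distribution$name,
                 label_b = cohort_b$spec$config$distribution$name,
                 tests = tests),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison: %s vs %s\n", x$label_a, x$label_b))
  if (!is.null(x$tests$relapse_time)) {
    cat(sprintf("  relapse time: %.2f vs %.2f (t = %.3f, p = %.4g)\n",
                x$summary_a$relapse_time$mean, x$summary_b$relapse_time$mean,
                x$tests$relapse_time$statistic, x$tests$relapse_time$p.value))
  }
  if (!is.null(x$tests$ratio_slope)) {
    cat(sprintf("  ratio slope: %.4f vs %.4f (t = %.3f, p = %.4g)\n",
                x$summary_a$ratio_slope$mean, x$summary_b$ratio_slope$mean,
                x$tests$ratio_slope$statistic, x$tests$ratio_slope$p.value))
  }
  invisible(x)
}
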