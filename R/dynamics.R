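# Internal vectorised dose rules operating on raw gene-copy counts.
# These are the hot path; the exported *_probability() wrappers add the
# genotype-state interface and input checks.

p_apoptosis_vec <- function(n_apop, params) {
  p <- switch(params$dose_response,
    linear = params$alpha * n_apop,
    exponential = 1 - exp(-params$alpha * n_apop)
  )
  pmin(p, 1)
}

p_division_vec <- function(n_div, params, crowded = FALSE) {
  p <- switch(params$dose_response,
    linear = params$delta * n_div,
    exponential = 1 - exp(-params$delta * n_div)
  )
  p <- pmin(p, 1)
  if (crowded && params$division_crowding_scale < 1) {
    p <- p * params$division_crowding_scale
  }
  p
}

p_misseg_vec <- function(n_seg, params) {
  # inverse dose, calibrated so the diploid (n_seg = 2) value equals mu;
  # total loss of segregation genes means certain mis-segregation.
  ifelse(n_seg <= 0, 1, pmin(2 * params$mu / n_seg, 1))
}

state_component <- function(state, i) {
  s <- as.numeric(state)
  if (length(s) != 3L) stop("a genotype state has three components",
                            call. = FALSE)
  s[i]
}

#' Per-cell probability rules
#'
#' The three gene-dose rules driving the model. Apoptosis is gated on
#' crowding: it is zero unless the step-start population exceeds the carrying
#' capacity, and then grows with the number of apoptosis-gene copies.
#' Division grows with the number of division-gene copies. Mis-segregation
#' (conditional on division) falls with the number of segregation-gene
#' copies, equals `mu` at diploidy, and is certain when all segregation genes
#' are lost.
#'
#' @param state genotype state: length-3 numeric (division, apoptosis,
#'   segregation gene copies).
#' @param population step-start population count (frozen for the whole step).
#' @param params a [rate_params()] object.
#' @param capacity homeostatic carrying capacity (cells).
#' @return a probability in \[0, 1\].
#' @examples
#' p <- rate_params()
#' apoptosis_probability(c(2, 2, 2), population = 201, p, capacity = 200)
#' division_probability(c(6, 0, 0), p) / division_probability(c(2, 2, 2), p)
#' missegregation_probability(c(2, 2, 2), p)
#' @export
apoptosis_probability <- function(state, population, params, capacity) {
  stopifnot(population >= 0)
  if (population <= capacity) return(0)
  as.numeric(p_apoptosis_vec(state_component(state, 2L), params))
}

#' @rdname apoptosis_probability
#' @export
division_probability <- function(state, params) {
  as.numeric(p_division_vec(state_component(state, 1L), params))
}

#' @rdname apoptosis_probability
#' @export
missegregation_probability <- function(state, params) {
  as.numeric(p_misseg_vec(state_component(state, 3L), params))
}

#' Tissue: an ordered population of cells
#'
#' The tissue is an ordered sequence of cells (the model's "linked list"):
#' daughters are inserted adjacent to their mother, so neighbouring cells
#' tend to be related by lineage. Internally the tissue stores an integer
#' matrix of chromosome copy counts, one row per cell in list order.
#'
#' `new_tissue()` builds a homogeneous diploid tissue; `tissue_from_genomes()`
#' builds one from an explicit ordered list of genomes.
#'
#' @param n_cells number of diploid cells.
#' @param distribution gene distribution name or [gene_distribution()].
#' @param capacity homeostatic carrying capacity.
#' @return an object of class `tissue`.
#' @examples
#' tis <- new_tissue(100, "A", capacity = 200)
#' @export
new_tissue <- function(n_cells, distribution, capacity = 200L) {
  dist <- as_gene_distribution(distribution)
  m <- matrix(2L, nrow = as.integer(n_cells), ncol = nrow(dist$content),
              dimnames = list(NULL, rownames(dist$content)))
  structure(list(cells = m, distribution = dist,
                 capacity = as.integer(capacity)),
            class = "tissue")
}

#' @rdname new_tissue
#' @param genomes an ordered list of `genome` objects sharing one distribution.
#' @export
tissue_from_genomes <- function(genomes, capacity = 200L) {
  stopifnot(length(genomes) >= 1L)
  dist <- attr(genomes[[1L]], "distribution")
  m <- do.call(rbind, lapply(genomes, function(g) as.integer(unclass(g))))
  colnames(m) <- rownames(dist$content)
  structure(list(cells = m, distribution = dist,
                 capacity = as.integer(capacity)),
            class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("Tissue: %d cells (distribution %s, capacity %d)\n",
              nrow(x$cells), x$distribution$name, x$capacity))
  invisible(x)
}

# one synchronous update of the raw cell matrix.
#
# Random draws, in fixed order per step: (1) one uniform per cell for death,
# only when the step-start count exceeds capacity; (2) one uniform per
# survivor for division; (3) one uniform per divider for mis-segregation
# (skipped under chemotherapy); (4) per mis-segregating cell, the chromosome
# pick then a fair coin for which daughter (gain/lose) takes the mother's
# list position.
sim_step <- function(M, G, params, capacity, chemo_active = FALSE) {
  n0 <- nrow(M)
  if (n0 == 0L) {
    return(list(M = M, deaths = 0L, divisions = 0L, missegregations = 0L,
                chemo_kills = 0L))
  }
  crowded <- n0 > capacity
  if (crowded) {
    n_apop <- M %*% G[, 2L]
    dead <- stats::runif(n0) < p_apoptosis_vec(n_apop, params)
  } else {
    dead <- logical(n0)
  }
  alive <- which(!dead)
  deaths <- n0 - length(alive)
  if (!length(alive)) {
    return(list(M = M[0L, , drop = FALSE], deaths = deaths, divisions = 0L,
                missegregations = 0L, chemo_kills = 0L))
  }
  n_div <- M[alive, , drop = FALSE] %*% G[, 1L]
  div <- stats::runif(length(alive)) < p_division_vec(n_div, params, crowded)
  dividers <- alive[div]
  if (chemo_active) {
    # anti-mitotic kill: every cell attempting division dies before
    # producing daughters
    keep <- alive[!div]
    return(list(M = M[keep, , drop = FALSE], deaths = deaths, divisions = 0L,
                missegregations = 0L, chemo_kills = length(dividers)))
  }
  mis <- integer(0)
  if (length(dividers)) {
    n_seg <- M[dividers, , drop = FALSE] %*% G[, 3L]
    misflag <- stats::runif(length(dividers)) < p_misseg_vec(n_seg, params)
    mis <- dividers[misflag]
  }
  times <- integer(n0)
  times[alive] <- 1L
  times[dividers] <- 2L
  M2 <- M[rep.int(seq_len(n0), times), , drop = FALSE]
  drop_rows <- integer(0)
  if (length(mis)) {
    start <- cumsum(times) - times + 1L
    for (i in mis) {
      k <- pick_chromosome(M[i, ], params$misseg_sampling)
      r1 <- start[i]
      gain_first <- stats::runif(1L) < 0.5
      g <- if (gain_first) r1 else r1 + 1L
      l <- if (gain_first) r1 + 1L else r1
      M2[g, k] <- M2[g, k] + 1L
      M2[l, k] <- M2[l, k] - 1L
      if (all(M2[l, ] == 0L)) drop_rows <- c(drop_rows, l)
    }
    if (length(drop_rows)) M2 <- M2[-drop_rows, , drop = FALSE]
  }
  list(M = M2, deaths = deaths, divisions = length(dividers),
       missegregations = length(mis), chemo_kills = 0L)
}

#' One synchronous time step of a tissue
#'
#' Applies the update rules to every cell in list order, using the population
#' count frozen at step start. Each cell (a) dies with the crowding-gated
#' apoptosis probability, (b) if it survived, divides with the gene-dose
#' division probability, (c) if dividing while chemotherapy is active, is
#' killed instead, and (d) if dividing normally, mis-segregates one
#' chromosome with the gene-dose mis-segregation probability. Daughters are
#' placed adjacent to the mother's list position and are not updated until
#' the next step. A daughter losing its last chromosome copy is nonviable
#' and removed at creation.
#'
#' @param tissue a [new_tissue()] object.
#' @param params a [rate_params()] object.
#' @param chemo_active logical: is an anti-mitotic treatment active this step?
#' @return a list with elements `tissue` (updated) and `record` (counts of
#'   deaths, divisions, mis-segregations and chemotherapy kills).
#' @export
step_tissue <- function(tissue, params = rate_params(), chemo_active = FALSE) {
  stopifnot(inherits(tissue, "tissue"))
  res <- sim_step(tissue$cells, tissue$distribution$content, params,
                  tissue$capacity, chemo_active)
  tissue$cells <- res$M
  list(tissue = tissue,
       record = res[c("deaths", "divisions", "missegregations", "chemo_kills")])
}

# genotype composition of a cell-state matrix S (rows = cells, cols = d,a,s)
composition_table <- function(S) {
  if (nrow(S) == 0L) {
    return(data.frame(n_div = integer(0), n_apop = integer(0),
                      n_seg = integer(0), count = integer(0)))
  }
  key <- paste(S[, 1L], S[, 2L], S[, 3L])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  out <- data.frame(n_div = as.integer(parts[, 1L]),
                    n_apop = as.integer(parts[, 2L]),
                    n_seg = as.integer(parts[, 3L]),
                    count = as.integer(tab))
  out[order(out$n_div, out$n_apop, out$n_seg), , drop = FALSE]
}

#' Run one simulation
#'
#' Grows an initial diploid population under the stochastic death / division /
#' mis-segregation rules, applying the configured therapy once when the
#' tumour is detected, until the population reaches `max_population`, the run
#' reaches `max_steps`, or the tissue goes extinct. Identical configurations
#' with identical seeds yield identical trajectories.
#'
#' Detection is checked on the end-of-step population; the intervention
#' executes at the start of the following step (so growth during the
#' detection step creates the overshoot that leaves surgical residuals
#' slightly above the retained head). Relapse is the first step, from the
#' intervention onwards, whose end-of-step population again reaches the
#' detection threshold.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_trajectory`: list with the config, a
#'   per-step data frame `steps`, optional long-format `composition`, an
#'   `events` list (detection / intervention / relapse steps, chemotherapy
#'   window, termination reason) and, if requested, the final `tissue`.
#' @examples
#' tr <- run_simulation(sim_config(distribution = "A", max_steps = 50, seed = 7))
#' summary(tr)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dist <- config$distribution
  G <- dist$content
  params <- config$rates
  plan <- config$therapy
  scenario <- if (is.null(plan)) "none" else plan$scenario

  M <- matrix(2L, nrow = config$initial_population, ncol = nrow(G),
              dimnames = list(NULL, rownames(G)))

  n_steps <- config$max_steps
  rec <- data.frame(step = seq_len(n_steps), population = NA_integer_,
                    pop_start = NA_integer_, mean_div = NA_real_,
                    mean_apop = NA_real_, mean_seg = NA_real_,
                    deaths = NA_integer_, divisions = NA_integer_,
                    missegregations = NA_integer_, chemo_kills = NA_integer_,
                    n_genotypes = NA_integer_)
  comp <- if (config$record_composition) vector("list", n_steps) else NULL

  detection_step <- NA_integer_
  intervention_step <- NA_integer_
  relapse_step <- NA_integer_
  cells_at_detection <- NA_integer_
  cells_post_surgery <- NA_integer_
  chemo_first <- NA_integer_
  chemo_last <- NA_integer_
  treated <- FALSE
  termination <- "max_steps"
  last_step <- 0L

  for (t in seq_len(n_steps)) {
    if (!is.na(intervention_step) && t == intervention_step &&
        scenario %in% c("surgery", "combination")) {
      M <- surgery_matrix(M, plan)
      cells_post_surgery <- nrow(M)
    }
    chemo_active <- !is.na(chemo_first) && t >= chemo_first && t <= chemo_last
    pop_start <- nrow(M)
    res <- sim_step(M, G, params, config$capacity, chemo_active)
    M <- res$M
    pop <- nrow(M)
    S <- M %*% G
    rec$population[t] <- pop
    rec$pop_start[t] <- pop_start
    rec$mean_div[t] <- if (pop) mean(S[, 1L]) else NA_real_
    rec$mean_apop[t] <- if (pop) mean(S[, 2L]) else NA_real_
    rec$mean_seg[t] <- if (pop) mean(S[, 3L]) else NA_real_
    rec$deaths[t] <- res$deaths
    rec$divisions[t] <- res$divisions
    rec$missegregations[t] <- res$missegregations
    rec$chemo_kills[t] <- res$chemo_kills
    if (pop) {
      # numeric state key; copy numbers stay far below 1e4 (they change by
      # at most one per division over <= max_steps steps)
      key <- (S[, 1L] * 1e4 + S[, 2L]) * 1e4 + S[, 3L]
      rec$n_genotypes[t] <- length(unique(key))
    } else {
      rec$n_genotypes[t] <- 0L
    }
    if (config$record_composition) comp[[t]] <- composition_table(S)
    last_step <- t

    if (!treated && scenario != "none" && pop >= plan$detection_threshold) {
      treated <- TRUE
      detection_step <- t
      cells_at_detection <- pop
      intervention_step <- t + 1L
      if (scenario %in% c("chemotherapy", "combination")) {
        chemo_first <- if (plan$chemo_includes_intervention_step) t + 1L else t + 2L
        chemo_last <- chemo_first + plan$chemo_rounds - 1L
      }
    } else if (treated && is.na(relapse_step) && t >= intervention_step &&
               pop >= plan$detection_threshold) {
      relapse_step <- t
    }

    if (pop == 0L) { termination <- "extinction"; break }
    if (pop >= config$max_population) { termination <- "max_population"; break }
  }
  if (last_step < n_steps) rec <- rec[seq_len(last_step), , drop = FALSE]
  if (!is.null(comp)) {
    comp <- comp[seq_len(last_step)]
    nrows <- vapply(comp, nrow, 0L)
    comp <- do.call(rbind, comp)
    comp <- cbind(step = rep.int(seq_len(last_step), nrows), comp)
    rownames(comp) <- NULL
  }

  events <- list(detection_step = detection_step,
                 intervention_step = intervention_step,
                 cells_at_detection = cells_at_detection,
                 cells_post_surgery = cells_post_surgery,
                 chemo_first = chemo_first, chemo_last = chemo_last,
                 relapse_step = relapse_step,
                 scenario = scenario,
                 termination = termination)
  out <- list(config = config, steps = rec, composition = comp,
              events = events)
  if (config$keep_tissue) {
    out$tissue <- structure(list(cells = M, distribution = dist,
                                 capacity = config$capacity),
                            class = "tissue")
  }
  structure(out, class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  e <- x$events
  n <- nrow(x$steps)
  cat(sprintf("Simulation trajectory: distribution %s, %d steps, final population %d\n",
              x$config$distribution$name, n,
              if (n) x$steps$population[n] else x$config$initial_population))
  cat("  termination:", e$termination, "\n")
  if (e$scenario != "none") {
    cat(sprintf("  therapy: %s, detected at step %s, relapse at step %s\n",
                e$scenario,
                ifelse(is.na(e$detection_step), "-", e$detection_step),
                ifelse(is.na(e$relapse_step), "- (censored)", e$relapse_step)))
  }
  invisible(x)
}

#' @export
summary.sim_trajectory <- function(object, ...) {
  s <- object$steps
  e <- object$events
  out <- list(
    distribution = object$config$distribution$name,
    n_steps = nrow(s),
    final_population = if (nrow(s)) s$population[nrow(s)] else NA_integer_,
    termination = e$termination,
    scenario = e$scenario,
    detection_step = e$detection_step,
    relapse_step = e$relapse_step,
    relapse_time = trajectory_relapse_time(object),
    total_divisions = sum(s$divisions),
    total_deaths = sum(s$deaths),
    total_missegregations = sum(s$missegregations),
    max_genotypes = if (nrow(s)) max(s$n_genotypes) else 0L
  )
  class(out) <- "summary.sim_trajectory"
  out
}

#' @export
print.summary.sim_trajectory <- function(x, ...) {
  cat(sprintf("Distribution %s: %d steps, final population %d (%s)\n",
              x$distribution, x$n_steps, x$final_population, x$termination))
  cat(sprintf("  %d divisions, %d deaths, %d mis-segregations, up to %d coexisting genotypes\n",
              x$total_divisions, x$total_deaths, x$total_missegregations,
              x$max_genotypes))
  if (x$scenario != "none") {
    cat(sprintf("  %s: detection at step %s, relapse time %s\n", x$scenario,
                ifelse(is.na(x$detection_step), "-", x$detection_step),
                ifelse(is.na(x$relapse_time), "censored", x$relapse_time)))
  }
  invisible(x)
}
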