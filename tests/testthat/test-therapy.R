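plan_surgery <- therapy_plan("surgery")

test_that("tumour detection fires at the threshold, once per run", {
  expect_false(detect_tumour(999, plan_surgery))
  expect_true(detect_tumour(1000, plan_surgery))
  expect_true(detect_tumour(1500, plan_surgery))
  expect_false(detect_tumour(1500, plan_surgery, already_treated = TRUE))
})

test_that("surgery keeps the list head, removes a contiguous block, keeps the tail", {
  dist <- gene_distribution("unlinked")
  mk_tissue <- function(n) {
    tis <- new_tissue(n, dist, capacity = 200L)
    tis$cells[, 2L] <- seq_len(n)  # tag each cell by position
    tis
  }
  # at exactly the detection threshold both modes leave the 100-cell head
  for (mode in c("fraction", "fixed")) {
    plan <- therapy_plan("surgery", surgery_mode = mode)
    out <- apply_surgery(mk_tissue(1000L), plan)
    expect_equal(nrow(out$cells), 100L)
    expect_equal(out$cells[, 2L], 1:100)
  }
  # overshoot: fixed mode removes exactly 900; fraction mode removes 90%
  fixed <- therapy_plan("surgery", surgery_mode = "fixed")
  out <- apply_surgery(mk_tissue(1010L), fixed)
  expect_equal(nrow(out$cells), 110L)
  expect_equal(out$cells[, 2L], c(1:100, 1001:1010))  # head + overshoot tail
  frac <- therapy_plan("surgery", surgery_mode = "fraction")
  out <- apply_surgery(mk_tissue(1010L), frac)
  expect_equal(nrow(out$cells), 101L)
  expect_equal(out$cells[, 2L], c(1:100, 1010L))
  # too few cells is a domain error
  expect_error(apply_surgery(mk_tissue(900L), fixed), "surgery needs")
  expect_error(apply_surgery(mk_tissue(90L), frac), "surgery needs")
})

test_that("therapy plan invariants hold", {
  expect_error(therapy_plan("surgery", surgery_keep_head = 50),
               "must equal detection_threshold")
  expect_error(therapy_plan("chemotherapy", chemo_rounds = 0), "chemo_rounds")
  p <- therapy_plan("combination", detection_threshold = 500,
                    surgery_keep_head = 50, surgery_removal = 450)
  expect_equal(p$surgery_keep_head + p$surgery_removal, p$detection_threshold)
})

test_that("the chemotherapy window covers the configured rounds after detection", {
  plan <- therapy_plan("chemotherapy")
  expect_equal(chemo_window(100L, plan), 101:109)
  late <- therapy_plan("chemotherapy", chemo_includes_intervention_step = FALSE)
  expect_equal(chemo_window(100L, late), 102:110)
  short <- therapy_plan("chemotherapy", chemo_rounds = 3)
  expect_equal(chemo_window(50L, short), 51:53)
})

test_that("chemo kills match the division probability in expectation and never add cells", {
  # homogeneous diploid population, no crowding deaths: expected kills
  # per active step = N * P_division = 1000 * 0.09 = 90
  tis <- new_tissue(1000L, "B", capacity = 5000L)
  set.seed(8)
  reps <- 200L
  kills <- vapply(seq_len(reps), function(i) {
    step_tissue(tis, rate_params(), chemo_active = TRUE)$record$chemo_kills
  }, 0L)
  se <- sqrt(1000 * 0.09 * 0.91 / reps)
  expect_lt(abs(mean(kills) - 90), 3 * se)
  # cells with no division genes are never targeted
  dist <- gene_distribution("unlinked")
  g <- genome_with_counts(dist, c(0L, 2L, 2L))
  tis0 <- tissue_from_genomes(rep(list(g), 50L), capacity = 10L)
  out <- step_tissue(tis0, rate_params(alpha = 0), chemo_active = TRUE)
  expect_equal(out$record$chemo_kills, 0L)
  expect_equal(nrow(out$tissue$cells), 50L)
})

test_that("population never increases during an active chemotherapy step", {
  cfg <- default_therapy_config("B", "chemotherapy", seed = 23)
  tr <- run_simulation(cfg)
  e <- tr$events
  expect_false(is.na(e$chemo_first))
  w <- e$chemo_first:e$chemo_last
  s <- tr$steps
  expect_true(all(s$population[w] <= s$pop_start[w]))
  expect_true(all(s$divisions[w] == 0L))
})

test_that("relapse time is measured from treatment end, with the intervention origin available", {
  # surgery: treatment is instantaneous, both origins coincide
  tr <- fake_treated_trajectory(detection_step = 100L, relapse_step = 135L)
  expect_equal(relapse_time(tr), 35L)
  expect_equal(relapse_time(tr, origin = "intervention"), 35L)
  # chemotherapy: window 101..109; regrowth clock starts at step 109
  tr <- fake_treated_trajectory(100L, 131L, scenario = "chemotherapy",
                                chemo_last = 109L)
  expect_equal(relapse_time(tr), 22L)
  expect_equal(relapse_time(tr, origin = "intervention"), 31L)
  # censored and untreated cases
  tr <- fake_treated_trajectory(100L, NA_integer_)
  expect_true(is.na(relapse_time(tr)))
  untr <- fake_treated_trajectory(NA_integer_, NA_integer_)
  untr$events$scenario <- "none"
  expect_error(relapse_time(untr), "treated trajectory")
})

test_that("a surgery run fires one intervention with consistent markers", {
  cfg <- default_therapy_config("B", "surgery", seed = 12)
  tr <- run_simulation(cfg)
  e <- tr$events
  s <- tr$steps
  expect_false(is.na(e$detection_step))
  # detection marks the first threshold crossing
  expect_gte(s$population[e$detection_step], 1000L)
  expect_true(all(s$population[seq_len(e$detection_step - 1L)] < 1000L))
  expect_equal(e$cells_at_detection, s$population[e$detection_step])
  # surgery happened at the start of the intervention step and only there:
  # the step-start count drops from the detection count to the residual
  expect_equal(s$pop_start[e$intervention_step], e$cells_post_surgery)
  expect_lt(e$cells_post_surgery, 0.15 * e$cells_at_detection)
  # residual is ~10% of the detected tumour under the default fraction mode
  expect_equal(e$cells_post_surgery,
               e$cells_at_detection -
                 round(e$cells_at_detection * 0.9) )
  # relapse marker is the first re-crossing at/after the intervention
  if (!is.na(e$relapse_step)) {
    expect_gte(s$population[e$relapse_step], 1000L)
    between <- seq(e$intervention_step, e$relapse_step - 1L)
    expect_true(all(s$population[between] < 1000L))
  }
  out <- therapy_outcome(tr)
  expect_equal(out$relapse_time,
               out$relapse_step - out$detection_step)
})

test_that("combination therapy applies surgery then a full chemo window", {
  cfg <- default_therapy_config("C", "combination", seed = 41)
  tr <- run_simulation(cfg)
  e <- tr$events
  expect_equal(e$chemo_first, e$intervention_step)
  expect_equal(e$chemo_last - e$chemo_first + 1L, 9L)
  expect_false(is.na(e$cells_post_surgery))
  out <- therapy_outcome(tr)
  expect_false(is.na(out$cells_end_chemo))
  expect_lt(out$cells_end_chemo, out$cells_post_surgery)
})
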