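test_that("daughters replace the mother adjacently, preserving list order", {
  # three cells in order; only the middle one can divide (delta = 1, one
  # division gene), no deaths (below capacity), no mis-segregation
  dist <- gene_distribution("unlinked")
  c1 <- genome_with_counts(dist, c(0L, 2L, 2L))
  c2 <- genome_with_counts(dist, c(1L, 3L, 2L))
  c3 <- genome_with_counts(dist, c(0L, 4L, 2L))
  tis <- tissue_from_genomes(list(c1, c2, c3), capacity = 100L)
  set.seed(1)
  out <- step_tissue(tis, rate_params(alpha = 0, delta = 1, mu = 0))
  m <- out$tissue$cells
  expect_equal(nrow(m), 4L)
  expect_equal(m[1L, ], unclass(c1), ignore_attr = TRUE)
  expect_equal(m[2L, ], unclass(c2), ignore_attr = TRUE)
  expect_equal(m[3L, ], unclass(c2), ignore_attr = TRUE)
  expect_equal(m[4L, ], unclass(c3), ignore_attr = TRUE)
  expect_equal(out$record$divisions, 1L)
})

test_that("with perfect fidelity every cell stays diploid for the whole run", {
  cfg <- sim_config(distribution = "A", rates = rate_params(mu = 0),
                    max_steps = 60, seed = 5)
  tr <- run_simulation(cfg)
  expect_true(all(tr$steps$n_genotypes == 1L))
  expect_true(all(tr$steps$mean_div == 2))
  expect_true(all(tr$steps$missegregations == 0L))
  expect_true(all(tr$tissue$cells == 2L))
})

test_that("division counts match the binomial expectation below capacity", {
  # 100 diploid cells below capacity: divisions ~ Binomial(100, 0.09)
  tis <- new_tissue(100L, "A", capacity = 200L)
  set.seed(99)
  reps <- 400L
  divs <- vapply(seq_len(reps), function(i) {
    step_tissue(tis, rate_params())$record$divisions
  }, 0L)
  se <- sqrt(100 * 0.09 * 0.91 / reps)
  expect_lt(abs(mean(divs) - 9), 3 * se)
  # growth law: E[N_t+1] = N_t (1 + P_d), and no deaths below capacity
  expect_lt(abs(mean(100 + divs) - 100 * 1.09), 3 * se)
})

test_that("identical seeds give identical trajectories, different seeds differ", {
  cfg <- default_therapy_config("B", "surgery", seed = 31)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$events, t2$events)
  cfg$seed <- 32L
  t3 <- run_simulation(cfg)
  expect_false(identical(t1$steps, t3$steps))
})

test_that("a chemo-killed divider leaves no daughters and an empty tissue stays empty", {
  dist <- gene_distribution("unlinked")
  g <- genome_with_counts(dist, c(1L, 1L, 1L))
  tis <- tissue_from_genomes(list(g), capacity = 10L)
  set.seed(2)
  out <- step_tissue(tis, rate_params(alpha = 0, delta = 1, mu = 0),
                     chemo_active = TRUE)
  expect_equal(nrow(out$tissue$cells), 0L)
  expect_equal(out$record$chemo_kills, 1L)
  again <- step_tissue(out$tissue, rate_params())
  expect_equal(nrow(again$tissue$cells), 0L)
  expect_equal(again$record$divisions, 0L)
})

test_that("a daughter losing its last chromosome is nonviable and removed at creation", {
  # one chromosome type carrying all classes; a single copy mis-segregates
  # into a 2-copy daughter and a 0-copy (nonviable) one
  dist <- gene_distribution(list(chr1 = c(division = 1, apoptosis = 1,
                                          segregation = 1)))
  g <- genome_with_counts(dist, 1L)
  tis <- tissue_from_genomes(list(g), capacity = 10L)
  set.seed(3)
  out <- step_tissue(tis, rate_params(alpha = 0, delta = 1, mu = 0.5))
  expect_equal(out$record$missegregations, 1L)
  expect_equal(nrow(out$tissue$cells), 1L)
  expect_equal(unname(out$tissue$cells[1L, ]), 2L)
})

test_that("step records are internally consistent across a stochastic run", {
  cfg <- sim_config(distribution = "C", max_steps = 120, seed = 17)
  tr <- run_simulation(cfg)
  s <- tr$steps
  # population accounting: N_t = N_{t-1} - deaths + divisions (faithful and
  # mis-segregating divisions both add one net cell unless a daughter was
  # nonviable, which can only reduce the count)
  n_prev <- c(cfg$initial_population, s$population[-nrow(s)])
  expect_true(all(s$population <= n_prev - s$deaths + s$divisions))
  expect_true(all(s$population >= n_prev - s$deaths + s$divisions -
                    s$missegregations))
  expect_true(all(s$missegregations <= s$divisions))
  # composition counts sum to the recorded population at every step
  comp_pop <- tapply(tr$composition$count, tr$composition$step, sum)
  expect_equal(unname(comp_pop), s$population[as.integer(names(comp_pop))],
               ignore_attr = TRUE)
  # diversity column matches the composition table
  comp_div <- tapply(tr$composition$count > 0, tr$composition$step, sum)
  expect_equal(as.integer(comp_div), s$n_genotypes[as.integer(names(comp_div))])
})

test_that("invalid configurations are rejected before any stepping", {
  expect_error(sim_config(initial_population = 0), "positive")
  expect_error(sim_config(initial_population = 500, capacity = 200),
               "exceed capacity")
  expect_error(sim_config(capacity = 2000, detection_threshold = 1000),
               "below detection_threshold")
  expect_error(sim_config(detection_threshold = 8000, max_population = 7000),
               "max_population")
  expect_error(rate_params(alpha = 1.5), "probability")
  expect_error(rate_params(mu = -0.1), "probability")
})
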