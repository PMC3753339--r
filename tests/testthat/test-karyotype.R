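test_that("named gene distributions partition the three gene classes as specified", {
  layouts <- list(
    A = list(linked = c("division", "apoptosis"), alone = "segregation"),
    B = list(linked = c("division", "segregation"), alone = "apoptosis"),
    C = list(linked = c("apoptosis", "segregation"), alone = "division")
  )
  for (nm in names(layouts)) {
    d <- gene_distribution(nm)
    expect_equal(nrow(d$content), 2L)
    # every class on exactly one chromosome type
    expect_true(all(colSums(d$content > 0L) == 1L))
    carrier <- apply(d$content[, layouts[[nm]]$linked] > 0L, 2L, which)
    expect_length(unique(carrier), 1L)  # the linked pair shares a type
    alone_type <- which(d$content[, layouts[[nm]]$alone] > 0L)
    expect_false(alone_type %in% carrier)
  }
  u <- gene_distribution("unlinked")
  expect_equal(nrow(u$content), 3L)
  expect_true(all(rowSums(u$content > 0L) == 1L))
})

test_that("unknown distribution names and bad custom layouts are rejected", {
  expect_error(gene_distribution("Z"), "unknown gene distribution")
  # a class appearing on two chromosome types breaks the partition
  expect_error(
    gene_distribution(list(chr1 = c(division = 1, apoptosis = 1),
                           chr2 = c(division = 1, segregation = 1))),
    "exactly one chromosome type")
  expect_error(gene_distribution(list(chr1 = c(division = 1))),
               "exactly one chromosome type")
})

test_that("initial genomes are diploid with genotype state (2,2,2) in every layout", {
  for (nm in c("A", "B", "C", "unlinked")) {
    g <- make_initial_genome(nm)
    expect_true(all(unclass(g) == 2L))
    expect_equal(unname(genotype_state(g)), c(2L, 2L, 2L))
  }
  a <- make_initial_genome("A")
  expect_equal(length(unclass(a)), 2L)  # two chromosome types
})

test_that("genotype_state sums copies times per-chromosome gene content", {
  g <- genome_with_counts("A", c(3L, 1L))  # type1 {div,apop} x3, type2 {seg} x1
  expect_equal(unname(genotype_state(g)), c(3L, 3L, 1L))
  empty <- genome_with_counts("A", c(0L, 0L))
  expect_equal(unname(genotype_state(empty)), c(0L, 0L, 0L))
  custom <- gene_distribution(list(chrX = c(division = 2, segregation = 1),
                                   chrY = c(apoptosis = 1)))
  gc <- make_initial_genome(custom)
  expect_equal(unname(genotype_state(gc)), c(4L, 2L, 2L))
})

test_that("faithful segregation duplicates the mother exactly", {
  g <- make_initial_genome("B")
  d <- segregate(g, missegregate = FALSE)
  expect_equal(unclass(d[[1]]), unclass(g))
  expect_equal(unclass(d[[2]]), unclass(g))
})

test_that("mis-segregation moves one chromosome copy between daughters, conserving copy number", {
  set.seed(42)
  for (nm in c("A", "B", "C", "unlinked")) {
    g <- make_initial_genome(nm)
    for (i in 1:100) {
      d <- segregate(g, missegregate = TRUE)
      counts <- lapply(d, function(x) if (is.null(x)) 0L * unclass(g)
                       else unclass(x))
      # conservation: daughters sum to twice the mother
      expect_equal(counts[[1]] + counts[[2]], 2L * unclass(g))
      # exactly one type differs by +/-1
      diff1 <- counts[[1]] - unclass(g)
      expect_equal(sum(abs(diff1)), 1L)
      # genotype-state additivity
      states <- lapply(d, function(x) if (is.null(x)) c(0L, 0L, 0L)
                       else unname(genotype_state(x)))
      expect_equal(states[[1]] + states[[2]],
                   2L * unname(genotype_state(g)))
      # walk: continue from a random viable daughter
      viable <- Filter(Negate(is.null), d)
      g <- viable[[sample.int(length(viable), 1L)]]
    }
    g <- make_initial_genome(nm)
  }
})

test_that("linkage couples gene counts along every mis-segregation walk", {
  set.seed(7)
  coupled <- list(A = c(1L, 2L), B = c(1L, 3L), C = c(2L, 3L))
  for (nm in names(coupled)) {
    g <- make_initial_genome(nm)
    for (i in 1:300) {
      d <- segregate(g, missegregate = runif(1) < 0.5)
      viable <- Filter(Negate(is.null), d)
      g <- viable[[sample.int(length(viable), 1L)]]
      s <- genotype_state(g)
      expect_equal(s[[coupled[[nm]][1L]]], s[[coupled[[nm]][2L]]])
    }
  }
})

test_that("mis-segregating an empty genome is a domain error", {
  g <- genome_with_counts("A", c(0L, 0L))
  expect_error(segregate(g, missegregate = TRUE), "zero chromosomes")
})

test_that("per-type sampling picks each present chromosome type equally", {
  set.seed(11)
  g <- genome_with_counts("A", c(9L, 1L))  # per-copy would pick type1 90%
  picks <- replicate(2000, {
    d <- segregate(g, missegregate = TRUE, sampling = "type")
    which(unclass(d[[1]]) != unclass(g) | unclass(d[[2]]) != unclass(g))
  })
  frac_type1 <- mean(picks == 1L)
  expect_gt(frac_type1, 0.45)
  expect_lt(frac_type1, 0.55)
})

test_that("rgb colour key normalises, clamps and hits the documented anchors", {
  expect_equal(unname(rgb_color(c(0, 0, 0), c(5, 5, 5))), c(0, 0, 0))
  expect_equal(unname(rgb_color(c(2, 2, 2), c(5, 5, 5))), c(0.4, 0.4, 0.4))
  expect_equal(unname(rgb_color(c(5, 5, 5), c(5, 5, 5))), c(1, 1, 1))
  # zero max component maps to 0; values clamp into [0,1]
  expect_equal(unname(rgb_color(c(3, 0, 2), c(6, 0, 2))), c(0.5, 0, 1))
  # componentwise monotone in the state
  set.seed(3)
  for (i in 1:50) {
    mx <- c(6, 6, 6)
    s1 <- runif(3, 0, 6)
    s2 <- pmin(s1 + runif(3, 0, 2), 6)
    expect_true(all(rgb_color(s2, mx) >= rgb_color(s1, mx)))
  }
})
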