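---
title: "Modelling chromosome mis-segregation in tumour evolution with karyosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chromosome mis-segregation in tumour evolution with karyosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyosim)
```

## The model

`karyosim` is an agent-based model of tissue homeostasis and its breakdown
under whole-chromosome mis-segregation. Each cell is an agent carrying a
genome: an integer number of copies of each chromosome type. Chromosomes
bundle three abstract gene classes whose copy numbers drive all behaviour:

* **cell-division regulators** (a proto-oncogene abstraction, e.g. Ras, Myc):
  more copies, more frequent division;
* **apoptosis regulators** (a tumour-suppressor abstraction, e.g. p53): more
  copies, more crowding-induced death;
* **chromosome-segregation regulators** (genetic-stability genes, e.g. BUB1,
  MAD2): more copies, higher fidelity at division.

A cell's clone identity is its *genotype state* `(n_div, n_apop, n_seg)`,
the total copies of each class; every run starts from diploid `(2, 2, 2)`
cells. Gene *linkage* is the experimental variable: which classes share a
chromosome, and are therefore gained or lost together when a chromosome
mis-segregates. The named layouts are distribution **A** (division +
apoptosis linked), **B** (division + segregation linked), **C** (apoptosis +
segregation linked) and **unlinked** (three chromosomes, one class each, as
a control); custom layouts can be declared in the configuration.

The tissue is an ordered list of cells. It is not spatially explicit, but
order matters: daughters are inserted adjacent to their mother, so
contiguous segments are lineage-correlated, which is what makes simulated
surgery (removal of a contiguous block) biologically meaningful.

## Update rules

Time advances in synchronous steps. The population count `N` is frozen at
step start, and each cell is visited in list order:

1. **Crowding-gated death.** If `N > K` (carrying capacity, default 200),
   the cell dies with probability `min(1, alpha * n_apop)`. Below capacity
   nobody dies: crowding is the only death signal.
2. **Division.** A surviving cell divides with probability
   `min(1, delta * n_div)`.
3. **Mis-segregation.** A dividing cell mis-segregates one chromosome with
   probability `min(1, 2 * mu / n_seg)` (probability 1 if `n_seg = 0`): one
   chromosome copy, drawn uniformly over all copies in the genome, goes to
   one daughter twice and to the other not at all. Otherwise the genome is
   copied faithfully. Copy number is always conserved: the daughters sum to
   twice the mother.

Daughters take the mother's list position as an adjacent pair and are not
updated until the next step. A daughter that loses its last chromosome copy
is nonviable and removed at creation; partial nullisomy (e.g. `(3, 0, 0)`)
is viable, and no upper bound is placed on copy numbers.

The probabilities are conditional — a dead cell cannot divide, and
mis-segregation happens only at division — so the realised mis-segregation
rate per cell-step is small (about `0.09 * 0.02` per diploid cell-step at
the defaults) even though the conditional probability is the largest of the
three.

### Why these functional forms

The three dose-response forms are declared modelling choices of this
package:

* Division is *linear* in `n_div`. This is anchored by the behaviour the
  model is meant to exhibit: a `(6,0,0)` clone divides exactly 3x as often
  as the diploid baseline.
* Death is linear in `n_apop` with the same per-copy rate
  (`alpha = delta = 0.045`), which makes the diploid genotype exactly
  balanced above capacity — the homeostatic fixed point. Above capacity a
  diploid population shrinks slightly per step
  (`(1 - 0.09)(1 + 0.09) < 1`) and below it grows by 9%, so the population
  hovers just above `K`.
* Mis-segregation is *inverse* in `n_seg`, calibrated so the diploid value
  equals the printed rate `mu = 0.02`: it is monotone decreasing in the
  number of stability genes, and total loss of them (`n_seg = 0`) makes
  mis-segregation certain, producing the runaway `(4,0,0) -> (5,0,0) ->
  (6,0,0)` cascades that unstable simulated tumours show.

Both gene-dose probabilities can be switched to a saturating exponential
form (`1 - exp(-rate * n)`) via `rate_params(dose_response =
"exponential")` for sensitivity analysis; all defaults above are what the
test suite and cohort statistics use.

Two further choices were genuinely open and are switchable:

* **Mis-segregation target.** The mis-segregating chromosome is drawn
  uniformly over chromosome *copies* (so an amplified chromosome is
  proportionally more likely to mis-segregate), which we consider the
  biophysically natural reading; `misseg_sampling = "type"` draws uniformly
  over types instead.
* **Contact inhibition.** Crowding acts through death only; division is
  never hard-blocked (tumours must be able to exceed capacity). A
  `division_crowding_scale` parameter can down-scale division above
  capacity for sensitivity analysis (default 1 = off).

### Why linkage decides the outcome

Under distribution A every mis-segregation changes `n_div` and `n_apop`
together, so `n_div = n_apop` holds along every lineage and death always
balances division above capacity: A tissues stay homeostatic indefinitely,
drifting only in segregation-gene dosage. Under B and C, division and death
genes are on different chromosomes, so single mis-segregation events create
supercritical clones (e.g. `(3,2,3)` or `(2,1,2)`), and the tissue
eventually escapes into exponential growth. B couples division to fidelity
(gaining division genes also gains stability — relatively stable aneuploid
tumours); C couples death to fidelity (losing tumour suppression also loses
stability — increasingly heterogeneous, aggressive tumours). This is the
mechanistic core the cohort statistics quantify.

## Therapies and bookkeeping

Detection is checked on the end-of-step population; a run's single
intervention executes at the start of the following step. Because the
tumour grows ~6%/step near the 1000-cell detection threshold, the detected
population overshoots the threshold by a few tens of cells.

* **Surgery** keeps the first 100 cells in list order and removes a
  contiguous 90% block of the population present at the intervention
  (`surgery_mode = "fraction"`, the default), leaving a residual of about a
  tenth of the detected tumour (~105 cells). A `"fixed"` mode removing
  exactly 900 cells regardless of overshoot is available; the two coincide
  without overshoot.
* **Chemotherapy** kills every cell that attempts division during 9
  consecutive steps starting at the intervention step (a
  `chemo_includes_intervention_step = FALSE` switch delays the window by
  one step). Kills happen before daughters are produced, so the population
  never grows during the window.
* **Combination** is surgery at the intervention step with the 9-round
  chemotherapy window running from that same step.

**Relapse time** is the number of steps until the population re-reaches the
detection threshold, measured from the *end of treatment*: the surgery step
for surgery (treatment is instantaneous) and the last chemotherapy round
otherwise. We adopted this origin because the model's regrowth clock is
only comparable across scenarios once treatment has stopped; the
alternative intervention-start origin inflates chemotherapy-containing
relapse times by exactly the window length, and is reported per replicate
as `relapse_time_from_intervention` for users who prefer it. Runs that end
(at 7000 cells or 300 steps) before re-reaching the threshold are censored:
cohort summaries report both the complete-case mean and a mean with
censored replicates carried at their censoring time.

Two chemotherapy intensity metrics are exported per replicate: the
anti-mitotic kill fraction proper (`chemo_kill_frac`, kills / step-start
population) and the total per-step population decline during the window
(`chemo_decline_frac`, which also counts crowding deaths; there are no
births under active chemotherapy). The decline fraction is the headline
"killed per step" figure in the cohort summaries, since that is what the
window's population decay curve measures.

## Cohorts, statistics, reproducibility

`run_cohort()` runs `n` independent replicates, replicate `i` seeded
`base_seed + i`; every stochastic choice in a run (death, division,
mis-segregation, chromosome pick, daughter order) draws from the one
seeded stream in a fixed documented order, so identical seeds give
bit-identical trajectories. Summaries report sample (n-1) standard
deviations. Cohorts are compared with the classical unpaired equal-variance
two-tailed t-test on relapse times and on post-intervention gene-ratio
slopes.

*Genotypic diversity* is the number of distinct genotype states present
(richness — the minimal reading; Shannon entropy is exported alongside as a
robustness check). The *gene-ratio slope* is the OLS slope of the
mean-apoptosis / mean-division gene ratio over the 25 steps from the
intervention (intervention step = index 0); replicates whose run ends
inside the window contribute their available points (at least 2).

Standard experiment sizes, used by the test suite and the acceptance
script: 100 initial cells, capacity 200, detection at 1000 cells,
termination at 7000 cells or 300 steps, 100 replicates per cohort arm, and
20 seeds for homeostasis checks. These match the model's standard
conditions; the only scaled-down sizes in the tests are small fixtures used
for exact enumeration (2-3 cells) and I/O round-trips.

## Numerical and degenerate-input conventions

* The crowding gate is strict (`N > K`); at `N = K` nobody dies.
* `min(1, .)` saturation keeps all three rules valid probabilities at any
  copy number.
* The RGB genotype key normalises componentwise by the maximum observed
  state (red = division, green = apoptosis, blue = segregation); a class
  whose maximum is 0 maps to intensity 0.
* An empty tissue is a fixed point (extinction terminates the run); a
  genome with zero copies of *all* chromosomes is nonviable by convention,
  while any partial nullisomy is allowed.
* Detection fires at most once per run; a population that never reaches the
  threshold yields an untreated, censored replicate.

## What the simulator does and does not emulate

All inputs are generated by the simulator itself; there is no external
biological data. The model deliberately ignores sub-chromosomal mutation
(substitutions, indels, translocations), spatial geometry and mechanics,
pharmacokinetics, repeated treatment cycles, and metastasis. Passing cohort
checks therefore show that whole-chromosome dosage dynamics plus linkage
reproduce the qualitative and quantitative behaviour of this abstraction —
not that real tumours follow the same numbers. The printed equations govern
gene dose only through totals per class; polygenic regulation, expression
noise and karyotype-specific fitness effects are out of scope.

## A worked example

```{r, eval = FALSE}
library(karyosim)

cfg <- sim_config(distribution = "B", therapy = therapy_plan("surgery"),
                  seed = 11)
tr <- run_simulation(cfg)
summary(tr)
plot(tr)            # population trace with intervention/relapse markers

co_b <- run_cohort(sim_config(distribution = "B",
                              therapy = therapy_plan("surgery"),
                              record_composition = FALSE,
                              keep_tissue = FALSE),
                   n_replicates = 100, base_seed = 1000)
co_c <- run_cohort(sim_config(distribution = "C",
                              therapy = therapy_plan("surgery"),
                              record_composition = FALSE,
                              keep_tissue = FALSE),
                   n_replicates = 100, base_seed = 2000)
compare_cohorts(co_b, co_c)
```

## Known limitations

* The list adjacency is a 1-D abstraction of lineage-correlated space; real
  surgical margins are 3-D and imaging-guided.
* Relapse-time means over censored replicates are reported both
  complete-case and censored-at-end; a survival-analysis treatment is
  deliberately not included.
* Cohort-level quantities are stochastic; the test suite checks them
  against bands of about two replicate standard deviations, so single-seed
  values move within those bands.
* Runtime scales with total cell-steps; a 100-replicate therapy cohort at
  the standard sizes takes on the order of ten seconds per arm on one CPU.
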