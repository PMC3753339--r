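# Plotting is a convenience layer over the exported data series; base
# graphics throughout, one diagram style per function.

#' Broom diagram
#'
#' Overlays per-replicate traces of a per-step quantity with the pointwise
#' median as a thick black line, computed until the first replicate ends
#' (where the shared time axis stops being comparable).
#'
#' @param trajectories list of `sim_trajectory` objects (e.g. from
#'   [run_cohort()] with `keep_trajectories = TRUE`).
#' @param what column of the step table to plot (default `"population"`).
#' @param col trace colours, recycled across replicates.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the step x replicate matrix plotted.
#' @export
plot_broom <- function(trajectories, what = "population",
                       col = grDevices::hcl.colors(length(trajectories),
                                                   "Dark 3"), ...) {
  stopifnot(length(trajectories) >= 1L)
  n <- min(vapply(trajectories, function(tr) nrow(tr$steps), 0L))
  mat <- vapply(trajectories, function(tr) tr$steps[[what]][seq_len(n)],
                numeric(n))
  graphics::matplot(seq_len(n), mat, type = "l", lty = 1L, col = col,
                    xlab = "time step", ylab = what, ...)
  graphics::lines(seq_len(n), apply(mat, 1L, stats::median), lwd = 3L)
  invisible(mat)
}

#' Marble diagram
#'
#' Stacked per-step genotype composition percentages, each genotype coloured
#' by its RGB key (red = division, green = apoptosis, blue = segregation gene
#' copies, normalised by the maximum observed state). Therapy start and
#' relapse are marked with solid and dashed vertical lines.
#'
#' @param trajectory a `sim_trajectory` run with `record_composition = TRUE`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the genotype key data frame (genotype, colour).
#' @export
plot_marble <- function(trajectory, ...) {
  comp <- trajectory$composition
  if (is.null(comp)) {
    stop("trajectory has no composition record; rerun with record_composition = TRUE",
         call. = FALSE)
  }
  max_state <- c(max(comp$n_div), max(comp$n_apop), max(comp$n_seg))
  key <- unique(comp[, c("n_div", "n_apop", "n_seg")])
  key <- key[order(key$n_div, key$n_apop, key$n_seg), , drop = FALSE]
  key$colour <- apply(key, 1L, function(s) {
    v <- rgb_color(s, max_state)
    grDevices::rgb(v[1L], v[2L], v[3L])
  })
  steps <- sort(unique(comp$step))
  graphics::plot(range(steps), c(0, 100), type = "n", xlab = "time step",
                 ylab = "% of population", ...)
  id <- function(d) paste(d$n_div, d$n_apop, d$n_seg)
  key_id <- id(key)
  # per-step cumulative percentage bands, drawn as thin rectangles
  for (t in steps) {
    d <- comp[comp$step == t, , drop = FALSE]
    pct <- 100 * d$count / sum(d$count)
    top <- cumsum(pct)
    bottom <- top - pct
    cols <- key$colour[match(id(d), key_id)]
    graphics::rect(t - 0.5, bottom, t + 0.5, top, col = cols, border = NA)
  }
  e <- trajectory$events
  if (!is.na(e$intervention_step)) graphics::abline(v = e$intervention_step)
  if (!is.na(e$relapse_step)) graphics::abline(v = e$relapse_step, lty = 2L)
  invisible(key)
}

#' Gene-ratio diagram
#'
#' Median apoptosis/division gene-ratio series across replicates with an
#' interquartile dispersion band, indexed from the intervention step.
#'
#' @param trajectories list of treated `sim_trajectory` objects.
#' @param window steps shown from the intervention (default 25).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the step x replicate ratio matrix.
#' @export
plot_ratio <- function(trajectories, window = 25L, ...) {
  series <- lapply(trajectories, ratio_series, window = window)
  mat <- matrix(NA_real_, nrow = window, ncol = length(series))
  for (j in seq_along(series)) {
    s <- series[[j]]
    mat[s$step_rel + 1L, j] <- s$ratio
  }
  med <- apply(mat, 1L, stats::median, na.rm = TRUE)
  lo <- apply(mat, 1L, stats::quantile, 0.25, na.rm = TRUE)
  hi <- apply(mat, 1L, stats::quantile, 0.75, na.rm = TRUE)
  xs <- seq_len(window) - 1L
  graphics::plot(xs, med, type = "n", ylim = range(c(lo, hi), na.rm = TRUE),
                 xlab = "steps since intervention",
                 ylab = "apoptosis / division gene ratio", ...)
  ok <- !is.na(lo) & !is.na(hi)
  graphics::polygon(c(xs[ok], rev(xs[ok])), c(lo[ok], rev(hi[ok])),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(xs, med, lwd = 2L)
  invisible(mat)
}

#' Render diagrams to image files
#'
#' Thin wrapper writing one of the three diagram styles to a PNG file.
#'
#' @param x a `sim_trajectory` (style `"marble"`) or list of trajectories
#'   (styles `"broom"`, `"ratio"`).
#' @param style one of `"broom"`, `"marble"`, `"ratio"`.
#' @param file output PNG path.
#' @param width,height device size in pixels.
#' @param ... passed to the underlying plot function.
#' @return `file`, invisibly.
#' @export
render_plots <- function(x, style = c("broom", "marble", "ratio"), file,
                         width = 900, height = 600, ...) {
  style <- match.arg(style)
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  switch(style,
    broom = plot_broom(x, ...),
    marble = plot_marble(x, ...),
    ratio = plot_ratio(x, ...)
  )
  invisible(file)
}

#' @export
plot.sim_trajectory <- function(x, ...) {
  s <- x$steps
  graphics::plot(s$step, s$population, type = "l", xlab = "time step",
                 ylab = "population (cells)", ...)
  graphics::abline(h = x$config$capacity, lty = 3L)
  e <- x$events
  if (!is.na(e$intervention_step)) graphics::abline(v = e$intervention_step)
  if (!is.na(e$relapse_step)) graphics::abline(v = e$relapse_step, lty = 2L)
  invisible(x)
}

#' @export
plot.sim_cohort <- function(x, what = "population", ...) {
  if (is.null(x$trajectories)) {
    stop("cohort was run without keep_trajectories = TRUE", call. = FALSE)
  }
  plot_broom(x$trajectories, what = what, ...)
  invisible(x)
}
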