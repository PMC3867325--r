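# Kaplan-Meier and funnel plot rendering (base graphics, SVG + PNG).

fmt_p <- function(p) formatC(p, format = "g", digits = 2)
fmt_hr <- function(x) formatC(x, format = "f", digits = 2)

km_annotation <- function(result) {
  sprintf("HR = %s (%s-%s), logrank p = %s", fmt_hr(result$hr),
          fmt_hr(result$ci_low), fmt_hr(result$ci_high),
          fmt_p(result$logrank_p))
}

km_steps <- function(km) {
  list(x = c(0, km$time), y = c(1, km$surv))
}

draw_km <- function(result, main) {
  lowc <- "#1f78b4"; highc <- "#e31a1c"
  xmax <- max(c(result$km_low$time, result$km_high$time))
  plot(NA, xlim = c(0, xmax * 1.02), ylim = c(0, 1.05),
       xlab = "Time (months)", ylab = "Survival probability", main = main)
  for (side in list(list(km = result$km_low, col = lowc),
                    list(km = result$km_high, col = highc))) {
    st <- km_steps(side$km)
    lines(st$x, st$y, type = "s", col = side$col, lwd = 2)
    cens <- side$km[side$km$n_censor > 0, , drop = FALSE]
    if (nrow(cens)) points(cens$time, cens$surv, pch = 3, col = side$col)
  }
  legend("bottomleft",
         legend = c(sprintf("low (n = %d)", result$n_low),
                    sprintf("high (n = %d)", result$n_high)),
         col = c(lowc, highc), lwd = 2, bty = "n")
  mtext(km_annotation(result), side = 3, line = 0.2, cex = 0.9)
  at_times <- pretty(c(0, xmax), 4)
  at_risk <- function(km, t) {
    n0 <- km$n_risk[1] %||% 0
    vapply(t, function(tt) {
      before <- km$time <= tt
      if (!any(before)) n0 else km$n_risk[max(which(before))] -
        km$n_event[max(which(before))] - km$n_censor[max(which(before))]
    }, 0)
  }
  mtext(sprintf("at risk (low): %s",
                paste(at_risk(result$km_low, at_times), collapse = " / ")),
        side = 1, line = 3.8, cex = 0.7, adj = 0)
  mtext(sprintf("at risk (high): %s",
                paste(at_risk(result$km_high, at_times), collapse = " / ")),
        side = 1, line = 4.6, cex = 0.7, adj = 0)
}

open_device <- function(path, width = 7, height = 6) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100, height = height * 100,
                              res = 100),
         stopf("unsupported plot format '%s'", ext))
}

#' Render a Kaplan-Meier plot for a biomarker result
#'
#' Draws the two dichotomized groups as step curves with censoring ticks, a
#' legend with group sizes, per-group at-risk counts, and an annotation of
#' the hazard ratio with its 95% confidence interval and the logrank p
#' (HR to two decimals, p to two significant figures).
#'
#' @param result A `BiomarkerResult` or `BestCutoffResult`.
#' @param path Output stem or file path; with no (or another) extension,
#'   both `<path>.svg` and `<path>.png` are written.
#' @return Character vector of files written, invisibly.
#' @export
render_km_plot <- function(result, path) {
  if (inherits(result, "BiomarkerResult")) {
    main <- sprintf("%s (%s)", result$target, result$endpoint)
    result <- result$analysis
  } else main <- "Kaplan-Meier"
  stopifnot(inherits(result, "BestCutoffResult"))
  if (result$n_low == 0 || result$n_high == 0)
    stopf("degenerate groups: cannot plot")
  files <- plot_targets(path)
  for (f in files) {
    open_device(f)
    op <- graphics::par(mar = c(6.5, 4, 3, 1))
    draw_km(result, main)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(files)
}

plot_targets <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("svg", "png")) return(path)
  paste0(path, c(".svg", ".png"))
}

#' Render a funnel plot of per-dataset hazard ratios
#'
#' Hazard ratio (log scale, with confidence-interval whiskers) on the
#' horizontal axis against dataset sample size on the vertical axis, with a
#' reference line at HR = 1: larger cohorts should scatter more tightly
#' around the common effect.
#'
#' @param records Funnel records from [per_dataset_analysis()].
#' @param path Output stem or file path (as in [render_km_plot()]).
#' @return Character vector of files written, invisibly.
#' @export
render_funnel_plot <- function(records, path) {
  if (nrow(records) == 0) stopf("no funnel records to plot")
  files <- plot_targets(path)
  xlim <- range(c(records$ci_low, records$ci_high, 1))
  for (f in files) {
    open_device(f)
    plot(records$hr, records$n, log = "x", xlim = xlim,
         ylim = c(0, max(records$n) * 1.1), pch = 19,
         xlab = "Hazard ratio (95% CI)", ylab = "Sample size",
         main = "Per-dataset meta-analysis")
    graphics::segments(records$ci_low, records$n, records$ci_high, records$n)
    graphics::abline(v = 1, lty = 2, col = "grey40")
    graphics::text(records$hr, records$n, records$dataset_id,
                   pos = 3, cex = 0.8)
    grDevices::dev.off()
  }
  invisible(files)
}
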