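#' Violin plots of a dynamics variable by group
#'
#' Base-graphics violin plot of one summary variable per group, in the
#' style used for filopodia dynamics figures: a mirrored kernel-density
#' outline per group, a diamond at the mean and a horizontal line at the
#' median.
#'
#' @param summaries Data frame from [summarize_cohort()].
#' @param variable One of `"Emax"`, `"lifetime"`, `"Ve"`, `"Vr"`.
#' @param col Fill colour(s), recycled over groups.
#' @param main Plot title; defaults to the variable name.
#' @return Invisibly, the list of group value vectors plotted.
#' @export
plot_cohort_violins <- function(summaries,
                                variable = c("Emax", "lifetime", "Ve", "Vr"),
                                col = "#9ecae1", main = NULL) {
  variable <- match.arg(variable)
  vals <- lapply(split(summaries, summaries$group_label),
                 variable_values, variable = variable)
  vals <- vals[vapply(vals, length, 1L) > 0]
  if (length(vals) == 0) stop("no values to plot for ", variable)
  unit <- switch(variable, Emax = "µm", lifetime = "min",
                 "µm/min")
  ylim <- range(unlist(vals))
  graphics::plot(NA, xlim = c(0.5, length(vals) + 0.5), ylim = ylim,
                 xaxt = "n", xlab = "", ylab = paste0(variable, " (", unit, ")"),
                 main = if (is.null(main)) variable else main)
  graphics::axis(1, at = seq_along(vals), labels = names(vals), las = 2)
  col <- rep_len(col, length(vals))
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (length(v) >= 3 && stats::var(v) > 0) {
      d <- stats::density(v)
      w <- 0.35 * d$y / max(d$y)
      graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                        col = col[i], border = "grey30")
    }
    graphics::segments(i - 0.2, stats::median(v), i + 0.2, stats::median(v),
                       lwd = 2)
    graphics::points(i, mean(v), pch = 23, bg = "white", cex = 1.2)
  }
  invisible(vals)
}
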