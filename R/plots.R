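# Base-graphics view of the per-box marginal-mean curves.

#' Plot per-box marginal-mean curves for one variable and muscle
#'
#' Adjusted means by box position for both conditions, with standard-error
#' bars: the per-box view of the exoskeleton effect across the exercise.
#'
#' @param curves The `curves` table from [run_effects()].
#' @param variable,muscle Which fit to plot.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted subset.
#' @export
plot_box_curves <- function(curves, variable, muscle, ...) {
  sub <- curves[curves$variable == variable & curves$muscle == muscle, ]
  if (!nrow(sub)) abort_input("no curve rows for this variable and muscle")
  sub$box <- as.integer(as.character(sub$box))
  cols <- c(noexo = "grey25", exo = "firebrick")
  ylim <- range(sub$emmean - sub$SE, sub$emmean + sub$SE)
  graphics::plot(NA, xlim = range(sub$box), ylim = ylim, xlab = "box",
                 ylab = variable, main = muscle, ...)
  for (cond in c("noexo", "exo")) {
    cc <- sub[sub$exo == cond, ]
    cc <- cc[order(cc$box), ]
    graphics::lines(cc$box, cc$emmean, col = cols[[cond]], lwd = 2)
    graphics::arrows(cc$box, cc$emmean - cc$SE, cc$box, cc$emmean + cc$SE,
                     angle = 90, code = 3, length = 0.03, col = cols[[cond]])
  }
  graphics::legend("topleft", legend = c("without exo", "with exo"),
                   col = cols, lwd = 2, bty = "n")
  invisible(sub)
}
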