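#' Plot a scenario sweep with 99% confidence bands
#'
#' Convenience line plot of one score against the varied parameter, one line
#' per discovery x validation combination, with shaded 99% confidence bands.
#' Purely a visualization aid; all reported quantities come from the result
#' tables.
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param score one of `"fdr"`, `"mspe"`, `"sv"`, `"cs"`.
#' @param file optional PNG path; when given the plot is written there.
#' @param log_x plot the parameter axis on a log scale.
#' @return Invisibly, the summary rows plotted.
#' @export
plot_scenario <- function(result, score = c("fdr", "mspe", "sv", "cs"),
                          file = NULL, log_x = FALSE) {
  stopifnot(inherits(result, "scenario_result"))
  score <- match.arg(score)
  s <- result$summary[result$summary$score == score, ]
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  combos <- unique(s[c("disc_design", "val_design")])
  cols <- c(SC.SC = "#1b9e77", SC.MC = "#66c2a5",
            MC.SC = "#d95f02", MC.MC = "#fc8d62")
  lab <- c(fdr = "false discovery rate", mspe = "mean squared prediction error",
           sv = "rate of successful validation", cs = "calibration slope")
  plot(range(s$param_value), range(c(s$ci_lo, s$ci_hi)), type = "n",
       log = if (log_x) "x" else "",
       xlab = result$varied, ylab = lab[score],
       main = sprintf("Scenario %d: %s", result$scenario, lab[score]))
  for (k in seq_len(nrow(combos))) {
    sub <- s[s$disc_design == combos$disc_design[k] &
               s$val_design == combos$val_design[k], ]
    sub <- sub[order(sub$param_value), ]
    col <- cols[paste(combos$disc_design[k], combos$val_design[k], sep = ".")]
    graphics::polygon(c(sub$param_value, rev(sub$param_value)),
                      c(sub$ci_lo, rev(sub$ci_hi)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
    graphics::lines(sub$param_value, sub$mean, col = col, lwd = 2)
    graphics::points(sub$param_value, sub$mean, col = col, pch = 16)
  }
  graphics::legend("topright", bty = "n", lwd = 2, col = cols,
                   legend = paste(combos$disc_design, "disc /",
                                  combos$val_design, "val"))
  invisible(s)
}
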