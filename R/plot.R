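# Concentration-profile plotting in the conventional form: log-scale
# concentration (ug/L) on the y axis, days on the x axis.

#' Plot simulated concentration profiles
#'
#' @param x A `cd_simulation`.
#' @param compartments Concentration columns to draw (default blood,
#'   liver, adipose and brain).
#' @param log Axis spec passed to [graphics::matplot()]; `"y"` (default)
#'   gives the conventional semi-log profile.
#' @param ... Further arguments to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.cd_simulation <- function(x, compartments = c("blood_total", "liver",
                                                   "adipose", "brain"),
                               log = "y", ...) {
  cc <- x$conc
  keep <- intersect(compartments, names(cc))
  y <- as.matrix(cc[keep])
  pos <- y > 0
  if (log %in% c("y", "xy") && !any(pos)) log <- ""
  y[y <= 0] <- NA  # log-scale: drop zero rows (pre-dose)
  graphics::matplot(cc$time_days, y, type = "l", lty = 1, col = seq_along(keep),
                    xlab = "time (days)", ylab = "CD concentration (ug/L)",
                    log = log, ...)
  graphics::legend("topright", legend = keep, col = seq_along(keep), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Bar chart of a sensitivity screen
#'
#' @param x A `cd_sensitivity` report.
#' @param top Number of parameters to display (default 12).
#' @param ... Further arguments to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.cd_sensitivity <- function(x, top = 12, ...) {
  tab <- utils::head(x$table[!is.na(x$table$max_abs), ], top)
  graphics::barplot(rev(tab$max_abs), names.arg = rev(tab$parameter),
                    horiz = TRUE, las = 1,
                    xlab = sprintf("max |SA%%| (delta = %.0f%%)",
                                   100 * x$delta), ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
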