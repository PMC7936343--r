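#' Plot a per-cycle record stream
#'
#' Trajectories of the slow type's mean relative abundance in patches and in
#' dispersing hosts, cycle by cycle.
#'
#' @param x An \code{mp_records} data.frame from [run_simulation()].
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.mp_records <- function(x, ...) {
  graphics::plot(x$cycle, x$f_patch, type = "l", col = "steelblue", lwd = 2,
                 ylim = c(0, max(c(x$f_patch, x$f_host, 0.1), na.rm = TRUE)),
                 xlab = "dispersal cycle",
                 ylab = "slow-type relative abundance", ...)
  graphics::lines(x$cycle, x$f_host, col = "darkorange", lwd = 2)
  graphics::legend("topleft", legend = c("in patches", "in hosts"),
                   col = c("steelblue", "darkorange"), lwd = 2, bty = "n")
  invisible(x)
}

#' Plot a fixation-probability sweep
#'
#' Fixation probability of the slow type against the swept parameter, with
#' binomial confidence intervals.
#'
#' @param x An \code{mp_sweep} data.frame from [run_sweep()].
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.mp_sweep <- function(x, ...) {
  graphics::plot(x$value, x$fixation, type = "b", pch = 19,
                 ylim = c(0, max(c(x$ci_hi, 0.05), na.rm = TRUE)),
                 xlab = unique(x$param)[1],
                 ylab = "fixation probability of the slow type", ...)
  graphics::arrows(x$value, x$ci_lo, x$value, x$ci_hi, angle = 90, code = 3,
                   length = 0.04)
  invisible(x)
}

#' Plot an independent-patch experiment
#'
#' Histogram of final slow-type proportions across independent patches.
#'
#' @param x A \code{patch_experiment} from [independent_patches_experiment()].
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments passed to [graphics::hist()].
#' @export
plot.patch_experiment <- function(x, breaks = 30, ...) {
  graphics::hist(x$final_f, breaks = breaks, col = "grey80",
                 xlab = "final slow-type proportion", main = "", ...)
  invisible(x)
}
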