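# Minimal diagnostic figures (base graphics): raster and TSR.

#' Raster plot of spike events
#'
#' @param spikes A [spike_events()] table.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `spikes`.
#' @export
plot_raster <- function(spikes, ...) {
  graphics::plot(spikes$time_s, as.integer(factor(spikes$channel)),
                 pch = ".", xlab = "time (s)", ylab = "electrode", ...)
  invisible(spikes)
}

#' Plot the total spiking rate with optional detected intervals
#'
#' @param tsr A [compute_tsr()] result.
#' @param intervals Optional [interval_set()]; detected intervals are shaded.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `tsr`.
#' @export
plot_tsr <- function(tsr, intervals = NULL, ...) {
  graphics::plot(tsr_centers(tsr), tsr$counts, type = "h",
                 xlab = "time (s)", ylab = "spikes per bin", ...)
  if (!is.null(intervals) && nrow(intervals) > 0) {
    graphics::rect(intervals$start, 0, intervals$end, max(tsr$counts),
                   col = grDevices::adjustcolor("red", 0.2), border = NA)
  }
  invisible(tsr)
}
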