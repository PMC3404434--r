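#' Raster plot of recorded spikes
#'
#' @param spikes spike data.frame from [run_network()].
#' @param layer which layer to show (1 = input, 2 = output).
#' @param pop `"E"` or `"I"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_raster <- function(spikes, layer = 2, pop = "E", ...) {
  sp <- spikes[spikes$layer == layer & spikes$pop == pop, ]
  graphics::plot(sp$time_ms, sp$neuron, pch = ".", cex = 1.5,
                 xlab = "time (ms)", ylab = "neuron",
                 main = sprintf("layer %d (%s)", layer, pop), ...)
  invisible(sp)
}

#' Single-cell information by cell rank
#'
#' @param info an `info_result` from [multi_cell_info()], or the
#'   [single_cell_info()] list.
#' @param ... passed to [graphics::plot()].
#' @export
plot_single_cell_info <- function(info, ...) {
  bits <- if (!is.null(info$single_cell)) info$single_cell$max_bits
          else info$max_bits
  graphics::plot(sort(bits, decreasing = TRUE), type = "s",
                 xlab = "cell rank", ylab = "information (bits)",
                 main = "stimulus-specific single-cell information", ...)
  invisible(bits)
}

#' Multiple-cell information by ensemble size
#'
#' @param info an `info_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_multi_cell_info <- function(info, ...) {
  graphics::plot(seq_along(info$bits), info$bits, type = "b",
                 ylim = c(0, max(1, info$bits)),
                 xlab = "ensemble size", ylab = "information (bits)",
                 main = "multiple-cell information", ...)
  invisible(info$bits)
}

#' Histogram of the plastic efficacies
#'
#' @param Dg efficacy matrix (or `network_state`).
#' @param n_bins number of bins.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_weight_histogram <- function(Dg, n_bins = 20, ...) {
  if (inherits(Dg, "network_state")) Dg <- Dg$weights
  h <- weight_histogram(Dg, n_bins)
  graphics::barplot(h$count, names.arg = sprintf("%.2f", h$bin_left),
                    xlab = "synaptic efficacy", ylab = "count", ...)
  invisible(h)
}
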