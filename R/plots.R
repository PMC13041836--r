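#' Plot an OCR trace with phase shading
#'
#' @param x an `OCRTrace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.OCRTrace <- function(x, ...) {
  cols <- c(basal = "#00000000", oligomycin = "#d9e8f5", fccp = "#e8f5d9",
            rot_aa = "#f5d9d9")
  graphics::plot(x$time_min, x$ocr, type = "n", xlab = "time (min)",
                 ylab = "OCR (pmol O2/min)", ...)
  usr <- graphics::par("usr")
  for (p in unique(x$phase)) {
    t <- x$time_min[x$phase == p]
    graphics::rect(min(t) - 3, usr[3L], max(t) + 3, usr[4L],
                   col = cols[[p]], border = NA)
  }
  graphics::lines(x$time_min, x$ocr, type = "b", pch = 16)
  graphics::box()
  invisible(x)
}

#' Plot a line profile with detected peaks
#'
#' @param x a [line_profile()].
#' @param peaks optional peak indices from [detect_peaks()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.LineProfile <- function(x, peaks = NULL, ...) {
  pos <- (seq_along(x$intensities) - 1L) * x$pixel_size_um
  graphics::plot(pos, x$intensities, type = "l", xlab = "position (um)",
                 ylab = "intensity", ...)
  if (length(peaks))
    graphics::points(pos[peaks], x$intensities[peaks], col = "red", pch = 19)
  invisible(x)
}

#' Plot vesicle nucleus-distance distribution with the peripheral threshold
#'
#' @param x a `SpatialDistribution`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.SpatialDistribution <- function(x, ...) {
  graphics::hist(x$distances$distance_um, xlab = "distance to nucleus (um)",
                 main = "lysosome distribution", col = "grey85", ...)
  graphics::abline(v = x$percentile_threshold_um, col = "red", lwd = 2)
  invisible(x)
}

#' Bar plot of mitolysosome means in the two flux arms
#'
#' @param x a `FluxResult`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.FluxResult <- function(x, ...) {
  graphics::barplot(c(`-inh` = x$mean_minus, `+inh` = x$mean_plus),
                    ylab = "mitolysosomes per cell", ...)
  invisible(x)
}
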