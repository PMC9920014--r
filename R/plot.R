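#' Plot a phantom tissue map
#'
#' Tissue-index image in the phantom's mm frame with antenna positions
#' marked; depth increases downward.
#'
#' @param x a `phantom`.
#' @param ... passed to [graphics::image()].
#' @export
plot.phantom <- function(x, ...) {
  cols <- c("white", "#d9a066", "#f2e394", "#b23a48", "#f7d8c3",
            "#9ecae1", "#3182bd", "#fcae91", "#cb181d")
  graphics::image(x$lateral, x$depth, t(x$tissue), ylim = rev(range(x$depth)),
                  col = cols[sort(unique(as.vector(x$tissue))) + 1],
                  xlab = "lateral (mm)", ylab = "depth (mm)",
                  main = "tissue map", useRaster = TRUE, ...)
  graphics::points(x$antennas$x, x$antennas$depth, pch = 25, bg = "black")
  invisible(x)
}

#' Plot a backscattered-energy map
#'
#' Energy image (normalized to its peak) with the ground-truth ALN outlines
#' overlaid when a phantom is supplied.
#'
#' @param x an `energy_map`.
#' @param phantom optional `phantom` providing the ground truth overlay.
#' @param ... passed to [graphics::image()].
#' @export
plot.energy_map <- function(x, phantom = NULL, ...) {
  e <- x$energy / max(x$energy)
  graphics::image(x$lateral, x$depth, t(e), ylim = rev(range(x$depth)),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "lateral (mm)", ylab = "depth (mm)",
                  main = x$method, useRaster = TRUE, ...)
  if (!is.null(phantom)) {
    for (t in phantom$truth) {
      idx <- which(t$mask, arr.ind = TRUE)
      graphics::points(phantom$lateral[idx[, 2]], phantom$depth[idx[, 1]],
                       pch = ".", col = "white")
      graphics::points(t$center["x"], t$center["d"], pch = 3, col = "white")
    }
  }
  invisible(x)
}
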