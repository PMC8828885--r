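#' Plot a channel, mask or label image
#'
#' Quick base-graphics viewers for the package's image containers,
#' drawn with the origin at the top-left to match pixel coordinates.
#'
#' @param channel numeric matrix (or [binary_mask] / [label_image]).
#' @param main plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_channel <- function(channel, main = "") {
  m <- if (inherits(channel, "binary_mask")) channel$pixels * 1
       else if (inherits(channel, "label_image")) channel$pixels
       else channel
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE,
                  main = main, col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE)
  invisible(NULL)
}

#' Plot cell centroids coloured by type
#'
#' @param cells a `cell_table`.
#' @param colour_by column used for colouring (default `cell_type`).
#' @param main plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_cells <- function(cells, colour_by = "cell_type", main = "") {
  v <- cells[[colour_by]]
  v[is.na(v)] <- "unassigned"
  f <- factor(v)
  cols <- grDevices::hcl.colors(max(3L, nlevels(f)), "Dark 3")
  graphics::plot(cells$centroid_x_um, -cells$centroid_y_um,
                 col = cols[as.integer(f)], pch = 16, cex = 0.6,
                 xlab = "x (um)", ylab = "y (um, flipped)", main = main)
  graphics::legend("topright", legend = levels(f),
                   col = cols[seq_len(nlevels(f))], pch = 16, cex = 0.7)
  invisible(NULL)
}
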