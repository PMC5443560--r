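#' Plot one slice of a registered label volume
#'
#' Draws a single plane of a 3D cluster-label volume (as produced by
#' [register_labels()]) as a colour image, background (0) in white and
#' cluster k in the k-th colour of `palette`.
#'
#' @param volume 3D integer label volume.
#' @param axis Axis perpendicular to the slice: `"x"`, `"y"` or `"z"`.
#' @param index 0-based slice index along `axis`.
#' @param palette Colours indexed by cluster number.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the 2D slice matrix.
#' @export
plot_label_slice <- function(volume, axis = c("z", "x", "y"), index = 0L,
                             palette = grDevices::hcl.colors(max(volume), "Dark 3"),
                             ...) {
  axis <- match.arg(axis)
  sl <- switch(axis,
               x = volume[index + 1L, , ],
               y = volume[, index + 1L, ],
               z = volume[, , index + 1L])
  cols <- c("white", palette)
  graphics::image(seq_len(nrow(sl)) - 1L, seq_len(ncol(sl)) - 1L, sl,
                  col = cols[sort(unique(as.vector(sl))) + 1L],
                  xlab = "", ylab = "", asp = 1, axes = FALSE, ...)
  invisible(sl)
}

#' Polar ("star") plots of per-cluster mean weight vectors
#'
#' Draws the [block_profiles()] matrix as one radial plot per cluster,
#' illustrating how exclusively each block of voxels loads on its own
#' weight dimension.
#'
#' @param profiles s-by-k matrix from [block_profiles()].
#' @param ... Passed to [graphics::stars()].
#' @export
plot_block_profiles <- function(profiles, ...) {
  graphics::stars(t(profiles), draw.segments = TRUE, scale = FALSE,
                  key.loc = NULL, ...)
}

#' @export
plot.accuracy_curve <- function(x, ...) {
  graphics::plot(x$gene_count, x$mean_accuracy, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "number of genes",
                 ylab = "accuracy", ...)
  graphics::lines(x$gene_count, x$perfect_fraction, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("bottomright",
                   legend = c("mean accuracy", "fraction of perfectly classified voxels"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
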