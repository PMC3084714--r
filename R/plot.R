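#' Plot simulated cell tracks
#'
#' Simple base-graphics rendering of one or more tracks: paths in grey,
#' directed samples over-plotted in blue, end points as solid circles.
#' A convenience for eyeballing simulations; not a publication figure.
#'
#' @param x a \code{cell_track} data frame (optionally with a
#'   \code{track_id} column).
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.cell_track <- function(x, ...) {
  df <- as.data.frame(x)
  if (!"track_id" %in% names(df)) df$track_id <- 1L
  graphics::plot(df$x_um, df$y_um, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  for (id in unique(df$track_id)) {
    tr <- df[df$track_id == id, ]
    graphics::lines(tr$x_um, tr$y_um, col = "grey40")
    dirp <- tr$mode == "directed"
    if (any(dirp))
      graphics::points(tr$x_um[dirp], tr$y_um[dirp], col = "steelblue",
                       pch = ".", cex = 2)
    graphics::points(tr$x_um[nrow(tr)], tr$y_um[nrow(tr)], pch = 16)
  }
  invisible(x)
}
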