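#' Draw a cobweb misclassification plot
#'
#' Radar-style plot of the R^2 - R off-diagonal misclassification rates,
#' with the chance polygon (1/R on every axis) overlaid for reference; for
#' three classes the chance polygon is a regular hexagon. Axes start at the
#' top and proceed clockwise in the polygon's recorded order.
#'
#' @param polygon A `"cobweb_polygon"` from [cobweb_coordinates()].
#' @param main Plot title.
#' @param ... Further [graphics::par()] settings.
#' @return `polygon`, invisibly.
#' @export
plot_cobweb <- function(polygon, main = "Misclassification cobweb", ...) {
  stopifnot(inherits(polygon, "cobweb_polygon"))
  vals <- polygon$value
  chance <- attr(polygon, "chance")
  n <- length(vals)
  # top axis, clockwise
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1L) / n
  rmax <- max(vals, chance) * 1.15
  op <- graphics::par(mar = c(1, 1, 3, 1), ...)
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.45, 1.45) * rmax,
                 ylim = c(-1.35, 1.35) * rmax,
                 axes = FALSE, xlab = "", ylab = "", main = main,
                 asp = 1)
  for (frac in c(0.25, 0.5, 0.75, 1)) {
    r <- rmax * frac
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey85")
  }
  graphics::segments(0, 0, rmax * cos(ang), rmax * sin(ang),
                     col = "grey85")
  graphics::polygon(chance * cos(ang), chance * sin(ang),
                    border = "grey40", lty = 2)
  graphics::polygon(vals * cos(ang), vals * sin(ang),
                    border = "firebrick", col = grDevices::adjustcolor(
                      "firebrick", alpha.f = 0.25), lwd = 2)
  graphics::text(1.25 * rmax * cos(ang), 1.25 * rmax * sin(ang),
                 labels = polygon$axis, cex = 0.7, xpd = NA)
  graphics::legend("bottomright", bty = "n", cex = 0.7, lty = c(1, 2),
                   col = c("firebrick", "grey40"),
                   legend = c("classifier", sprintf("chance (1/R = %.2f)",
                                                    chance)))
  invisible(polygon)
}

#' Render a cobweb plot to an SVG or PNG file
#'
#' The output format follows the file extension (`.svg` or `.png`).
#'
#' @inheritParams plot_cobweb
#' @param path Output file path ending in `.svg` or `.png`.
#' @return `path`, invisibly; the file exists and is non-empty on return.
#' @export
render_cobweb <- function(polygon, path,
                          main = "Misclassification cobweb") {
  ext <- tolower(tools::file_ext(path))
  opened <- tryCatch({
    switch(ext,
           svg = grDevices::svg(path, width = 7, height = 7),
           png = grDevices::png(path, width = 900, height = 900,
                                res = 130),
           stopf("unsupported figure format '.%s' (use .svg or .png)", ext))
    TRUE
  }, error = function(e) stopf("cannot open figure file %s: %s", path,
                               conditionMessage(e)))
  on.exit(grDevices::dev.off())
  plot_cobweb(polygon, main = main)
  invisible(path)
}
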