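# Rendering helpers mirroring the field's standard map figures.

#' Plot a connectivity map
#'
#' Renders the 2-d grid with square size proportional to |Z| and
#' significant sites (Z above threshold) in red, silent sites in black.
#'
#' @param map a [ConnectivityMap-class].
#' @param threshold significance threshold.
#' @param ... passed to \code{plot()}.
#' @export
plotMap <- function(map, threshold = significanceThreshold(), ...) {
  s <- map@sites
  sig <- s$z > threshold
  cex <- 0.5 + 2 * pmin(1, abs(s$z) / max(abs(s$z), 1))
  plot(s$ml_um, s$depth_row, pch = 15, cex = cex,
       col = ifelse(sig, "red", "black"),
       xlab = "distance from midline (um)", ylab = "depth row",
       main = map@cellId, yaxt = "n", ...)
  graphics::axis(2, at = unique(s$depth_row))
  graphics::abline(v = 0, lty = 3, col = "grey50")
}

#' Plot a mediolateral input pattern
#'
#' Significant stretches (Z above threshold) are drawn in red, silent
#' stretches in black, with the significance threshold as a dashed line.
#'
#' @param pattern a [MediolateralPattern-class].
#' @param threshold significance threshold.
#' @param ... passed to \code{plot()}.
#' @export
plotPattern <- function(pattern, threshold = significanceThreshold(), ...) {
  x <- pattern@positions; y <- pattern@values
  plot(x, y, type = "n", xlab = "distance from midline (um)",
       ylab = "Z-score", main = pattern@cellId, ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  above <- y > threshold
  graphics::lines(x, ifelse(above, NA, y), col = "black")
  graphics::lines(x, ifelse(above, y, NA), col = "red")
  if (is.finite(pattern@somaPosition))
    graphics::abline(v = pattern@somaPosition, lty = 3, col = "grey60")
}

#' Heatmap of a correlation matrix with cluster outlines
#'
#' Uses \pkg{pheatmap} when available, otherwise a base \code{image()}.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param assign optional [ClusterAssignment-class]; cluster memberships
#'   are drawn as row/column annotations.
#' @export
plotCorrelationMatrix <- function(cm, assign = NULL) {
  r <- cm@r
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ann <- NULL
    if (!is.null(assign)) {
      ann <- data.frame(cluster = factor(assign@clusters),
                        row.names = rownames(r))
    }
    pheatmap::pheatmap(r, cluster_rows = FALSE, cluster_cols = FALSE,
                       annotation_row = ann, annotation_col = ann,
                       main = "median-pattern correlation")
  } else {
    image(cm@centers, cm@centers, r, xlab = "group center (um)",
          ylab = "group center (um)", main = "median-pattern correlation",
          col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
          zlim = c(-1, 1))
  }
  invisible(NULL)
}
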