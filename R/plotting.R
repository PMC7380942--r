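## Base-graphics renderings of the regime map, phase portrait and
## kymograph.

.REGIME_COLORS <- c(`0` = "#c6dbef", `1` = "#2171b5", `2` = "#74c476",
                    `3` = "#cb181d", `4` = "#fd8d3c", `5` = "#9e9ac8",
                    `6` = "#fee08b", `7` = "#8c510a", `8` = "#dd3497")

#' Plot a regime map
#'
#' Colour-coded two-parameter bifurcation diagram; unclassified points
#' are grey.
#'
#' @param map a \linkS4class{RegimeMap}.
#' @param ... passed to \code{graphics::image}.
#' @export
plotRegimeMap <- function(map, ...) {
  stopifnot(is(map, "RegimeMap"))
  z <- map@labels
  graphics::image(map@grid1, map@grid2, matrix(match(as.character(z),
                                                     names(.REGIME_COLORS)),
                                               nrow(z), ncol(z)),
                  col = unname(.REGIME_COLORS), zlim = c(1, 9),
                  xlab = map@axis1, ylab = map@axis2,
                  main = "Dynamic regimes of the RhoA-Rac1 network", ...)
  present <- sort(unique(as.vector(z[!is.na(z)])))
  graphics::legend("topright", legend = present, bg = "white",
                   fill = .REGIME_COLORS[as.character(present)],
                   title = "regime")
  invisible(NULL)
}

#' Plot a reduced phase portrait
#'
#' RhoA nullcline in red, Rac1 nullcline in blue, vector field as arrows,
#' fixed points as filled (stable) or open (unstable) markers, the
#' projected limit cycle in green.
#'
#' @param portrait output of \code{\link{computePhasePortrait}}.
#' @export
plotPhasePortrait <- function(portrait) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "active RhoA fraction", ylab = "active Rac1 fraction",
                 main = "Quasi-steady-state phase portrait")
  vf <- portrait$vectorField
  sc <- 0.04 / stats::median(sqrt(vf$drho^2 + vf$drac^2) + 1e-12)
  graphics::arrows(vf$rho, vf$rac, vf$rho + sc * vf$drho,
                   vf$rac + sc * vf$drac, length = 0.03, col = "grey70")
  for (s in portrait$rhoNullcline) graphics::lines(s$rho, s$rac, col = "red", lwd = 2)
  for (s in portrait$racNullcline) graphics::lines(s$rho, s$rac, col = "blue", lwd = 2)
  if (!is.null(portrait$cycleProjection)) {
    graphics::lines(portrait$cycleProjection$rho, portrait$cycleProjection$rac,
                    col = "darkgreen", lwd = 2)
  }
  if (!is.null(portrait$intersections)) {
    stab <- grepl("^stable", portrait$intersections$type)
    graphics::points(portrait$intersections$rho, portrait$intersections$rac,
                     pch = ifelse(stab, 19, 2), cex = 1.4)
  }
  invisible(NULL)
}

#' Plot a kymograph
#'
#' @param K matrix from \code{\link{buildKymograph}}.
#' @param ... passed to \code{graphics::image}.
#' @export
plotKymograph <- function(K, ...) {
  x <- attr(K, "x"); tt <- attr(K, "time")
  graphics::image(tt, x, t(K), xlab = "time (s)", ylab = "position (um)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "activity kymograph", ...)
  invisible(NULL)
}
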