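## Synthetic data generators: cell masks, pseudo-FRET ratio movies from
## simulations, and PLA-like point patterns with per-segment densities.
## Everything is bit-reproducible under a fixed seed.

#' Generate a synthetic polarized cell mask
#'
#' Builds a simply connected binary mask shaped as an ellipse or a
#' teardrop (wide end = front, at the right).  The outline is modulated
#' by a seeded low-frequency perturbation so that masks look organic but
#' remain reproducible.
#'
#' @param lengthPx,widthPx mask dimensions in pixels (>= 40 x 20).
#' @param shape "ellipse" or "teardrop".
#' @param seed integer seed controlling the boundary perturbation.
#' @param roughness relative amplitude of the boundary perturbation.
#' @return logical matrix (widthPx x lengthPx), TRUE inside the cell.
#' @export
generateCellMask <- function(lengthPx = 120, widthPx = 50,
                             shape = c("ellipse", "teardrop"), seed = 1,
                             roughness = 0.05) {
  shape <- match.arg(shape)
  if (lengthPx < 40 || widthPx < 20) stop("mask must be at least 40 x 20 px")
  rng <- .withSeed(seed, {
    list(a = runif(3, 0, roughness), ph = runif(3, 0, 2 * pi))
  })
  u <- (seq_len(lengthPx) - 0.5) / lengthPx
  halfWidth <- switch(shape,
    ellipse = sqrt(pmax(u * (1 - u), 0)) * 2,        # max 1 at u = 0.5
    teardrop = {
      h <- sqrt(pmax(u * (1 - u), 0)) * (0.55 + 0.9 * u)
      h / max(h)
    })
  pert <- 1 + rng$a[1L] * sin(2 * pi * u + rng$ph[1L]) +
    rng$a[2L] * sin(4 * pi * u + rng$ph[2L]) +
    rng$a[3L] * sin(6 * pi * u + rng$ph[3L])
  hw <- pmax(halfWidth * pert, 0) * (widthPx / 2)
  y0 <- (widthPx + 1) / 2
  mask <- sapply(seq_len(lengthPx), function(j) {
    abs(seq_len(widthPx) - y0) < hw[j]
  })
  mask <- .fillHoles(mask)
  lab <- .labelComponents(mask)
  if (max(lab) > 1L) mask <- lab == which.max(tabulate(lab[lab > 0L]))
  mask
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render a pseudo-FRET ratio movie from a simulation
#'
#' Emulates ratiometric biosensor imaging of the active RhoA field:
#' frames are the rho field resampled to the movie cadence, multiplied by
#' an exponential photobleaching decay and by seeded multiplicative
#' Gaussian noise.  The burst times detected on the noiseless resampled
#' movie (per 10/70/20 region) are carried alongside as ground truth.
#'
#' @param solution a \linkS4class{SpatioTemporalSolution}.
#' @param noiseSd noise standard deviation as a fraction of the signal.
#' @param photobleachRate bleaching rate (1/s).
#' @param frameInterval movie frame interval (s); must be >= the solution
#'   output interval.
#' @param seed integer noise seed.
#' @param species imaged species (default "rho").
#' @return list of class "FretMovie": frames (time x pixel matrix), times,
#'   coords, groundTruthBursts (list per region), and the generation
#'   settings.
#' @export
renderFretMovie <- function(solution, noiseSd = 0.1, photobleachRate = 0,
                            frameInterval = 5, seed = 1, species = "rho") {
  stopifnot(is(solution, "SpatioTemporalSolution"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (frameInterval <= 0) stop("frameInterval must be positive")
  solDt <- stats::median(diff(solution@times))
  if (solDt > frameInterval + 1e-9) {
    stop("solution frame interval (", solDt, " s) exceeds the movie cadence (",
         frameInterval, " s)")
  }
  tt <- seq(min(solution@times), max(solution@times), by = frameInterval)
  f <- solutionField(solution, species)
  clean <- vapply(seq_len(ncol(f)), function(j) {
    approx(solution@times, f[, j], xout = tt)$y
  }, numeric(length(tt)))
  clean <- clean * exp(-photobleachRate * (tt - tt[1L]))
  frames <- if (noiseSd > 0) {
    noise <- .withSeed(seed, matrix(rnorm(length(clean), 0, noiseSd),
                                    nrow(clean), ncol(clean)))
    clean * (1 + noise)
  } else clean
  seg <- .segmentOfXfrac(solution@coords$xfrac)
  gt <- lapply(setNames(c("front", "middle", "rear"),
                        c("front", "middle", "rear")), function(rg) {
    sel <- seg == rg
    if (!any(sel)) return(numeric(0))
    detectBursts(rowMeans(clean[, sel, drop = FALSE]), frameInterval)
  })
  structure(list(frames = frames, times = tt, coords = solution@coords,
                 groundTruthBursts = gt, noiseSd = noiseSd,
                 photobleachRate = photobleachRate,
                 frameInterval = frameInterval, seed = seed),
            class = "FretMovie")
}

## segment of each mask pixel (matrix of NA/front/middle/rear)
.maskSegments <- function(mask, frontAtRight = TRUE) {
  cols <- which(colSums(mask) > 0)
  cr <- range(cols)
  xf <- (col(mask) - cr[1L]) / max(cr[2L] - cr[1L], 1L)
  if (!frontAtRight) xf <- 1 - xf
  seg <- matrix(NA_character_, nrow(mask), ncol(mask))
  seg[mask] <- .segmentOfXfrac(xf[mask])
  seg
}

#' Generate a PLA-like point pattern
#'
#' Homogeneous spatial point process per cell segment: the mask is split
#' longitudinally into front (10%), middle (70%) and rear (20%) segments
#' and each segment receives Poisson(density x area) points placed
#' uniformly over its pixels.  Channel presets reproduce the observed
#' polarity: RhoA-DIA complexes are front-enriched, RhoA-ROCK complexes
#' rear-enriched.
#'
#' @param mask logical matrix (TRUE inside the cell).
#' @param channel "RhoA-DIA" or "RhoA-ROCK" (sets default densities), or
#'   "custom".
#' @param densities named numeric c(front, middle, rear), points per
#'   pixel; defaults depend on the channel.
#' @param seed integer seed.
#' @param frontAtRight logical, orientation of the mask.
#' @return data.frame of class "PlaPattern" with columns x, y (pixel
#'   coordinates), segment, channel.
#' @export
generatePlaPattern <- function(mask, channel = c("RhoA-DIA", "RhoA-ROCK", "custom"),
                               densities = NULL, seed = 1, frontAtRight = TRUE) {
  channel <- match.arg(channel)
  if (is.null(densities)) {
    densities <- switch(channel,
      "RhoA-DIA" = c(front = 0.12, middle = 0.05, rear = 0.02),
      "RhoA-ROCK" = c(front = 0.03, middle = 0.06, rear = 0.12),
      stop("'densities' must be given for channel = \"custom\""))
  }
  if (!all(c("front", "middle", "rear") %in% names(densities))) {
    stop("densities must be named front, middle, rear")
  }
  if (any(densities < 0)) stop("densities must be >= 0")
  seg <- .maskSegments(mask, frontAtRight)
  pts <- .withSeed(seed, {
    out <- NULL
    for (rg in c("front", "middle", "rear")) {
      pix <- which(!is.na(seg) & seg == rg)
      if (!length(pix)) next
      n <- stats::rpois(1L, densities[[rg]] * length(pix))
      if (n == 0L) next
      take <- sample(pix, n, replace = TRUE)
      i <- (take - 1L) %% nrow(mask) + 1L
      j <- (take - 1L) %/% nrow(mask) + 1L
      out <- rbind(out, data.frame(x = j - runif(n), y = i - runif(n),
                                   segment = rg))
    }
    out
  })
  if (is.null(pts)) pts <- data.frame(x = numeric(0), y = numeric(0),
                                      segment = character(0))
  pts$channel <- rep(if (channel == "custom") "custom" else channel,
                     nrow(pts))
  class(pts) <- c("PlaPattern", class(pts))
  pts
}

#' Quantify a PLA point pattern by cell segment
#'
#' Counts points per 10/70/20 segment and divides by the segment pixel
#' area; round-trips the generator densities within sampling error.
#' Points falling outside the mask are an error listing their indices.
#'
#' @param pattern a data.frame with columns x, y (pixel coordinates).
#' @param mask logical matrix used to generate the pattern.
#' @param frontAtRight logical, orientation of the mask.
#' @return data.frame with columns segment, count, areaPx, density.
#' @export
quantifyPlaSegments <- function(pattern, mask, frontAtRight = TRUE) {
  seg <- .maskSegments(mask, frontAtRight)
  if (nrow(pattern)) {
    i <- pmin(pmax(ceiling(pattern$y), 1L), nrow(mask))
    j <- pmin(pmax(ceiling(pattern$x), 1L), ncol(mask))
    inside <- mask[cbind(i, j)] &
      pattern$x >= 0 & pattern$x <= ncol(mask) &
      pattern$y >= 0 & pattern$y <= nrow(mask)
    if (any(!inside)) {
      stop("points outside the mask at indices: ",
           paste(which(!inside), collapse = ", "))
    }
    ptSeg <- seg[cbind(i, j)]
  } else ptSeg <- character(0)
  regions <- c("front", "middle", "rear")
  counts <- vapply(regions, function(rg) sum(ptSeg == rg), integer(1))
  areas <- vapply(regions, function(rg) sum(!is.na(seg) & seg == rg), integer(1))
  data.frame(segment = regions, count = counts, areaPx = areas,
             density = ifelse(areas > 0, counts / areas, NA_real_))
}

#' Write a binary mask as a PNG image
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
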