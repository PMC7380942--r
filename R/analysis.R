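## Quantification of simulations and synthetic movies: bursts by region,
## kymographs, oscillatory centers, hysteresis protocols.

## longitudinal 10/70/20 segmentation shared with the PLA quantification:
## front = leading 10% of the cell length, middle = next 70%, rear = 20%
.segmentOfXfrac <- function(xfrac) {
  ifelse(xfrac >= 0.9, "front", ifelse(xfrac <= 0.2, "rear", "middle"))
}

#' Detect activity bursts in a time series
#'
#' A burst is an upward crossing of the threshold
#' \code{baseline + thresholdFrac * (max - baseline)} where the baseline
#' is the 10th percentile of the series; crossings within the refractory
#' time of the previous burst are ignored.  A constant series yields zero
#' bursts.  The threshold is quantile/range based, so burst counts are
#' invariant to affine rescaling of the series.
#'
#' @param series numeric activity time series.
#' @param dt sampling interval (s).
#' @param thresholdFrac fraction of the baseline-to-max range.
#' @param refractory minimal time between bursts (s).
#' @param baselineQuantile quantile defining the baseline.
#' @param minRange amplitude floor: a series whose total range is below
#'   this value is treated as quiescent (0 bursts).  The default, 0.1 of
#'   the dimensionless activity scale, matches the typical ratiometric
#'   biosensor noise floor (and the synthetic movie generator's default
#'   noise); set to 0 for a purely range-relative detector.
#' @return numeric vector of burst times (s, relative to series start).
#' @export
detectBursts <- function(series, dt, thresholdFrac = 0.5, refractory = 20,
                         baselineQuantile = 0.1, minRange = 0.1) {
  if (length(series) < 2L) return(numeric(0))
  if (any(!is.finite(series))) stop("series must be finite")
  rng <- range(series)
  if (diff(rng) <= max(minRange, .Machine$double.eps * max(1, abs(rng[2L])))) {
    return(numeric(0))
  }
  base <- quantile(series, baselineQuantile, names = FALSE)
  thr <- base + thresholdFrac * (max(series) - base)
  up <- which(series[-1L] > thr & series[-length(series)] <= thr)
  if (!length(up)) return(numeric(0))
  times <- up * dt
  keep <- times[1L]
  for (tt in times[-1L]) {
    if (tt - keep[length(keep)] >= refractory) keep <- c(keep, tt)
  }
  keep
}

#' Count RhoA activity bursts by cell region
#'
#' Splits the cell into front (leading 10% of the length), middle (70%)
#' and rear (20%) segments, mirroring the PLA segmentation; computes the
#' spatial mean of active RhoA over each region; and counts bursts with
#' \code{\link{detectBursts}} over the requested time window.
#'
#' @param solution a \linkS4class{SpatioTemporalSolution}.
#' @param window numeric c(start, end) in seconds, or a scalar duration
#'   taken from the end of the run (default 600 s).
#' @param species species to analyze (default "rho").
#' @param ... passed to \code{\link{detectBursts}}.
#' @return data.frame (class "BurstTable") with columns region, windowStart,
#'   windowEnd, burstCount; burst times in the attribute "burstTimes".
#' @export
countBurstsByRegion <- function(solution, window = 600, species = "rho", ...) {
  stopifnot(is(solution, "SpatioTemporalSolution"))
  tt <- solution@times
  if (length(window) == 1L) window <- c(max(tt) - window, max(tt))
  if (window[1L] < min(tt) - 1e-9 || window[2L] > max(tt) + 1e-9) {
    stop("window [", window[1L], ", ", window[2L], "] exceeds the solution span [",
         min(tt), ", ", max(tt), "]")
  }
  keep <- tt >= window[1L] & tt <= window[2L]
  dt <- stats::median(diff(tt))
  f <- solutionField(solution, species)[keep, , drop = FALSE]
  seg <- .segmentOfXfrac(solution@coords$xfrac)
  regions <- c("front", "middle", "rear")
  bt <- lapply(setNames(regions, regions), function(rg) {
    sel <- seg == rg
    if (!any(sel)) return(numeric(0))
    detectBursts(rowMeans(f[, sel, drop = FALSE]), dt, ...)
  })
  out <- data.frame(region = regions,
                    windowStart = window[1L], windowEnd = window[2L],
                    burstCount = vapply(bt, length, integer(1)))
  attr(out, "burstTimes") <- bt
  class(out) <- c("BurstTable", class(out))
  out
}

#' Locate the wave-arrival analysis window of a movement cycle
#'
#' During a movement cycle the oscillatory GTPase zone spreads from the
#' leading edge toward the rear; the phase in which the rear experiences
#' RhoA activity changes is centred on the half-rise of the rear-region
#' mean RhoA.  This helper returns a window of the requested length
#' centred on that time (clipped to the solution span), which is the
#' protocol window for region-resolved burst counting.
#'
#' @param solution a \linkS4class{SpatioTemporalSolution}.
#' @param length window length (s).
#' @return numeric c(start, end).
#' @export
movementCycleWindow <- function(solution, length = 600) {
  stopifnot(is(solution, "SpatioTemporalSolution"))
  tt <- solution@times
  seg <- .segmentOfXfrac(solution@coords$xfrac)
  rear <- rowMeans(solutionField(solution, "rho")[, seg == "rear", drop = FALSE])
  half <- (min(rear) + max(rear)) / 2
  tHalf <- tt[which(rear >= half)[1L]]
  lo <- max(min(tt), tHalf - length / 2)
  hi <- min(max(tt), lo + length)
  c(hi - length, hi)
}

#' Build a kymograph (space x time map)
#'
#' Each column of the kymograph is the width-averaged longitudinal
#' profile of the requested species at one output time.
#'
#' @param solution a \linkS4class{SpatioTemporalSolution}.
#' @param species species name.
#' @return numeric matrix (space x time) with attributes "x" (positions,
#'   um) and "time" (s).
#' @export
buildKymograph <- function(solution, species = "rho") {
  stopifnot(is(solution, "SpatioTemporalSolution"))
  f <- solutionField(solution, species)
  col <- solution@coords$col
  cols <- sort(unique(col))
  K <- matrix(NA_real_, length(cols), length(solution@times))
  for (i in seq_along(cols)) {
    sel <- col == cols[i]
    K[i, ] <- colMeans(t(f[, sel, drop = FALSE]))
  }
  attr(K, "x") <- (cols - 0.5) * solution@domain@spacing
  attr(K, "time") <- solution@times
  K
}

#' Count oscillatory centers of GTPase activity
#'
#' An oscillatory center is a domain of the cell oscillating with a
#' common rhythm.  The function computes the per-pixel peak-to-peak
#' oscillation amplitude of active Rac1 after discarding the transient,
#' restricts to pixels above half of the global maximal amplitude, and
#' estimates each pixel's dominant period (mean inter-peak interval).
#' Pixels are clustered by period: frequency plateaus separated by a
#' relative gap larger than \code{periodGap} count as distinct centers,
#' because a single pacemaker entrains its whole wave train to one
#' frequency, whereas decoherent centers (as under ROCK inhibition) run
#' at incommensurate rhythms.  Cluster centers closer than
#' \code{minSeparation} are merged.  A stationary solution has zero
#' centers.
#'
#' @param solution a \linkS4class{SpatioTemporalSolution}.
#' @param minSeparation minimal center separation (um).
#' @param species species whose oscillation is mapped (default "rac").
#' @param transientFrac fraction of the run discarded as transient.
#' @param ampTol amplitude below which the solution counts as stationary.
#' @param periodGap relative period difference separating distinct
#'   frequency plateaus.
#' @param minPeaks minimal number of oscillation peaks required at the
#'   strongest pixel (run-length precondition).
#' @return integer count with attribute "centers" (data.frame x, y,
#'   amplitude, period).
#' @export
countOscillatoryCenters <- function(solution, minSeparation = 10,
                                    species = "rac", transientFrac = 0.5,
                                    ampTol = 0.02, periodGap = 0.02,
                                    minPeaks = 3L) {
  stopifnot(is(solution, "SpatioTemporalSolution"))
  tt <- solution@times
  keep <- tt >= min(tt) + transientFrac * diff(range(tt))
  dt <- stats::median(diff(tt))
  f <- solutionField(solution, species)[keep, , drop = FALSE]
  amp <- apply(f, 2L, function(z) diff(range(z)))
  if (max(amp) < ampTol) {
    out <- 0L
    attr(out, "centers") <- data.frame(x = numeric(0), y = numeric(0),
                                       amplitude = numeric(0),
                                       period = numeric(0))
    return(out)
  }
  strongest <- f[, which.max(amp)]
  pk0 <- which(diff(sign(diff(strongest))) == -2)
  if (length(pk0) < minPeaks) {
    stop("solution too short: only ", length(pk0), " oscillation peaks after ",
         "the transient; need >= ", minPeaks)
  }
  co <- solution@coords
  hot <- which(amp >= 0.5 * max(amp))
  per <- vapply(hot, function(k) {
    pk <- which(diff(sign(diff(f[, k]))) == -2)
    if (length(pk) < 2L) NA_real_ else mean(diff(pk)) * dt
  }, numeric(1))
  ok <- !is.na(per)
  hot <- hot[ok]; per <- per[ok]
  o <- order(per)
  hot <- hot[o]; per <- per[o]
  cl <- cumsum(c(1, diff(per) > periodGap * per[-length(per)]))
  centers <- do.call(rbind, lapply(seq_len(max(cl)), function(cc) {
    px <- hot[cl == cc]
    w <- amp[px] / sum(amp[px])
    data.frame(x = sum(co$x[px] * w), y = sum(co$y[px] * w),
               amplitude = max(amp[px]), period = mean(per[cl == cc]))
  }))
  centers <- centers[order(-centers$amplitude), , drop = FALSE]
  sel <- NULL
  for (k in seq_len(nrow(centers))) {
    if (is.null(sel) ||
        all(sqrt((centers$x[k] - sel$x)^2 + (centers$y[k] - sel$y)^2) >=
            minSeparation)) {
      sel <- rbind(sel, centers[k, ])
    }
  }
  rownames(sel) <- NULL
  out <- nrow(sel)
  attr(out, "centers") <- sel
  out
}

#' Run a PAK (or IPA-3) hysteresis ramp protocol
#'
#' Steps the control parameter down a strictly monotone ladder and back
#' up, starting each level's simulation from the previous level's final
#' state, simulating a fixed horizon per level, discarding the post-switch
#' transient, and recording the space-and-time averaged active RhoA and
#' Rac1.
#'
#' @param params base \linkS4class{KineticParams}.
#' @param control "PAKtot" (abundance scale) or "ipa3" (dose in uM).
#' @param values strictly monotone decreasing ladder of control values
#'   (the ascending branch retraces them in reverse).
#' @param spatial logical: TRUE for the 1-D reaction-diffusion protocol
#'   (default), FALSE for the cheaper well-mixed protocol.
#' @param levelTime simulated seconds per level.
#' @param transientFrac fraction of each level discarded before averaging.
#' @param profile,diffusion,inhibitors,nNodes spatial-mode settings.
#' @param localTotals numeric c(d, r): local DIA/ROCK totals for the
#'   well-mixed mode (ignored in spatial mode).
#' @param x0 initial state of the first level (well-mixed mode): a
#'   \linkS4class{NetworkState}; defaults to a low-RhoA/high-Rac state in
#'   the oscillatory basin.
#' @param ... further arguments to \code{\link{simulate1d}}.
#' @return data.frame (class "HysteresisCurve") with columns control,
#'   branch ("descending"/"ascending"), meanRho, meanRac.
#' @export
runHysteresisProtocol <- function(params = defaultKineticParams(),
                                  control = c("PAKtot", "ipa3"),
                                  values = seq(1, 0.1, by = -0.1),
                                  spatial = TRUE, levelTime = 400,
                                  transientFrac = 0.5,
                                  profile = spatialProfile(),
                                  diffusion = diffusionParams(),
                                  inhibitors = inhibitorParams(),
                                  nNodes = 100,
                                  localTotals = c(d = 1, r = 1),
                                  x0 = networkState(rho = 0.1, rac = 0.6,
                                                    pak = 0.3), ...) {
  control <- match.arg(control)
  if (any(diff(values) >= 0)) stop("'values' must be strictly decreasing")
  ladder <- c(values, rev(values))
  branch <- rep(c("descending", "ascending"), each = length(values))
  state <- NULL
  rows <- vector("list", length(ladder))
  for (k in seq_along(ladder)) {
    lev <- ladder[k]
    if (control == "PAKtot") {
      v <- params@values; v["p"] <- params@values[["p"]] * lev
      pk <- new("KineticParams", values = v)
      inh <- inhibitors
    } else {
      pk <- params
      inh <- inhibitorParams(ipa3Dose = lev, kIPAK = inhibitors@kIPAK,
                             y27632Dose = inhibitors@y27632Dose,
                             kIROCK = inhibitors@kIROCK,
                             atp = inhibitors@atp, kdATP = inhibitors@kdATP)
    }
    if (spatial) {
      sol <- tryCatch(
        simulate1d(profile, pk, diffusion, inh, x0 = state, nNodes = nNodes,
                   tMax = levelTime, ...),
        error = function(e) stop("hysteresis level ", k, " (", control, " = ",
                                 lev, ") failed: ", conditionMessage(e)))
      nt <- length(sol@times)
      keep <- sol@times >= transientFrac * levelTime
      mr <- mean(solutionField(sol, "rho")[keep, ])
      mc <- mean(solutionField(sol, "rac")[keep, ])
      S <- vapply(.STATE_KEYS, function(sp) solutionField(sol, sp)[nt, ],
                  numeric(nrow(sol@coords)))
      state <- matrix(S, ncol = 7L, dimnames = list(NULL, .STATE_KEYS))
    } else {
      xs <- if (is.null(state)) x0 else state
      tr <- tryCatch(
        simulateOde(pk, inh, x0 = xs, times = seq(0, levelTime, 1),
                    localTotals = localTotals),
        error = function(e) stop("hysteresis level ", k, " (", control, " = ",
                                 lev, ") failed: ", conditionMessage(e)))
      keep <- tr$time >= transientFrac * levelTime
      mr <- mean(tr$rho[keep]); mc <- mean(tr$rac[keep])
      last <- tr[nrow(tr), ]
      state <- networkState(rho = last$rho, dia = last$dia, rock = last$rock,
                            rac = last$rac, pak = last$pak)
    }
    rows[[k]] <- data.frame(control = lev, branch = branch[k],
                            meanRho = mr, meanRac = mc)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("HysteresisCurve", class(out))
  out
}
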