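## Steady-state enumeration, stability classification, limit-cycle
## detection and two-parameter regime scans.

## numeric Jacobian of the 5-variable reaction system (central differences)
.jacobian5 <- function(x, v, d, r, p, beta, kaScale, h = 1e-6) {
  J <- matrix(0, 5L, 5L)
  for (i in 1:5) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (.rhs5(xp, v, d, r, p, beta, kaScale) -
               .rhs5(xm, v, d, r, p, beta, kaScale)) / (2 * h)
  }
  J
}

## damped Newton iteration restricted to the admissible box
.newton5 <- function(x0, v, d, r, p, beta, kaScale, tol = 1e-11, maxit = 80L) {
  ub <- c(1, d, r, 1, p) - 1e-9
  x <- pmin(pmax(x0, 1e-9), ub)
  for (it in seq_len(maxit)) {
    f <- .rhs5(x, v, d, r, p, beta, kaScale)
    if (max(abs(f)) < tol) break
    J <- .jacobian5(x, v, d, r, p, beta, kaScale)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      x1 <- pmin(pmax(x + lam * step, 1e-9), ub)
      f1 <- .rhs5(x1, v, d, r, p, beta, kaScale)
      if (max(abs(f1)) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(x1 - x)) < 1e-15) { x <- x1; break }
    x <- x1
  }
  if (max(abs(.rhs5(x, v, d, r, p, beta, kaScale))) < 1e-9) x else NULL
}

## eigenvalue-based local stability type; near-zero real parts are
## reported as "borderline" rather than silently classified
.stabilityType <- function(ev, tol = 1e-8) {
  re <- Re(ev); im <- Im(ev)
  if (any(abs(re) <= tol)) return("borderline")
  pos <- re > tol
  if (!any(pos)) {
    lead <- which.max(re)
    return(if (abs(im[lead]) > tol) "stable focus" else "stable node")
  }
  if (any(pos & abs(im) > tol)) return("unstable focus")
  if (sum(pos) == 1L) "saddle" else "unstable node"
}

#' Enumerate steady states of the reaction network
#'
#' Multi-start damped Newton root finding on the five-dimensional
#' reaction system.  Starts are drawn from a deterministic 3-level
#' lattice over the admissible box (0.05, 0.5, 0.95 of each species
#' total, 243 starts) plus the endpoints of short integrations from four
#' corner states.  Roots are deduplicated at a state-space tolerance of
#' 1e-6; every returned root satisfies \code{max|rhs| < 1e-9}.  The
#' Jacobian is computed by central differences and eigen-decomposed to
#' classify local stability.
#'
#' @param params a \linkS4class{KineticParams}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param localTotals numeric c(d, r): local dimensionless DIA/ROCK totals.
#' @param dedupTol state-space deduplication tolerance.
#' @return a \linkS4class{SteadyStateCensus}.
#' @examples
#' \donttest{
#' findSteadyStates(defaultKineticParams())
#' }
#' @export
findSteadyStates <- function(params, inhibitors = inhibitorParams(),
                             localTotals = c(d = 1, r = 1), dedupTol = 1e-6) {
  stopifnot(is(params, "KineticParams"), is(inhibitors, "InhibitorParams"))
  v <- as.list(params@values)
  d <- unname(localTotals[1L]); r <- unname(localTotals[2L])
  p <- v$p
  beta <- rockInhibitionBeta(inhibitors)
  kaScale <- 1 + inhibitors@ipa3Dose / inhibitors@kIPAK
  lv <- c(0.05, 0.5, 0.95)
  lattice <- as.matrix(expand.grid(lv, lv, lv, lv, lv))
  lattice <- sweep(lattice, 2L, c(1, d, r, 1, p), "*")
  corners <- rbind(c(0.9, 0.05 * d, 0.05 * r, 0.05, 0.05 * p),
                   c(0.05, 0.05 * d, 0.05 * r, 0.9, 0.9 * p),
                   c(0.9, 0.9 * d, 0.9 * r, 0.05, 0.05 * p),
                   c(0.05, 0.9 * d, 0.9 * r, 0.9, 0.9 * p))
  vv <- v
  fode <- function(t, y, parms) list(.rhs5(y, vv, d, r, p, beta, kaScale))
  ends <- t(apply(corners, 1L, function(x0) {
    sol <- try(deSolve::ode(y = x0, times = c(0, 500), func = fode, parms = NULL,
                            method = "lsoda", rtol = 1e-8, atol = 1e-10),
               silent = TRUE)
    if (inherits(sol, "try-error")) x0 else sol[nrow(sol), -1L]
  }))
  starts <- rbind(lattice, ends)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- .newton5(starts[i, ], v, d, r, p, beta, kaScale)
    if (is.null(x)) next
    if (!any(vapply(roots, function(rt) max(abs(rt - x)) < dedupTol, logical(1)))) {
      roots[[length(roots) + 1L]] <- x
    }
  }
  if (!length(roots)) {
    stop("no steady state found from any start; the parameter point is ",
         "outside the admissible range of the solver")
  }
  states <- do.call(rbind, roots)
  colnames(states) <- .ODE_KEYS
  evs <- vector("list", nrow(states))
  typ <- character(nrow(states))
  res <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    J <- .jacobian5(states[i, ], v, d, r, p, beta, kaScale)
    evs[[i]] <- eigen(J, only.values = TRUE)$values
    typ[i] <- .stabilityType(evs[[i]])
    res[i] <- max(abs(.rhs5(states[i, ], v, d, r, p, beta, kaScale)))
  }
  ord <- order(-states[, "rho"])
  new("SteadyStateCensus", states = states[ord, , drop = FALSE],
      eigenvalues = evs[ord], type = typ[ord], residual = res[ord])
}

#' Detect a stable limit cycle by long integration
#'
#' Integrates the well-mixed system from perturbations around every
#' unstable focus of the census and from high-Rho/low-Rac and
#' low-Rho/high-Rac corner states, discards the transient, and declares an
#' oscillation when at least five successive rho peaks have peak-to-peak
#' amplitude above 1 percent of the total and the inter-peak intervals
#' have a coefficient of variation below 5 percent.
#'
#' @param params a \linkS4class{KineticParams}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param localTotals numeric c(d, r).
#' @param census optionally a precomputed \linkS4class{SteadyStateCensus}.
#' @param tMax integration horizon (s); the first \code{transientFrac} of
#'   each trajectory is discarded.
#' @param transientFrac fraction of the trajectory discarded as transient.
#' @param ampTol minimal peak-to-peak rho amplitude (fraction of total).
#' @param cvTol maximal coefficient of variation of the period.
#' @return list with elements \code{exists}, \code{period} (s), and
#'   \code{amplitude} (named per-species peak-to-peak amplitudes), plus
#'   \code{trajectory} (the data.frame of the detecting run) when a cycle
#'   is found.
#' @export
detectLimitCycle <- function(params, inhibitors = inhibitorParams(),
                             localTotals = c(d = 1, r = 1), census = NULL,
                             tMax = 20000, transientFrac = 0.5,
                             ampTol = 0.01, cvTol = 0.05) {
  stopifnot(is(params, "KineticParams"))
  d <- unname(localTotals[1L]); r <- unname(localTotals[2L])
  p <- params@values[["p"]]
  if (is.null(census)) census <- findSteadyStates(params, inhibitors, localTotals)
  starts <- list(c(0.9, 0.05 * d, 0.05 * r, 0.05, 0.05 * p),
                 c(0.05, 0.05 * d, 0.05 * r, 0.9, 0.9 * p))
  for (i in seq_len(nrow(census@states))) {
    if (census@type[i] == "unstable focus") {
      x <- census@states[i, ] * 1.01 + 0.002
      starts[[length(starts) + 1L]] <- pmin(pmax(x, 1e-6), c(1, d, r, 1, p) - 1e-6)
    }
  }
  for (x0 in starts) {
    st <- networkState(rho = x0[1L], dia = x0[2L], rock = x0[3L],
                       rac = x0[4L], pak = x0[5L])
    tr <- tryCatch(
      simulateOde(params, inhibitors, st, times = seq(0, tMax, 2),
                  localTotals = localTotals),
      error = function(e) stop("limit-cycle integration failed from state (",
                               paste(signif(x0, 3), collapse = ", "), "): ",
                               conditionMessage(e)))
    keep <- tr$time >= transientFrac * tMax
    rho <- tr$rho[keep]; tt <- tr$time[keep]
    pk <- which(diff(sign(diff(rho))) == -2) + 1L
    if (length(pk) < 5L) next
    amp <- max(rho) - min(rho)
    if (amp <= ampTol) next
    per <- diff(tt[pk])
    if (sd(per) / mean(per) >= cvTol) next
    amps <- vapply(.ODE_KEYS,
                   function(k) diff(range(tr[[k]][keep])), numeric(1))
    return(list(exists = TRUE, period = mean(per), amplitude = amps,
                trajectory = tr))
  }
  list(exists = FALSE, period = NA_real_,
       amplitude = setNames(rep(NA_real_, 5L), .ODE_KEYS))
}

#' Classify the dynamic regime from a census and cycle flag
#'
#' Deterministic mapping from the steady-state census pattern and
#' limit-cycle existence to the regime taxonomy 0-8:
#' 0 single stable focus, no cycle; 1 single unstable focus with cycle;
#' 2 unstable focus + saddle + stable node, no cycle (excitable);
#' 3 the same census with a cycle (BiDR); 4 stable focus + saddle +
#' stable node; 5 stable node + unstable focus + saddle; 6 single stable
#' node; 7 two stable nodes + two saddles + unstable focus; 8 two stable
#' nodes + saddle.  A census matching none of these returns NA with a
#' diagnostic attribute rather than a silent guess.
#'
#' @param census a \linkS4class{SteadyStateCensus}.
#' @param limitCycle logical: does a stable limit cycle exist?
#' @return integer regime label 0-8, or NA (attribute "diagnostic") when
#'   unclassified.
#' @export
classifyRegime <- function(census, limitCycle) {
  stopifnot(is(census, "SteadyStateCensus"), nrow(census@states) > 0L)
  ty <- sort(census@type)
  if (any(ty == "borderline")) {
    out <- NA_integer_
    attr(out, "diagnostic") <- "borderline eigenvalues in census"
    return(out)
  }
  sig <- paste(ty, collapse = "|")
  n <- length(ty)
  sf <- sum(ty == "stable focus"); sn <- sum(ty == "stable node")
  uf <- sum(ty == "unstable focus"); sdl <- sum(ty == "saddle")
  lab <- NA_integer_
  if (n == 1L && sf == 1L && !limitCycle) lab <- 0L
  else if (n == 1L && uf == 1L && limitCycle) lab <- 1L
  else if (n == 3L && uf == 1L && sdl == 1L && sn == 1L && limitCycle) lab <- 3L
  else if (n == 3L && uf == 1L && sdl == 1L && sn == 1L) {
    ## regimes 2 and 5 share this census; they differ in the attractor:
    ## high-RhoA/low-Rac node (excitable, 2) vs high-Rac node (5)
    st <- census@states[census@type == "stable node", , drop = FALSE]
    lab <- if (st[1L, "rac"] > 0.5) 5L else 2L
  } else if (n == 3L && sf == 1L && sdl == 1L && sn == 1L && !limitCycle) lab <- 4L
  else if (n == 3L && sf == 1L && sdl == 1L && uf == 1L && !limitCycle) {
    ## single stable state accompanied by an unstable focus / saddle pair;
    ## high-Rac focus shares the regime-5 phenomenology, low-Rac regime 0
    st <- census@states[census@type == "stable focus", , drop = FALSE]
    lab <- if (st[1L, "rac"] > 0.5) 5L else 0L
  } else if (n == 1L && sn == 1L && !limitCycle) lab <- 6L
  else if (n == 5L && sn == 2L && sdl == 2L && uf == 1L && !limitCycle) lab <- 7L
  else if (n == 3L && sn == 2L && sdl == 1L && !limitCycle) lab <- 8L
  else if (n == 3L && sn == 1L && sf == 1L && sdl == 1L && !limitCycle) lab <- 4L
  else if (n == 3L && sn == 1L && uf == 1L && sdl == 1L && limitCycle) lab <- 3L
  if (is.na(lab)) attr(lab, "diagnostic") <- paste("unclassified census:", sig,
                                                   "cycle =", limitCycle)
  lab
}

## census + cycle + label at one (d, r) point; shared by scan and trace
.regimePoint <- function(params, inhibitors, d, r, cycleTMax = 20000) {
  cen <- findSteadyStates(params, inhibitors, c(d = d, r = r))
  needCycle <- any(cen@type == "unstable focus")
  cyc <- if (needCycle) {
    detectLimitCycle(params, inhibitors, c(d = d, r = r), census = cen,
                     tMax = cycleTMax)
  } else list(exists = FALSE, period = NA_real_)
  list(census = cen, cycle = cyc$exists, period = cyc$period,
       label = classifyRegime(cen, cyc$exists))
}

#' Scan a two-abundance plane into a regime map
#'
#' Computes the steady-state census, limit-cycle flag and regime label on
#' a grid over two abundance axes (chosen among DIAtot, ROCKtot and
#' PAKtot scalings, normalized to unperturbed = 1).  A contiguity
#' post-pass marks isolated single-point regimes as suspect (attribute
#' \code{"suspect"}).  Per-point failures are recorded as NA labels and
#' the scan continues.
#'
#' @param params base \linkS4class{KineticParams}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param axis1,axis2 axis names: "DIAtot", "ROCKtot" or "PAKtot".
#' @param range1,range2 numeric c(min, max) scan ranges (scale factors).
#' @param resolution points per axis (scalar or length 2).
#' @param cycleTMax integration horizon for cycle detection (s).
#' @return a \linkS4class{RegimeMap}.
#' @export
scanBifurcationPlane <- function(params, inhibitors = inhibitorParams(),
                                 axis1 = "DIAtot", axis2 = "ROCKtot",
                                 range1 = c(0.1, 3), range2 = c(0.1, 3),
                                 resolution = 41, cycleTMax = 20000) {
  axes <- c("DIAtot", "ROCKtot", "PAKtot")
  if (!axis1 %in% axes || !axis2 %in% axes || axis1 == axis2) {
    stop("axes must be two distinct names among ", paste(axes, collapse = ", "))
  }
  resolution <- rep_len(resolution, 2L)
  g1 <- seq(range1[1L], range1[2L], length.out = resolution[1L])
  g2 <- seq(range2[1L], range2[2L], length.out = resolution[2L])
  lab <- matrix(NA_integer_, length(g1), length(g2))
  nSt <- matrix(NA_integer_, length(g1), length(g2))
  nStab <- matrix(NA_integer_, length(g1), length(g2))
  cyc <- matrix(FALSE, length(g1), length(g2))
  cens <- vector("list", length(g1))
  for (i in seq_along(g1)) {
    cens[[i]] <- vector("list", length(g2))
    for (j in seq_along(g2)) {
      pt <- .scalePoint(params, setNames(c(g1[i], g2[j]), c(axis1, axis2)))
      res <- tryCatch(.regimePoint(pt$params, inhibitors, pt$d, pt$r, cycleTMax),
                      error = function(e) NULL)
      if (is.null(res)) next
      lab[i, j] <- res$label
      nSt[i, j] <- nrow(res$census@states)
      nStab[i, j] <- sum(grepl("^stable", res$census@type))
      cyc[i, j] <- res$cycle
      cens[[i]][[j]] <- res$census
    }
  }
  map <- new("RegimeMap", axis1 = axis1, axis2 = axis2, grid1 = g1, grid2 = g2,
             labels = lab, nStates = nSt, nStable = nStab, limitCycle = cyc,
             census = cens)
  attr(map, "suspect") <- .isolatedPoints(lab)
  map
}

## translate axis scale factors into (d, r) totals and/or a scaled p
.scalePoint <- function(params, scales) {
  d <- 1; r <- 1
  pars <- params
  for (nm in names(scales)) {
    if (nm == "DIAtot") d <- scales[[nm]]
    else if (nm == "ROCKtot") r <- scales[[nm]]
    else if (nm == "PAKtot") {
      v <- pars@values
      v["p"] <- params@values[["p"]] * scales[[nm]]
      pars <- new("KineticParams", values = v)
    }
  }
  list(params = pars, d = d, r = r)
}

## flag grid points whose label differs from all 4-neighbours
.isolatedPoints <- function(lab) {
  n1 <- nrow(lab); n2 <- ncol(lab)
  out <- NULL
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (is.na(lab[i, j])) next
    nb <- c(if (i > 1) lab[i - 1, j], if (i < n1) lab[i + 1, j],
            if (j > 1) lab[i, j - 1], if (j < n2) lab[i, j + 1])
    nb <- nb[!is.na(nb)]
    if (length(nb) && !any(nb == lab[i, j])) out <- rbind(out, c(i, j))
  }
  out
}

#' Trace a one-parameter branch diagram
#'
#' Census and cycle envelope of rho and rac along a 1-D ray in parameter
#' space; bifurcation points are bracketed where the census pattern or
#' cycle existence changes between neighbouring points.
#'
#' @param params base \linkS4class{KineticParams}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param axis "DIAtot", "ROCKtot" or "PAKtot".
#' @param range numeric c(min, max) scale range.
#' @param resolution number of points along the ray.
#' @param fixed named scale factors for the non-scanned abundances.
#' @param cycleTMax cycle-detection horizon (s).
#' @return data.frame with one row per (point, steady state): columns
#'   value, stateIndex, type, rho, rac, cycle, cycleMinRho, cycleMaxRho,
#'   cycleMinRac, cycleMaxRac, label; attribute "bifurcations" holds the
#'   bracketing intervals.
#' @export
traceBranch <- function(params, inhibitors = inhibitorParams(),
                        axis = "PAKtot", range = c(0.1, 1), resolution = 21,
                        fixed = c(DIAtot = 1, ROCKtot = 1),
                        cycleTMax = 20000) {
  vals <- seq(range[1L], range[2L], length.out = resolution)
  rows <- list()
  sig <- character(resolution)
  cycv <- logical(resolution)
  for (k in seq_along(vals)) {
    pt <- .scalePoint(params, c(setNames(vals[k], axis), fixed[setdiff(names(fixed), axis)]))
    res <- tryCatch(.regimePoint(pt$params, inhibitors, pt$d, pt$r, cycleTMax),
                    error = function(e) NULL)
    if (is.null(res)) { sig[k] <- "error"; next }
    sig[k] <- paste(sort(res$census@type), collapse = "|")
    cycv[k] <- res$cycle
    env <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    if (res$cycle) {
      cy <- detectLimitCycle(pt$params, inhibitors, c(d = pt$d, r = pt$r),
                             census = res$census, tMax = cycleTMax)
      if (cy$exists) {
        tr <- cy$trajectory
        keep <- tr$time >= 0.5 * max(tr$time)
        env <- c(min(tr$rho[keep]), max(tr$rho[keep]),
                 min(tr$rac[keep]), max(tr$rac[keep]))
      }
    }
    for (i in seq_len(nrow(res$census@states))) {
      rows[[length(rows) + 1L]] <- data.frame(
        value = vals[k], stateIndex = i, type = res$census@type[i],
        rho = res$census@states[i, "rho"], rac = res$census@states[i, "rac"],
        cycle = res$cycle, cycleMinRho = env[1L], cycleMaxRho = env[2L],
        cycleMinRac = env[3L], cycleMaxRac = env[4L],
        label = as.integer(res$label))
    }
  }
  out <- do.call(rbind, rows)
  bif <- NULL
  for (k in seq_len(resolution - 1L)) {
    if (sig[k] != sig[k + 1L] || cycv[k] != cycv[k + 1L]) {
      bif <- rbind(bif, c(vals[k], vals[k + 1L]))
    }
  }
  attr(out, "bifurcations") <- bif
  out
}
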