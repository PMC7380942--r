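## Core dimensionless kinetics of the RhoA-Rac1-DIA-ROCK-PAK network.
##
## The canonical variables are the dimensionless fractions of Eq.-(12)-style
## nondimensionalization: rho = [Rho-GTP]/Rhotot, dia = [DIA*]/DIAtot, etc.
## Every activation/deactivation flux is Michaelis-Menten in the substrate
## fraction, multiplied by hyperbolic regulatory modifiers.

## saturating flux u/(1+u)
.phi <- function(u) u / (1 + u)

#' Hyperbolic regulatory modifier
#'
#' The dimensionless multiplier \eqn{\alpha_{YX} = (1 + \gamma a/K)/(1 + a/K)}
#' by which the active form of protein Y at level \code{active} modifies a
#' rate acting on protein X.  \code{gamma > 1} encodes activation,
#' \code{gamma < 1} inhibition, and \code{gamma = 1} the absence of a
#' regulatory interaction.  The value is bounded between
#' \code{min(1, gamma)} and \code{max(1, gamma)} and is monotone in
#' \code{active}.
#'
#' @param active active-protein level (dimensionless, >= 0); vectorized.
#' @param gamma modifier strength (> 0).
#' @param k modifier half-saturation constant (> 0).
#' @return numeric vector of modifier values.
#' @examples
#' modifierAlpha(1, gamma = 2, k = 1)   # 1.5
#' modifierAlpha(0, gamma = 5, k = 0.3) # 1: no modifier without active protein
#' @export
modifierAlpha <- function(active, gamma, k) {
  if (!all(is.finite(active)) || any(active < 0)) {
    stop("'active' must be finite and non-negative")
  }
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be positive")
  if (!is.finite(k) || k <= 0) stop("'k' must be positive")
  u <- active / k
  (1 + gamma * u) / (1 + u)
}

#' ROCK inhibition multiplier for Y-27632
#'
#' Y-27632 competes with ATP for the active ROCK conformation; the kinase
#' activity is scaled by
#' \eqn{\beta = (1 + [ATP]/K_d) / (1 + [ATP]/K_d + [Y]/K_I) \le 1}.
#' \code{beta} multiplies the active ROCK level inside the ROCK-to-Rac
#' modifier.
#'
#' @param inhibitors an \linkS4class{InhibitorParams} object.
#' @return the dimensionless factor beta in (0, 1].
#' @examples
#' rockInhibitionBeta(inhibitorParams())                  # 1 at zero dose
#' rockInhibitionBeta(inhibitorParams(y27632Dose = 2.5))  # < 1
#' @export
rockInhibitionBeta <- function(inhibitors) {
  stopifnot(is(inhibitors, "InhibitorParams"))
  a <- inhibitors@atp / inhibitors@kdATP
  (1 + a) / (1 + a + inhibitors@y27632Dose / inhibitors@kIROCK)
}

#' Apply the IPA-3 transform to the kinetic parameters
#'
#' IPA-3 binds the inactive PAK conformation and blocks activation; under
#' rapid equilibrium this scales the PAK activation constant:
#' \code{kaPAK -> kaPAK * (1 + dose/K_I)}.  All other parameters are
#' unchanged.
#'
#' @param params a \linkS4class{KineticParams} object.
#' @param inhibitors an \linkS4class{InhibitorParams} object.
#' @return a \linkS4class{KineticParams} with the scaled kaPAK.
#' @export
applyPakInhibitor <- function(params, inhibitors) {
  stopifnot(is(params, "KineticParams"), is(inhibitors, "InhibitorParams"))
  v <- params@values
  v["kaPAK"] <- v["kaPAK"] * (1 + inhibitors@ipa3Dose / inhibitors@kIPAK)
  new("KineticParams", values = v)
}

## internal 5-variable reaction right-hand side on plain numerics.
## x = c(rho, dia, rock, rac, pak); d, r = local dimensionless DIA/ROCK
## totals; p = dimensionless total PAK; kaPakScale = 1 + [IPA-3]/K_I.
.rhs5 <- function(x, v, d, r, p, beta = 1, kaPakScale = 1) {
  rho <- x[1L]; dia <- x[2L]; rock <- x[3L]; rac <- x[4L]; pak <- x[5L]
  aDIARho  <- (1 + v[["gammaDIARho"]]  * dia  / v[["kDIARho"]])  / (1 + dia  / v[["kDIARho"]])
  aPAKRho  <- (1 + v[["gammaPAKRho"]]  * pak  / v[["kPAKRho"]])  / (1 + pak  / v[["kPAKRho"]])
  aRhoDIA  <- (1 + v[["gammaRhoDIA"]]  * rho  / v[["kRhoDIA"]])  / (1 + rho  / v[["kRhoDIA"]])
  aRhoROCK <- (1 + v[["gammaRhoROCK"]] * rho  / v[["kRhoROCK"]]) / (1 + rho  / v[["kRhoROCK"]])
  aDIARac  <- (1 + v[["gammaDIARac"]]  * dia  / v[["kDIARac"]])  / (1 + dia  / v[["kDIARac"]])
  aPAKRac  <- (1 + v[["gammaPAKRac"]]  * pak  / v[["kPAKRac"]])  / (1 + pak  / v[["kPAKRac"]])
  brock <- beta * rock
  aROCKRac <- (1 + v[["gammaROCKRac"]] * brock / v[["kROCKRac"]]) / (1 + brock / v[["kROCKRac"]])
  aRacPAK  <- (1 + v[["gammaRacPAK"]]  * rac  / v[["kRacPAK"]])  / (1 + rac  / v[["kRacPAK"]])
  kaPAK <- v[["kaPAK"]] * kaPakScale
  c(v[["vGEFRho"]] * aDIARho * aPAKRho * .phi((1 - rho) / v[["kGEFRho"]]) -
      v[["vGAPRho"]] * .phi(rho / v[["kGAPRho"]]),
    v[["vaDIA"]] * aRhoDIA * .phi((d - dia) / v[["kaDIA"]]) -
      v[["viDIA"]] * .phi(dia / v[["kiDIA"]]),
    v[["vaROCK"]] * aRhoROCK * .phi((r - rock) / v[["kaROCK"]]) -
      v[["viROCK"]] * .phi(rock / v[["kiROCK"]]),
    v[["vGEFRac"]] * aDIARac * aPAKRac * .phi((1 - rac) / v[["kGEFRac"]]) -
      v[["vGAPRac"]] * aROCKRac * .phi(rac / v[["kGAPRac"]]),
    v[["vaPAK"]] * aRacPAK * .phi((p - pak) / kaPAK) -
      v[["viPAK"]] * .phi(pak / v[["kiPAK"]]))
}

#' Reaction right-hand side of the network
#'
#' Time derivatives of all seven dimensionless species fractions at a
#' well-mixed point.  Conservation holds by construction:
#' \code{d(rho)/dt + d(rhod)/dt = 0} and likewise for Rac1.  ROCK
#' inhibition (Y-27632) enters only through the beta multiplier on the
#' ROCK-to-Rac branch; IPA-3 enters only through the scaled PAK activation
#' constant.
#'
#' @param state a \linkS4class{NetworkState} or named numeric vector with
#'   fields rho, rhod, dia, rock, rac, racd, pak.
#' @param params a \linkS4class{KineticParams}.
#' @param localTotals optional numeric c(d, r): local dimensionless DIA
#'   and ROCK totals (defaults to 1, 1, i.e. unperturbed abundances).
#' @param inhibitors an \linkS4class{InhibitorParams}; defaults to no
#'   inhibitor.
#' @return named numeric vector of time derivatives (1/s) for all seven
#'   fields.
#' @export
odeRhs <- function(state, params, localTotals = c(d = 1, r = 1),
                   inhibitors = inhibitorParams()) {
  stopifnot(is(params, "KineticParams"))
  s <- if (is(state, "NetworkState")) state@values else state
  if (!all(.STATE_KEYS %in% names(s))) {
    stop("state must contain fields: ", paste(.STATE_KEYS, collapse = ", "))
  }
  d <- unname(localTotals[1L]); r <- unname(localTotals[2L])
  v <- params@values
  p <- v[["p"]]
  .checkStateBounds(s, d, r, p)
  f <- .rhs5(s[.ODE_KEYS], v, d, r, p,
             beta = rockInhibitionBeta(inhibitors),
             kaPakScale = 1 + inhibitors@ipa3Dose / inhibitors@kIPAK)
  out <- c(f[1L], -f[1L], f[2L], f[3L], f[4L], -f[4L], f[5L])
  names(out) <- c("rho", "rhod", "dia", "rock", "rac", "racd", "pak")
  out
}

.checkStateBounds <- function(s, d, r, p, tol = 1e-9) {
  if (any(!is.finite(s))) stop("state must be finite")
  if (any(s < -tol)) stop("state fractions must be non-negative")
  if (s[["rho"]] > 1 + tol || s[["rac"]] > 1 + tol) {
    stop("rho and rac are fractions of the GTPase totals and must be <= 1")
  }
  if (s[["dia"]] > d + tol) stop("dia exceeds the local DIA total")
  if (s[["rock"]] > r + tol) stop("rock exceeds the local ROCK total")
  if (s[["pak"]] > p + tol) stop("pak exceeds the dimensionless PAK total")
  invisible(TRUE)
}

#' Integrate the well-mixed network
#'
#' Adaptive fifth-order Cash-Karp embedded Runge-Kutta integration (via
#' \pkg{deSolve}) of the five-variable reaction system, reported on a user
#' output grid.  The inactive GTPase fractions follow from conservation.
#'
#' @param params a \linkS4class{KineticParams}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param x0 initial \linkS4class{NetworkState} (or named vector).
#' @param times output time grid (s), or scalar end time (then 1-s grid).
#' @param localTotals numeric c(d, r) local DIA/ROCK totals.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return data.frame with columns time and the seven species fractions.
#' @examples
#' tr <- simulateOde(defaultKineticParams(), x0 = networkState(),
#'                   times = seq(0, 100, 1))
#' head(tr)
#' @export
simulateOde <- function(params, inhibitors = inhibitorParams(),
                        x0 = networkState(), times = seq(0, 1000, 1),
                        localTotals = c(d = 1, r = 1),
                        rtol = 1e-7, atol = 1e-9) {
  stopifnot(is(params, "KineticParams"), is(inhibitors, "InhibitorParams"))
  s <- if (is(x0, "NetworkState")) x0@values else x0
  if (length(times) == 1L) times <- seq(0, times, by = 1)
  d <- unname(localTotals[1L]); r <- unname(localTotals[2L])
  v <- params@values
  p <- v[["p"]]
  .checkStateBounds(s, d, r, p)
  beta <- rockInhibitionBeta(inhibitors)
  kaScale <- 1 + inhibitors@ipa3Dose / inhibitors@kIPAK
  vv <- as.list(v)
  f <- function(t, y, parms) list(.rhs5(y, vv, d, r, p, beta, kaScale))
  sol <- deSolve::ode(y = unname(s[.ODE_KEYS]), times = times, func = f,
                      parms = NULL, method = deSolve::rkMethod("rk45ck"),
                      rtol = rtol, atol = atol, hmax = diff(range(times)) / 10)
  if (attr(sol, "istate")[1L] < 0) {
    stop("integration failed near t = ", max(sol[, 1L]), " s")
  }
  out <- data.frame(time = sol[, 1L], rho = sol[, 2L], rhod = 1 - sol[, 2L],
                    dia = sol[, 3L], rock = sol[, 4L], rac = sol[, 5L],
                    racd = 1 - sol[, 5L], pak = sol[, 6L])
  out
}

#' Effector-complex concentration under rapid equilibrium
#'
#' Concentration of the complex between active RhoA and an effector
#' (DIA or ROCK) whose total abundance is far below the RhoA abundance.
#' The linear variant neglects sequestration of RhoA-GTP into the complex,
#' \code{complex = effectorTotal * rhoGtp / (kd + rhoGtp)}; the exact
#' variant solves the rapid-equilibrium binding quadratic without that
#' approximation.
#'
#' @param effectorTotal total effector abundance (concentration units).
#' @param rhoGtp active RhoA concentration.
#' @param kd dissociation constant of the complex.
#' @param variant "linear" or "exact".
#' @return complex concentration (same units).
#' @export
effectorComplexFraction <- function(effectorTotal, rhoGtp, kd,
                                    variant = c("linear", "exact")) {
  variant <- match.arg(variant)
  vals <- c(effectorTotal, rhoGtp, kd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("inputs must be finite and non-negative")
  }
  if (variant == "linear") {
    if (kd + rhoGtp == 0) return(0)
    return(effectorTotal * rhoGtp / (kd + rhoGtp))
  }
  ## exact: complex c solves c^2 - (E + R + kd) c + E R = 0, c <= min(E, R)
  b <- effectorTotal + rhoGtp + kd
  disc <- b^2 - 4 * effectorTotal * rhoGtp
  c0 <- (b - sqrt(max(disc, 0))) / 2
  min(c0, effectorTotal, rhoGtp)
}
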