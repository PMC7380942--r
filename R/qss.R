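## Quasi-steady-state reduction to the (rho, rac) plane: effector
## balances solved per point, reduced right-hand side, nullclines and
## phase portraits.

## scalar effector balance: va*alpha(act)*phi((tot-e)/ka) = vi*phi(e/ki),
## solved on [0, tot] by bracketed root finding (monotone in e)
.effectorBalance <- function(act, va, ka, vi, ki, gamma, k, tot, tol = 1e-10) {
  A <- va * modifierAlpha(act, gamma, k)
  f <- function(e) A * .phi((tot - e) / ka) - vi * .phi(e / ki)
  if (f(0) <= 0) return(0)
  if (f(tot) >= 0) return(tot)
  uniroot(f, c(0, tot), tol = tol)$root
}

#' Solve the effector quasi-steady-state balances
#'
#' For given active RhoA and Rac1 fractions, solves the three scalar
#' activation/deactivation balances of DIA, ROCK and PAK to 1e-10 by
#' bracketed root finding on [0, total].  Under the implemented kinetics
#' the DIA and ROCK balances depend only on rho and the PAK balance only
#' on rac; both arguments are kept for interface generality and the
#' independence is asserted in the test suite rather than assumed.
#'
#' @param rho,rac active GTPase fractions in [0, 1].
#' @param params a \linkS4class{KineticParams}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param localTotals numeric c(d, r).
#' @return named numeric c(dia, rock, pak).
#' @export
solveEffectorQss <- function(rho, rac, params, inhibitors = inhibitorParams(),
                             localTotals = c(d = 1, r = 1)) {
  stopifnot(is(params, "KineticParams"))
  if (!is.finite(rho) || !is.finite(rac) || rho < 0 || rho > 1 || rac < 0 || rac > 1) {
    stop("rho and rac must lie in [0, 1]")
  }
  v <- params@values
  d <- unname(localTotals[1L]); r <- unname(localTotals[2L])
  kaScale <- 1 + inhibitors@ipa3Dose / inhibitors@kIPAK
  c(dia = .effectorBalance(rho, v[["vaDIA"]], v[["kaDIA"]], v[["viDIA"]],
                           v[["kiDIA"]], v[["gammaRhoDIA"]], v[["kRhoDIA"]], d),
    rock = .effectorBalance(rho, v[["vaROCK"]], v[["kaROCK"]], v[["viROCK"]],
                            v[["kiROCK"]], v[["gammaRhoROCK"]], v[["kRhoROCK"]], r),
    pak = .effectorBalance(rac, v[["vaPAK"]], v[["kaPAK"]] * kaScale,
                           v[["viPAK"]], v[["kiPAK"]], v[["gammaRacPAK"]],
                           v[["kRacPAK"]], v[["p"]]))
}

#' Reduced two-variable right-hand side
#'
#' Time derivatives of rho and rac with DIA, ROCK and PAK at their
#' quasi-steady-state levels (Tikhonov reduction: the effectors are an
#' order of magnitude less abundant and equilibrate fast).
#'
#' @inheritParams solveEffectorQss
#' @return named numeric c(drho, drac) (1/s).
#' @export
reducedRhs <- function(rho, rac, params, inhibitors = inhibitorParams(),
                       localTotals = c(d = 1, r = 1)) {
  eff <- solveEffectorQss(rho, rac, params, inhibitors, localTotals)
  v <- as.list(params@values)
  beta <- rockInhibitionBeta(inhibitors)
  kaScale <- 1 + inhibitors@ipa3Dose / inhibitors@kIPAK
  f <- .rhs5(c(rho, eff[["dia"]], eff[["rock"]], rac, eff[["pak"]]),
             v, unname(localTotals[1L]), unname(localTotals[2L]), v$p,
             beta, kaScale)
  c(drho = f[1L], drac = f[4L])
}

#' Compute a phase portrait of the reduced system
#'
#' Nullclines are extracted as zero contours of the reduced derivatives
#' on a regular grid over [0, 1]^2 (marching-squares via
#' \code{grDevices::contourLines}); intersections are refined by 2-D
#' Newton iteration on the reduced system and tagged with the stability
#' type of the corresponding full-system steady state.  When the full
#' system has a limit cycle, its (rho, rac) projection is attached.
#'
#' @inheritParams solveEffectorQss
#' @param gridResolution grid points per axis (default 201).
#' @param cycleProjection logical: also detect and project the
#'   five-dimensional limit cycle (slower).
#' @return list with components \code{rhoNullcline}, \code{racNullcline}
#'   (lists of data.frames with x = rho, y = rac), \code{vectorField}
#'   (data.frame rho, rac, drho, drac on a coarse grid),
#'   \code{intersections} (data.frame rho, rac, type), and optionally
#'   \code{cycleProjection} (data.frame rho, rac).
#' @export
computePhasePortrait <- function(params, inhibitors = inhibitorParams(),
                                 localTotals = c(d = 1, r = 1),
                                 gridResolution = 201,
                                 cycleProjection = FALSE) {
  g <- seq(0, 1, length.out = gridResolution)
  v <- as.list(params@values)
  d <- unname(localTotals[1L]); r <- unname(localTotals[2L])
  beta <- rockInhibitionBeta(inhibitors)
  kaScale <- 1 + inhibitors@ipa3Dose / inhibitors@kIPAK
  ## effector QSS levels depend on one GTPase each: tabulate once per axis
  diaTab <- vapply(g, function(x) .effectorBalance(x, v$vaDIA, v$kaDIA, v$viDIA,
                                                   v$kiDIA, v$gammaRhoDIA,
                                                   v$kRhoDIA, d), numeric(1))
  rockTab <- vapply(g, function(x) .effectorBalance(x, v$vaROCK, v$kaROCK, v$viROCK,
                                                    v$kiROCK, v$gammaRhoROCK,
                                                    v$kRhoROCK, r), numeric(1))
  pakTab <- vapply(g, function(x) .effectorBalance(x, v$vaPAK, v$kaPAK * kaScale,
                                                   v$viPAK, v$kiPAK, v$gammaRacPAK,
                                                   v$kRacPAK, v$p), numeric(1))
  DR <- matrix(0, gridResolution, gridResolution)
  DC <- matrix(0, gridResolution, gridResolution)
  for (j in seq_along(g)) {
    rac <- g[j]; pak <- pakTab[j]
    f <- vapply(seq_along(g), function(i) {
      .rhs5(c(g[i], diaTab[i], rockTab[i], rac, pak), v, d, r, v$p,
            beta, kaScale)[c(1L, 4L)]
    }, numeric(2))
    DR[, j] <- f[1L, ]
    DC[, j] <- f[2L, ]
  }
  if (all(DR > 0) || all(DR < 0) || all(DC > 0) || all(DC < 0)) {
    stop("degenerate grid: a reduced derivative does not change sign")
  }
  toDf <- function(cl) lapply(cl, function(s) data.frame(rho = s$x, rac = s$y))
  rhoN <- toDf(grDevices::contourLines(g, g, DR, levels = 0))
  racN <- toDf(grDevices::contourLines(g, g, DC, levels = 0))
  ## coarse vector field
  cg <- g[seq(1L, gridResolution, length.out = 21L)]
  vf <- expand.grid(rho = cg, rac = cg)
  dv <- t(vapply(seq_len(nrow(vf)), function(k) {
    reducedRhs(vf$rho[k], vf$rac[k], params, inhibitors, localTotals)
  }, numeric(2)))
  vf$drho <- dv[, 1L]; vf$drac <- dv[, 2L]
  ## intersections: seed 2-D Newton from sign-change cells of both fields
  seeds <- which(.signChangeCells(DR) & .signChangeCells(DC), arr.ind = TRUE)
  fixed <- NULL
  for (k in seq_len(nrow(seeds))) {
    x <- c(g[seeds[k, 1L]], g[seeds[k, 2L]])
    root <- .newton2(x, params, inhibitors, localTotals)
    if (is.null(root)) next
    if (is.null(fixed) ||
        !any(sqrt(rowSums(sweep(fixed, 2L, root)^2)) < 1e-4)) {
      fixed <- rbind(fixed, root)
    }
  }
  inter <- NULL
  if (!is.null(fixed)) {
    full <- findSteadyStates(params, inhibitors, localTotals)
    type <- vapply(seq_len(nrow(fixed)), function(i) {
      dd <- sqrt((full@states[, "rho"] - fixed[i, 1L])^2 +
                 (full@states[, "rac"] - fixed[i, 2L])^2)
      full@type[which.min(dd)]
    }, character(1))
    inter <- data.frame(rho = fixed[, 1L], rac = fixed[, 2L], type = type)
  }
  out <- list(rhoNullcline = rhoN, racNullcline = racN, vectorField = vf,
              intersections = inter)
  if (cycleProjection) {
    cy <- detectLimitCycle(params, inhibitors, localTotals)
    if (cy$exists) {
      tr <- cy$trajectory
      keep <- tr$time >= 0.5 * max(tr$time)
      out$cycleProjection <- data.frame(rho = tr$rho[keep], rac = tr$rac[keep])
    }
  }
  out
}

## cells of a grid field where any corner pair changes sign
.signChangeCells <- function(F) {
  n1 <- nrow(F); n2 <- ncol(F)
  s <- sign(F)
  ch <- matrix(FALSE, n1, n2)
  ch[-n1, -n2] <- (s[-n1, -n2] != s[-1, -n2]) | (s[-n1, -n2] != s[-n1, -1]) |
    (s[-n1, -n2] != s[-1, -1])
  ch
}

## damped 2-D Newton on the reduced system
.newton2 <- function(x0, params, inhibitors, localTotals, tol = 1e-11,
                     maxit = 60L) {
  x <- pmin(pmax(x0, 1e-9), 1 - 1e-9)
  for (it in seq_len(maxit)) {
    f <- reducedRhs(x[1L], x[2L], params, inhibitors, localTotals)
    if (max(abs(f)) < tol) return(x)
    h <- 1e-6
    J <- matrix(0, 2L, 2L)
    for (i in 1:2) {
      xp <- x; xp[i] <- min(x[i] + h, 1)
      xm <- x; xm[i] <- max(x[i] - h, 0)
      J[, i] <- (reducedRhs(xp[1L], xp[2L], params, inhibitors, localTotals) -
                 reducedRhs(xm[1L], xm[2L], params, inhibitors, localTotals)) /
        (xp[i] - xm[i])
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      x1 <- pmin(pmax(x + lam * step, 1e-9), 1 - 1e-9)
      f1 <- reducedRhs(x1[1L], x1[2L], params, inhibitors, localTotals)
      if (max(abs(f1)) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(x1 - x)) < 1e-15) { x <- x1; break }
    x <- x1
  }
  f <- reducedRhs(x[1L], x[2L], params, inhibitors, localTotals)
  if (max(abs(f)) < 1e-8) x else NULL
}
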