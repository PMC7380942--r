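## Reaction-diffusion simulation on 1-D abundance profiles and 2-D
## rasterized cell masks: graded DIA/ROCK totals, zero-flux boundaries,
## Strang splitting (implicit diffusion / adaptive Cash-Karp reaction).

#' Spatial DIA/ROCK abundance profile parameters
#'
#' The cell is oriented rear (x = 0) to front (x = L).  The DIA total
#' ramps linearly from \code{diaLow} at the rear to \code{diaHigh} at the
#' front (DIA is enriched at the leading edge); the ROCK total is
#' \code{rockHigh} on the rear/body segment [0, xSwitch*L] and
#' \code{rockLow} on the front segment (ROCK is enriched at the rear and
#' cell body).  Totals are dimensionless scale factors relative to the
#' unperturbed abundances, so the leading edge sits at the oscillatory
#' physiological point (diaHigh, rockLow) = (1, 1) by default.
#'
#' @param diaHigh,diaLow,rockHigh,rockLow dimensionless totals.
#' @param xSwitch rear/front switch position as a fraction of cell length.
#' @param cellLength cell length L in micrometres.
#' @return object of class "SpatialProfileParams" (list).
#' @export
spatialProfile <- function(diaHigh = 1, diaLow = 0.4, rockHigh = 2,
                           rockLow = 1, xSwitch = 0.9, cellLength = 50) {
  if (!(diaHigh >= diaLow && diaLow > 0)) stop("need diaHigh >= diaLow > 0")
  if (!(rockHigh >= rockLow && rockLow > 0)) stop("need rockHigh >= rockLow > 0")
  if (!(xSwitch > 0 && xSwitch < 1)) stop("xSwitch must lie in (0, 1)")
  if (cellLength <= 0) stop("cellLength must be positive")
  structure(list(diaHigh = diaHigh, diaLow = diaLow, rockHigh = rockHigh,
                 rockLow = rockLow, xSwitch = xSwitch,
                 cellLength = cellLength),
            class = "SpatialProfileParams")
}

#' Diffusion coefficients of the GTPase forms
#'
#' Active (membrane-bound) forms diffuse slower than inactive
#' (GDI-bound, cytosolic) forms; effector species carry no diffusion
#' term.
#'
#' @param dRhoActive,dRhoInactive,dRacActive,dRacInactive coefficients in
#'   um^2/s.
#' @return object of class "DiffusionParams" (list).
#' @export
diffusionParams <- function(dRhoActive = 0.2, dRhoInactive = 20,
                            dRacActive = 0.2, dRacInactive = 20) {
  v <- c(dRhoActive, dRhoInactive, dRacActive, dRacInactive)
  if (any(!is.finite(v)) || any(v < 0)) stop("diffusion coefficients must be non-negative")
  if (dRhoInactive < dRhoActive || dRacInactive < dRacActive) {
    stop("inactive-form coefficients must be >= active-form coefficients")
  }
  structure(list(dRhoActive = dRhoActive, dRhoInactive = dRhoInactive,
                 dRacActive = dRacActive, dRacInactive = dRacInactive),
            class = "DiffusionParams")
}

#' Build DIA/ROCK abundance fields on a domain
#'
#' @param profile a \code{spatialProfile()} object.
#' @param domain a \linkS4class{CellDomain}.
#' @return list with numeric vectors \code{d} and \code{r}, one value per
#'   interior pixel (constant across the cell width), plus the pixel
#'   x-coordinates as fractions of the occupied length.
#' @export
buildAbundanceProfiles <- function(profile, domain) {
  stopifnot(inherits(profile, "SpatialProfileParams"), is(domain, "CellDomain"))
  idx <- which(domain@mask, arr.ind = TRUE)
  cols <- idx[, 2L]
  cr <- range(cols)
  xfrac <- if (cr[2L] > cr[1L]) (cols - cr[1L]) / (cr[2L] - cr[1L]) else rep(0, length(cols))
  if (!domain@frontAtRight) xfrac <- 1 - xfrac
  d <- profile$diaLow + (profile$diaHigh - profile$diaLow) * xfrac
  r <- ifelse(xfrac <= profile$xSwitch, profile$rockHigh, profile$rockLow)
  list(d = d, r = r, xfrac = xfrac)
}

## ---- mask utilities ----------------------------------------------------

## 4-connected component labelling (masks are small; BFS in R)
.labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  n1 <- nrow(mask); n2 <- ncol(mask)
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (q - 1L) %% n1 + 1L
      j <- (q - 1L) %/% n1 + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1L] < 1L || nb[1L] > n1 || nb[2L] < 1L || nb[2L] > n2) next
        k <- (nb[2L] - 1L) * n1 + nb[1L]
        if (mask[k] && lab[k] == 0L) {
          lab[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

## fill interior holes: flood the complement from the border, anything
## not reached is a hole
.fillHoles <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  comp <- .labelComponents(!pad)
  outside <- comp[1L, 1L]
  filled <- pad | (comp != outside)
  filled[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

#' Rasterize a binary mask image into a simulation domain
#'
#' Reads a binary cell-mask image (PNG, TIFF, or a logical/numeric
#' matrix), keeps the largest connected component after rejecting images
#' with more than one substantial component, fills interior holes,
#' optionally downsamples to the solver's working resolution, and assigns
#' the front to the wider end of the cell (teardrop heuristic,
#' overridable).
#'
#' @param maskImage file path or logical/numeric matrix (> 0.5 = inside).
#' @param spacing micrometres per pixel.
#' @param frontAtRight optional logical overriding the width heuristic.
#' @param maxDim integer c(rows, cols) working-resolution cap; larger
#'   masks are block-downsampled (default c(60, 120)).
#' @param noiseFraction components smaller than this fraction of the
#'   largest one are treated as salt noise and removed silently; larger
#'   secondary components are an error.
#' @return a \linkS4class{CellDomain}.
#' @export
rasterizeDomain <- function(maskImage, spacing = 1, frontAtRight = NULL,
                            maxDim = c(60, 120), noiseFraction = 0.05) {
  m <- maskImage
  if (is.character(m)) {
    if (grepl("\\.png$", m, ignore.case = TRUE)) {
      img <- png::readPNG(m)
    } else if (grepl("\\.tiff?$", m, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF masks requires the 'tiff' package")
      }
      img <- tiff::readTIFF(m)
    } else stop("unsupported mask image format: ", m)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- img
  }
  mask <- as.matrix(m) > 0.5
  if (!any(mask)) stop("mask image contains no foreground")
  lab <- .labelComponents(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L) {
    big <- sizes >= noiseFraction * max(sizes)
    if (sum(big) > 1L) {
      stop("mask contains ", sum(big), " substantial connected components; ",
           "expected exactly 1")
    }
    mask <- lab == which.max(sizes)
  }
  mask <- .fillHoles(mask)
  ## crop to bounding box with a 0-pixel margin
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  mask <- mask[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  ## downsample to working resolution
  f <- max(ceiling(nrow(mask) / maxDim[1L]), ceiling(ncol(mask) / maxDim[2L]))
  if (f > 1L) {
    nr <- floor(nrow(mask) / f); nc <- floor(ncol(mask) / f)
    sub <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      blk <- mask[((i - 1L) * f + 1L):(i * f), ((j - 1L) * f + 1L):(j * f)]
      sub[i, j] <- mean(blk) >= 0.5
    }
    lab2 <- .labelComponents(sub)
    if (max(lab2) >= 1L) {
      sz <- tabulate(lab2[lab2 > 0L])
      sub <- lab2 == which.max(sz)
    }
    mask <- .fillHoles(sub)
    spacing <- spacing * f
  }
  if (is.null(frontAtRight)) {
    w <- colSums(mask)
    nz <- which(w > 0)
    third <- max(1L, floor(length(nz) / 3))
    frontAtRight <- mean(w[nz[seq(length(nz) - third + 1L, length(nz))]]) >=
      mean(w[nz[seq_len(third)]])
  }
  new("CellDomain", mask = mask, spacing = spacing, frontAtRight = frontAtRight)
}

## ---- solver internals --------------------------------------------------

## fixed parameter order for the C++ kernel
.cppParamVector <- function(params, inhibitors) {
  v <- params@values
  c(v[["vGEFRho"]], v[["kGEFRho"]], v[["vGAPRho"]], v[["kGAPRho"]],
    v[["vaDIA"]], v[["kaDIA"]], v[["viDIA"]], v[["kiDIA"]],
    v[["vaROCK"]], v[["kaROCK"]], v[["viROCK"]], v[["kiROCK"]],
    v[["vGEFRac"]], v[["kGEFRac"]], v[["vGAPRac"]], v[["kGAPRac"]],
    v[["vaPAK"]], v[["kaPAK"]], v[["viPAK"]], v[["kiPAK"]],
    v[["gammaDIARho"]], v[["kDIARho"]], v[["gammaPAKRho"]], v[["kPAKRho"]],
    v[["gammaRhoDIA"]], v[["kRhoDIA"]], v[["gammaRhoROCK"]], v[["kRhoROCK"]],
    v[["gammaDIARac"]], v[["kDIARac"]], v[["gammaPAKRac"]], v[["kPAKRac"]],
    v[["gammaROCKRac"]], v[["kROCKRac"]], v[["gammaRacPAK"]], v[["kRacPAK"]],
    v[["p"]], rockInhibitionBeta(inhibitors),
    1 + inhibitors@ipa3Dose / inhibitors@kIPAK)
}

## sparse 5-point Laplacian over interior pixels with zero-flux boundaries
.maskLaplacian <- function(mask, spacing) {
  idx <- matrix(0L, nrow(mask), ncol(mask))
  ins <- which(mask)
  idx[ins] <- seq_along(ins)
  n1 <- nrow(mask)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  deg <- numeric(length(ins))
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    pos <- which(mask, arr.ind = TRUE)
    nb <- cbind(pos[, 1L] + off[1L], pos[, 2L] + off[2L])
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= nrow(mask) &
      nb[, 2L] >= 1L & nb[, 2L] <= ncol(mask)
    ok[ok] <- mask[nb[ok, , drop = FALSE]]
    from <- idx[pos[ok, , drop = FALSE]]
    to <- idx[nb[ok, , drop = FALSE]]
    ii <- c(ii, from); jj <- c(jj, to); xx <- c(xx, rep(1, length(from)))
    deg[from] <- deg[from] + 1
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_along(ins)), j = c(jj, seq_along(ins)),
                            x = c(xx, -deg), dims = c(length(ins), length(ins)))
  L / spacing^2
}

#' Simulate the reaction-diffusion model on a 2-D cell domain
#'
#' Operator splitting per global step (Strang: half implicit diffusion,
#' full reaction, half implicit diffusion).  The reaction is advanced
#' pixel-wise with an adaptive embedded Cash-Karp Runge-Kutta scheme (in
#' compiled code); diffusion uses a mask-aware 5-point stencil with
#' zero-flux boundaries, advanced by a Crank-Nicolson-style implicit
#' solve (sparse Cholesky, unconditionally stable).  Effector species do
#' not diffuse.  Per-GTPase total mass is conserved to solver round-off;
#' any non-finite value aborts with the first bad frame index.
#'
#' @param domain a \linkS4class{CellDomain}.
#' @param profile a \code{spatialProfile()}.
#' @param params a \linkS4class{KineticParams}.
#' @param diffusion a \code{diffusionParams()}.
#' @param inhibitors an \linkS4class{InhibitorParams}.
#' @param x0 initial condition: NULL for the default recipe (rear-branch
#'   steady state everywhere plus a Rac1 perturbation seeding the front
#'   pacemaker), a \linkS4class{NetworkState} applied uniformly, or a
#'   7-column matrix (one row per interior pixel).
#' @param tMax simulation horizon (s).
#' @param outputDt frame interval of the stored solution (s).
#' @param dt global splitting step (s).
#' @param rtol,atol reaction sub-step tolerances.
#' @param frontPerturbation list(fraction, rac) for the default x0 recipe:
#'   the front fraction of the cell length whose Rac1 is raised to the
#'   given value.
#' @return a \linkS4class{SpatioTemporalSolution}.
#' @export
simulatePde <- function(domain, profile = spatialProfile(),
                        params = defaultKineticParams(),
                        diffusion = diffusionParams(),
                        inhibitors = inhibitorParams(), x0 = NULL,
                        tMax = 600, outputDt = 5, dt = 1,
                        rtol = 1e-7, atol = 1e-9,
                        frontPerturbation = list(fraction = 0.1, rac = 0.5)) {
  stopifnot(is(domain, "CellDomain"), inherits(profile, "SpatialProfileParams"),
            is(params, "KineticParams"), inherits(diffusion, "DiffusionParams"),
            is(inhibitors, "InhibitorParams"))
  prof <- buildAbundanceProfiles(profile, domain)
  np <- length(prof$d)
  p <- params@values[["p"]]
  S <- .initialField(x0, prof, params, inhibitors, frontPerturbation)
  vpar <- .cppParamVector(params, inhibitors)
  L <- .maskLaplacian(domain@mask, domain@spacing)
  dcoef <- c(rho = diffusion$dRhoActive, rhod = diffusion$dRhoInactive,
             rac = diffusion$dRacActive, racd = diffusion$dRacInactive)
  I <- Matrix::Diagonal(np)
  half <- lapply(dcoef, function(D) {
    if (D <= 0 || np == 1L) NULL else Matrix::Cholesky(I - (dt / 2) * D * L)
  })
  dIdx <- c(rho = 1L, rhod = 2L, rac = 5L, racd = 6L)
  times <- seq(0, tMax, by = outputDt)
  fields <- lapply(setNames(.STATE_KEYS, .STATE_KEYS),
                   function(k) matrix(NA_real_, length(times), np))
  .store <- function(fr, S) {
    for (k in seq_along(.STATE_KEYS)) fields[[k]][fr, ] <<- S[, k]
  }
  .store(1L, S)
  t <- 0
  frame <- 2L
  nStep <- round(tMax / dt)
  diffuseHalf <- function(S) {
    for (nm in names(dIdx)) {
      ch <- half[[nm]]
      if (!is.null(ch)) {
        S[, dIdx[[nm]]] <- as.numeric(Matrix::solve(ch, S[, dIdx[[nm]]]))
      }
    }
    S
  }
  hState <- rep(dt, np)
  for (s in seq_len(nStep)) {
    S <- diffuseHalf(S)
    S <- .reactionStepCpp(S, vpar, prof$d, prof$r, dt, rtol, atol, hState)
    S <- diffuseHalf(S)
    t <- t + dt
    if (frame <= length(times) && t >= times[frame] - 1e-9) {
      if (any(!is.finite(S))) {
        stop("non-finite field values at frame ", frame, " (t = ", t, " s)")
      }
      .store(frame, S)
      frame <- frame + 1L
    }
  }
  pos <- which(domain@mask, arr.ind = TRUE)
  coords <- data.frame(row = pos[, 1L], col = pos[, 2L],
                       x = (pos[, 2L] - 0.5) * domain@spacing,
                       y = (pos[, 1L] - 0.5) * domain@spacing,
                       xfrac = prof$xfrac)
  new("SpatioTemporalSolution", times = times, fields = fields,
      coords = coords, domain = domain,
      profiles = list(d = prof$d, r = prof$r), params = params,
      inhibitors = inhibitors)
}

## default initial field: rear-branch steady state everywhere (clamped to
## local totals) + Rac perturbation at the front
.initialField <- function(x0, prof, params, inhibitors, frontPerturbation) {
  np <- length(prof$d)
  p <- params@values[["p"]]
  if (is.matrix(x0)) {
    if (!identical(dim(x0), c(np, 7L))) stop("x0 matrix must be pixels x 7")
    return(x0)
  }
  if (is(x0, "NetworkState")) {
    s <- x0@values[.STATE_KEYS]
    S <- matrix(rep(s, each = np), np, 7L)
    colnames(S) <- .STATE_KEYS
    return(S)
  }
  if (!is.null(x0)) stop("x0 must be NULL, a NetworkState, or a matrix")
  st <- .rearBranchState(params, inhibitors, d = min(prof$d), r = max(prof$r))
  S <- cbind(rho = rep(st[["rho"]], np), rhod = 1 - st[["rho"]],
             dia = pmin(st[["dia"]], prof$d), rock = pmin(st[["rock"]], prof$r),
             rac = st[["rac"]], racd = 1 - st[["rac"]],
             pak = min(st[["pak"]], p))
  front <- prof$xfrac >= 1 - frontPerturbation$fraction
  S[front, "rac"] <- frontPerturbation$rac
  S[front, "racd"] <- 1 - frontPerturbation$rac
  S
}

## high-RhoA rear-branch steady state found by integrating from a
## high-Rho/low-Rac corner and polishing with Newton (cheaper than the
## full multi-start census)
.rearBranchState <- function(params, inhibitors, d, r) {
  v <- as.list(params@values)
  p <- v$p
  beta <- rockInhibitionBeta(inhibitors)
  kaScale <- 1 + inhibitors@ipa3Dose / inhibitors@kIPAK
  x0 <- c(0.9, 0.5 * d, 0.5 * r, 0.05, 0.05 * p)
  f <- function(t, y, parms) list(.rhs5(y, v, d, r, p, beta, kaScale))
  sol <- deSolve::ode(y = x0, times = c(0, 1000), func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  x <- .newton5(sol[nrow(sol), -1L], v, d, r, p, beta, kaScale)
  if (is.null(x)) x <- sol[nrow(sol), -1L]
  setNames(x, .ODE_KEYS)
}

#' Simulate the model on a 1-D section of a cell
#'
#' Specializes \code{\link{simulatePde}} to a 1-row domain of
#' \code{nNodes} nodes spanning the cell length.
#'
#' @inheritParams simulatePde
#' @param nNodes number of nodes along the cell length (default 200).
#' @return a \linkS4class{SpatioTemporalSolution}.
#' @export
simulate1d <- function(profile = spatialProfile(),
                       params = defaultKineticParams(),
                       diffusion = diffusionParams(),
                       inhibitors = inhibitorParams(), x0 = NULL,
                       nNodes = 200, tMax = 600, outputDt = 5, dt = 1,
                       rtol = 1e-7, atol = 1e-9,
                       frontPerturbation = list(fraction = 0.1, rac = 0.5)) {
  domain <- new("CellDomain",
                mask = matrix(TRUE, 1L, nNodes),
                spacing = profile$cellLength / nNodes, frontAtRight = TRUE)
  simulatePde(domain, profile, params, diffusion, inhibitors, x0,
              tMax, outputDt, dt, rtol, atol, frontPerturbation)
}

## ---- solution accessors ------------------------------------------------

#' Solution accessors
#'
#' \code{solutionTimes} returns the output time grid; \code{solutionField}
#' one species' matrix (time x pixel); \code{solutionCoords} the pixel
#' coordinate table; \code{gtpaseMass} the total (active + inactive) mass
#' of a GTPase per frame, for conservation checks.
#'
#' @param solution a \linkS4class{SpatioTemporalSolution}.
#' @param species one of rho, rhod, dia, rock, rac, racd, pak.
#' @return see description.
#' @export
solutionTimes <- function(solution) solution@times

#' @rdname solutionTimes
#' @export
solutionField <- function(solution, species = "rho") {
  stopifnot(species %in% .STATE_KEYS)
  solution@fields[[species]]
}

#' @rdname solutionTimes
#' @export
solutionCoords <- function(solution) solution@coords

#' @rdname solutionTimes
#' @param gtpase "rho" or "rac".
#' @export
gtpaseMass <- function(solution, gtpase = c("rho", "rac")) {
  gtpase <- match.arg(gtpase)
  act <- solution@fields[[gtpase]]
  ina <- solution@fields[[paste0(gtpase, "d")]]
  rowSums(act) + rowSums(ina)
}
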