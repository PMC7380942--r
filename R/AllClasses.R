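#' @import methods
#' @importFrom stats uniroot sd quantile setNames rnorm runif approx dist
#' @importFrom utils read.table write.table modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib RhoRacWaves, .registration = TRUE
NULL

## canonical parameter key sets -------------------------------------------

.RATE_KEYS <- c("vGEFRho", "vGAPRho", "vaDIA", "viDIA", "vaROCK", "viROCK",
                "vGEFRac", "vGAPRac", "vaPAK", "viPAK")
.MM_KEYS   <- c("kGEFRho", "kGAPRho", "kaDIA", "kiDIA", "kaROCK", "kiROCK",
                "kGEFRac", "kGAPRac", "kaPAK", "kiPAK")
.GAMMA_KEYS <- c("gammaDIARho", "gammaPAKRho", "gammaRhoDIA", "gammaRhoROCK",
                 "gammaDIARac", "gammaPAKRac", "gammaROCKRac", "gammaRacPAK")
.MODK_KEYS <- c("kDIARho", "kPAKRho", "kRhoDIA", "kRhoROCK",
                "kDIARac", "kPAKRac", "kROCKRac", "kRacPAK")
.TOT_KEYS  <- c("Rhotot", "Ractot", "DIAtot", "ROCKtot", "PAKtot")
.PARAM_KEYS <- c(.RATE_KEYS, .MM_KEYS, .GAMMA_KEYS, .MODK_KEYS, .TOT_KEYS, "p")

.STATE_KEYS <- c("rho", "rhod", "dia", "rock", "rac", "racd", "pak")
.ODE_KEYS   <- c("rho", "dia", "rock", "rac", "pak")

## classes ----------------------------------------------------------------

#' Kinetic parameters of the RhoA-Rac1-DIA-ROCK-PAK network
#'
#' Holds every rate constant, Michaelis constant, regulatory modifier
#' strength and half-saturation, total abundance and the dimensionless
#' total PAK of the dimensionless network model.  Rates are in 1/s;
#' Michaelis and modifier constants are dimensionless (scaled by the
#' respective total abundance); abundances are in arbitrary concentration
#' units and are used only for nondimensionalization and the
#' effector-complex module.
#'
#' @slot values named numeric vector with the full canonical key set.
#' @seealso [defaultKineticParams()], [kineticValues()]
#' @export
setClass("KineticParams", representation(values = "numeric"))

setValidity("KineticParams", function(object) {
  v <- object@values
  missing <- setdiff(.PARAM_KEYS, names(v))
  extra <- setdiff(names(v), .PARAM_KEYS)
  if (length(missing)) return(paste("missing parameters:", paste(missing, collapse = ", ")))
  if (length(extra)) return(paste("unknown parameters:", paste(extra, collapse = ", ")))
  if (any(!is.finite(v))) return("all parameters must be finite")
  if (any(v <= 0)) {
    return(paste("parameters must be strictly positive:",
                 paste(names(v)[v <= 0], collapse = ", ")))
  }
  ## gamma = 1 encodes the absence of a regulatory interaction and is
  ## admissible (it decouples the network for oracle tests)
  act <- c("gammaDIARho", "gammaRhoDIA", "gammaRhoROCK", "gammaDIARac",
           "gammaRacPAK", "gammaPAKRac", "gammaROCKRac")
  if (any(v[act] < 1)) {
    return(paste("activation strengths must be >= 1:",
                 paste(act[v[act] < 1], collapse = ", ")))
  }
  if (v["gammaPAKRho"] > 1) return("gammaPAKRho must be <= 1 (PAK inhibits RhoA)")
  if (v["Rhotot"] < 10 * v["DIAtot"] || v["Rhotot"] < 10 * v["ROCKtot"]) {
    return("Rhotot must be at least 10-fold above DIAtot and ROCKtot")
  }
  TRUE
})

#' Inhibitor doses and binding constants
#'
#' IPA-3 (allosteric PAK inhibitor binding the inactive conformation) and
#' Y-27632 (ATP-competitive ROCK inhibitor) with the cellular ATP level.
#' All concentrations share one unit (conventionally micromolar).
#'
#' @slot ipa3Dose IPA-3 concentration.
#' @slot kIPAK IPA-3 binding constant for inactive PAK.
#' @slot y27632Dose Y-27632 concentration.
#' @slot kIROCK Y-27632 inhibition constant for ROCK.
#' @slot atp cellular ATP concentration.
#' @slot kdATP ATP binding constant of the ROCK kinase.
#' @seealso [rockInhibitionBeta()], [applyPakInhibitor()]
#' @export
setClass("InhibitorParams",
         representation(ipa3Dose = "numeric", kIPAK = "numeric",
                        y27632Dose = "numeric", kIROCK = "numeric",
                        atp = "numeric", kdATP = "numeric"))

setValidity("InhibitorParams", function(object) {
  v <- c(object@ipa3Dose, object@kIPAK, object@y27632Dose, object@kIROCK,
         object@atp, object@kdATP)
  if (length(v) != 6L || any(!is.finite(v))) return("all fields must be finite scalars")
  if (any(v < 0)) return("inhibitor fields must be non-negative")
  if (object@kIPAK == 0 || object@kIROCK == 0 || object@kdATP == 0) {
    return("binding constants must be strictly positive")
  }
  TRUE
})

#' Network state (dimensionless species fractions)
#'
#' Active/inactive RhoA and Rac1 fractions (of the respective GTPase
#' total) plus active DIA, ROCK and PAK fractions (of their reference
#' totals).  In the well-mixed model rho + rhod = 1 and rac + racd = 1.
#'
#' @slot values named numeric vector (rho, rhod, dia, rock, rac, racd, pak).
#' @export
setClass("NetworkState", representation(values = "numeric"))

setValidity("NetworkState", function(object) {
  v <- object@values
  if (!identical(sort(names(v)), sort(.STATE_KEYS))) {
    return(paste("state needs exactly the fields:", paste(.STATE_KEYS, collapse = ", ")))
  }
  if (any(!is.finite(v))) return("state must be finite")
  if (any(v < -1e-12)) return("state fractions must be non-negative")
  if (abs(v["rho"] + v["rhod"] - 1) > 1e-6) return("rho + rhod must equal 1")
  if (abs(v["rac"] + v["racd"] - 1) > 1e-6) return("rac + racd must equal 1")
  TRUE
})

#' Census of network steady states
#'
#' Roots of the five-dimensional reaction system with their Jacobian
#' eigenvalues and local stability type (stable/unstable node or focus,
#' saddle), deduplicated at a state-space tolerance.
#'
#' @slot states matrix, one row per steady state (columns rho, dia, rock,
#'   rac, pak).
#' @slot eigenvalues list of complex eigenvalue vectors.
#' @slot type character vector of stability types.
#' @slot residual numeric max-norm residuals of the right-hand side.
#' @export
setClass("SteadyStateCensus",
         representation(states = "matrix", eigenvalues = "list",
                        type = "character", residual = "numeric"))

setValidity("SteadyStateCensus", function(object) {
  n <- nrow(object@states)
  if (length(object@eigenvalues) != n || length(object@type) != n ||
      length(object@residual) != n) {
    return("states, eigenvalues, type and residual must be congruent")
  }
  ok <- c("stable node", "stable focus", "unstable node", "unstable focus",
          "saddle", "borderline")
  if (n > 0 && !all(object@type %in% ok)) return("unknown stability type")
  if (n > 1) {
    d <- as.matrix(dist(object@states))
    diag(d) <- Inf
    if (any(d < 1e-8)) return("duplicate steady states below tolerance")
  }
  TRUE
})

#' Two-parameter regime map
#'
#' Grid over two abundance axes (normalized to unperturbed = 1) with the
#' dynamic-regime label 0-8 (or NA where unclassified), the per-point
#' steady-state census summary and limit-cycle flags.
#'
#' @slot axis1,axis2 axis names (one of DIAtot, ROCKtot, PAKtot).
#' @slot grid1,grid2 axis grids.
#' @slot labels integer matrix (length(grid1) x length(grid2)) of regime
#'   labels; NA marks unclassified points.
#' @slot nStates,nStable integer matrices of census counts.
#' @slot limitCycle logical matrix.
#' @slot census list-of-lists of \linkS4class{SteadyStateCensus}.
#' @export
setClass("RegimeMap",
         representation(axis1 = "character", axis2 = "character",
                        grid1 = "numeric", grid2 = "numeric",
                        labels = "matrix", nStates = "matrix",
                        nStable = "matrix", limitCycle = "matrix",
                        census = "list"))

setValidity("RegimeMap", function(object) {
  d <- c(length(object@grid1), length(object@grid2))
  for (nm in c("labels", "nStates", "nStable", "limitCycle")) {
    if (!identical(dim(slot(object, nm)), as.integer(d))) {
      return(paste(nm, "grid not congruent with axes"))
    }
  }
  lab <- object@labels
  if (any(!is.na(lab) & (lab < 0 | lab > 8))) return("labels must be 0-8 or NA")
  TRUE
})

#' Rasterized cell domain for spatial simulation
#'
#' @slot mask logical matrix, TRUE inside the cell; simply connected.
#' @slot spacing micrometres per pixel.
#' @slot frontAtRight TRUE when the cell front (leading edge) is at
#'   increasing x (column index).
#' @export
setClass("CellDomain",
         representation(mask = "matrix", spacing = "numeric",
                        frontAtRight = "logical"))

setValidity("CellDomain", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask is empty")
  if (object@spacing <= 0) return("spacing must be positive")
  cw <- range(which(colSums(object@mask) > 0))
  widths <- colSums(object@mask)[seq(cw[1], cw[2])]
  if (min(widths[widths > 0]) < 1) return("degenerate mask column")
  TRUE
})

#' Spatio-temporal solution of the reaction-diffusion model
#'
#' Fields of all seven species over a masked grid (2-D) or node line
#' (1-D), sampled on an output time grid, plus the abundance profiles and
#' parameter provenance of the run.
#'
#' @slot times output times (s).
#' @slot fields named list of matrices, one per species, dimension
#'   length(times) x number of interior pixels.
#' @slot coords data.frame with pixel coordinates (x, y in micrometres,
#'   column/row indices).
#' @slot domain the \linkS4class{CellDomain} (1-row mask for 1-D runs).
#' @slot profiles named list with per-pixel DIA/ROCK totals d and r.
#' @slot params the \linkS4class{KineticParams} used.
#' @slot inhibitors the \linkS4class{InhibitorParams} used.
#' @export
setClass("SpatioTemporalSolution",
         representation(times = "numeric", fields = "list",
                        coords = "data.frame", domain = "CellDomain",
                        profiles = "list", params = "KineticParams",
                        inhibitors = "InhibitorParams"))

setValidity("SpatioTemporalSolution", function(object) {
  if (!all(.STATE_KEYS %in% names(object@fields))) {
    return("fields must contain all seven species")
  }
  np <- nrow(object@coords)
  nt <- length(object@times)
  for (k in .STATE_KEYS) {
    f <- object@fields[[k]]
    if (!identical(dim(f), c(nt, np))) return(paste("field", k, "has wrong dimension"))
  }
  if (is.unsorted(object@times, strictly = TRUE)) return("times must be increasing")
  TRUE
})

## show methods -----------------------------------------------------------

setMethod("show", "KineticParams", function(object) {
  v <- object@values
  cat("KineticParams (dimensionless RhoA-Rac1-DIA-ROCK-PAK network)\n")
  cat(sprintf("  GTPase turnover: vGEFRho=%.3g vGAPRho=%.3g vGEFRac=%.3g vGAPRac=%.3g 1/s\n",
              v["vGEFRho"], v["vGAPRho"], v["vGEFRac"], v["vGAPRac"]))
  cat(sprintf("  abundances: Rho=%.3g Rac=%.3g DIA=%.3g ROCK=%.3g PAK=%.3g (Rho/DIA=%.1f)\n",
              v["Rhotot"], v["Ractot"], v["DIAtot"], v["ROCKtot"], v["PAKtot"],
              v["Rhotot"] / v["DIAtot"]))
  cat(sprintf("  dimensionless total PAK p = %.3g\n", v["p"]))
})

setMethod("show", "InhibitorParams", function(object) {
  cat("InhibitorParams\n")
  cat(sprintf("  IPA-3: dose=%.3g (K_I=%.3g)  Y-27632: dose=%.3g (K_I=%.3g)\n",
              object@ipa3Dose, object@kIPAK, object@y27632Dose, object@kIROCK))
  cat(sprintf("  ATP=%.3g Kd_ATP=%.3g -> beta=%.4f, kaPAK scale=%.4g\n",
              object@atp, object@kdATP, rockInhibitionBeta(object),
              1 + object@ipa3Dose / object@kIPAK))
})

setMethod("show", "NetworkState", function(object) {
  cat("NetworkState:", paste(sprintf("%s=%.4f", names(object@values), object@values),
                             collapse = " "), "\n")
})

setMethod("show", "SteadyStateCensus", function(object) {
  n <- nrow(object@states)
  cat("SteadyStateCensus:", n, "steady state(s)\n")
  if (n > 0) {
    for (i in seq_len(n)) {
      cat(sprintf("  [%d] %-15s rho=%.3f rac=%.3f pak=%.3f (|rhs|=%.1e)\n",
                  i, object@type[i], object@states[i, "rho"],
                  object@states[i, "rac"], object@states[i, "pak"],
                  object@residual[i]))
    }
  }
})

setMethod("show", "RegimeMap", function(object) {
  cat(sprintf("RegimeMap: %s x %s, %d x %d points\n", object@axis1, object@axis2,
              length(object@grid1), length(object@grid2)))
  tab <- table(factor(object@labels, levels = 0:8), useNA = "ifany")
  cat("  regime counts:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "CellDomain", function(object) {
  cat(sprintf("CellDomain: %d x %d px grid, %d interior px, %.2f um/px, front at %s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@spacing, if (object@frontAtRight) "right" else "left"))
})

setMethod("show", "SpatioTemporalSolution", function(object) {
  cat(sprintf("SpatioTemporalSolution: %d frames (t = %.4g..%.4g s), %d pixels\n",
              length(object@times), min(object@times), max(object@times),
              nrow(object@coords)))
})
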