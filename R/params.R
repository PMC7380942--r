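## Constructors, calibrated defaults and flat-file parameter I/O.

#' Construct kinetic parameters
#'
#' Builds a validated \linkS4class{KineticParams} from the calibrated
#' defaults, overriding any named subset of parameters.
#'
#' @param ... named numeric overrides of canonical parameter keys.
#' @param values optionally a full named numeric vector replacing the
#'   defaults entirely.
#' @return a \linkS4class{KineticParams}.
#' @examples
#' kineticParams(vGEFRho = 0.15)
#' @export
kineticParams <- function(..., values = NULL) {
  v <- if (is.null(values)) .defaultParamValues() else values
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), .PARAM_KEYS)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(over)] <- over
  }
  new("KineticParams", values = v[.PARAM_KEYS])
}

#' Calibrated default parameter set
#'
#' The package's reference parameterization of the dimensionless network.
#' It satisfies the qualitative constraints that pin down the model's
#' biology: the unperturbed point (DIA, ROCK) = (1, 1) lies in the
#' oscillatory regime with a period near one minute; raising ROCK at
#' fixed DIA leads into the bi-dynamic (BiDR) regime; the low-DIA /
#' high-ROCK corner used for the cell rear is a bistable excitable regime
#' whose dominant attractor has high RhoA and low Rac1; reducing total
#' PAK quenches the oscillations and leaves a single high-RhoA steady
#' state; and the RhoA abundance exceeds the DIA and ROCK abundances more
#' than tenfold.
#'
#' @return a \linkS4class{KineticParams}.
#' @export
defaultKineticParams <- function() new("KineticParams", values = .defaultParamValues())

.defaultParamValues <- function() {
  c(
    ## GTPase activation/deactivation (1/s; constants dimensionless)
    vGEFRho = 0.12, kGEFRho = 0.30, vGAPRho = 0.19, kGAPRho = 0.30,
    vGEFRac = 0.033, kGEFRac = 0.30, vGAPRac = 0.105, kGAPRac = 0.15,
    ## effector turnover: DIA and ROCK are fast switches, PAK is the slow
    ## variable that paces the relaxation oscillation
    vaDIA = 0.40, kaDIA = 0.04, viDIA = 1.00, kiDIA = 0.02,
    vaROCK = 0.40, kaROCK = 0.06, viROCK = 1.00, kiROCK = 0.03,
    vaPAK = 0.06, kaPAK = 0.60, viPAK = 0.106, kiPAK = 0.005,
    ## regulatory modifier strengths and half-saturations
    gammaDIARho = 5.0, kDIARho = 0.60,
    gammaPAKRho = 0.02, kPAKRho = 0.09,
    gammaRhoDIA = 4.0, kRhoDIA = 0.16,
    gammaRhoROCK = 4.0, kRhoROCK = 0.35,
    gammaDIARac = 5.0, kDIARac = 0.45,
    gammaPAKRac = 1.6, kPAKRac = 0.40,
    gammaROCKRac = 3.5, kROCKRac = 6.0,
    gammaRacPAK = 6.0, kRacPAK = 0.35,
    ## abundances (arbitrary concentration units); RhoA and Rac1 exceed
    ## the effectors by more than an order of magnitude
    Rhotot = 25, Ractot = 20, DIAtot = 2.0, ROCKtot = 2.2, PAKtot = 2.0,
    ## dimensionless total PAK (PAKtot / unperturbed PAKtot)
    p = 1
  )
}

#' Construct inhibitor parameters
#'
#' @param ipa3Dose IPA-3 concentration (uM), default 0.
#' @param kIPAK IPA-3 binding constant (uM).
#' @param y27632Dose Y-27632 concentration (uM), default 0.
#' @param kIROCK Y-27632 inhibition constant (uM).
#' @param atp cellular ATP concentration (uM).
#' @param kdATP ATP binding constant of ROCK (uM).
#' @return an \linkS4class{InhibitorParams}.
#' @export
inhibitorParams <- function(ipa3Dose = 0, kIPAK = 2.5, y27632Dose = 0,
                            kIROCK = 0.1, atp = 1000, kdATP = 300) {
  new("InhibitorParams", ipa3Dose = ipa3Dose, kIPAK = kIPAK,
      y27632Dose = y27632Dose, kIROCK = kIROCK, atp = atp, kdATP = kdATP)
}

#' Construct a network state
#'
#' @param rho,dia,rock,rac,pak active fractions; the inactive GTPase
#'   fractions follow from conservation.
#' @return a \linkS4class{NetworkState}.
#' @export
networkState <- function(rho = 0.25, dia = 0.1, rock = 0.1, rac = 0.1,
                         pak = 0.02) {
  rho <- unname(rho); dia <- unname(dia); rock <- unname(rock)
  rac <- unname(rac); pak <- unname(pak)
  v <- c(rho = rho, rhod = 1 - rho, dia = dia, rock = rock,
         rac = rac, racd = 1 - rac, pak = pak)
  new("NetworkState", values = v)
}

#' Access the parameter vector
#'
#' @param params a \linkS4class{KineticParams}.
#' @return named numeric vector of all parameter values.
#' @export
kineticValues <- function(params) {
  stopifnot(is(params, "KineticParams"))
  params@values
}

#' State vector of a NetworkState
#'
#' @param state a \linkS4class{NetworkState}.
#' @return named numeric vector of the seven species fractions.
#' @export
stateValues <- function(state) {
  stopifnot(is(state, "NetworkState"))
  state@values
}

## parameter file I/O -----------------------------------------------------

#' Read kinetic parameters from a YAML/JSON key-value file
#'
#' The file holds one flat mapping with keys named exactly as the
#' canonical parameter set (units in comments).  Unknown keys, missing
#' keys, and non-positive values are errors listing the offending keys.
#'
#' @param path file path.
#' @return a \linkS4class{KineticParams}.
#' @seealso [writeKineticParams()]
#' @export
readKineticParams <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) stop("expected a flat key/value mapping")
  num <- vapply(raw, function(x) as.numeric(x)[1L], numeric(1))
  kineticParams(values = {
    missing <- setdiff(.PARAM_KEYS, names(num))
    extra <- setdiff(names(num), .PARAM_KEYS)
    if (length(missing)) stop("missing parameter keys: ", paste(missing, collapse = ", "))
    if (length(extra)) stop("unknown parameter keys: ", paste(extra, collapse = ", "))
    num[.PARAM_KEYS]
  })
}

#' Write kinetic parameters to a YAML file
#'
#' @param params a \linkS4class{KineticParams}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeKineticParams <- function(params, path) {
  stopifnot(is(params, "KineticParams"))
  v <- params@values
  hdr <- c("# RhoA-Rac1 network kinetic parameters.",
           "# v*: maximal rates (1/s); k*: dimensionless Michaelis/modifier constants;",
           "# gamma*: dimensionless modifier strengths; *tot: abundances (conc. units);",
           "# p: dimensionless total PAK.")
  body <- vapply(names(v), function(k) sprintf("%s: %.12g", k, v[[k]]), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
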