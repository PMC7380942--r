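# Shared fixtures, built once per test run and cached in this environment.
# All simulations are deterministic; seeds appear only in the synthetic
# data generators.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

defaultParams <- function() fixture("kp", defaultKineticParams)

# calibrated 1-D movement-cycle run (front pacemaker + high-RhoA rear)
run1d <- function() fixture("run1d", function() {
  simulate1d(nNodes = 200, tMax = 1200, outputDt = 5)
})

# long 1-D run at full abundances, settled wave pattern
run1dLong <- function() fixture("run1dLong", function() {
  simulate1d(nNodes = 200, tMax = 4000, outputDt = 5)
})

# 1-D run under 2.5 uM Y-27632
run1dY <- function() fixture("run1dY", function() {
  simulate1d(inhibitors = inhibitorParams(y27632Dose = 2.5), nNodes = 200,
             tMax = 2000, outputDt = 5)
})

# census at the physiological point and at a bistable atlas point
censusPhys <- function() fixture("censusPhys", function() {
  findSteadyStates(defaultParams())
})
censusBistable <- function() fixture("censusBistable", function() {
  findSteadyStates(defaultParams(), localTotals = c(d = 0.4, r = 1.2))
})

# a decoupled parameter set (all regulatory interactions switched off)
decoupledParams <- function() fixture("kpDecoupled", function() {
  kineticParams(gammaDIARho = 1, gammaPAKRho = 1, gammaRhoDIA = 1,
                gammaRhoROCK = 1, gammaDIARac = 1, gammaPAKRac = 1,
                gammaROCKRac = 1, gammaRacPAK = 1)
})

# independent scalar oracle: steady state of one activation/deactivation
# balance by bisection to 1e-10
bisectBalance <- function(va, ka, vi, ki, tot, tol = 1e-10) {
  f <- function(x) va * (tot - x) / ka / (1 + (tot - x) / ka) -
    vi * (x / ki) / (1 + x / ki)
  lo <- 0; hi <- tot
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
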