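test_that("burst detection follows the threshold/refractory convention", {
  expect_length(detectBursts(rep(0.5, 200), dt = 1), 0L)
  # sinusoid of period 60 s over 600 s spanning the threshold: 10 bursts
  t <- seq(0, 600 - 1, by = 1)
  s <- 0.5 + 0.4 * sin(2 * pi * t / 60)
  expect_length(detectBursts(s, dt = 1), 10L)
  # two pulses closer than the refractory time count once
  p <- rep(0, 300)
  p[100:104] <- 1
  p[110:114] <- 1
  expect_length(detectBursts(p, dt = 1), 1L)
  p[200:204] <- 1
  expect_length(detectBursts(p, dt = 1), 2L)
  # sub-floor ripples are quiescent
  expect_length(detectBursts(0.5 + 0.01 * sin(2 * pi * t / 60), dt = 1), 0L)
})

test_that("burst counts are invariant to affine rescaling of the series", {
  t <- seq(0, 600 - 1, by = 1)
  s <- 0.5 + 0.4 * sin(2 * pi * t / 60) + 0.05 * sin(2 * pi * t / 17)
  n0 <- length(detectBursts(s, 1, minRange = 0))
  for (ab in list(c(3, 0), c(0.2, 5), c(10, -4))) {
    n <- length(detectBursts(ab[1] * s + ab[2], 1, minRange = 0))
    expect_equal(n, n0)
  }
})

test_that("region-resolved bursts reproduce the front/rear asymmetry", {
  sol <- run1d()
  w <- movementCycleWindow(sol)
  bt <- countBurstsByRegion(sol, window = w)
  counts <- setNames(bt$burstCount, bt$region)
  expect_gte(counts[["front"]], 8L)   # about one burst per minute
  expect_lte(counts[["front"]], 14L)
  expect_lte(counts[["rear"]], 2L)    # at most 1-2 bursts in 10 min
  expect_gte(counts[["front"]] / max(counts[["rear"]], 1L), 3)
  expect_error(countBurstsByRegion(sol, window = c(-100, 500)), "exceeds")
})

test_that("a spatially stationary run yields zero bursts in every region", {
  solIII <- fixture("solIII", function() {
    simulate1d(params = kineticParams(p = 0.2), nNodes = 100, tMax = 1500,
               outputDt = 10)
  })
  bt <- countBurstsByRegion(solIII, window = 600)
  expect_true(all(bt$burstCount == 0L))
})

test_that("kymographs preserve stationarity and ridge velocity", {
  solIII <- fixture("solIII", function() {
    simulate1d(params = kineticParams(p = 0.2), nNodes = 100, tMax = 1500,
               outputDt = 10)
  })
  K <- buildKymograph(solIII)
  late <- K[, ncol(K) - 0:5]
  expect_lt(max(apply(late, 1, function(z) diff(range(z)))), 1e-3)
  # synthetic travelling pulse of known speed: ridge slope recovers it
  nps <- 100; times <- seq(0, 200, 2); v <- 0.12; spacing <- 0.5
  x <- (seq_len(nps) - 0.5) * spacing
  F <- t(vapply(times, function(tt) exp(-((x - 5 - v * tt) / 3)^2),
                numeric(nps)))
  dom <- new("CellDomain", mask = matrix(TRUE, 1, nps), spacing = spacing,
             frontAtRight = TRUE)
  fields <- lapply(setNames(, c("rho", "rhod", "dia", "rock", "rac",
                                "racd", "pak")), function(k) F)
  solP <- new("SpatioTemporalSolution", times = times, fields = fields,
              coords = data.frame(row = 1L, col = seq_len(nps), x = x, y = 0.25,
                                  xfrac = seq(0, 1, length.out = nps)),
              domain = dom, profiles = list(d = rep(1, nps), r = rep(1, nps)),
              params = defaultParams(), inhibitors = inhibitorParams())
  Kp <- buildKymograph(solP)
  ridge <- attr(Kp, "x")[apply(Kp, 2, which.max)]
  fit <- coef(lm(ridge ~ attr(Kp, "time")))
  expect_equal(unname(fit[2]), v, tolerance = 0.05)
})

test_that("oscillatory center counting distinguishes mono- and multi-polar runs", {
  solIII <- fixture("solIII", function() {
    simulate1d(params = kineticParams(p = 0.2), nNodes = 100, tMax = 1500,
               outputDt = 10)
  })
  expect_equal(as.integer(countOscillatoryCenters(solIII)), 0L)
  n1 <- countOscillatoryCenters(run1dLong(), transientFrac = 0.7)
  expect_equal(as.integer(n1), 1L)
  nY <- countOscillatoryCenters(run1dY(), transientFrac = 0.6)
  expect_gte(as.integer(nY), 2L)
  # the ROCK-inhibited centers run at distinct rhythms
  cY <- attr(nY, "centers")
  expect_gt(max(cY$period) / min(cY$period), 1.02)
})

test_that("hysteresis branches coincide on a monostable ladder", {
  hm <- runHysteresisProtocol(values = seq(0.5, 0.2, -0.05), spatial = FALSE,
                              levelTime = 1200)
  dn <- hm[hm$branch == "descending", ]
  up <- hm[hm$branch == "ascending", ]
  up <- up[match(dn$control, up$control), ]
  expect_lt(max(abs(dn$meanRac - up$meanRac)), 1e-6)
  expect_lt(max(abs(dn$meanRho - up$meanRho)), 1e-6)
})

test_that("a ladder crossing the BiDR regime opens a hysteresis loop", {
  hc <- runHysteresisProtocol(values = seq(1, 0.5, -0.05), spatial = FALSE,
                              levelTime = 1200, localTotals = c(d = 1, r = 3))
  dn <- hc[hc$branch == "descending", ]
  up <- hc[hc$branch == "ascending", ]
  up <- up[match(dn$control, up$control), ]
  gap <- abs(dn$meanRac - up$meanRac)
  expect_gt(max(gap), 0.05)          # branches separate where the cycle lives
  expect_gt(sum(gap * 0.05), 0.001)  # loop area > 0
  # the descending branch carries the higher mean Rac1 (it rides the cycle)
  expect_gt(dn$meanRac[1], up$meanRac[nrow(up)] + 0.05)
})

test_that("the ramp protocol recovers the saddle-nodes of a cusp toy system", {
  # independent oracle: dx/dt = a + x - x^3 has saddle-node bifurcations
  # at a = +/- 2/(3*sqrt(3)); ramp a down then up with level chaining
  aStar <- 2 / (3 * sqrt(3))
  ladder <- seq(0.6, -0.6, by = -0.02)
  f <- function(t, y, parms) list(parms + y - y^3)
  runRamp <- function(vals, x0) {
    xs <- numeric(length(vals)); x <- x0
    for (i in seq_along(vals)) {
      sol <- deSolve::ode(y = x, times = c(0, 400), func = f, parms = vals[i],
                          method = "lsoda", rtol = 1e-9, atol = 1e-11)
      x <- sol[nrow(sol), 2]
      xs[i] <- x
    }
    xs
  }
  down <- runRamp(ladder, x0 = 1)
  up <- runRamp(rev(ladder), x0 = down[length(down)])
  jumpDown <- ladder[which(diff(down) < -1)[1] + 1L]
  jumpUp <- rev(ladder)[which(diff(up) > 1)[1] + 1L]
  expect_equal(jumpDown, -aStar, tolerance = 0.05)
  expect_equal(jumpUp, aStar, tolerance = 0.05)
})
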