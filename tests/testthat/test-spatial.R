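test_that("abundance profiles ramp DIA to the front and step ROCK at the rear", {
  dom <- new("CellDomain", mask = matrix(TRUE, 1, 50), spacing = 1,
             frontAtRight = TRUE)
  prof <- buildAbundanceProfiles(spatialProfile(), dom)
  front <- which.max(prof$xfrac); rear <- which.min(prof$xfrac)
  expect_equal(prof$d[front], 1)
  expect_equal(prof$d[rear], 0.4)
  expect_equal(prof$r[rear], 2)
  expect_equal(prof$r[front], 1)
  # the switch splits the domain at xSwitch
  expect_equal(sort(unique(prof$r)), c(1, 2))
  expect_true(all(prof$r[prof$xfrac <= 0.9] == 2))
  # homogeneous medium when the levels coincide
  ph <- buildAbundanceProfiles(spatialProfile(diaHigh = 0.7, diaLow = 0.7,
                                              rockHigh = 1.3, rockLow = 1.3), dom)
  expect_true(all(ph$d == 0.7) && all(ph$r == 1.3))
})

test_that("mask rasterization keeps one clean component and rejects two", {
  # synthetic ellipse
  mk <- generateCellMask(80, 40, "ellipse", seed = 1, roughness = 0)
  dom <- rasterizeDomain(mk, spacing = 1)
  expect_equal(sum(dom@mask), sum(mk))
  # salt noise: isolated pixels are removed, area within 1% of clean mask
  noisy <- mk
  set.seed(5)
  salt <- sample(which(!mk), 12)
  noisy[salt] <- TRUE
  dom2 <- rasterizeDomain(noisy, spacing = 1)
  expect_lt(abs(sum(dom2@mask) - sum(dom@mask)) / sum(dom@mask), 0.01)
  # two substantial blobs are an error reporting the count
  two <- matrix(FALSE, 40, 100)
  two[10:30, 5:40] <- TRUE
  two[10:30, 60:95] <- TRUE
  expect_error(rasterizeDomain(two), "2 substantial connected components")
  # teardrop orientation: wide end is the front
  td <- generateCellMask(100, 44, "teardrop", seed = 2)
  domT <- rasterizeDomain(td, spacing = 1)
  expect_true(domT@frontAtRight)
})

test_that("zero-diffusion homogeneous medium reproduces the well-mixed solution", {
  kp <- defaultParams()
  prof <- spatialProfile(diaHigh = 1, diaLow = 1 - 1e-12,
                         rockHigh = 1 + 1e-12, rockLow = 1)
  x0 <- networkState(rho = 0.3, dia = 0.2, rock = 0.2, rac = 0.3, pak = 0.05)
  sol <- simulate1d(profile = prof, params = kp,
                    diffusion = diffusionParams(0, 0, 0, 0),
                    x0 = x0, nNodes = 12, tMax = 300, outputDt = 5)
  tr <- simulateOde(kp, x0 = x0, times = solutionTimes(sol))
  rho <- solutionField(sol, "rho")
  for (j in c(1L, 6L, 12L)) {
    expect_equal(rho[, j], tr$rho, tolerance = 1e-5)
  }
  # pixels are exactly mutually identical (no coupling, same kinetics)
  expect_lt(max(abs(rho[, 1] - rho[, 12])), 1e-10)
})

test_that("a homogeneous non-oscillatory medium settles to a uniform steady state", {
  prof <- spatialProfile(diaHigh = 0.4, diaLow = 0.4 - 1e-12,
                         rockHigh = 2 + 1e-12, rockLow = 2)
  sol <- simulate1d(profile = prof, x0 = networkState(rho = 0.6, rac = 0.1),
                    nNodes = 40, tMax = 800, outputDt = 10)
  rho <- solutionField(sol, "rho")
  nt <- nrow(rho)
  expect_lt(diff(range(rho[nt, ])), 1e-6)               # uniform in space
  expect_lt(max(abs(rho[nt, ] - rho[nt - 1L, ])), 1e-6) # stationary in time
})

test_that("GTPase mass is conserved and fields stay within bounds", {
  sol <- run1d()
  for (g in c("rho", "rac")) {
    m <- gtpaseMass(sol, g)
    expect_lt(diff(range(m)) / m[1], 1e-6)
  }
  rho <- solutionField(sol, "rho"); rhod <- solutionField(sol, "rhod")
  dia <- solutionField(sol, "dia")
  expect_true(all(rho >= -1e-9) && all(rhod >= -1e-9))
  expect_true(all(dia <= max(sol@profiles$d) + 1e-9))
  pakMax <- kineticValues(sol@params)[["p"]]
  expect_true(all(solutionField(sol, "pak") <= pakMax + 1e-9))
})

test_that("activity waves travel from the front toward the rear", {
  sol <- run1dLong()
  tt <- solutionTimes(sol)
  keep <- tt >= 2500
  rho <- solutionField(sol, "rho")[keep, ]
  xf <- sol@coords$xfrac
  # sample positions inside the oscillatory zone, front to body
  pos <- vapply(c(0.95, 0.85, 0.75, 0.65, 0.55), function(x0) {
    which.min(abs(xf - x0))
  }, integer(1))
  lags <- vapply(seq_len(length(pos) - 1L), function(i) {
    cc <- stats::ccf(rho[, pos[i]], rho[, pos[i + 1L]], lag.max = 6,
                     plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }, numeric(1))
  expect_true(all(lags != 0))
  expect_equal(length(unique(sign(lags))), 1L)
})

test_that("reduced PAK pins the wave; strong reduction is uniformly high-RhoA", {
  # point II: stalled wave with stationary profiles and Rac1 at the front
  kpII <- kineticParams(p = 0.55)
  solII <- fixture("solII", function() {
    simulate1d(params = kpII, nNodes = 100, tMax = 2500, outputDt = 10)
  })
  rho <- solutionField(solII, "rho"); rac <- solutionField(solII, "rac")
  nt <- nrow(rho)
  expect_lt(max(abs(rho[nt, ] - rho[nt - 2L, ])), 1e-3)
  xf <- solII@coords$xfrac
  expect_gt(mean(rac[nt, xf > 0.9]), 2 * mean(rac[nt, xf < 0.2]))
  # point III: high RhoA and low Rac1 along the entire cell
  kpIII <- kineticParams(p = 0.2)
  solIII <- fixture("solIII", function() {
    simulate1d(params = kpIII, nNodes = 100, tMax = 1500, outputDt = 10)
  })
  rho3 <- solutionField(solIII, "rho")[nrow(solutionField(solIII, "rho")), ]
  rac3 <- solutionField(solIII, "rac")[nrow(solutionField(solIII, "rac")), ]
  expect_gt(min(rho3), 0.4)
  expect_lt(max(rac3), 0.35)
})

test_that("doubling the grid leaves the stationary profile nearly unchanged", {
  kp <- kineticParams(p = 0.55)
  s1 <- fixture("solII", function() {
    simulate1d(params = kp, nNodes = 100, tMax = 2500, outputDt = 10)
  })
  s2 <- fixture("solII200", function() {
    simulate1d(params = kp, nNodes = 200, tMax = 2500, outputDt = 10)
  })
  p1 <- solutionField(s1, "rho")[251, ]
  p2 <- solutionField(s2, "rho")[251, ]
  x1 <- s1@coords$xfrac; x2 <- s2@coords$xfrac
  p2i <- approx(x2, p2, xout = x1)$y
  expect_lt(max(abs(p1 - p2i)), 0.02 * max(abs(p1)))
})

test_that("non-admissible spatial inputs are rejected", {
  expect_error(spatialProfile(diaHigh = 0.2, diaLow = 0.4), "diaHigh")
  expect_error(spatialProfile(xSwitch = 1.2), "xSwitch")
  expect_error(diffusionParams(dRhoActive = 5, dRhoInactive = 1), "inactive")
  expect_error(rasterizeDomain(matrix(FALSE, 10, 10)), "no foreground")
})
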