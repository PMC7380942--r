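test_that("hyperbolic modifier matches hand evaluation and bounds", {
  expect_equal(modifierAlpha(1, gamma = 2, k = 1), 1.5)
  expect_equal(modifierAlpha(0, gamma = 5, k = 0.3), 1)
  expect_equal(modifierAlpha(0.7, gamma = 1, k = 0.2), 1)
  # bounds and monotonicity over a grid of modifier settings
  for (gamma in c(0.05, 0.4, 1, 2.5, 8)) {
    for (k in c(0.05, 0.3, 2)) {
      a <- seq(0, 5, length.out = 120)
      v <- modifierAlpha(a, gamma, k)
      expect_true(all(v >= min(1, gamma) - 1e-12 & v <= max(1, gamma) + 1e-12))
      expect_true(all(diff(v) * sign(gamma - 1) >= -1e-12))
    }
  }
  expect_error(modifierAlpha(-0.1, 2, 1), "non-negative")
  expect_error(modifierAlpha(Inf, 2, 1), "finite")
  expect_error(modifierAlpha(1, -2, 1), "positive")
})

test_that("ROCK inhibition multiplier follows the competitive-binding form", {
  expect_equal(rockInhibitionBeta(inhibitorParams()), 1)
  # ATP = Kd and dose = K_I gives beta = 2/3
  inh <- inhibitorParams(y27632Dose = 0.1, kIROCK = 0.1, atp = 300, kdATP = 300)
  expect_equal(rockInhibitionBeta(inh), 2 / 3)
  # strictly decreasing in dose, towards 0
  doses <- c(0, 0.1, 0.5, 2, 10, 1e5)
  betas <- vapply(doses, function(dd) {
    rockInhibitionBeta(inhibitorParams(y27632Dose = dd))
  }, numeric(1))
  expect_true(all(diff(betas) < 0))
  expect_lt(betas[length(betas)], 1e-3)
})

test_that("IPA-3 scales only the PAK activation constant", {
  kp <- defaultParams()
  expect_equal(kineticValues(applyPakInhibitor(kp, inhibitorParams())),
               kineticValues(kp))
  inh <- inhibitorParams(ipa3Dose = 2.5, kIPAK = 2.5)
  kp2 <- applyPakInhibitor(kp, inh)
  v1 <- kineticValues(kp); v2 <- kineticValues(kp2)
  expect_equal(v2[["kaPAK"]], 2 * v1[["kaPAK"]])
  other <- setdiff(names(v1), "kaPAK")
  expect_equal(v2[other], v1[other])
})

test_that("steady-state PAK activity decreases monotonically with IPA-3 dose", {
  kp <- defaultParams()
  # monostable configuration: low-DIA / high-ROCK rear corner
  pakSS <- vapply(c(0, 1, 2.5, 5, 10), function(dose) {
    inh <- inhibitorParams(ipa3Dose = dose)
    tr <- simulateOde(kp, inh, x0 = networkState(rho = 0.7, rac = 0.05),
                      times = seq(0, 3000, 10), localTotals = c(d = 0.4, r = 2))
    tr$pak[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(pakSS) < 1e-6))
})

test_that("per-GTPase conservation holds identically in the right-hand side", {
  kp <- defaultParams()
  set.seed(42)
  for (i in 1:25) {
    s <- networkState(rho = runif(1), dia = runif(1, 0, 1),
                      rock = runif(1, 0, 1), rac = runif(1),
                      pak = runif(1, 0, 1))
    f <- odeRhs(s, kp)
    expect_identical(f[["rho"]] + f[["rhod"]], 0)
    expect_identical(f[["rac"]] + f[["racd"]], 0)
  }
})

test_that("the vector field points inward on the admissible boundary", {
  kp <- defaultParams()
  set.seed(7)
  for (i in 1:20) {
    base <- c(rho = runif(1, 0.05, 0.95), dia = runif(1, 0.05, 0.95),
              rock = runif(1, 0.05, 0.95), rac = runif(1, 0.05, 0.95),
              pak = runif(1, 0.05, 0.95))
    for (k in seq_along(base)) {
      for (edge in c(0, 1)) {
        s <- base; s[k] <- edge
        st <- networkState(rho = s[["rho"]], dia = s[["dia"]],
                           rock = s[["rock"]], rac = s[["rac"]],
                           pak = s[["pak"]])
        f <- odeRhs(st, kp)
        der <- f[[names(base)[k]]]
        if (edge == 0) expect_gte(der, 0) else expect_lte(der, 0)
      }
    }
  }
})

test_that("fully extreme states relax: active pool at 1 must decay", {
  f <- odeRhs(networkState(rho = 1, rac = 0.5), defaultParams())
  expect_lt(f[["rho"]], 0)
  f2 <- odeRhs(networkState(rho = 0.5, rac = 1), defaultParams())
  expect_lt(f2[["rac"]], 0)
})

test_that("decoupled network steady state equals independent scalar balances", {
  kp <- decoupledParams()
  v <- kineticValues(kp)
  cen <- findSteadyStates(kp)
  expect_equal(nrow(cen@states), 1L)
  oracle <- c(
    rho = bisectBalance(v[["vGEFRho"]], v[["kGEFRho"]], v[["vGAPRho"]], v[["kGAPRho"]], 1),
    dia = bisectBalance(v[["vaDIA"]], v[["kaDIA"]], v[["viDIA"]], v[["kiDIA"]], 1),
    rock = bisectBalance(v[["vaROCK"]], v[["kaROCK"]], v[["viROCK"]], v[["kiROCK"]], 1),
    rac = bisectBalance(v[["vGEFRac"]], v[["kGEFRac"]], v[["vGAPRac"]], v[["kGAPRac"]], 1),
    pak = bisectBalance(v[["vaPAK"]], v[["kaPAK"]], v[["viPAK"]], v[["kiPAK"]], v[["p"]]))
  expect_equal(unname(cen@states[1, names(oracle)]), unname(oracle),
               tolerance = 1e-7)
  # scalar gradient-like dynamics cannot oscillate
  cyc <- detectLimitCycle(kp, census = cen, tMax = 4000)
  expect_false(cyc$exists)
})

test_that("trajectories stay in the admissible box and park at steady states", {
  kp <- defaultParams()
  # started exactly at a root of the rear corner, the trajectory is flat
  cen <- findSteadyStates(kp, localTotals = c(d = 0.4, r = 2))
  st <- cen@states[1, ]
  tr <- simulateOde(kp, x0 = networkState(rho = st[["rho"]], dia = st[["dia"]],
                                          rock = st[["rock"]], rac = st[["rac"]],
                                          pak = st[["pak"]]),
                    times = seq(0, 500, 1), localTotals = c(d = 0.4, r = 2))
  expect_lt(max(abs(tr$rho - st[["rho"]])), 1e-5)
  # a generic trajectory respects positivity and the totals
  tr2 <- simulateOde(kp, times = seq(0, 2000, 1))
  expect_true(all(tr2$rho >= -1e-9 & tr2$rho <= 1 + 1e-9))
  expect_true(all(tr2$pak <= kineticValues(kp)[["p"]] + 1e-9))
  expect_true(all(tr2$dia >= -1e-9))
})

test_that("oscillations at full abundances have stationary amplitude", {
  tr <- simulateOde(defaultParams(), times = seq(0, 4000, 2))
  half1 <- tr$rho[tr$time > 2000 & tr$time <= 3000]
  half2 <- tr$rho[tr$time > 3000]
  expect_gt(diff(range(half2)), 0.2)
  expect_equal(diff(range(half1)), diff(range(half2)), tolerance = 0.05)
})

test_that("tightening solver tolerances shrinks trajectory differences", {
  kp <- defaultParams()
  x0 <- networkState(rho = 0.3, rac = 0.3, pak = 0.05)
  times <- seq(0, 300, 1)
  ref <- simulateOde(kp, x0 = x0, times = times, rtol = 1e-11, atol = 1e-13)
  errs <- vapply(c(1e-4, 1e-6, 1e-8), function(rt) {
    tr <- simulateOde(kp, x0 = x0, times = times, rtol = rt, atol = rt * 1e-2)
    max(abs(tr$rho - ref$rho))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 50)
})

test_that("effector complex: linear and exact variants agree in their regime", {
  # kd -> 0 saturates the effector
  expect_equal(effectorComplexFraction(2, 5, 1e-12), 2, tolerance = 1e-9)
  expect_equal(effectorComplexFraction(2, 500, 1, "linear"), 2, tolerance = 1e-2)
  # exact never exceeds either pool
  expect_lte(effectorComplexFraction(2, 0.5, 0.3, "exact"), 0.5)
  # at 10-fold GTPase excess and small kd the linearization errs < 10%
  rhoT <- 25; eff <- 2.5; kd <- rhoT / 100
  lin <- effectorComplexFraction(eff, rhoT, kd, "linear")
  exa <- effectorComplexFraction(eff, rhoT, kd, "exact")
  expect_lt(abs(lin - exa) / exa, 0.10)
  # independent oracle: solve the mass-action relation (E-c)(R-c) = kd*c
  cplx <- uniroot(function(cc) (eff - cc) * (rhoT - cc) - kd * cc,
                  c(0, min(eff, rhoT)), tol = 1e-12)$root
  expect_equal(exa, cplx, tolerance = 1e-9)
})

test_that("parameter objects validate their invariants", {
  expect_error(kineticParams(vGEFRho = -1), "positive")
  expect_error(kineticParams(gammaPAKRho = 2), "gammaPAKRho")
  expect_error(kineticParams(DIAtot = 10), "10-fold")
  expect_error(kineticParams(nonsense = 1), "unknown")
  expect_error(inhibitorParams(ipa3Dose = -1), "non-negative")
  st <- networkState(rho = 0.3)
  expect_equal(stateValues(st)[["rhod"]], 0.7)
})

test_that("parameter files round-trip and reject malformed keys", {
  kp <- kineticParams(vGEFRho = 0.1234)
  path <- tempfile(fileext = ".yaml")
  writeKineticParams(kp, path)
  kp2 <- readKineticParams(path)
  expect_equal(kineticValues(kp2), kineticValues(kp))
  # unknown key
  writeLines(c(readLines(path), "bogus: 1"), path)
  expect_error(readKineticParams(path), "bogus")
  # missing key
  lines <- readLines(path)
  writeLines(lines[!grepl("^vGAPRac|^bogus", lines)], path)
  expect_error(readKineticParams(path), "vGAPRac")
})
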