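test_that("the physiological point has a single unstable focus and a cycle", {
  cen <- censusPhys()
  expect_equal(nrow(cen@states), 1L)
  expect_equal(cen@type, "unstable focus")
  expect_lt(max(cen@residual), 1e-9)
  cyc <- detectLimitCycle(defaultParams(), census = cen, tMax = 6000)
  expect_true(cyc$exists)
  expect_gt(cyc$period, 20)
  expect_lt(cyc$period, 200)
  expect_gt(cyc$amplitude[["rho"]], 0.2)
})

test_that("a bistable atlas point has exactly two stable steady states", {
  cen <- censusBistable()
  expect_equal(nrow(cen@states), 3L)
  expect_equal(sum(grepl("^stable", cen@type)), 2L)
  expect_equal(sum(cen@type == "saddle"), 1L)
})

test_that("the low-DIA/high-ROCK rear corner holds high RhoA and low Rac1", {
  cen <- findSteadyStates(defaultParams(), localTotals = c(d = 0.4, r = 2))
  stable <- which(grepl("^stable", cen@type))
  expect_gte(length(stable), 1L)
  expect_gt(cen@states[stable[1], "rho"], 0.4)
  expect_lt(cen@states[stable[1], "rac"], 0.3)
  cyc <- detectLimitCycle(defaultParams(), localTotals = c(d = 0.4, r = 2),
                          census = cen, tMax = 6000)
  expect_false(cyc$exists)
})

test_that("raising ROCK at fixed DIA leads from oscillation to the BiDR regime", {
  cen3 <- findSteadyStates(defaultParams(), localTotals = c(d = 1, r = 3))
  expect_equal(nrow(cen3@states), 3L)
  expect_true("unstable focus" %in% cen3@type)
  expect_true("saddle" %in% cen3@type)
  node <- which(cen3@type == "stable node")
  expect_equal(length(node), 1L)
  # the coexisting steady state has high RhoA and low Rac1
  expect_gt(cen3@states[node, "rho"], 0.4)
  expect_lt(cen3@states[node, "rac"], 0.3)
  cyc <- detectLimitCycle(defaultParams(), localTotals = c(d = 1, r = 3),
                          census = cen3, tMax = 6000)
  expect_true(cyc$exists)
  expect_equal(classifyRegime(cen3, cyc$exists), 3L)
})

test_that("regime classification follows the census taxonomy", {
  mkCensus <- function(types, racs = NULL) {
    n <- length(types)
    states <- matrix(runif(5 * n), n, 5,
                     dimnames = list(NULL, c("rho", "dia", "rock", "rac", "pak")))
    if (!is.null(racs)) states[, "rac"] <- racs
    ev <- lapply(types, function(ty) switch(ty,
      "stable focus" = c(-0.1 + 0.2i, -0.1 - 0.2i, -1, -1, -1),
      "stable node" = c(-0.1, -0.2, -1, -1, -1),
      "unstable focus" = c(0.1 + 0.2i, 0.1 - 0.2i, -1, -1, -1),
      "saddle" = c(0.1, -0.2, -1, -1, -1),
      "unstable node" = c(0.1, 0.2, -1, -1, -1)))
    new("SteadyStateCensus", states = states, eigenvalues = ev,
        type = types, residual = rep(1e-12, n))
  }
  expect_equal(classifyRegime(mkCensus("stable focus"), FALSE), 0L)
  expect_equal(classifyRegime(mkCensus("unstable focus"), TRUE), 1L)
  expect_equal(classifyRegime(
    mkCensus(c("unstable focus", "saddle", "stable node")), FALSE), 2L)
  expect_equal(classifyRegime(
    mkCensus(c("unstable focus", "saddle", "stable node")), TRUE), 3L)
  expect_equal(classifyRegime(
    mkCensus(c("stable focus", "saddle", "stable node")), FALSE), 4L)
  expect_equal(classifyRegime(
    mkCensus(c("stable node", "unstable focus", "saddle"), racs = c(0.9, 0.5, 0.5)),
    FALSE), 5L)
  expect_equal(classifyRegime(mkCensus("stable node"), FALSE), 6L)
  expect_equal(classifyRegime(
    mkCensus(c("stable node", "stable node", "saddle", "saddle",
               "unstable focus")), FALSE), 7L)
  expect_equal(classifyRegime(
    mkCensus(c("stable node", "stable node", "saddle")), FALSE), 8L)
  # unmatched census is flagged, never guessed
  un <- classifyRegime(mkCensus(c("unstable node", "saddle")), FALSE)
  expect_true(is.na(un))
  expect_match(attr(un, "diagnostic"), "unclassified")
})

test_that("classified stability agrees with perturbed long integration", {
  kp <- defaultParams()
  pts <- list(c(0.4, 2), c(1, 3), c(0.4, 1.2), c(1, 1))
  for (pt in pts) {
    cen <- findSteadyStates(kp, localTotals = c(d = pt[1], r = pt[2]))
    for (i in seq_len(nrow(cen@states))) {
      ty <- cen@type[i]
      if (ty == "saddle" || ty == "borderline") next
      st <- cen@states[i, ]
      x0 <- pmin(pmax(st * 1.01 + 0.002, 1e-6),
                 c(1, pt[1], pt[2], 1, kineticValues(kp)[["p"]]) - 1e-6)
      tr <- simulateOde(kp, x0 = networkState(rho = x0[1], dia = x0[2],
                                              rock = x0[3], rac = x0[4],
                                              pak = x0[5]),
                        times = seq(0, 3000, 5),
                        localTotals = c(d = pt[1], r = pt[2]))
      endDev <- sqrt(sum((c(tr$rho[nrow(tr)], tr$rac[nrow(tr)]) -
                          st[c("rho", "rac")])^2))
      if (grepl("^stable", ty)) {
        expect_lt(endDev, 0.02)
      } else {
        maxDev <- max(sqrt((tr$rho - st[["rho"]])^2 + (tr$rac - st[["rac"]])^2))
        expect_gt(maxDev, 0.05)
      }
    }
  }
})

test_that("a coarse DIA-ROCK scan reproduces the regime geography", {
  map <- scanBifurcationPlane(defaultParams(),
                              range1 = c(0.5, 1.5), range2 = c(0.5, 1.5),
                              resolution = 3, cycleTMax = 6000)
  # centre point (1, 1) is the oscillatory physiological point
  expect_equal(map@labels[2, 2], 1L)
  tab <- regimeMapTable(map)
  expect_equal(nrow(tab), 9L)
  expect_true(all(c("DIAtot", "ROCKtot", "label", "cycle") %in% names(tab)))
  # determinism: identical inputs give identical maps
  map2 <- scanBifurcationPlane(defaultParams(),
                               range1 = c(0.5, 1.5), range2 = c(0.5, 1.5),
                               resolution = 3, cycleTMax = 6000)
  expect_identical(map@labels, map2@labels)
  expect_identical(map@limitCycle, map2@limitCycle)
})

test_that("cycles coexist only with regime 1 and 3 census patterns", {
  map <- fixture("mapRock", function() {
    scanBifurcationPlane(defaultParams(), axis1 = "DIAtot", axis2 = "ROCKtot",
                         range1 = c(1, 1), range2 = c(0.5, 3.5),
                         resolution = c(1, 4), cycleTMax = 6000)
  })
  cyc <- which(map@limitCycle)
  expect_gt(length(cyc), 0L)
  expect_true(all(map@labels[cyc] %in% c(1L, 3L)))
})

test_that("a branch trace across the oscillation boundary brackets the Hopf point", {
  kp <- defaultParams()
  br <- traceBranch(kp, axis = "DIAtot", range = c(0.35, 1), resolution = 6,
                    fixed = c(ROCKtot = 1), cycleTMax = 6000)
  # low-DIA end is non-oscillatory, high-DIA end oscillates
  lo <- br[br$value == min(br$value), ]
  hi <- br[br$value == max(br$value), ]
  expect_false(any(lo$cycle))
  expect_true(all(hi$cycle))
  expect_true(all(is.finite(hi$cycleMaxRho)))
  bif <- attr(br, "bifurcations")
  expect_gte(nrow(bif), 1L)
  # Hopf consistency: the leading eigenvalue real part changes sign across
  # the bracketing interval that contains the 0 <-> 1 transition
  leadRe <- function(d) {
    cen <- findSteadyStates(kp, localTotals = c(d = d, r = 1))
    max(vapply(cen@eigenvalues, function(ev) max(Re(ev)), numeric(1)))
  }
  crossed <- any(apply(bif, 1L, function(iv) leadRe(iv[1]) * leadRe(iv[2]) < 0))
  expect_true(crossed)
})

test_that("a constant ray yields constant labels, matching a degenerate scan", {
  br <- traceBranch(defaultParams(), axis = "ROCKtot", range = c(1, 1),
                    resolution = 3, fixed = c(DIAtot = 1), cycleTMax = 6000)
  expect_equal(length(unique(br$label)), 1L)
  map <- fixture("mapDegenerate", function() {
    scanBifurcationPlane(defaultParams(), range1 = c(1, 1), range2 = c(1, 1),
                         resolution = c(1, 3), cycleTMax = 6000)
  })
  expect_true(all(map@labels == br$label[1]))
})
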