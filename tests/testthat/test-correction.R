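# Probe-set MLE, the two adjustment modes, and degradation-limit fitting.

test_that("the IPS estimator reproduces worked cases exactly", {
  expect_equal(estimateIps(c(4, 6, 8), c(1, 1, 1))$ips, 6)   # reduces to mean
  expect_equal(estimateIps(c(10, 5), c(1, 0.5))$ips, 10)     # (10+2.5)/1.25
  # noise-free model data: exact fit, zero residual scale
  p <- c(0.1, 0.4, 0.8, 1)
  fit <- estimateIps(250 * p, p)
  expect_equal(fit$ips, 250)
  expect_equal(fit$residualScale, 0)
  expect_identical(fit$flag, "ok")
  # negative estimates are clamped and flagged
  neg <- estimateIps(c(-4, -2), c(1, 0.5))
  expect_identical(neg$ips, 0)
  expect_identical(neg$flag, "clamped_negative")
})

test_that("the closed form equals an independent least-squares minimizer", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:15, 1)
    p <- runif(n, 0.05, 1)
    pm <- runif(n, 0, 500)
    ips <- estimateIps(pm, p)$ips
    viaQr <- unname(stats::lm.fit(matrix(p), pm)$coefficients)
    expect_equal(ips, max(viaQr, 0), tolerance = 1e-9)
    obj <- function(c) sum((pm - c * p)^2)
    viaOpt <- stats::optimize(obj, c(0, 2000), tol = 1e-10)$minimum
    expect_equal(ips, viaOpt, tolerance = 1e-6)
  }
})

test_that("invert mode divides by the floored retaining rate", {
  # cycle-1 curve gives known rates: p1(150) = 0.5, p1(3) = 0.01
  tab <- makeProbeTable(z = c(150, 3, 500, 600), pm = c(50, 50, 80, 90))
  adj <- adjustProbes(tab, fixtureCurve1, mode = "invert", pFloor = 0.05)
  expect_equal(adj$pm_adj[1], 100)          # 50 / 0.5
  expect_equal(adj$pm_adj[2], 1000)         # 50 / floor 0.05
  expect_equal(adj$pm_adj[3:4], c(80, 90))  # plateau, p = 1
  expect_identical(attr(adj, "mode"), "invert")
})

test_that("mle-residual mode restores lost signal without scaling noise", {
  # noise-free probes: both modes recover the ideal intensity exactly
  z <- c(350, 450, 550, 650)
  p <- p1RetainingRate(z, fixtureParams)   # all 1 on the plateau
  tab <- makeProbeTable(z = z, pm = 120 * p)
  for (mode in c("mle-residual", "invert")) {
    adj <- adjustProbes(tab, fixtureCurve1, mode = mode)
    expect_equal(adj$pm_adj, tab$pm, info = mode)  # p = 1: identity
  }
  z2 <- c(60, 150, 240, 500)
  p2 <- p1RetainingRate(z2, fixtureParams)
  tab2 <- makeProbeTable(z = z2, pm = 120 * p2)
  adj2 <- adjustProbes(tab2, fixtureCurve1, mode = "mle-residual")
  expect_equal(adj2$pm_adj, rep(120, 4))
  expect_equal(unique(adj2$ips), 120)
})

test_that("MM intensities are adjusted with the same retaining rates", {
  z <- c(150, 500, 600)
  tab <- makeProbeTable(z = z, pm = c(50, 80, 90), mm = c(10, 8, 6))
  adj <- adjustProbes(tab, fixtureCurve1, mode = "invert")
  expect_equal(adj$mm_adj, c(10 / 0.5, 8, 6))
})

test_that("adjustment never produces negative intensities on valid input", {
  adj <- adjustProbes(smallSim$probes, fixtureCurve2, mode = "mle-residual")
  expect_true(all(adj$pm_adj >= 0))
  inv <- adjustProbes(smallSim$probes, fixtureCurve2, mode = "invert")
  expect_true(all(inv$pm_adj >= 0))
  expect_error(adjustProbes(smallSim$probes, fixtureCurve2, mode = "scale"))
})

test_that("probe sets without usable retaining rates pass through flagged", {
  # all probes within 10 bp of the 3' end: p2 below any sensible floor
  low <- makeProbeTable(z = c(2, 5, 8), pm = c(40, 50, 60),
                        probeset = "psLow")
  mix <- rbind(low, makeProbeTable(z = c(400, 500, 2, 3), pm = c(90, 80, 10, 10),
                                   probeset = "psTwo"))
  adj <- adjustProbes(mix, fixtureCurve2, pFloor = 0.05)
  expect_identical(unique(adj$flag[adj$probeset_id == "psLow"]),
                   "uncorrectable")
  expect_identical(adj$pm_adj[adj$probeset_id == "psLow"], low$pm)
  # 2 probes above the floor: passed through with the low-count flag
  expect_identical(unique(adj$flag[adj$probeset_id == "psTwo"]),
                   "low_p_passthrough")
  expect_identical(adj$pm_adj[adj$probeset_id == "psTwo"],
                   mix$pm[mix$probeset_id == "psTwo"])
})

test_that("a zero-residual profile recovers its own grid point", {
  # probes whose mean profile is exactly c * p2(z) for (a, b) = (300, 200)
  crv10 <- retainingRateCurve(fixtureParams, 2, gridStep = 10, quadStep = 2)
  z <- 12:577
  tab <- makeProbeTable(z = z, pm = 7 * retainingRate(crv10, z))
  fit <- fitDegradationLimits(tab, L = 1000, aGrid = c(250, 300, 350),
                              bGrid = c(150, 200, 250))
  expect_equal(degLimit3p(fit$params), 300)
  expect_equal(degLimit5p(fit$params), 200)
  expect_equal(fit$scale, 7 / mean(tab$pm), tolerance = 1e-6)
  expect_lt(min(fit$sse$sse), 1e-10)
  # search grid is ordered smaller-a-then-smaller-b; first minimum wins
  expect_false(is.unsorted(fit$sse$a))
  fitDup <- fitDegradationLimits(tab, L = 1000, aGrid = 300,
                                 bGrid = c(200, 200))
  expect_equal(nrow(fitDup$sse), 2)
  expect_equal(degLimit5p(fitDup$params), 200)
})

test_that("degradation limits are recovered from synthetic data", {
  sim <- generateProbeData(syntheticSpec(nProbeSets = 8000, seed = 3),
                           curve = fixtureCurve2)
  fit <- fitDegradationLimits(sim$probes, L = 1000)
  expect_lte(abs(degLimit3p(fit$params) - 300), 50)  # one grid step
  expect_lte(abs(degLimit5p(fit$params) - 200), 50)
})

test_that("IPS recovery under proportional probe noise is accurate", {
  sim <- generateProbeData(syntheticSpec(nProbeSets = 2000, seed = 8,
                                         noiseModel = "proportional"),
                           curve = fixtureCurve2)
  adj <- adjustProbes(sim$probes, fixtureCurve2)
  key <- !duplicated(adj$probeset_id)
  relErr <- abs(adj$ips[key] - sim$truth$ips_true[key]) /
    sim$truth$ips_true[key]
  expect_lt(median(relErr), 0.05)
})

test_that("fit diagnostics catch empty windows and flat profiles", {
  tab <- makeProbeTable(z = c(700, 800), pm = c(1, 2))
  expect_error(fitDegradationLimits(tab, L = 1000), "window")
  flat <- makeProbeTable(z = 100:150, pm = rep(5, 51))
  expect_error(fitDegradationLimits(flat, L = 1000), "flat")
})
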