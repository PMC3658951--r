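# Endpoint-shortening process: closed-form cycle-1 rate, joint endpoint CDF,
# trajectory sampling, and the quadrature/Monte-Carlo cycle-2 rate.

test_that("p1 matches the piecewise closed form on a dense grid", {
  z <- seq(0, 1000, by = 0.5)
  expect_equal(p1RetainingRate(z, fixtureParams),
               p1Oracle(z, 1000, 300, 200), tolerance = 1e-15)
  # worked points: ramp, plateau, far edge
  expect_identical(p1RetainingRate(550, fixtureParams), 1)
  expect_identical(p1RetainingRate(0, fixtureParams), 0)
  expect_equal(p1RetainingRate(150, fixtureParams), 0.5)
  expect_identical(p1RetainingRate(1000, fixtureParams), 0)
  # continuity at both breakpoints
  eps <- 1e-9
  expect_equal(p1RetainingRate(300 - eps, fixtureParams),
               p1RetainingRate(300 + eps, fixtureParams), tolerance = 1e-8)
  expect_equal(p1RetainingRate(800 - eps, fixtureParams),
               p1RetainingRate(800 + eps, fixtureParams), tolerance = 1e-8)
})

test_that("short transcripts (a + b >= L) warn and use the product form", {
  expect_warning(p <- degradationParams(100, 80, 50), "a \\+ b >= L")
  z <- seq(0, 100, by = 1)
  expect_equal(p1RetainingRate(z, p),
               pmin(z / 80, 1) * pmin((100 - z) / 50, 1))
  # the product form reduces to the piecewise form in the standard regime
  expect_equal(p1RetainingRate(z * 10, fixtureParams),
               p1Oracle(z * 10, 1000, 300, 200))
})

test_that("cycle-1 joint CDF obeys CDF laws and clamped evaluation", {
  p <- fixtureParams
  expect_identical(jointCdfCycle1(300, 1000, p), 1)
  expect_identical(jointCdfCycle1(150, 800, p), 0)
  expect_equal(jointCdfCycle1(150, 900, p), 0.25)
  # monotone in each argument
  xs <- seq(0, 300, by = 10)
  ys <- seq(800, 1000, by = 10)
  expect_true(all(diff(jointCdfCycle1(xs, 950, p)) >= 0))
  expect_true(all(diff(jointCdfCycle1(120, ys, p)) >= 0))
  # out-of-support arguments clamp per CDF semantics
  expect_identical(jointCdfCycle1(-5, 900, p), 0)
  expect_identical(jointCdfCycle1(400, 1200, p), 1)
})

test_that("trajectories satisfy the pathwise invariants and are reproducible", {
  tr <- sampleTrajectories(fixtureParams, 2000, seed = 7)
  expect_true(all(tr$A1 >= 0 & tr$A1 <= 300))
  expect_true(all(tr$B1 >= 800 & tr$B1 <= 1000))
  expect_identical(tr$A2, tr$A1)
  expect_true(all(tr$B2 >= tr$A1 & tr$B2 <= tr$B1))
  expect_true(all(tr$A3 >= tr$A2 & tr$A3 <= tr$A2 + 300))
  expect_true(all(tr$B3 >= tr$B2 - 200 & tr$B3 <= tr$B2))
  expect_identical(tr, sampleTrajectories(fixtureParams, 2000, seed = 7))
  # mean of A1 ~ U[0, a] is a/2, within 3 standard errors
  big <- sampleTrajectories(fixtureParams, 1e5, seed = 1)
  se <- 300 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(big$A1) - 150), 3 * se)
  # fully degraded products are retained, not resampled
  expect_gte(mean(big$B3 < big$A3), 0)
})

test_that("quadrature p2 agrees with the Monte-Carlo oracle", {
  z <- seq(0, 1000, by = 50)
  q <- p2RetainingRate(z, fixtureParams, "quadrature", step = 1)
  n <- 2e5
  m <- p2RetainingRate(z, fixtureParams, "monte-carlo", n = n, seed = 11)
  se <- sqrt(pmax(m * (1 - m), 1 / n) / n)
  expect_true(all(abs(q - m) <= 3 * se + 1e-7))
})

test_that("p2 is dominated by p1, vanishes at both transcript ends", {
  z <- curveGrid(fixtureCurve2)
  p2 <- curveValues(fixtureCurve2)
  p1 <- p1RetainingRate(z, fixtureParams)
  expect_true(all(p2 <= p1 + 1e-9))
  expect_true(all(p1 <= 1))
  expect_equal(p2[z == 0], 0)
  expect_equal(p2[z == 1000], 0)
  expect_lt(p2RetainingRate(1000, fixtureParams, "monte-carlo",
                            n = 1e4, seed = 2), 1e-3)
})

test_that("as a, b -> 0 only random-primer truncation remains: p2 -> 1 - z/L", {
  # z = 0 is excluded: p2(0) = 0 for every a > 0 (the 3' end never survives)
  p <- degradationParams(1000, 1, 1)
  z <- seq(5, 1000, by = 25)
  expect_lt(max(abs(p2RetainingRate(z, p, step = 0.5) - (1 - z / 1000))),
            0.02)
})

test_that("curve tabulation is faithful, deterministic, and refinement-stable", {
  expect_equal(curveValues(fixtureCurve1),
               p1RetainingRate(curveGrid(fixtureCurve1), fixtureParams))
  # Monte-Carlo curves with identical seed are identical
  c1 <- retainingRateCurve(fixtureParams, 2, gridStep = 100,
                           method = "monte-carlo", n = 1e4, seed = 5)
  c2 <- retainingRateCurve(fixtureParams, 2, gridStep = 100,
                           method = "monte-carlo", n = 1e4, seed = 5)
  expect_identical(curveValues(c1), curveValues(c2))
  # halving the tabulation step moves interpolated values by < 0.01
  fine <- retainingRateCurve(fixtureParams, 2, gridStep = 2.5, quadStep = 2)
  z <- seq(0, 1000, by = 1)
  expect_lt(max(abs(retainingRate(fixtureCurve2, z) -
                      retainingRate(fine, z))), 0.01)
})

test_that("domain and parameter validation is enforced", {
  expect_error(p1RetainingRate(-1, fixtureParams), "\\[0, L\\]")
  expect_error(p1RetainingRate(1001, fixtureParams), "\\[0, L\\]")
  expect_error(new("DegradationParams", L = -1, a = 300, b = 200))
  expect_error(degradationParams(1000, 0, 200))
  expect_warning(shortP <- degradationParams(400, 300, 200))
  expect_error(p2RetainingRate(100, shortP), "a \\+ b < L")
  expect_error(retainingRate(fixtureCurve2, 2000), "\\[0, L\\]")
})
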