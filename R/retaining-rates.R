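# Three-stage endpoint-shortening process of two-cycle IVT amplification.
#
# A transcript occupies [0, L], position measured from the 3' end. The two
# labeling cycles shorten it three times:
#   (1) IVT degradation, cycle 1:  A1 ~ U[0, a],        B1 ~ U[L - b, L]
#   (2) random-primer truncation:  A2 = A1,             B2 ~ U[A1, B1]
#   (3) IVT degradation, cycle 2:  A3 ~ A2 + U[0, a],   B3 ~ B2 - U[0, b]
# The cycle-j retaining rate p_j(z) = P(A_{2j-1} <= z <= B_{2j-1}) is the
# probability that position z is still covered after cycle j.

# run expr with a local RNG seed, restoring global RNG state afterwards
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.checkParams <- function(params) {
  stopifnot(is(params, "DegradationParams"))
  validObject(params)
  invisible(params)
}

.checkZ <- function(z, L) {
  if (any(!is.finite(z)) || any(z < 0) || any(z > L))
    stop("position z must lie in [0, L] = [0, ", L, "]")
  invisible(z)
}

#' First-cycle retaining rate p1(z)
#'
#' Probability that position z (bp from the 3' end) survives the first IVT
#' degradation: p1(z) = P(A1 <= z <= B1) with A1 ~ U[0, a] and B1 ~ U[L-b, L]
#' independent. In the standard regime a + b < L this is the piecewise-linear
#' ramp z/a on [0, a], 1 on (a, L-b), (L-z)/b on [L-b, L]; for short
#' transcripts (a + b >= L) the general product form
#' min(z/a, 1) * min((L-z)/b, 1) is used, to which the piecewise form reduces
#' whenever a + b < L.
#'
#' @param z position(s) in bp from the 3' end, within [0, L].
#' @param params a [DegradationParams-class].
#' @return retaining probabilities, same length as \code{z}.
#' @examples
#' p <- degradationParams(1000, 300, 200)
#' p1RetainingRate(c(0, 150, 550, 1000), p)  # 0, 0.5, 1, 0
#' @export
p1RetainingRate <- function(z, params) {
  .checkParams(params)
  .checkZ(z, params@L)
  pmin(z / params@a, 1) * pmin((params@L - z) / params@b, 1)
}

#' Joint CDF of the cycle-1 endpoints
#'
#' F1(x, y) = P(A1 <= x, B1 <= y) = x (y + b - L) / (a b) on the support
#' rectangle x in [0, a], y in [L-b, L]. Arguments outside the rectangle are
#' clamped per CDF semantics (x below 0 contributes 0, above a contributes a;
#' likewise for y).
#'
#' @param x 3'-end position (bp); vectorised.
#' @param y 5'-end position (bp); vectorised.
#' @param params a [DegradationParams-class].
#' @return probabilities.
#' @examples
#' p <- degradationParams(1000, 300, 200)
#' jointCdfCycle1(150, 900, p)  # 0.25
#' @export
jointCdfCycle1 <- function(x, y, params) {
  .checkParams(params)
  xc <- pmin(pmax(x, 0), params@a)
  yc <- pmin(pmax(y, params@L - params@b), params@L)
  xc * (yc + params@b - params@L) / (params@a * params@b)
}

#' Sample endpoint trajectories of the three shortenings
#'
#' Draws n independent trajectories (A1, B1, A2, B2, A3, B3) of the
#' endpoint-shortening process. Fully degraded products (B3 < A3) are kept:
#' they simply cover no position.
#'
#' @param params a [DegradationParams-class] with a + b < L.
#' @param n number of trajectories (>= 1).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @return data.frame with columns A1, B1, A2, B2, A3, B3 (bp).
#' @examples
#' head(sampleTrajectories(degradationParams(1000, 300, 200), 5, seed = 7))
#' @export
sampleTrajectories <- function(params, n, seed = 1L) {
  .checkParams(params)
  if (params@a + params@b >= params@L)
    stop("cycle-2 process requires a + b < L")
  stopifnot(n >= 1)
  .withSeed(seed, {
    A1 <- runif(n, 0, params@a)
    B1 <- runif(n, params@L - params@b, params@L)
    B2 <- runif(n, A1, B1)
    A3 <- A1 + runif(n, 0, params@a)
    B3 <- B2 - runif(n, 0, params@b)
    data.frame(A1 = A1, B1 = B1, A2 = A1, B2 = B2, A3 = A3, B3 = B3)
  })
}

# antiderivative of u -> clamp01((u - z) / b)
.Gclamp <- function(u, z, b) {
  ifelse(u <= z, 0,
         ifelse(u <= z + b, (u - z)^2 / (2 * b), (u - z) - b / 2))
}

# deterministic quadrature for p2(z) = P(A3 <= z <= B3).
# Conditional on (A1, B1, B2): A3 and B3 are independent, so
#   p2(z) = E[ clamp01((z - A1)/a) * clamp01((B2 - z)/b) ].
# The B2 | (A1, B1) ~ U[A1, B1] expectation of clamp01((B2 - z)/b) has the
# closed antiderivative .Gclamp, leaving a 2-D integral over the independent
# uniforms A1 ~ U[0, a], B1 ~ U[L-b, L], evaluated by composite trapezoid
# with step `step` (bp). Kinks of the integrand sit on integer positions, so
# integer-valued z keeps the trapezoid error far below Monte-Carlo noise.
.p2Quadrature <- function(z, params, step) {
  a <- params@a; b <- params@b; L <- params@L
  x <- seq(0, a, by = step)
  if (x[length(x)] < a) x <- c(x, a)
  y <- seq(L - b, L, by = step)
  if (y[length(y)] < L) y <- c(y, L)
  wx <- diff(x); wx <- c(wx, 0) / 2 + c(0, wx) / 2   # trapezoid weights
  wy <- diff(y); wy <- c(wy, 0) / 2 + c(0, wy) / 2
  vapply(z, function(zz) {
    w <- pmin(pmax((zz - x) / a, 0), 1)
    if (all(w == 0)) return(0)
    J <- outer(-.Gclamp(x, zz, b), .Gclamp(y, zz, b), `+`)  # G(B1) - G(A1)
    D <- outer(-x, y, `+`)                                   # B1 - A1
    sum((wx * w) %*% (J / D) * wy) / (a * b)
  }, numeric(1))
}

#' Second-cycle retaining rate p2(z)
#'
#' Probability that position z is still covered after both amplification
#' cycles, i.e. P(A3 <= z <= B3) under the endpoint process. Computed either
#' by deterministic nested quadrature over (A1, B1, B2) — the innermost
#' integral taken in closed form, the outer two by composite trapezoid — or
#' as the empirical coverage fraction over Monte-Carlo trajectories.
#'
#' @param z position(s) in bp from the 3' end, within [0, L].
#' @param params a [DegradationParams-class] with a + b < L.
#' @param method \code{"quadrature"} (default, deterministic) or
#'   \code{"monte-carlo"}.
#' @param step trapezoid step in bp for the quadrature
#'   (default \code{max(1, L/2000)}).
#' @param n number of Monte-Carlo trajectories.
#' @param seed Monte-Carlo seed.
#' @param checkConvergence if TRUE (quadrature only), recompute with the step
#'   halved and attach attribute \code{converged} (largest change <= 1e-4).
#' @return retaining probabilities, same length as \code{z}.
#' @examples
#' p <- degradationParams(1000, 300, 200)
#' p2RetainingRate(c(100, 300, 500), p)
#' @export
p2RetainingRate <- function(z, params, method = c("quadrature", "monte-carlo"),
                            step = NULL, n = 1e6, seed = 1L,
                            checkConvergence = FALSE) {
  .checkParams(params)
  if (params@a + params@b >= params@L)
    stop("cycle-2 retaining rate requires a + b < L")
  .checkZ(z, params@L)
  method <- match.arg(method)
  if (method == "quadrature") {
    if (is.null(step)) step <- max(1, params@L / 2000)
    out <- .p2Quadrature(z, params, step)
    if (checkConvergence) {
      ref <- .p2Quadrature(z, params, step / 2)
      attr(out, "converged") <- max(abs(out - ref)) <= 1e-4
    }
    out
  } else {
    tr <- sampleTrajectories(params, n, seed)
    vapply(z, function(zz) mean(tr$A3 <= zz & tr$B3 >= zz), numeric(1))
  }
}

#' Tabulate a retaining-rate curve
#'
#' Evaluates p1 (closed form) or p2 (quadrature or Monte Carlo) on an evenly
#' spaced grid covering [0, L] and returns a [RetainingRateCurve-class] for
#' reuse by the correction functions. Deterministic given (params, cycle,
#' gridStep, method, quadStep/n, seed).
#'
#' @param params a [DegradationParams-class].
#' @param cycle 1 or 2.
#' @param gridStep tabulation grid step in bp (> 0; default 5).
#' @param method for cycle 2: \code{"quadrature"} or \code{"monte-carlo"};
#'   ignored for cycle 1.
#' @param quadStep quadrature step (bp), default \code{max(1, L/2000)}.
#' @param n Monte-Carlo sample count.
#' @param seed Monte-Carlo seed.
#' @return A [RetainingRateCurve-class].
#' @examples
#' crv <- retainingRateCurve(degradationParams(1000, 300, 200), cycle = 1)
#' crv
#' @export
retainingRateCurve <- function(params, cycle = 2L, gridStep = 5,
                               method = c("quadrature", "monte-carlo"),
                               quadStep = NULL, n = 1e6, seed = 1L) {
  .checkParams(params)
  stopifnot(gridStep > 0)
  method <- match.arg(method)
  L <- params@L
  grid <- seq(0, L, by = gridStep)
  if (grid[length(grid)] < L) grid <- c(grid, L)
  if (cycle == 1L) {
    vals <- p1RetainingRate(grid, params)
    meth <- "closed-form"
    meta <- list(gridStep = gridStep)
  } else {
    vals <- p2RetainingRate(grid, params, method = method, step = quadStep,
                            n = n, seed = seed)
    meth <- method
    meta <- if (method == "quadrature") {
      list(gridStep = gridStep,
           quadStep = if (is.null(quadStep)) max(1, L / 2000) else quadStep)
    } else {
      list(gridStep = gridStep, n = n, seed = seed)
    }
  }
  vals <- pmin(pmax(vals, 0), 1)
  vals[length(vals)] <- 0
  new("RetainingRateCurve", cycle = as.integer(cycle), grid = grid,
      values = vals, params = params, method = meth, metadata = meta)
}

#' Evaluate a retaining-rate curve at arbitrary positions
#'
#' Linear interpolation between the tabulated grid points.
#'
#' @param curve a [RetainingRateCurve-class].
#' @param z positions in bp, within [0, L].
#' @return interpolated retaining rates.
#' @export
retainingRate <- function(curve, z) {
  stopifnot(is(curve, "RetainingRateCurve"))
  .checkZ(z, curve@params@L)
  approx(curve@grid, curve@values, xout = z)$y
}
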