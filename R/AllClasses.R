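#' @import methods
#' @importFrom stats approx lowess sd cor hclust as.dist wilcox.test rnorm
#'   runif aggregate
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom tools file_ext
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom ape as.phylo write.tree
#' @importFrom yaml read_yaml
NULL

#' Degradation parameters of the two-cycle amplification model
#'
#' Holds the transcript length \code{L} and the per-cycle degradation limits
#' \code{a} (3' end) and \code{b} (5' end), all in base pairs. During each
#' in vitro transcription step the 3' end advances by a U[0, a] amount and the
#' 5' end recedes by a U[0, b] amount; \code{a + b < L} is the standard regime
#' in which a transcript cannot be consumed entirely by a single cycle's
#' exonucleolytic shortening.
#'
#' @slot L transcript length (bp), positive.
#' @slot a 3'-end degradation limit (bp), positive.
#' @slot b 5'-end degradation limit (bp), positive.
#'
#' @seealso [degradationParams()], [retainingRateCurve()]
#' @export
setClass("DegradationParams",
  representation(L = "numeric", a = "numeric", b = "numeric"))

setValidity("DegradationParams", function(object) {
  msg <- character()
  for (s in c("L", "a", "b")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct degradation parameters
#'
#' @param L transcript length in bp (> 0).
#' @param a 3'-end degradation limit in bp (> 0).
#' @param b 5'-end degradation limit in bp (> 0).
#'
#' @details If \code{a + b >= L} the object is still valid (short-transcript
#' regime) but a warning is emitted: the first-cycle retaining rate then loses
#' its plateau and is computed from the general product form, and second-cycle
#' quantities are not defined by this model.
#'
#' @return A [DegradationParams-class] object.
#' @examples
#' degradationParams(L = 1000, a = 300, b = 200)
#' @export
degradationParams <- function(L, a, b) {
  obj <- new("DegradationParams", L = as.numeric(L), a = as.numeric(a),
             b = as.numeric(b))
  if (a + b >= L)
    warning("a + b >= L: short-transcript regime; first-cycle retaining ",
            "rate falls back to the general product form and cycle-2 ",
            "quantities are unavailable")
  obj
}

#' @describeIn DegradationParams-class transcript length L (bp)
#' @param object,x a \code{DegradationParams} object.
#' @export
transcriptLength <- function(x) x@L

#' @describeIn DegradationParams-class 3'-end degradation limit a (bp)
#' @export
degLimit3p <- function(x) x@a

#' @describeIn DegradationParams-class 5'-end degradation limit b (bp)
#' @export
degLimit5p <- function(x) x@b

setMethod("show", "DegradationParams", function(object) {
  cat(sprintf("DegradationParams: L = %g bp, a = %g bp (3'), b = %g bp (5')%s\n",
              object@L, object@a, object@b,
              if (object@a + object@b >= object@L) "  [a + b >= L]" else ""))
})

#' Tabulated retaining-rate curve
#'
#' The retaining rate p_j(z) is the probability that the nucleotide at
#' distance z (bp) from the transcript's 3' end is still covered by the
#' surviving fragment after amplification cycle j. Curves are tabulated on an
#' evenly spaced grid over [0, L] and evaluated elsewhere by linear
#' interpolation (see [retainingRate()]).
#'
#' @slot cycle integer, 1 or 2.
#' @slot grid numeric, ordered positions in [0, L] including both endpoints.
#' @slot values numeric, probabilities in [0, 1]; value at z = L is 0.
#' @slot params the generating [DegradationParams-class].
#' @slot method one of \code{"closed-form"}, \code{"quadrature"},
#'   \code{"monte-carlo"}.
#' @slot metadata list of method details (grid step, quadrature step, Monte
#'   Carlo sample count and seed, convergence flag).
#' @export
setClass("RetainingRateCurve",
  representation(cycle = "integer", grid = "numeric", values = "numeric",
                 params = "DegradationParams", method = "character",
                 metadata = "list"))

setValidity("RetainingRateCurve", function(object) {
  msg <- character()
  if (!object@cycle %in% c(1L, 2L)) msg <- c(msg, "cycle must be 1 or 2")
  if (length(object@grid) != length(object@values))
    msg <- c(msg, "grid and values differ in length")
  if (is.unsorted(object@grid, strictly = TRUE))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
    msg <- c(msg, "values must lie in [0, 1]")
  L <- object@params@L
  if (length(object@grid) &&
      (abs(object@grid[1]) > 1e-9 || abs(object@grid[length(object@grid)] - L) > 1e-9))
    msg <- c(msg, "grid must span [0, L]")
  if (length(object@values) && abs(object@values[length(object@values)]) > 1e-9)
    msg <- c(msg, "value at z = L must be 0")
  if (!object@method %in% c("closed-form", "quadrature", "monte-carlo"))
    msg <- c(msg, "unknown method tag")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RetainingRateCurve", function(object) {
  cat(sprintf("RetainingRateCurve: cycle %d, %s, %d grid points on [0, %g]\n",
              object@cycle, object@method, length(object@grid),
              object@params@L))
  cat(sprintf("  params: L = %g, a = %g, b = %g; max p = %.4g\n",
              object@params@L, object@params@a, object@params@b,
              max(object@values)))
})

#' @describeIn RetainingRateCurve-class the generating parameters
#' @param x a \code{RetainingRateCurve}.
#' @export
curveParams <- function(x) x@params

#' @describeIn RetainingRateCurve-class amplification cycle (1 or 2)
#' @export
curveCycle <- function(x) x@cycle

#' @describeIn RetainingRateCurve-class tabulation grid (bp)
#' @export
curveGrid <- function(x) x@grid

#' @describeIn RetainingRateCurve-class tabulated retaining rates
#' @export
curveValues <- function(x) x@values

#' @describeIn RetainingRateCurve-class method tag and metadata
#' @export
curveMethod <- function(x) c(list(method = x@method), x@metadata)

#' Coerce a retaining-rate curve to a data.frame
#'
#' @param x a [RetainingRateCurve-class].
#' @param ... ignored.
#' @return data.frame with columns \code{z} and \code{p}.
#' @export
setMethod("as.data.frame", "RetainingRateCurve", function(x, ...) {
  data.frame(z = x@grid, p = x@values)
})

#' Probe-level intensity container
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding probe-level
#' intensities: rows are probes (with \code{probeset_id}, \code{probe_id},
#' \code{z} — distance of the probe's middle nucleotide from the 3' end — and
#' transcript length \code{L} in \code{rowData}), columns are samples, and
#' assays hold \code{pm} and optionally \code{mm} and \code{present}
#' matrices. Construct from the long interchange table with
#' [probeIntensitySet()]; recover the long table with [longFormat()].
#'
#' @export
setClass("ProbeIntensitySet", contains = "SummarizedExperiment")

setValidity("ProbeIntensitySet", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  need <- c("probeset_id", "probe_id", "z", "L")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("rowData lacks column(s):", paste(miss, collapse = ", ")))
  if (!"pm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'pm' is required")
  if (!length(msg)) {
    if (any(rd$z < 0 | rd$z > rd$L))
      msg <- c(msg, "probe positions z must lie in [0, L]")
    pm <- SummarizedExperiment::assay(object, "pm")
    if (any(!is.finite(pm)) || any(pm < 0))
      msg <- c(msg, "pm intensities must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProbeIntensitySet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("ProbeIntensitySet: %d probes / %d probe sets x %d samples; assays: %s\n",
              nrow(object), length(unique(rd$probeset_id)), ncol(object),
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
})
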