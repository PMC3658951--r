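# Evaluation statistics: per-probe-set coefficient of variation with a
# paired one-sided Wilcoxon signed-rank comparison, inter-sample Pearson
# correlation on probe-set summaries, and average-linkage hierarchical
# clustering of samples on the 1 - r distance.

#' Coefficient of variation of a probe set's intensities
#'
#' Sample standard deviation (n - 1 denominator) over the mean. Undefined
#' (NA) for fewer than 2 values or non-positive mean.
#'
#' @param pm nonnegative intensities of one probe set.
#' @return the CV, or NA when undefined.
#' @examples
#' probeSetCV(c(1, 2, 3))  # 0.5
#' @export
probeSetCV <- function(pm) {
  if (length(pm) < 2 || mean(pm) <= 0) return(NA_real_)
  sd(pm) / mean(pm)
}

#' Per-probe-set CVs for a whole table
#'
#' @param probes long probe table or [ProbeIntensitySet-class].
#' @param column intensity column to use (default \code{"pm"}).
#' @return data.frame with sample_id, probeset_id, cv (NA where undefined).
#' @export
probeSetCVTable <- function(probes, column = "pm") {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  probes <- .checkProbeColumns(probes, need = c("sample_id", "probeset_id",
                                                column))
  grp <- factor(paste(probes$sample_id, probes$probeset_id, sep = "\r"))
  gi <- as.integer(grp)
  x <- probes[[column]]
  n <- rowsum(rep(1, length(x)), gi)[, 1]
  mu <- rowsum(x, gi)[, 1] / n
  ssd <- rowsum(x^2, gi)[, 1] - n * mu^2
  cv <- ifelse(n >= 2 & mu > 0, sqrt(pmax(ssd, 0) / (n - 1)) / mu, NA_real_)
  first <- probes[match(levels(grp), paste(probes$sample_id,
                                           probes$probeset_id, sep = "\r")), ]
  data.frame(sample_id = first$sample_id, probeset_id = first$probeset_id,
             cv = cv, row.names = NULL)
}

#' Paired Wilcoxon test for CV decrease
#'
#' One-sided Wilcoxon signed-rank test of the paired differences
#' before - after (alternative: median difference > 0, i.e. the CV
#' decreased). Zero differences are dropped; with no non-zero difference the
#' result is degenerate (p = 1). The exact distribution is used for n <= 25
#' untied differences, the normal approximation with continuity correction
#' otherwise.
#'
#' @param cvBefore,cvAfter paired CV vectors (same probe-set order); pairs
#'   with NA in either member are dropped.
#' @return list with \code{statistic} (V), \code{pValue}, \code{n} (pairs
#'   used after zero/NA removal) and \code{degenerate}.
#' @export
cvWilcoxon <- function(cvBefore, cvAfter) {
  stopifnot(length(cvBefore) == length(cvAfter))
  ok <- is.finite(cvBefore) & is.finite(cvAfter)
  d <- cvBefore[ok] - cvAfter[ok]
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, pValue = 1, n = 0L, degenerate = TRUE))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- wilcox.test(d, alternative = "greater", mu = 0, exact = exact,
                    correct = TRUE)
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       n = length(d), degenerate = FALSE)
}

#' Sample-by-sample correlation matrix
#'
#' Pearson correlation between sample columns of a probe-set x sample
#' summary matrix, optionally restricted to a probe-set subset. Constant
#' columns give NA entries (flagged by a warning).
#'
#' @param expression numeric matrix, probe sets in rows (rownames are
#'   probe-set ids), samples in columns.
#' @param subset optional character vector of probe-set ids to use.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sampleCorrelationMatrix <- function(expression, subset = NULL) {
  stopifnot(is.matrix(expression), ncol(expression) >= 2)
  if (!is.null(subset)) {
    if (!length(subset)) stop("empty probe-set subset")
    expression <- expression[rownames(expression) %in% subset, , drop = FALSE]
    if (!nrow(expression)) stop("subset matches no probe sets")
  }
  const <- apply(expression, 2, sd) == 0
  if (any(const))
    warning("constant sample column(s): ",
            paste(colnames(expression)[const], collapse = ", "),
            "; correlation undefined (NA)")
  r <- suppressWarnings(cor(expression))
  diag(r) <- 1
  r
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Agglomerative clustering with distance 1 - r and, by default, average
#' linkage. Deterministic given the input; stats::hclust breaks ties toward
#' the lowest pair indices.
#'
#' @param corMatrix symmetric correlation matrix (unit diagonal).
#' @param linkage linkage method passed to [stats::hclust()], default
#'   \code{"average"}.
#' @return an \code{hclust} object.
#' @export
clusterSamples <- function(corMatrix, linkage = "average") {
  stopifnot(is.matrix(corMatrix), nrow(corMatrix) == ncol(corMatrix))
  hclust(as.dist(1 - corMatrix), method = linkage)
}

#' Newick string for a sample dendrogram
#'
#' @param hc an \code{hclust} object from [clusterSamples()].
#' @return a single Newick-format string (with branch lengths).
#' @export
dendrogramNewick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Summarise probe sets to a probe-set x sample matrix
#'
#' Mean of the chosen intensity column per probe set per sample; the common
#' input to [sampleCorrelationMatrix()].
#'
#' @param probes long probe table or [ProbeIntensitySet-class].
#' @param column intensity column (default \code{"pm"}).
#' @return numeric matrix, probe sets x samples.
#' @export
probeSetSummaryMatrix <- function(probes, column = "pm") {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  probes <- .checkProbeColumns(probes, need = c("sample_id", "probeset_id",
                                                column))
  sets <- sort(unique(probes$probeset_id))
  samples <- sort(unique(probes$sample_id))
  m <- matrix(NA_real_, length(sets), length(samples),
              dimnames = list(sets, samples))
  mu <- tapply(probes[[column]],
               list(factor(probes$probeset_id, sets),
                    factor(probes$sample_id, samples)), mean)
  m[] <- mu
  m
}

#' End-to-end evaluation of an adjustment
#'
#' Computes the paired before/after CV comparison (Wilcoxon), the
#' inter-sample correlation matrices and the sample dendrograms for an
#' adjusted probe table.
#'
#' @param adjusted output of [adjustProbes()] or [applyCurveAdjustment()]
#'   (must contain \code{pm} and \code{pm_adj}).
#' @param subset optional probe-set subset for the correlation matrices.
#' @return list with \code{cvPairs} (data.frame sample_id, probeset_id,
#'   cv_before, cv_after), \code{wilcoxon} (see [cvWilcoxon()]),
#'   \code{corBefore}, \code{corAfter} (matrices or NULL with < 2 samples),
#'   \code{treeBefore}, \code{treeAfter} (Newick strings or NULL).
#' @export
evaluateAdjustment <- function(adjusted, subset = NULL) {
  stopifnot("pm_adj" %in% names(adjusted))
  cvB <- probeSetCVTable(adjusted, "pm")
  cvA <- probeSetCVTable(adjusted, "pm_adj")
  cvPairs <- data.frame(sample_id = cvB$sample_id,
                        probeset_id = cvB$probeset_id,
                        cv_before = cvB$cv, cv_after = cvA$cv)
  res <- list(cvPairs = cvPairs,
              wilcoxon = cvWilcoxon(cvPairs$cv_before, cvPairs$cv_after),
              corBefore = NULL, corAfter = NULL,
              treeBefore = NULL, treeAfter = NULL)
  if (length(unique(adjusted$sample_id)) >= 2) {
    res$corBefore <- sampleCorrelationMatrix(
      probeSetSummaryMatrix(adjusted, "pm"), subset)
    res$corAfter <- sampleCorrelationMatrix(
      probeSetSummaryMatrix(adjusted, "pm_adj"), subset)
    res$treeBefore <- dendrogramNewick(clusterSamples(res$corBefore))
    res$treeAfter <- dendrogramNewick(clusterSamples(res$corAfter))
  }
  res
}
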