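# qPCR degradation statistics. Relative expression of amplicon i in sample j
# (reference: the pre-amplified pool PAM) is R_ij = 2^-(CT(i,j) - CT(i,PAM)),
# and the Degradation Proportion DP_ij = 1 - R_ij / max_i(R_ij) measures the
# positional loss of each amplicon relative to the best-preserved region:
# 0 = unaffected, 1 = completely degraded.

#' Relative expression from cycle-threshold values
#'
#' R = 2^-(CT_sample - CT_reference): one extra cycle to threshold halves the
#' template amount.
#'
#' @param ctSample CT of the amplicon in the test sample; vectorised.
#' @param ctReference CT of the same amplicon in the reference sample.
#' @return relative expression values (positive).
#' @examples
#' relativeExpression(c(21, 22, 19), 21)  # 1, 0.5, 4
#' @export
relativeExpression <- function(ctSample, ctReference) {
  if (any(!is.finite(ctReference)))
    stop("missing or non-finite reference CT")
  if (any(!is.finite(ctSample)))
    stop("missing or non-finite sample CT")
  2^(-(ctSample - ctReference))
}

#' Degradation proportion of amplicons
#'
#' DP_i = 1 - R_i / max(R): the amplicon(s) attaining the maximum relative
#' expression get DP = 0 exactly.
#'
#' @param r vector of relative expression values (at least one finite).
#' @return DP values in [0, 1].
#' @examples
#' degradationProportion(c(0.25, 1.0))  # 0.75, 0
#' @export
degradationProportion <- function(r) {
  if (!length(r) || all(!is.finite(r)))
    stop("no relative expression values")
  1 - r / max(r, na.rm = TRUE)
}

#' Degradation proportions for a CT panel
#'
#' Computes per-amplicon relative expression and degradation proportion for
#' every non-reference sample of every transcript in a long CT table.
#' Replicate CT values (several rows for one amplicon/sample) are averaged
#' before the computation. Ties at the maximum R all receive DP = 0.
#'
#' @param ct data.frame with columns \code{transcript_id},
#'   \code{amplicon_id}, \code{start_5prime}, \code{sample}, \code{ct}.
#' @param reference name of the reference sample, default \code{"PAM"}.
#' @return data.frame with one row per transcript x amplicon x non-reference
#'   sample and columns \code{transcript_id}, \code{amplicon_id},
#'   \code{start_5prime}, \code{sample}, \code{ct}, \code{r_rel}, \code{dp}.
#' @examples
#' ct <- data.frame(transcript_id = "t1", amplicon_id = c("A1", "A2"),
#'                  start_5prime = c(100, 900),
#'                  sample = rep(c("PAM", "TCS"), each = 2),
#'                  ct = c(20, 20, 24, 21))
#' qpcrDegradation(ct)
#' @export
qpcrDegradation <- function(ct, reference = "PAM") {
  need <- c("transcript_id", "amplicon_id", "start_5prime", "sample", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("CT table lacks required column(s): ", paste(miss, collapse = ", "))
  # replicate averaging
  agg <- stats::aggregate(ct ~ transcript_id + amplicon_id + start_5prime +
                            sample, data = ct[, need], FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$transcript_id), function(tr) {
    ref <- tr[tr$sample == reference, ]
    if (!nrow(ref)) stop("transcript ", tr$transcript_id[1],
                         ": no CT for reference sample '", reference, "'")
    tst <- tr[tr$sample != reference, ]
    if (!nrow(tst)) return(NULL)
    do.call(rbind, lapply(split(tst, tst$sample, drop = TRUE), function(sm) {
      i <- match(sm$amplicon_id, ref$amplicon_id)
      if (anyNA(i)) stop("transcript ", sm$transcript_id[1], ", sample ",
                         sm$sample[1], ": amplicon(s) without reference CT: ",
                         paste(sm$amplicon_id[is.na(i)], collapse = ", "))
      sm$r_rel <- relativeExpression(sm$ct, ref$ct[i])
      sm$dp <- degradationProportion(sm$r_rel)
      sm
    }))
  }))
  rownames(out) <- NULL
  out
}
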