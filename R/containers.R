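#' Build a ProbeIntensitySet from a long probe table
#'
#' Pivots the long interchange table (one row per sample x probe) into a
#' probes-by-samples [ProbeIntensitySet-class]. Every sample must report the
#' same probes.
#'
#' @param probes data.frame with columns \code{sample_id}, \code{probeset_id},
#'   \code{probe_id}, \code{z}, \code{pm}; optional \code{mm},
#'   \code{present} (0/1) and \code{L} (transcript length; if absent, \code{L}
#'   must be given).
#' @param L transcript length used when the table has no \code{L} column.
#' @return A [ProbeIntensitySet-class].
#' @examples
#' sim <- generateProbeData(syntheticSpec(nProbeSets = 5, seed = 1))
#' probeIntensitySet(sim$probes)
#' @export
probeIntensitySet <- function(probes, L = NULL) {
  probes <- .checkProbeColumns(probes)
  if (is.null(probes$L)) {
    if (is.null(L)) stop("no 'L' column in table and no 'L' argument given")
    probes$L <- L
  }
  key <- paste(probes$probeset_id, probes$probe_id, sep = "\r")
  samples <- unique(probes$sample_id)
  ukey <- unique(key)
  first <- probes[match(ukey, key), , drop = FALSE]
  pivot <- function(col) {
    m <- matrix(NA_real_, length(ukey), length(samples),
                dimnames = list(NULL, samples))
    m[cbind(match(key, ukey), match(probes$sample_id, samples))] <- probes[[col]]
    if (anyNA(m)) stop("samples do not share an identical probe panel ",
                       "(missing '", col, "' entries after pivot)")
    m
  }
  assays <- list(pm = pivot("pm"))
  if (!is.null(probes$mm)) assays$mm <- pivot("mm")
  if (!is.null(probes$present)) assays$present <- pivot("present")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(probeset_id = first$probeset_id,
                                   probe_id = first$probe_id,
                                   z = first$z, L = first$L))
  new("ProbeIntensitySet", se)
}

#' Long-format view of a ProbeIntensitySet
#'
#' @param x a [ProbeIntensitySet-class].
#' @return data.frame in the long interchange layout (sample_id, probeset_id,
#'   probe_id, z, pm, and mm / present / L where available).
#' @export
longFormat <- function(x) {
  stopifnot(is(x, "ProbeIntensitySet"))
  rd <- SummarizedExperiment::rowData(x)
  samples <- colnames(x)
  if (is.null(samples)) samples <- as.character(seq_len(ncol(x)))
  out <- data.frame(
    sample_id = rep(samples, each = nrow(x)),
    probeset_id = rep(rd$probeset_id, ncol(x)),
    probe_id = rep(rd$probe_id, ncol(x)),
    z = rep(rd$z, ncol(x)),
    pm = as.vector(SummarizedExperiment::assay(x, "pm")),
    stringsAsFactors = FALSE)
  if ("mm" %in% SummarizedExperiment::assayNames(x))
    out$mm <- as.vector(SummarizedExperiment::assay(x, "mm"))
  if ("present" %in% SummarizedExperiment::assayNames(x))
    out$present <- as.vector(SummarizedExperiment::assay(x, "present"))
  out$L <- rep(rd$L, ncol(x))
  out
}

# shared column check for long probe tables
.checkProbeColumns <- function(probes, need = c("sample_id", "probeset_id",
                                                "probe_id", "z", "pm")) {
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("probe table lacks required column(s): ", paste(miss, collapse = ", "))
  probes
}
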