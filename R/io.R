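# Tabular interchange. All files are tab-separated UTF-8 with a mandatory
# header row, '.' decimal separator, and '#' comment lines allowed.
# Binary CEL/CDF parsing is deliberately out of scope: external tooling is
# expected to export the long probe table (the method needs only
# probeset / position / PM).

.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a long-format probe table
#'
#' Reads and validates the probe-level interchange TSV. Required columns:
#' sample_id, probeset_id, probe_id, z, pm; optional: mm, present, L.
#' Rows with negative or non-finite pm, or with z outside [0, L], are
#' rejected with line-numbered diagnostics (the rejected count is reported
#' in a message and attached as attribute \code{rejected}).
#'
#' @param path TSV path.
#' @param L transcript length for the z range check when the table has no
#'   \code{L} column (default: checks z >= 0 only).
#' @return validated data.frame of probe records.
#' @export
readProbeTable <- function(path, L = NULL) {
  df <- .readTsv(path)
  miss <- setdiff(c("sample_id", "probeset_id", "probe_id", "z", "pm"),
                  names(df))
  if (length(miss))
    stop("probe table schema error; missing column(s): ",
         paste(miss, collapse = ", "))
  upper <- if (!is.null(df$L)) df$L else if (!is.null(L)) L else Inf
  bad <- !is.finite(df$pm) | df$pm < 0 | !is.finite(df$z) | df$z < 0 |
    df$z > upper
  if (any(bad)) {
    message(sum(bad), " row(s) rejected (lines ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "rejected") <- sum(bad)
  df
}

#' Write a long-format probe table
#'
#' @param probes data.frame (or [ProbeIntensitySet-class]) to write.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeProbeTable <- function(probes, path) {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  .writeTsv(probes, path)
}

#' Write a retaining-rate curve as TSV
#'
#' Two columns (z, p) preceded by header comment lines recording the
#' parameters, cycle and method metadata, so the curve can be rebuilt
#' faithfully by [readRetainingRateCurve()].
#'
#' @param curve a [RetainingRateCurve-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeRetainingRateCurve <- function(curve, path) {
  stopifnot(is(curve, "RetainingRateCurve"))
  p <- curve@params
  meta <- curve@metadata
  comments <- c(
    sprintf("retaining-rate curve: cycle=%d method=%s", curve@cycle,
            curve@method),
    sprintf("params: L=%.10g a=%.10g b=%.10g", p@L, p@a, p@b),
    sprintf("meta: %s", paste(names(meta), unlist(meta), sep = "=",
                              collapse = " ")))
  .writeTsv(data.frame(z = curve@grid, p = curve@values), path, comments)
}

#' Read a retaining-rate curve written by [writeRetainingRateCurve()]
#'
#' @param path TSV path.
#' @return a [RetainingRateCurve-class].
#' @export
readRetainingRateCurve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  cyc <- as.integer(sub(".*cycle=([0-9]+).*", "\\1",
                        grep("cycle=", hdr, value = TRUE)[1]))
  method <- sub(".*method=([a-z-]+).*", "\\1",
                grep("method=", hdr, value = TRUE)[1])
  pl <- grep("params:", hdr, value = TRUE)[1]
  getNum <- function(key)
    as.numeric(sub(paste0(".*", key, "=([-0-9.eE+]+).*"), "\\1", pl))
  df <- .readTsv(path)
  new("RetainingRateCurve", cycle = cyc, grid = df$z, values = df$p,
      params = new("DegradationParams", L = getNum("L"), a = getNum("a"),
                   b = getNum("b")),
      method = method, metadata = list())
}

#' Read a qPCR CT table
#'
#' Required columns: transcript_id, amplicon_id, start_5prime, sample, ct.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readCtTable <- function(path) {
  df <- .readTsv(path)
  miss <- setdiff(c("transcript_id", "amplicon_id", "start_5prime", "sample",
                    "ct"), names(df))
  if (length(miss))
    stop("CT table schema error; missing column(s): ",
         paste(miss, collapse = ", "))
  df
}
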