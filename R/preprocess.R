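#' Present/absent detection calls from raw intensities
#'
#' Reproduces the scanner's detection semantics: a cell is called present
#' ("P") when its raw-scale signal exceeds the background level, defined as
#' \code{backgroundMean + k * backgroundSd}; otherwise absent ("A").
#'
#' @param raw numeric vector or matrix of raw-scale (non-negative)
#'   intensities.
#' @param backgroundMean,backgroundSd background signal mean and standard
#'   deviation (sd must be >= 0).
#' @param k threshold multiplier (default 2).
#' @return character object of the same shape over \{"P","A"\}.
#' @examples
#' callDetection(c(100, 180), backgroundMean = 100, backgroundSd = 20)
#' @export
callDetection <- function(raw, backgroundMean, backgroundSd, k = 2) {
  if (backgroundSd < 0) stop("backgroundSd must be >= 0")
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  out <- ifelse(raw > backgroundMean + k * backgroundSd, "P", "A")
  if (is.matrix(raw)) dimnames(out) <- dimnames(raw)
  out
}

#' Keep probes detected in at least one sample
#'
#' Removes probes whose detection flag is "A" in every sample ("not
#' expressed"); a probe present in at least one sample is retained. Row
#' order is preserved and the operation is idempotent.
#'
#' @param dataset a [MigrantArrayExperiment-class].
#' @return the filtered dataset; the removed probe ids are attached as
#'   \code{metadata(x)$removedProbes}.
#' @export
filterExpressed <- function(dataset) {
  stopifnot(is(dataset, "MigrantArrayExperiment"))
  keep <- rowSums(detectionFlags(dataset) == "P") >= 1L
  if (!any(keep)) warning("no probe is present in any sample")
  out <- dataset[keep, ]
  metadata(out)$removedProbes <- rownames(dataset)[!keep]
  out
}

#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's values are replaced by the mean of the cross-sample order
#' statistics at their rank, ties receiving the average of the reference
#' values of the tied ranks. Raw-scale input is log2-transformed after
#' normalization.
#'
#' @param x numeric probe x sample matrix.
#' @param log2Input set TRUE (default) when \code{x} is already on the log2
#'   scale; FALSE for raw-scale input, which must then be strictly positive.
#' @return normalized (and, for raw input, log2-transformed) matrix with
#'   the dimnames of \code{x}.
#' @export
quantileNormalize <- function(x, log2Input = TRUE) {
  x <- as.matrix(x)
  if (!log2Input) {
    if (any(x <= 0))
      stop("raw-scale input must be strictly positive for log2 transform")
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  if (!log2Input) out <- log2(out)
  dimnames(out) <- dimnames(x)
  out
}

#' Quantile-normalize a dataset in place
#'
#' @param dataset a [MigrantArrayExperiment-class] holding log2 intensities.
#' @return the dataset with its \code{exprs} assay quantile-normalized.
#' @export
normalizeDataset <- function(dataset) {
  stopifnot(is(dataset, "MigrantArrayExperiment"))
  assays(dataset)$exprs <- quantileNormalize(intensities(dataset),
                                             log2Input = TRUE)
  dataset
}
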