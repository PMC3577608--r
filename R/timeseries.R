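# The pipeline's input unit: one subject's regional mean time series.

#' Construct a regional time-series object
#'
#' Holds one subject's regions x volumes matrix of regional mean BOLD signals
#' together with its sampling interval and region labels. This is the point
#' where the pipeline starts; voxel-level spatial preprocessing and averaging
#' into regions happen upstream.
#'
#' @param data numeric matrix, regions x volumes.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param region_labels character vector, one label per region. Defaults to
#'   `"R1".."Rn"`.
#' @param subject_id identifier string.
#' @param motion optional volumes x q matrix of motion parameters (q = 6 for
#'   three translations + three rotations), used as nuisance regressors.
#' @return an object of class `regional_ts`.
#' @export
regional_ts <- function(data, tr_seconds, region_labels = NULL,
                        subject_id = "subject", motion = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop("time-series data must be numeric with no missing values")
  }
  if (ncol(data) < 2L) stop("need at least 2 volumes")
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(data)))
  if (length(region_labels) != nrow(data)) {
    stop("region count (", nrow(data), ") does not match label count (",
         length(region_labels), ")")
  }
  if (anyDuplicated(region_labels)) stop("duplicate region labels")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != ncol(data)) {
      stop("motion table rows (", nrow(motion),
           ") must equal volume count (", ncol(data), ")")
    }
  }
  structure(list(data = data, tr_seconds = tr_seconds,
                 region_labels = as.character(region_labels),
                 subject_id = subject_id, motion = motion),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat("regional_ts '", x$subject_id, "': ", nrow(x$data), " regions x ",
      ncol(x$data), " volumes, TR = ", x$tr_seconds, " s",
      if (!is.null(x$motion)) paste0(", ", ncol(x$motion), " motion regressors"),
      "\n", sep = "")
  invisible(x)
}
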