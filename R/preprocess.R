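# Temporal preprocessing: initial-volume discard, Chebyshev band-pass,
# nuisance regression (global mean + motion parameters).

#' Discard initial volumes
#'
#' Drops the first `k` volumes of a series (magnetic-saturation volumes in the
#' original acquisition: 180 acquired, 5 discarded, 175 retained).
#'
#' @param ts a [regional_ts()].
#' @param k number of volumes to drop (default 5).
#' @return the shortened series; motion rows are dropped consistently.
#' @export
discard_initial_volumes <- function(ts, k = 5L) {
  stopifnot(inherits(ts, "regional_ts"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  if (k >= ncol(ts$data)) {
    stop("cannot discard ", k, " of ", ncol(ts$data),
         " volumes: series would be unusable")
  }
  if (k == 0L) return(ts)
  keep <- (k + 1L):ncol(ts$data)
  regional_ts(ts$data[, keep, drop = FALSE], ts$tr_seconds, ts$region_labels,
              ts$subject_id,
              motion = if (!is.null(ts$motion)) ts$motion[keep, , drop = FALSE])
}

#' Band-pass filter every regional series
#'
#' Chebyshev Type I band-pass (default 0.01-0.08 Hz, order 4, 0.5 dB
#' pass-band ripple) applied forward-backward so the net filter has zero
#' phase. Output length equals input length.
#'
#' @param ts a [regional_ts()].
#' @param low_hz,high_hz pass band in Hz.
#' @param order,ripple_db filter design parameters, see [cheby1_bandpass()].
#' @return filtered series. Regions left with (numerically) zero variance are
#'   flagged via the `degenerate_regions` attribute.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08,
                     order = 4L, ripple_db = 0.5) {
  stopifnot(inherits(ts, "regional_ts"))
  fs <- 1 / ts$tr_seconds
  filt <- cheby1_bandpass(low_hz, high_hz, fs, order = order,
                          ripple_db = ripple_db)
  out <- ts
  out$data <- t(apply(ts$data, 1, function(x) sosfiltfilt(filt, x)))
  v <- apply(out$data, 1, stats::var)
  degen <- which(v < .Machine$double.eps * 100)
  attr(out, "degenerate_regions") <- if (length(degen)) ts$region_labels[degen] else character(0)
  out
}

#' Per-volume global mean signal
#'
#' @param ts a [regional_ts()].
#' @return numeric vector, one value per volume: the mean over all regions.
#' @export
compute_global_mean <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  colMeans(ts$data)
}

#' Build a nuisance design matrix
#'
#' Intercept + global mean series + motion parameters. When `filter` is
#' given, the non-intercept regressors are band-pass filtered with the same
#' filter as the data, so their frequency content matches what they are meant
#' to explain.
#'
#' @param ts a [regional_ts()] (its `motion` table is used if present).
#' @param global logical, include the global mean signal.
#' @param filter optional filter from [cheby1_bandpass()] applied to the
#'   regressors.
#' @return volumes x q numeric matrix including the intercept column.
#' @export
nuisance_design <- function(ts, global = TRUE, filter = NULL) {
  n <- ncol(ts$data)
  cols <- list(intercept = rep(1, n))
  if (global) cols$global <- compute_global_mean(ts)
  if (!is.null(ts$motion)) {
    for (j in seq_len(ncol(ts$motion))) {
      nm <- colnames(ts$motion)[j]
      cols[[if (is.null(nm) || nm == "") paste0("motion", j) else nm]] <- ts$motion[, j]
    }
  }
  X <- do.call(cbind, cols)
  if (!is.null(filter)) {
    for (j in seq_len(ncol(X))[-1]) X[, j] <- sosfiltfilt(filter, X[, j])
  }
  X
}

#' Regress nuisance signals out of every regional series
#'
#' Ordinary least squares per region; the residuals replace the series.
#' Residuals are orthogonal to every design column by construction.
#'
#' @param ts a [regional_ts()].
#' @param design volumes x q numeric matrix (include an intercept column;
#'   [nuisance_design()] builds one).
#' @return the residual series.
#' @export
regress_nuisance <- function(ts, design) {
  stopifnot(inherits(ts, "regional_ts"))
  design <- as.matrix(design)
  if (nrow(design) != ncol(ts$data)) {
    stop("design rows (", nrow(design), ") must equal volume count (",
         ncol(ts$data), ")")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(if (is.null(dropped)) "<unnamed>" else dropped, collapse = ", "))
  }
  resid <- t(qr.resid(qrd, t(ts$data)))
  out <- ts
  out$data <- resid
  out
}

#' Full temporal preprocessing of one subject
#'
#' discard -> band-pass -> nuisance regression, the fixed stage order of the
#' pipeline. Nuisance regressors (global mean, motion) are filtered with the
#' same band-pass before regression.
#'
#' @param ts a [regional_ts()].
#' @param discard_volumes initial volumes to drop (default 0: the synthetic
#'   generator already emits retained volumes; use 5 for raw acquisitions).
#' @param low_hz,high_hz,order,ripple_db band-pass parameters.
#' @param global_regression include the global mean signal as a nuisance
#'   regressor (default TRUE).
#' @return preprocessed [regional_ts()].
#' @export
preprocess_subject <- function(ts, discard_volumes = 0L,
                               low_hz = 0.01, high_hz = 0.08,
                               order = 4L, ripple_db = 0.5,
                               global_regression = TRUE) {
  ts <- discard_initial_volumes(ts, discard_volumes)
  filt <- cheby1_bandpass(low_hz, high_hz, 1 / ts$tr_seconds,
                          order = order, ripple_db = ripple_db)
  filtered <- bandpass(ts, low_hz, high_hz, order, ripple_db)
  design <- nuisance_design(ts, global = global_regression, filter = filt)
  # the global mean is computed from the *filtered* data's scale-equivalent:
  # filtering is linear, so filtering the raw global mean equals the global
  # mean of the filtered data
  regress_nuisance(filtered, design)
}
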