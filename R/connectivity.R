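# Whole-brain connectivity features: pairwise Pearson correlations vectorized
# with a canonical row-major upper-triangle edge index.

#' Number of edges for an R-region parcellation
#'
#' @param n_regions region count R.
#' @return `R * (R - 1) / 2`; 6670 for the 116-region template.
#' @export
n_edges <- function(n_regions) {
  as.integer(n_regions * (n_regions - 1) / 2)
}

#' Map a region pair to its canonical edge position
#'
#' Edges are ordered row-major over the upper triangle:
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).
#'
#' @param i,j region indices with `i < j` (vectorized).
#' @param n_regions region count R.
#' @return 1-based edge positions.
#' @export
pair_to_edge <- function(i, j, n_regions) {
  if (any(i < 1L | j > n_regions | i >= j)) {
    stop("need 1 <= i < j <= ", n_regions)
  }
  as.integer((i - 1) * (2 * n_regions - i) / 2 + (j - i))
}

#' Map a canonical edge position back to its region pair
#'
#' @param index 1-based edge positions (vectorized).
#' @param n_regions region count R.
#' @return two-column integer matrix of (i, j) with `i < j`.
#' @export
edge_to_pair <- function(index, n_regions) {
  E <- n_edges(n_regions)
  if (any(index < 1L | index > E)) stop("edge index out of range 1..", E)
  pairs <- edge_pairs(n_regions)
  pairs[index, , drop = FALSE]
}

# all pairs in canonical order, as a two-column matrix (cached per R)
edge_pairs <- function(n_regions) {
  R <- as.integer(n_regions)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- sequence((R - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Pearson correlation matrix of a regional time series
#'
#' @param ts a [regional_ts()] object.
#' @return a list of class `conn_matrix` with `values` (R x R symmetric,
#'   unit diagonal) and `region_labels`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  x <- t(ts$data)  # volumes x regions
  if (nrow(x) < 3L) stop("need at least 3 volumes for a correlation")
  v <- apply(x, 2, stats::var)
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad)) {
    stop("zero-variance region(s): ",
         paste(ts$region_labels[bad], collapse = ", "))
  }
  cm <- stats::cor(x)
  diag(cm) <- 1
  structure(list(values = cm, region_labels = ts$region_labels),
            class = "conn_matrix")
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' @param cm a `conn_matrix` (or a plain symmetric matrix).
#' @return a list of class `conn_vector` with `values` (length E) and the
#'   `n_regions` needed to invert the mapping.
#' @export
vectorize_upper <- function(cm) {
  m <- if (inherits(cm, "conn_matrix")) cm$values else cm
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  R <- nrow(m)
  pairs <- edge_pairs(R)
  structure(list(values = m[pairs], n_regions = R,
                 region_labels = if (inherits(cm, "conn_matrix")) cm$region_labels else rownames(m)),
            class = "conn_vector")
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()] for symmetric unit-diagonal matrices.
#'
#' @param v a `conn_vector` or plain numeric vector of length `R(R-1)/2`.
#' @param n_regions region count (taken from `v` if available).
#' @param diag_value value placed on the diagonal (default 1).
#' @return R x R symmetric matrix.
#' @export
unvectorize <- function(v, n_regions = NULL, diag_value = 1) {
  vals <- if (inherits(v, "conn_vector")) v$values else v
  R <- if (inherits(v, "conn_vector")) v$n_regions else n_regions
  if (is.null(R)) stop("n_regions required for a plain vector")
  stopifnot(length(vals) == n_edges(R))
  m <- matrix(diag_value * diag(R), R, R)
  pairs <- edge_pairs(R)
  m[pairs] <- vals
  m[pairs[, c(2, 1)]] <- vals
  m
}

#' Stack per-subject connectivity vectors into a labeled feature matrix
#'
#' Runs `correlation_matrix` + `vectorize_upper` on every subject and returns
#' the cohort-level feature container used by the classifier.
#'
#' @param subjects list of [regional_ts()] objects (already preprocessed).
#' @param labels factor of class labels, one per subject, levels in the fixed
#'   class order (patient, sibling, control).
#' @param fisher_z if `TRUE`, apply the Fisher z-transform `atanh(r)` to the
#'   features. Off by default: the raw correlation is the feature.
#' @return a list of class `labeled_cohort` with `features` (subjects x E),
#'   `labels`, `n_regions`, `region_labels`.
#' @export
cohort_features <- function(subjects, labels, fisher_z = FALSE) {
  stopifnot(length(subjects) == length(labels))
  labels <- as_class_factor(labels)
  R <- nrow(subjects[[1]]$data)
  X <- t(vapply(subjects, function(s) {
    vectorize_upper(correlation_matrix(s))$values
  }, numeric(n_edges(R))))
  if (fisher_z) X <- atanh(pmin(pmax(X, -1 + 1e-12), 1 - 1e-12))
  rownames(X) <- vapply(subjects, function(s) s$subject_id, character(1))
  structure(list(features = X, labels = labels, n_regions = R,
                 region_labels = subjects[[1]]$region_labels),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("labeled_cohort:", nrow(x$features), "subjects x", ncol(x$features),
      "edges (", x$n_regions, "regions )\n")
  print(table(x$labels))
  invisible(x)
}

# the fixed three-class order: patient (schizophrenia), sibling, control
class_levels <- function() c("patient", "sibling", "control")

as_class_factor <- function(labels) {
  lv <- class_levels()
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), lv)
  if (length(bad)) {
    stop("unknown class name(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(lv, collapse = "/"), ")")
  }
  factor(labels, levels = lv)
}
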