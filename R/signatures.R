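# From fold-wise SVM weights to discriminative connectivity signatures.
#
# Each LOOCV fold trains its own PCA and its own k one-against-rest SVMs, so
# each fold's weight vector lives in that fold's PCA basis. Averaging raw
# d-dimensional weights across folds would mix incompatible bases; instead
# every fold's weight vector is first mapped back to the original edge space
# through that fold's own loadings, and the fold average is taken there. When
# all folds share one basis the two orders coincide.

#' Back-project a PCA-space weight vector to edge space
#'
#' For orthonormal loadings V the edge-space vector `V w` reproduces every
#' decision value exactly: `(V w)' (x - mean) = w' V' (x - mean)`.
#'
#' @param pca a `pca_transform`.
#' @param w length-d weight vector.
#' @return length-p vector of per-edge weights.
#' @export
backproject <- function(pca, w) {
  if (length(w) != ncol(pca$loadings)) {
    stop("weight length (", length(w), ") does not match retained dimension (",
         ncol(pca$loadings), ")")
  }
  as.numeric(pca$loadings %*% w)
}

#' Fold-average edge-space weights
#'
#' Back-projects each fold's weight vector through that fold's transform,
#' then averages across folds in edge space.
#'
#' @param per_fold_weights list of length-d numeric vectors.
#' @param per_fold_pca list of `pca_transform`s, aligned with the weights.
#' @return length-p mean edge-space weight vector.
#' @export
average_fold_weights <- function(per_fold_weights, per_fold_pca) {
  if (!length(per_fold_weights) ||
      length(per_fold_weights) != length(per_fold_pca)) {
    stop("need equally many fold weights and fold transforms (>= 1)")
  }
  mats <- mapply(backproject, per_fold_pca, per_fold_weights,
                 SIMPLIFY = TRUE)
  rowMeans(matrix(mats, ncol = length(per_fold_weights)))
}

#' Edge-space discriminative weight map of one classifier
#'
#' @param cv a `cv_result` from [loocv()] (run with `keep_transforms = TRUE`).
#' @param class_name which one-against-rest classifier.
#' @return list of class `edge_weight_map`: `classifier`, `weights`
#'   (length E, signed), `rank` (edge indices by descending |weight|).
#' @export
edge_weight_map <- function(cv, class_name) {
  if (is.null(cv$folds[[1]]$pca)) {
    stop("loocv was run with keep_transforms = FALSE; transforms unavailable")
  }
  w_list <- lapply(cv$folds, function(f) f$svm$weights[class_name, ])
  p_list <- lapply(cv$folds, function(f) f$pca)
  w <- average_fold_weights(w_list, p_list)
  structure(list(classifier = class_name, weights = w,
                 rank = order(-abs(w), seq_along(w))),
            class = "edge_weight_map")
}

#' Build an edge weight map from a plain weight vector
#'
#' @param weights length-E numeric vector of edge-space weights.
#' @param classifier classifier name to record.
#' @return an `edge_weight_map`.
#' @export
make_edge_weight_map <- function(weights, classifier = "unknown") {
  structure(list(classifier = classifier, weights = as.numeric(weights),
                 rank = order(-abs(weights), seq_along(weights))),
            class = "edge_weight_map")
}

#' Select the top fraction of edges by absolute weight
#'
#' @param map an `edge_weight_map`.
#' @param fraction fraction of edges to keep (default 0.05, the original
#'   analysis' 5%); `floor(fraction * E)` edges are returned.
#' @param top_k overrides `fraction` with an explicit count.
#' @return integer vector of edge indices, ordered by descending |weight|;
#'   ties at the cut go to the lower edge index.
#' @export
top_fraction <- function(map, fraction = 0.05, top_k = NULL) {
  E <- length(map$weights)
  k <- if (!is.null(top_k)) as.integer(top_k) else as.integer(floor(fraction * E))
  if (k < 1L || k > E) stop("selection size out of range 1..", E)
  map$rank[seq_len(k)]
}

#' Derive the state / trait / compensatory signature sets
#'
#' The mapping from one-against-rest classifiers to signature types follows
#' the semantics of each pattern: the patient-vs-rest classifier isolates
#' what makes patients different from everyone (state, illness expression);
#' the control-vs-rest classifier isolates what separates controls from the
#' two genetically loaded groups, i.e. abnormality shared by patients and
#' siblings (trait); the sibling-vs-rest classifier isolates what makes
#' unaffected siblings unlike both (compensatory).
#'
#' @param cv a `cv_result` from [loocv()].
#' @param fraction,top_k selection size, see [top_fraction()].
#' @param mapping named character vector classifier -> signature; the default
#'   is the mapping above.
#' @return list of class `signature_set`: `state_edges`, `trait_edges`,
#'   `compensatory_edges` (edge indices, descending |weight|), `maps` (the
#'   three `edge_weight_map`s keyed by classifier), `selection_fraction`,
#'   `top_k`, `overlap` (pairwise intersection counts).
#' @export
derive_signatures <- function(cv, fraction = 0.05, top_k = NULL,
                              mapping = c(patient = "state",
                                          control = "trait",
                                          sibling = "compensatory")) {
  stopifnot(setequal(names(mapping), class_levels()),
            setequal(mapping, c("state", "trait", "compensatory")))
  maps <- if (inherits(cv, "cv_result")) {
    lapply(stats::setNames(nm = class_levels()),
           function(cl) edge_weight_map(cv, cl))
  } else if (all(class_levels() %in% names(cv))) {
    cv[class_levels()]  # pre-built edge_weight_maps keyed by classifier
  } else {
    stop("need a cv_result or a named list of edge_weight_maps")
  }
  sets <- lapply(maps, top_fraction, fraction = fraction, top_k = top_k)
  out <- list(state_edges = sets[[names(which(mapping == "state"))]],
              trait_edges = sets[[names(which(mapping == "trait"))]],
              compensatory_edges = sets[[names(which(mapping == "compensatory"))]],
              maps = maps,
              selection_fraction = fraction,
              top_k = if (is.null(top_k)) length(sets[[1]]) else as.integer(top_k),
              mapping = mapping)
  nm <- c("state_edges", "trait_edges", "compensatory_edges")
  out$overlap <- outer(nm, nm, Vectorize(function(a, b)
    length(intersect(out[[a]], out[[b]]))))
  dimnames(out$overlap) <- list(nm, nm)
  structure(out, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", x$top_k, "edges per classifier (fraction",
      x$selection_fraction, ")\n")
  cat("pairwise overlaps:\n")
  print(x$overlap)
  invisible(x)
}

#' Hypergeometric enrichment of planted edges in a signature set
#'
#' Tests whether a selected edge set contains more planted ground-truth edges
#' than expected when drawing the same number of edges at random.
#'
#' @param selected integer vector of selected edge indices.
#' @param planted integer vector of planted (true) edge indices.
#' @param n_total total number of edges E.
#' @return list with `overlap`, `expected`, `p_value` (upper-tail
#'   hypergeometric).
#' @export
signature_enrichment <- function(selected, planted, n_total) {
  q <- length(intersect(selected, planted))
  m <- length(planted)
  k <- length(selected)
  list(overlap = q,
       expected = k * m / n_total,
       p_value = stats::phyper(q - 1L, m, n_total - m, k, lower.tail = FALSE))
}

#' Human-readable edge table for a signature
#'
#' @param edges integer vector of edge indices (e.g. a signature set).
#' @param region_labels character vector covering the parcellation.
#' @param map the `edge_weight_map` the edges were selected from.
#' @return data.frame with columns `edge`, `region_i`, `region_j`,
#'   `region_i_name`, `region_j_name`, `weight`, `abs_rank`, sorted by rank.
#' @export
label_edges <- function(edges, region_labels, map) {
  R <- length(region_labels)
  if (n_edges(R) != length(map$weights)) {
    stop("label count does not cover the parcellation of this weight map")
  }
  if (!length(edges)) {
    return(data.frame(edge = integer(0), region_i = integer(0),
                      region_j = integer(0), region_i_name = character(0),
                      region_j_name = character(0), weight = numeric(0),
                      abs_rank = integer(0)))
  }
  if (any(edges < 1L | edges > length(map$weights))) stop("unknown edge index")
  pairs <- edge_to_pair(edges, R)
  rank_of <- integer(length(map$weights))
  rank_of[map$rank] <- seq_along(map$rank)
  out <- data.frame(edge = as.integer(edges),
                    region_i = pairs[, 1], region_j = pairs[, 2],
                    region_i_name = region_labels[pairs[, 1]],
                    region_j_name = region_labels[pairs[, 2]],
                    weight = map$weights[edges],
                    abs_rank = rank_of[edges])
  out[order(out$abs_rank), , drop = FALSE]
}
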