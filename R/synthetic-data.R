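# Synthetic three-group cohort generator.
#
# The real fMRI cohort (patients with schizophrenia, their healthy siblings,
# matched healthy controls) was never deposited, so every downstream stage is
# exercised on simulated cohorts with a known ground truth. Group structure is
# encoded in the cross-regional correlation matrix: a shared background
# network, plus designated edges whose correlation is shifted by `delta_r` in
# specific groups —
#   state edges:        shifted in patients only,
#   trait edges:        shifted in patients AND siblings,
#   compensatory edges: shifted in siblings only.
# Subjects are sampled as lag-1 autoregressive Gaussian series whose
# stationary cross-sectional correlation equals the group matrix, then
# contaminated with a shared global-signal component and smooth motion-like
# regressors so the nuisance-regression stage has real work to do.

#' Configuration for a synthetic three-group cohort
#'
#' @param n_per_group integer vector of length 3: subjects per class in the
#'   order (patient, sibling, control). Default `c(24, 25, 22)`, the retained
#'   sample sizes of the original cohort; use e.g. `rep(20, 3)` for balanced
#'   designs.
#' @param n_regions parcellation size R. Default 116.
#' @param n_volumes retained volumes T per subject. Default 175 (180 acquired
#'   at TR = 2 s over 6 min, minus 5 discarded).
#' @param tr_seconds sampling interval. Default 2.
#' @param base_correlation mean off-diagonal correlation of the shared
#'   background network. Default 0.1.
#' @param planted_edges either `NULL` (sample disjoint random edges according
#'   to `n_planted`) or a named list with elements `state`, `trait`,
#'   `compensatory`, each a list with `pairs` (two-column matrix of region
#'   pairs, i < j) and `delta_r` (signed correlation shift).
#' @param n_planted integer vector of length 3: how many state / trait /
#'   compensatory edges to sample when `planted_edges` is `NULL`. Default
#'   `c(10, 10, 10)`.
#' @param delta_r default effect size used for sampled planted edges (scalar
#'   or length 3). Default 0.5.
#' @param ar_coefficient lag-1 autocorrelation of the regional series.
#'   Default 0.4, giving BOLD-like smoothness at TR = 2 s.
#' @param global_signal_sd amplitude of the shared global component added to
#'   every region. Default 0.5.
#' @param n_motion_regressors number of motion-like confound series. Default 6.
#' @param motion_sd amplitude of the motion contamination. Default 0.3.
#' @param seed integer seed controlling edge sampling and subject simulation.
#' @return an object of class `cohort_config` with concrete planted edge
#'   lists (sampling happens here, so the config fully determines the cohort).
#' @export
cohort_config <- function(n_per_group = c(24L, 25L, 22L),
                          n_regions = 116L,
                          n_volumes = 175L,
                          tr_seconds = 2,
                          base_correlation = 0.1,
                          planted_edges = NULL,
                          n_planted = c(10L, 10L, 10L),
                          delta_r = 0.5,
                          ar_coefficient = 0.4,
                          global_signal_sd = 0.5,
                          n_motion_regressors = 6L,
                          motion_sd = 0.3,
                          seed = 1L) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1L),
            n_regions >= 2L, n_volumes >= 2L, tr_seconds > 0,
            abs(base_correlation) < 1,
            abs(ar_coefficient) < 1, global_signal_sd >= 0,
            n_motion_regressors >= 0L, motion_sd >= 0)
  if (is.null(planted_edges)) {
    stopifnot(length(n_planted) == 3L)
    delta_r <- rep_len(delta_r, 3L)
    E <- n_edges(n_regions)
    total <- sum(n_planted)
    if (total > E) stop("more planted edges than available edges")
    idx <- withr_seed(seed, sample.int(E, total))
    pairs <- edge_pairs(n_regions)
    split_at <- cumsum(c(0L, n_planted))
    planted_edges <- list(
      state = list(pairs = pairs[idx[seq_len(n_planted[1])], , drop = FALSE],
                   delta_r = delta_r[1]),
      trait = list(pairs = pairs[idx[split_at[2] + seq_len(n_planted[2])], , drop = FALSE],
                   delta_r = delta_r[2]),
      compensatory = list(pairs = pairs[idx[split_at[3] + seq_len(n_planted[3])], , drop = FALSE],
                          delta_r = delta_r[3])
    )
  }
  cfg <- structure(list(n_per_group = as.integer(n_per_group),
                        n_regions = as.integer(n_regions),
                        n_volumes = as.integer(n_volumes),
                        tr_seconds = tr_seconds,
                        base_correlation = base_correlation,
                        planted_edges = planted_edges,
                        ar_coefficient = ar_coefficient,
                        global_signal_sd = global_signal_sd,
                        n_motion_regressors = as.integer(n_motion_regressors),
                        motion_sd = motion_sd,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  pe <- cfg$planted_edges
  stopifnot(setequal(names(pe), c("state", "trait", "compensatory")))
  E <- n_edges(cfg$n_regions)
  all_idx <- integer(0)
  for (nm in c("state", "trait", "compensatory")) {
    p <- pe[[nm]]$pairs
    if (nrow(p)) {
      if (any(p[, 1] >= p[, 2]) || any(p[, 1] < 1) || any(p[, 2] > cfg$n_regions)) {
        stop("planted ", nm, " edges must reference valid pairs i < j")
      }
      if (abs(cfg$base_correlation + pe[[nm]]$delta_r) >= 1) {
        stop("|base_correlation + delta_r| must be < 1 for ", nm, " edges")
      }
      all_idx <- c(all_idx, pair_to_edge(p[, 1], p[, 2], cfg$n_regions))
    }
  }
  if (anyDuplicated(all_idx)) stop("planted edge lists must be pairwise disjoint")
  invisible(cfg)
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build one group's target correlation matrix
#'
#' Starts from the shared background (constant `base_correlation` off the
#' diagonal), adds each planted list's `delta_r` on the edges active in the
#' requested group, and repairs the result to the nearest symmetric positive
#' definite correlation matrix if the perturbation broke positive
#' definiteness (eigenvalue flooring at 1e-6, then re-normalizing the
#' diagonal to 1).
#'
#' @param config a [cohort_config()].
#' @param group one of `"patient"`, `"sibling"`, `"control"`.
#' @return R x R correlation matrix with attributes `repaired` (logical) and
#'   `group`.
#' @export
make_group_covariance <- function(config, group = class_levels()) {
  group <- match.arg(group)
  R <- config$n_regions
  m <- matrix(config$base_correlation, R, R)
  diag(m) <- 1
  active <- switch(group,
                   patient = c("state", "trait"),
                   sibling = c("trait", "compensatory"),
                   control = character(0))
  for (nm in active) {
    p <- config$planted_edges[[nm]]$pairs
    if (!nrow(p)) next
    d <- config$planted_edges[[nm]]$delta_r
    newval <- m[p] + d
    if (any(abs(newval) >= 1)) {
      stop("planted ", nm, " shift drives |correlation| >= 1")
    }
    m[p] <- newval
    m[p[, c(2, 1), drop = FALSE]] <- newval
  }
  repaired <- FALSE
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) <= 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    repaired <- TRUE
  }
  attr(m, "repaired") <- repaired
  attr(m, "group") <- group
  m
}

#' Simulate one subject's regional time series
#'
#' Samples a lag-1 autoregressive Gaussian process initialized at
#' stationarity, so the cross-sectional correlation of the series equals
#' `cov` exactly in expectation: `x_t = phi * x_(t-1) + sqrt(1 - phi^2) * L z_t`
#' with `L` the Cholesky factor of `cov`. A shared global component (equal
#' loading on every region, scaled by `global_signal_sd`) and a linear
#' combination of smooth motion-like regressors are then added; the motion
#' table travels with the subject so nuisance regression can remove it.
#'
#' @param cov SPD correlation matrix (from [make_group_covariance()]).
#' @param config a [cohort_config()].
#' @param subject_id identifier for the returned object.
#' @param seed optional integer; when given, output is a deterministic
#'   function of `(cov, config, seed)`.
#' @return a [regional_ts()] carrying the motion table.
#' @export
simulate_subject <- function(cov, config, subject_id = "sim", seed = NULL) {
  R <- config$n_regions
  T <- config$n_volumes
  stopifnot(nrow(cov) == R, ncol(cov) == R)
  ev_min <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) stop("covariance must be symmetric positive definite")
  sim <- function() {
    L <- chol(cov)   # upper triangular, t(L) %*% L = cov
    phi <- config$ar_coefficient
    innov <- matrix(stats::rnorm(R * T), nrow = T) %*% L  # T x R, rows ~ N(0, cov)
    x <- matrix(0, nrow = T, ncol = R)
    x[1, ] <- innov[1, ]
    if (T > 1) {
      sc <- sqrt(1 - phi^2)
      for (t in 2:T) x[t, ] <- phi * x[t - 1, ] + sc * innov[t, ]
    }
    # shared global component with the same temporal smoothness
    if (config$global_signal_sd > 0) {
      g <- as.numeric(stats::arima.sim(list(ar = phi), n = T,
                                       innov = stats::rnorm(T) * sqrt(1 - phi^2),
                                       n.start = 50))
      x <- x + config$global_signal_sd * g
    }
    motion <- NULL
    if (config$n_motion_regressors > 0) {
      # slow drifts: standardized random walks
      motion <- apply(matrix(stats::rnorm(T * config$n_motion_regressors),
                             nrow = T), 2, cumsum)
      motion <- scale(motion)
      colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                            "rot_x", "rot_y", "rot_z",
                            paste0("m", seq_len(max(0, config$n_motion_regressors - 6L)) + 6L)
                            )[seq_len(config$n_motion_regressors)]
      if (config$motion_sd > 0) {
        B <- matrix(stats::rnorm(R * config$n_motion_regressors, sd = config$motion_sd),
                    nrow = config$n_motion_regressors)
        x <- x + motion %*% B
      }
    }
    regional_ts(t(x), tr_seconds = config$tr_seconds,
                subject_id = subject_id, motion = motion)
  }
  if (is.null(seed)) sim() else withr_seed(seed, sim())
}

#' Generate a full three-group cohort with ground truth
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with `subjects` (list of
#'   [regional_ts()]), `labels` (factor patient/sibling/control),
#'   `ground_truth` (canonical edge-index sets for the three planted lists,
#'   the three group correlation matrices, and repair flags) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  covs <- lapply(stats::setNames(class_levels(), class_levels()),
                 function(g) make_group_covariance(config, g))
  labels <- factor(rep(class_levels(), times = config$n_per_group),
                   levels = class_levels())
  n <- length(labels)
  subject_seeds <- withr_seed(config$seed, sample.int(.Machine$integer.max - 1L, n))
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    g <- as.character(labels[s])
    subjects[[s]] <- simulate_subject(covs[[g]], config,
                                      subject_id = sprintf("sub%03d_%s", s, g),
                                      seed = subject_seeds[s])
  }
  gt <- list(
    state_edges = planted_idx(config, "state"),
    trait_edges = planted_idx(config, "trait"),
    compensatory_edges = planted_idx(config, "compensatory"),
    group_covariances = covs,
    repaired = vapply(covs, function(m) attr(m, "repaired"), logical(1))
  )
  structure(list(subjects = subjects, labels = labels,
                 ground_truth = gt, config = config),
            class = "synthetic_cohort")
}

planted_idx <- function(config, which) {
  p <- config$planted_edges[[which]]$pairs
  if (!nrow(p)) return(integer(0))
  sort(pair_to_edge(p[, 1], p[, 2], config$n_regions))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$subjects), "subjects,",
      x$config$n_regions, "regions x", x$config$n_volumes, "volumes\n")
  print(table(x$labels))
  cat("planted edges: state", length(x$ground_truth$state_edges),
      "| trait", length(x$ground_truth$trait_edges),
      "| compensatory", length(x$ground_truth$compensatory_edges), "\n")
  invisible(x)
}
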