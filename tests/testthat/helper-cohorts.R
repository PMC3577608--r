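# shared fixture builders -- everything is generated in code at test time

class_order <- c("patient", "sibling", "control")

# a small, fast synthetic cohort with strong planted effects
small_cohort <- function(n = 8L, R = 20L, T = 120L, delta = 0.5, seed = 42L,
                         n_planted = c(5L, 5L, 5L), ...) {
  generate_cohort(cohort_config(n_per_group = rep(n, 3L), n_regions = R,
                                n_volumes = T, n_planted = n_planted,
                                delta_r = delta, seed = seed, ...))
}

# raw-feature cohort (no preprocessing)
plain_features <- function(cohort) {
  cohort_features(cohort$subjects, cohort$labels)
}

# a deterministic separable toy: features are a noisy one-hot class encoding
onehot_cohort <- function(n_per_class = 5L, noise = 0.01, p = 6L, seed = 1L) {
  labels <- factor(rep(class_order, each = n_per_class), levels = class_order)
  X <- local_seed(seed, {
    base <- diag(3)[as.integer(labels), , drop = FALSE]
    cbind(base, matrix(0, nrow(base), p - 3L)) +
      matrix(rnorm(length(labels) * p, sd = noise), ncol = p)
  })
  structure(list(features = X, labels = labels), class = "labeled_cohort")
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
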