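# cohort generator: covariance construction, AR(1) sampling, ground truth

manual_config <- function(base = 0.2, delta = 0.3, R = 6L, edge = c(1L, 2L)) {
  cohort_config(n_per_group = c(2L, 2L, 2L), n_regions = R, n_volumes = 40L,
                base_correlation = base,
                planted_edges = list(
                  state = list(pairs = matrix(integer(0), 0, 2), delta_r = 0),
                  trait = list(pairs = matrix(edge, 1, 2), delta_r = delta),
                  compensatory = list(pairs = matrix(integer(0), 0, 2), delta_r = 0)),
                seed = 3L)
}

test_that("group covariances encode state/trait/compensatory semantics", {
  # hand-built oracle: background 0.2 everywhere, trait edge (1,2) shifted by
  # +0.3 in patient and sibling only
  cfg <- manual_config()
  expected_control <- matrix(0.2, 6, 6); diag(expected_control) <- 1
  expected_shifted <- expected_control
  expected_shifted[1, 2] <- expected_shifted[2, 1] <- 0.5
  pat <- make_group_covariance(cfg, "patient")
  sib <- make_group_covariance(cfg, "sibling")
  ctl <- make_group_covariance(cfg, "control")
  expect_equal(unclass(ctl), expected_control, ignore_attr = TRUE)
  expect_equal(unclass(pat), expected_shifted, ignore_attr = TRUE)
  expect_equal(unclass(sib), expected_shifted, ignore_attr = TRUE)
  expect_false(attr(pat, "repaired"))

  # zero effect -> all three identical; zero background -> identity
  cfg0 <- manual_config(delta = 0)
  mats <- lapply(class_order, function(g) unclass(make_group_covariance(cfg0, g)))
  expect_equal(mats[[1]], mats[[2]], ignore_attr = TRUE)
  expect_equal(mats[[2]], mats[[3]], ignore_attr = TRUE)
  cfgI <- manual_config(base = 0, delta = 0)
  expect_equal(unclass(make_group_covariance(cfgI, "control")), diag(6),
               ignore_attr = TRUE)
})

test_that("covariances are SPD, with repair when perturbation breaks PD", {
  for (g in class_order) {
    m <- make_group_covariance(cohort_config(n_regions = 30L, seed = 5L), g)
    expect_true(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > 0)
    expect_equal(diag(m), rep(1, 30))
  }
  # high background with a strong negative shift is inconsistent with PD:
  # the repair must kick in and still return a unit-diagonal SPD matrix
  cfg <- manual_config(base = 0.9, delta = -1.6, R = 4L)
  pat <- make_group_covariance(cfg, "patient")
  expect_true(attr(pat, "repaired"))
  expect_true(min(eigen(pat, symmetric = TRUE, only.values = TRUE)$values) > 0)
  expect_equal(diag(pat), rep(1, 4))
  # entries that would leave [-1, 1] are rejected outright (at config time)
  expect_error(manual_config(base = 0.9, delta = 0.2), "< 1")
})

test_that("config validation rejects bad planted edge lists", {
  expect_error(cohort_config(planted_edges = list(
    state = list(pairs = matrix(c(2L, 1L), 1, 2), delta_r = 0.3),
    trait = list(pairs = matrix(integer(0), 0, 2), delta_r = 0),
    compensatory = list(pairs = matrix(integer(0), 0, 2), delta_r = 0))),
    "i < j")
  expect_error(cohort_config(planted_edges = list(
    state = list(pairs = matrix(c(1L, 2L), 1, 2), delta_r = 0.3),
    trait = list(pairs = matrix(c(1L, 2L), 1, 2), delta_r = 0.3),
    compensatory = list(pairs = matrix(integer(0), 0, 2), delta_r = 0))),
    "disjoint")
  expect_error(cohort_config(base_correlation = 0.6,
                             planted_edges = list(
    state = list(pairs = matrix(c(1L, 2L), 1, 2), delta_r = 0.5),
    trait = list(pairs = matrix(integer(0), 0, 2), delta_r = 0),
    compensatory = list(pairs = matrix(integer(0), 0, 2), delta_r = 0))),
    "delta_r")
})

test_that("simulated series match their target covariance and autocorrelation", {
  # law-of-large-numbers oracle: iid mode at T = 50,000, 5 regions
  cfg <- cohort_config(n_per_group = c(2L, 2L, 2L), n_regions = 5L,
                       n_volumes = 50000L, base_correlation = 0.3,
                       n_planted = c(0L, 0L, 0L), ar_coefficient = 0,
                       global_signal_sd = 0, n_motion_regressors = 0L,
                       seed = 9L)
  cov <- make_group_covariance(cfg, "control")
  ts <- simulate_subject(cov, cfg, seed = 17L)
  expect_lt(max(abs(stats::cor(t(ts$data)) - cov)), 0.02)

  # sample-ACF oracle: phi = 0.9 recovered within 0.05 at T = 5,000
  cfg_ar <- cohort_config(n_per_group = c(2L, 2L, 2L), n_regions = 3L,
                          n_volumes = 5000L, base_correlation = 0,
                          n_planted = c(0L, 0L, 0L), ar_coefficient = 0.9,
                          global_signal_sd = 0, n_motion_regressors = 0L,
                          seed = 9L)
  ts_ar <- simulate_subject(make_group_covariance(cfg_ar, "control"), cfg_ar,
                            seed = 23L)
  acf1 <- apply(ts_ar$data, 1, function(x)
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2])
  expect_true(all(abs(acf1 - 0.9) < 0.05))

  # seeded determinism is bit-exact
  a <- simulate_subject(cov, cfg, seed = 31L)
  b <- simulate_subject(cov, cfg, seed = 31L)
  expect_identical(a$data, b$data)
  expect_identical(a$motion, b$motion)

  expect_error(simulate_subject(matrix(1, 5, 5), cfg), "positive definite")
})

test_that("generate_cohort produces the requested group structure", {
  cfg <- cohort_config(n_per_group = c(24L, 25L, 22L), n_regions = 10L,
                       n_volumes = 20L, n_planted = c(2L, 2L, 2L), seed = 4L)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 71L)
  expect_equal(as.integer(table(coh$labels)), c(24L, 25L, 22L))
  expect_true(all(vapply(coh$subjects, function(s) !is.null(s$motion), logical(1))))
  expect_equal(dim(coh$subjects[[1]]$motion), c(20L, 6L))
  expect_length(coh$ground_truth$state_edges, 2L)

  tiny <- generate_cohort(cohort_config(n_per_group = c(1L, 1L, 1L),
                                        n_regions = 6L, n_volumes = 10L,
                                        n_planted = c(1L, 1L, 1L), seed = 4L))
  expect_equal(as.character(tiny$labels), class_order)
})

test_that("planted effects are recoverable in group-mean sample correlations", {
  # at delta = 0.5, n = 20/group, T = 175 the planted-edge group contrast
  # clears delta/2
  coh <- small_cohort(n = 20L, R = 20L, T = 175L, delta = 0.5, seed = 77L,
                      global_signal_sd = 0, n_motion_regressors = 0L)
  lc <- plain_features(coh)
  gmean <- function(g, e) mean(lc$features[lc$labels == g, e])
  st <- coh$ground_truth$state_edges
  expect_gt(gmean("patient", st) - gmean("control", st), 0.25)
  tr <- coh$ground_truth$trait_edges
  expect_gt(gmean("sibling", tr) - gmean("control", tr), 0.25)
  cp <- coh$ground_truth$compensatory_edges
  expect_gt(gmean("sibling", cp) - gmean("patient", cp), 0.25)
})

test_that("null cohorts are label-exchangeable (uniform permutation p-values)", {
  # downstream statistic: mean patient-vs-control difference over the first
  # 10 edges; its label-permutation p-value must be uniform across replicate
  # null cohorts
  n_rep <- 40L; n_perm <- 99L
  pvals <- vapply(seq_len(n_rep), function(r) {
    coh <- small_cohort(n = 5L, R = 10L, T = 60L, delta = 0, seed = 500L + r,
                        global_signal_sd = 0, n_motion_regressors = 0L)
    lc <- plain_features(coh)
    stat <- function(lab) {
      abs(mean(lc$features[lab == "patient", 1:10]) -
            mean(lc$features[lab == "control", 1:10]))
    }
    obs <- stat(lc$labels)
    null <- local_seed(900L + r, {
      vapply(seq_len(n_perm), function(i) stat(sample(lc$labels)), numeric(1))
    })
    (sum(null >= obs) + 1) / (n_perm + 1)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.005)
})
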