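# End-to-end convenience wrappers tying the stages together.

#' Preprocess every subject of a cohort
#'
#' @param subjects list of [regional_ts()].
#' @param ... passed to [preprocess_subject()].
#' @return list of preprocessed subjects.
#' @export
preprocess_cohort <- function(subjects, ...) {
  lapply(subjects, preprocess_subject, ...)
}

#' Run the full classification analysis on a cohort
#'
#' preprocess (optional) -> connectivity features -> LOOCV -> permutation
#' test -> signature derivation.
#'
#' @param subjects list of [regional_ts()] (raw or already preprocessed).
#' @param labels class labels (patient / sibling / control).
#' @param preprocess run temporal preprocessing first (default TRUE).
#' @param discard_volumes,low_hz,high_hz preprocessing parameters.
#' @param d,cost_c classifier parameters (see [loocv()]).
#' @param n_perm permutations for the null (0 skips the permutation test).
#' @param seed master seed for the permutation streams.
#' @param fraction,top_k signature selection size.
#' @return list of class `connsig_analysis` with `cohort`, `cv`, `perm`,
#'   `signatures` and the parameter set actually used.
#' @export
run_analysis <- function(subjects, labels, preprocess = TRUE,
                         discard_volumes = 0L, low_hz = 0.01, high_hz = 0.08,
                         d = NULL, cost_c = 1, n_perm = 1000L, seed = 1L,
                         fraction = 0.05, top_k = NULL) {
  if (preprocess) {
    subjects <- preprocess_cohort(subjects, discard_volumes = discard_volumes,
                                  low_hz = low_hz, high_hz = high_hz)
  }
  cohort <- cohort_features(subjects, labels)
  cv <- loocv(cohort, d = d, cost_c = cost_c)
  perm <- if (n_perm > 0L) {
    permutation_test(cohort, d = d, cost_c = cost_c, n_perm = n_perm,
                     seed = seed, observed = cv)
  }
  sigs <- derive_signatures(cv, fraction = fraction, top_k = top_k)
  structure(list(cohort = cohort, cv = cv, perm = perm, signatures = sigs,
                 params = list(preprocess = preprocess,
                               discard_volumes = discard_volumes,
                               low_hz = low_hz, high_hz = high_hz,
                               d = if (is.null(d)) "n_train - 1" else d,
                               cost_c = cost_c, n_perm = n_perm, seed = seed,
                               fraction = fraction,
                               top_k = sigs$top_k)),
            class = "connsig_analysis")
}

#' @export
print.connsig_analysis <- function(x, ...) {
  print(x$cv)
  if (!is.null(x$perm)) print(x$perm)
  print(x$signatures)
  invisible(x)
}
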