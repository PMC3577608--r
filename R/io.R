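# Delimited-text readers/writers and the results bundle.
#
# Time series travel as TSV with one header row of region labels and volumes
# as rows (a transposed file with regions as rows and a leading label column
# is auto-detected). Labels are a two-column subject/class table. Results are
# a JSON summary plus per-signature edge tables, all stamped with the
# configuration and seed that produced them.

#' Read a regional time-series table
#'
#' @param path TSV/CSV file. Canonical layout: header row of region labels,
#'   one row per volume. If the first column is non-numeric it is taken as
#'   region labels and the table as regions x volumes (transposed layout).
#' @param tr_seconds sampling interval to attach.
#' @param subject_id defaults to the file name.
#' @return a [regional_ts()].
#' @export
read_timeseries_table <- function(path, tr_seconds = 2,
                                  subject_id = sub("\\.[^.]*$", "", basename(path))) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(raw)) stop("empty table: ", path)
  transposed <- is.character(raw[[1]]) &&
    all(is.na(suppressWarnings(as.numeric(raw[[1]]))))
  if (transposed) {
    labels <- as.character(raw[[1]])
    body <- raw[, -1, drop = FALSE]
    mat <- sapply(body, function(col) check_numeric_col(col, path))
    data <- matrix(as.numeric(mat), nrow = length(labels))
  } else {
    labels <- colnames(raw)
    mat <- sapply(raw, function(col) check_numeric_col(col, path))
    data <- t(matrix(as.numeric(mat), nrow = nrow(raw)))
  }
  if (anyNA(data)) {
    bad <- which(is.na(data), arr.ind = TRUE)[1, ]
    stop("missing/malformed value in ", path, " at region ", bad[1],
         ", volume ", bad[2])
  }
  regional_ts(data, tr_seconds, region_labels = labels, subject_id = subject_id)
}

check_numeric_col <- function(col, path) {
  suppressWarnings(as.numeric(col))
}

#' Write a regional time-series table
#'
#' Canonical layout: header of region labels, one row per volume.
#' @param ts a [regional_ts()].
#' @param path output file.
#' @export
write_timeseries_table <- function(ts, path) {
  df <- as.data.frame(t(ts$data))
  colnames(df) <- ts$region_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a motion-regressor table
#' @param ts a [regional_ts()] carrying a motion table.
#' @param path output file.
#' @export
write_motion_table <- function(ts, path) {
  if (is.null(ts$motion)) stop("subject has no motion table")
  utils::write.table(as.data.frame(ts$motion), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion-regressor table
#' @param path TSV with one column per regressor, one row per volume.
#' @return numeric matrix.
#' @export
read_motion_table <- function(path) {
  as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' Read a subject-to-class label table
#'
#' @param path two-column delimited file `subject<TAB>class`; class must be
#'   one of patient / sibling / control.
#' @return data.frame with `subject` and `class` (factor in the fixed order).
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label table needs two columns: subject, class")
  names(df)[1:2] <- c("subject", "class")
  df$class <- as_class_factor(df$class)
  if (anyDuplicated(df$subject)) stop("duplicate subject ids in label table")
  df
}

#' Read an ordered region-label list
#' @param path one label per line.
#' @return character vector.
#' @export
read_region_labels <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  if (anyDuplicated(x)) stop("duplicate region labels")
  x
}

#' The 116-region anatomical parcellation labels
#'
#' Region names of the standard 116-region anatomical template (90 cerebral
#' regions in left/right pairs, 18 cerebellar hemispheric regions, 8 vermis
#' regions), in conventional template order.
#'
#' @return character vector of length 116.
#' @export
aal116_labels <- function() {
  cerebral <- c("Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
                "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
                "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area",
                "Olfactory", "Frontal_Sup_Medial", "Frontal_Med_Orb",
                "Rectus", "Insula", "Cingulum_Ant", "Cingulum_Mid",
                "Cingulum_Post", "Hippocampus", "ParaHippocampal", "Amygdala",
                "Calcarine", "Cuneus", "Lingual", "Occipital_Sup",
                "Occipital_Mid", "Occipital_Inf", "Fusiform", "Postcentral",
                "Parietal_Sup", "Parietal_Inf", "SupraMarginal", "Angular",
                "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
                "Pallidum", "Thalamus", "Heschl", "Temporal_Sup",
                "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
                "Temporal_Inf")
  cerebellum <- c("Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3",
                  "Cerebelum_4_5", "Cerebelum_6", "Cerebelum_7b",
                  "Cerebelum_8", "Cerebelum_9", "Cerebelum_10")
  vermis <- c("Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6", "Vermis_7",
              "Vermis_8", "Vermis_9", "Vermis_10")
  c(as.vector(rbind(paste0(cerebral, "_L"), paste0(cerebral, "_R"))),
    as.vector(rbind(paste0(cerebellum, "_L"), paste0(cerebellum, "_R"))),
    vermis)
}

#' Write the analysis results bundle
#'
#' Emits `summary.json` (accuracy, confusion matrix, permutation p-value,
#' configuration, seed), one `signature_<type>.tsv` edge table per signature,
#' and `edge_weights.tsv` with the three full fold-averaged weight vectors.
#'
#' @param cv a `cv_result`.
#' @param perm a `perm_result` (or `NULL` to skip).
#' @param sigs a `signature_set` (or `NULL` to skip).
#' @param out_dir output directory, created if missing.
#' @param region_labels parcellation labels for the edge tables.
#' @param config list of parameters to stamp into the summary.
#' @param timestamp include a timestamp in the JSON (default `FALSE` so
#'   identical runs produce byte-identical output).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(cv, perm = NULL, sigs = NULL, out_dir,
                          region_labels = NULL, config = list(),
                          timestamp = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    n_subjects = length(cv$predicted),
    accuracy_percent = 100 * cv$accuracy,
    confusion_percent = as.data.frame.matrix(cv$confusion),
    per_class_accuracy_percent = as.list(diag(cv$confusion)),
    config = config
  )
  if (!is.null(perm)) {
    summary$permutation <- list(n_perm = perm$n_perm,
                                p_value = perm$p_value,
                                null_mean_accuracy_percent =
                                  100 * mean(perm$null_accuracies),
                                seed = perm$seed)
  }
  if (timestamp) summary$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(sigs)) {
    if (is.null(region_labels)) {
      R <- (1 + sqrt(1 + 8 * length(sigs$maps[[1]]$weights))) / 2
      region_labels <- paste0("R", seq_len(R))
    }
    for (type in c("state", "trait", "compensatory")) {
      cls <- names(which(sigs$mapping == type))
      tab <- label_edges(sigs[[paste0(type, "_edges")]], region_labels,
                         sigs$maps[[cls]])
      utils::write.table(tab, file.path(out_dir, paste0("signature_", type, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    w <- data.frame(edge = seq_along(sigs$maps[[1]]$weights),
                    patient_vs_rest = sigs$maps$patient$weights,
                    sibling_vs_rest = sigs$maps$sibling$weights,
                    control_vs_rest = sigs$maps$control$weights)
    utils::write.table(w, file.path(out_dir, "edge_weights.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' Write a synthetic cohort to a directory
#'
#' Per-subject time-series and motion TSVs, a `labels.tsv` table, the region
#' labels, and the ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory.
#' @param region_labels optional label vector; defaults to `R1..Rn` (or the
#'   116-region template names when R = 116).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, region_labels = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  R <- cohort$config$n_regions
  if (is.null(region_labels)) {
    region_labels <- if (R == 116L) aal116_labels() else paste0("R", seq_len(R))
  }
  writeLines(region_labels, file.path(out_dir, "region_labels.txt"))
  ids <- character(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    sub$region_labels <- region_labels
    ids[s] <- sub$subject_id
    write_timeseries_table(sub, file.path(out_dir, paste0(sub$subject_id, "_ts.tsv")))
    if (!is.null(sub$motion)) {
      write_motion_table(sub, file.path(out_dir, paste0(sub$subject_id, "_motion.tsv")))
    }
  }
  utils::write.table(data.frame(subject = ids, class = as.character(cohort$labels)),
                     file.path(out_dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(list(state_edges = gt$state_edges,
                            trait_edges = gt$trait_edges,
                            compensatory_edges = gt$compensatory_edges,
                            repaired = as.list(gt$repaired),
                            seed = cohort$config$seed,
                            n_regions = R),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a cohort directory back into memory
#'
#' Counterpart of [write_cohort()]: expects `labels.tsv`,
#' `region_labels.txt`, and per-subject `<id>_ts.tsv` (+ optional
#' `<id>_motion.tsv`).
#'
#' @param dir cohort directory.
#' @param tr_seconds sampling interval to attach.
#' @return list with `subjects` and `labels`.
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  labels <- read_labels(file.path(dir, "labels.tsv"))
  region_labels <- read_region_labels(file.path(dir, "region_labels.txt"))
  subjects <- vector("list", nrow(labels))
  for (s in seq_len(nrow(labels))) {
    id <- labels$subject[s]
    ts_path <- file.path(dir, paste0(id, "_ts.tsv"))
    if (!file.exists(ts_path)) {
      stop("subject '", id, "' listed in labels.tsv has no time-series file")
    }
    ts <- read_timeseries_table(ts_path, tr_seconds, subject_id = id)
    if (!identical(ts$region_labels, region_labels)) {
      stop("region labels of subject '", id, "' do not match region_labels.txt")
    }
    motion_path <- file.path(dir, paste0(id, "_motion.tsv"))
    if (file.exists(motion_path)) ts$motion <- read_motion_table(motion_path)
    subjects[[s]] <- ts
  }
  list(subjects = subjects, labels = labels$class)
}
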