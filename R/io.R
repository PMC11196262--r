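#' Read a beat-level Doppler CSV
#'
#' Expected columns: `subject_id`, `stage` (one of [stage_labels()]),
#' `t_s`, `vti_cm`, `pv_cm_s`, `resp_phase`. One row per cardiac cycle.
#'
#' @param path CSV file path.
#' @return Data frame, validated.
#' @export
read_beat_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "stage", "t_s", "vti_cm", "pv_cm_s", "resp_phase")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("beat CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$stage), stage_labels())
  if (length(bad))
    stop("unknown stage labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a reading-level CSV into per-subject reading sets
#'
#' Expected columns: `subject_id`, `stage`, `reading_idx`, `vti_cm`, and
#' optionally `pv_cm_s`. Rows are the accepted end-expiratory readings.
#'
#' @param path CSV file path.
#' @return Named list (by subject) of lists with a `reading_sets`
#'   element, ready for [run_protocol()].
#' @export
read_reading_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "stage", "reading_idx", "vti_cm")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("reading CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_pv <- "pv_cm_s" %in% names(df)
  lapply(split(df, df$subject_id), function(sub) {
    sets <- lapply(split(sub, sub$stage), function(st) {
      st <- st[order(st$reading_idx), ]
      reading_set(st$vti_cm,
                  if (has_pv) st$pv_cm_s else NULL,
                  stage = st$stage[1])
    })
    list(subject_id = sub$subject_id[1], reading_sets = sets)
  })
}

#' Write a cohort's accepted readings and ground truth to CSV
#'
#' Emits `readings.csv` (subject_id, stage, reading_idx, vti_cm, pv_cm_s)
#' and `truth.csv` (the [cohort_truth()] table) into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    do.call(rbind, lapply(stage_labels(), function(st) {
      rs <- s$reading_sets[[st]]
      data.frame(subject_id = s$subject_id, stage = st,
                 reading_idx = seq_len(rs$n),
                 vti_cm = signif(rs$vti_cm, 6),
                 pv_cm_s = signif(rs$pv_cm_s, 6),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "readings.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- cohort_truth(cohort)
  tr[] <- lapply(tr, function(col)
    if (is.double(col)) signif(col, 6) else col)
  utils::write.csv(tr, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Analyse user-supplied readings
#'
#' The user-data entry point: computes the index panel for every subject
#' in a reading-level CSV (no simulation involved).
#'
#' @param path Reading-level CSV, see [read_reading_csv()].
#' @param repeat_tol_pct Repeat-consistency tolerance, percent.
#' @return Data frame of index panels, one row per subject.
#' @export
analyze_readings <- function(path, repeat_tol_pct = 5.0) {
  subjects <- read_reading_csv(path)
  do.call(rbind, lapply(subjects, run_protocol,
                        repeat_tol_pct = repeat_tol_pct))
}
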