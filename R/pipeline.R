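#' Compute the per-subject index panel from five-stage measurements
#'
#' Applies the central-five estimator to every stage's reading set and
#' derives the full index panel. The headline positional change is taken
#' from the FIRST elevation-to-supine pair (UBE1 to SUP1); the repeated
#' pair (UBE2, SUP2) is reserved for the repeat-consistency check, and its
#' change is retained alongside for sensitivity analysis. The
#' fluid-induced change compares the last pre-fluid supine stage (SUP2)
#' with the post-fluid stage.
#'
#' @param subject A `synthetic_subject`, or any list with a
#'   `reading_sets` element (named list over [stage_labels()]) and
#'   optionally `ijv_by_stage`, `map_by_stage`, `subject_id`, `group`,
#'   `age_y`.
#' @param repeat_tol_pct Repeat-consistency tolerance, percent.
#' @param ijv_sign_convention Sign convention for the positional IJV
#'   change, see [ijv_positional_change_pct()].
#' @return One-row data frame (the index panel).
#' @export
run_protocol <- function(subject, repeat_tol_pct = 5.0,
                         ijv_sign_convention = c("table", "formula")) {
  ijv_sign_convention <- match.arg(ijv_sign_convention)
  rs <- subject$reading_sets
  missing_stage <- setdiff(stage_labels(), names(rs))
  if (length(missing_stage))
    stop("protocol violation: missing stage ",
         paste(missing_stage, collapse = ", "), call. = FALSE)

  est_vti <- vapply(stage_labels(),
                    function(st) central_five_mean(rs[[st]], "vti")$value, 0)
  has_pv <- !is.null(rs[["UBE1"]]$pv_cm_s)
  est_pv <- if (has_pv)
    vapply(stage_labels(),
           function(st) central_five_mean(rs[[st]], "pv")$value, 0)
  else stats::setNames(rep(NA_real_, 5), stage_labels())

  panel <- data.frame(
    subject_id = subject$subject_id %||% NA_character_,
    group = subject$group %||% NA_character_,
    age_y = subject$age_y %||% NA_real_,
    est_vti_ube1 = est_vti[["UBE1"]], est_vti_sup1 = est_vti[["SUP1"]],
    est_vti_ube2 = est_vti[["UBE2"]], est_vti_sup2 = est_vti[["SUP2"]],
    est_vti_fluid = est_vti[["SUP_FLUID"]],
    ube_change_pct = symmetric_change_pct(est_vti[["UBE1"]],
                                          est_vti[["SUP1"]]),
    ube_change_repeat_pct = symmetric_change_pct(est_vti[["UBE2"]],
                                                 est_vti[["SUP2"]]),
    fluid_change_pct = symmetric_change_pct(est_vti[["SUP2"]],
                                            est_vti[["SUP_FLUID"]]),
    increase_ratio_pct = increase_ratio_pct(est_vti[["SUP1"]],
                                            est_vti[["UBE1"]]),
    pv_ube_change_pct = if (has_pv)
      symmetric_change_pct(est_pv[["UBE1"]], est_pv[["SUP1"]])
    else NA_real_,
    ube_consistent = repeat_consistency(est_vti[["UBE1"]],
                                        est_vti[["UBE2"]], repeat_tol_pct),
    sup_consistent = repeat_consistency(est_vti[["SUP1"]],
                                        est_vti[["SUP2"]], repeat_tol_pct),
    stringsAsFactors = FALSE
  )
  panel$consistent <- panel$ube_consistent && panel$sup_consistent

  ijv <- subject$ijv_by_stage
  if (!is.null(ijv)) {
    coll_d <- function(st) collapsibility_pct(ijv[[st]]$ijvd_max_mm,
                                              ijv[[st]]$ijvd_min_mm)
    coll_a <- function(st) collapsibility_pct(ijv[[st]]$ijva_max_mm2,
                                              ijv[[st]]$ijva_min_mm2)
    panel$ijvd_coll_ube_pct <- coll_d("UBE1")
    panel$ijvd_coll_sup_pct <- coll_d("SUP1")
    panel$ijva_coll_ube_pct <- coll_a("UBE1")
    panel$ijva_coll_sup_pct <- coll_a("SUP1")
    panel$ijvd_change_pct <- ijv_positional_change_pct(
      ijv[["SUP1"]]$ijvd_max_mm, ijv[["UBE1"]]$ijvd_max_mm,
      ijv_sign_convention)
    panel$ijva_change_pct <- ijv_positional_change_pct(
      ijv[["SUP1"]]$ijva_max_mm2, ijv[["UBE1"]]$ijva_max_mm2,
      ijv_sign_convention)
  }
  map <- subject$map_by_stage
  if (!is.null(map)) {
    panel$map_ube_mmHg <- map[["UBE1"]]
    panel$map_sup_mmHg <- map[["SUP1"]]
    panel$map_fluid_mmHg <- map[["SUP_FLUID"]]
    panel$map_change_pct <- symmetric_change_pct(map[["UBE1"]],
                                                 map[["SUP1"]])
  }
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screening decision for one subject
#'
#' Applies the eligibility gate for the fluid challenge with a fixed
#' exclusion precedence: an unusable ultrasound window excludes first;
#' then inconsistency between the repeated same-position estimates; then
#' a positional (UBE-induced) change below the screening threshold. Only
#' subjects passing all three proceed to the fluid challenge.
#'
#' @param panel One-row index panel from [run_protocol()].
#' @param window_clear Was the ultrasound window usable?
#' @param screen_pct Screening threshold, percent (`-Inf` disables the
#'   threshold gate, as for healthy volunteers who are challenged
#'   regardless).
#' @return One-row data frame: `subject_id`, `screened`,
#'   `exclusion_reason` (one of `none`, `unclear_window`,
#'   `inconsistent_repeat`, `screen_below_7pct`), `fluid_challenged`.
#' @export
apply_screening <- function(panel, window_clear = TRUE, screen_pct = 7.0) {
  reason <- if (!window_clear) "unclear_window"
  else if (!isTRUE(panel$consistent)) "inconsistent_repeat"
  else if (is.finite(screen_pct) &&
             !classify_threshold(panel$ube_change_pct, screen_pct))
    "screen_below_7pct"
  else "none"
  data.frame(subject_id = panel$subject_id, screened = TRUE,
             exclusion_reason = reason,
             fluid_challenged = reason == "none",
             stringsAsFactors = FALSE)
}

#' Run the full simulated study
#'
#' Generates a cohort, runs the five-stage protocol and screening flow on
#' every subject, classifies measured fluid responders (fluid-induced
#' change at or above the responder threshold) among the
#' fluid-challenged, and evaluates every index against the measured
#' responder label: median (IQR) group summaries, Mann-Whitney p-values,
#' rank AUCs, the ROC with Youden cut-off for the positional change, an
#' age-adjusted logistic fit, and the R-squared linking positional and
#' fluid-induced changes. Deterministic under a fixed `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `study_result` with elements `panels`,
#'   `screening`, `flow`, `summaries`, `roc_ube`, `logistic`,
#'   `r2_ube_vs_fluid`, `cohort`, `config`.
#' @export
run_study <- function(config = cohort_config()) {
  cohort <- generate_cohort(config)
  thr <- config$thresholds

  panels <- do.call(rbind, lapply(cohort, run_protocol,
                                  repeat_tol_pct = config$repeat_tol_pct,
                                  ijv_sign_convention =
                                    config$ijv_sign_convention))
  screening <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    gate <- if (s$group == "healthy" && !config$screen_healthy) -Inf
            else thr$screen_pct
    apply_screening(panels[i, ], window_clear = !isTRUE(s$unclear_window),
                    screen_pct = gate)
  }))
  panels$fluid_challenged <- screening$fluid_challenged
  panels$responder <- ifelse(
    panels$fluid_challenged,
    classify_threshold(panels$fluid_change_pct, thr$responder_pct), NA)

  flow <- lapply(split(screening, panels$group), function(sc) {
    tab <- table(factor(sc$exclusion_reason,
                        levels = c("none", "screen_below_7pct",
                                   "unclear_window", "inconsistent_repeat")))
    list(screened = nrow(sc), fluid_challenged = sum(sc$fluid_challenged),
         excluded = sum(!sc$fluid_challenged),
         excluded_screen_below_7pct = unname(tab[["screen_below_7pct"]]),
         excluded_unclear_window = unname(tab[["unclear_window"]]),
         excluded_inconsistent_repeat =
           unname(tab[["inconsistent_repeat"]]))
  })

  ch <- panels[panels$fluid_challenged, ]
  lab <- ch$responder
  diag_ok <- nrow(ch) > 0 && any(lab) && any(!lab)
  if (!diag_ok) {
    warning("no responder/non-responder contrast; diagnostics are empty")
    summaries <- data.frame()
    roc_ube <- NULL; logistic <- NULL; r2 <- NA_real_
  } else {
    idx_cols <- c("ube_change_pct", "ube_change_repeat_pct",
                  "pv_ube_change_pct", "increase_ratio_pct",
                  "ijvd_coll_ube_pct", "ijvd_coll_sup_pct",
                  "ijva_coll_ube_pct", "ijva_coll_sup_pct",
                  "ijvd_change_pct", "ijva_change_pct",
                  "map_ube_mmHg", "map_sup_mmHg", "map_change_pct")
    idx_cols <- intersect(idx_cols, names(ch))
    summaries <- do.call(rbind, lapply(idx_cols, function(col) {
      v <- ch[[col]]
      mw <- mann_whitney(v[!lab], v[lab])
      data.frame(index = col,
                 nonresponder = format_group_summary(group_summary(v[!lab])),
                 responder = format_group_summary(group_summary(v[lab])),
                 p_value = mw$p_value,
                 auc = auc_rank(v, lab),
                 stringsAsFactors = FALSE)
    }))
    roc_ube <- roc_and_youden(ch$ube_change_pct, lab)
    logistic <- logistic_association(lab, ch$ube_change_pct,
                                     covariates = ch[, "age_y",
                                                     drop = FALSE])
    r2 <- linear_r2(ch$ube_change_pct, ch$fluid_change_pct)
  }

  structure(list(panels = panels, screening = screening, flow = flow,
                 summaries = summaries, roc_ube = roc_ube,
                 logistic = logistic, r2_ube_vs_fluid = r2,
                 cohort = cohort, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result\n")
  for (g in names(x$flow)) {
    f <- x$flow[[g]]
    cat(sprintf(
      "  %s: %d screened, %d challenged (%d excluded: %d <7%%, %d window, %d inconsistent)\n",
      g, f$screened, f$fluid_challenged, f$excluded,
      f$excluded_screen_below_7pct, f$excluded_unclear_window,
      f$excluded_inconsistent_repeat))
  }
  ch <- x$panels[x$panels$fluid_challenged, ]
  if (nrow(ch)) {
    cat(sprintf("  challenged: %d (%d responders, %d non-responders)\n",
                nrow(ch), sum(ch$responder), sum(!ch$responder)))
  }
  if (!is.null(x$roc_ube)) {
    cat(sprintf(
      "  positional change vs responder: AUC %.3f, Youden cut-off %.3g%%\n",
      x$roc_ube$auc, x$roc_ube$youden_cutoff))
    cat(sprintf("  R^2 (positional vs fluid-induced change): %.3f\n",
                x$r2_ube_vs_fluid))
  }
  invisible(x)
}

#' Write study outputs as plain CSV/JSON files
#'
#' Emits `panels.csv`, `screening.csv`, `summaries.csv`, `flow.json` and
#' `diagnostics.json` into `dir` with fixed column orders and
#' 6-significant-digit floats, so a rerun under the same seed is
#' byte-identical.
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) ifelse(is.na(col), "", signif(col, 6)) else col)
    df
  }
  utils::write.csv(fmt(result$panels), file.path(dir, "panels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(result$screening), file.path(dir, "screening.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(result$summaries), file.path(dir, "summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$flow, file.path(dir, "flow.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  diag <- list(seed = result$config$seed,
               r2_ube_vs_fluid = result$r2_ube_vs_fluid)
  if (!is.null(result$roc_ube))
    diag$roc_ube <- list(auc = result$roc_ube$auc,
                         youden_cutoff = result$roc_ube$youden_cutoff,
                         youden_j = result$roc_ube$youden_j)
  if (!is.null(result$logistic))
    diag$logistic <- c(list(separation = result$logistic$separation),
                       as.list(result$logistic$table))
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
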