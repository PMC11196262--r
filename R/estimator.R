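#' Select end-expiratory maximal readings from a beat sequence
#'
#' Spontaneous respiration modulates the left-ventricular outflow tract
#' VTI beat by beat, and probe misalignment can only deflate it. The
#' measurement statistic therefore keeps, per respiratory cycle, the single
#' largest VTI among beats falling inside a narrow end-expiratory phase
#' window, and discards inspiratory beats entirely (the low values they
#' carry are dominated by respiratory variation and misalignment rather
#' than stroke volume).
#'
#' Respiratory phase is coded in \[0, 1) with end-expiration at 0. Beats
#' with phase within `window` of 0 — i.e. phase <= `window` or phase >=
#' 1 - `window` — are end-expiratory; a beat just before the wrap
#' (phase >= 1 - `window`) is attributed to the end-expiration it is
#' approaching, i.e. to the following cycle. Selection does not repair
#' noise: a deflated end-expiratory beat yields a deflated reading, and it
#' is the downstream trimming in [central_five_mean()] that rejects it.
#'
#' @param beats Data frame with columns `t_s`, `vti_cm`, `pv_cm_s`,
#'   `resp_phase` (one row per cardiac cycle, time-ordered).
#' @param window End-expiratory phase half-width, in (0, 0.25\]. Default
#'   0.10 of the respiratory cycle.
#' @param stage Optional stage label stored on the result.
#' @param max_readings Protocol cap on accepted readings (default 17);
#'   the earliest cycles are dropped beyond it.
#' @return A `reading_set`: list with `stage`, `vti_cm`, `pv_cm_s` (the
#'   per-cycle maxima, paired beat-wise), and `n`.
#' @export
select_end_expiratory_maxima <- function(beats, window = 0.10, stage = NA,
                                         max_readings = 17L) {
  validate_beats(beats)
  if (window <= 0 || window > 0.25)
    stop("window must lie in (0, 0.25]", call. = FALSE)

  phase <- beats$resp_phase
  # cycle index advances when the phase wraps past 0
  cycle <- cumsum(c(1L, as.integer(diff(phase) < 0)))
  near_end <- phase <= window
  near_wrap <- phase >= 1 - window
  keep <- near_end | near_wrap
  # beats approaching the wrap belong to the next cycle's end-expiration
  cycle_attr <- cycle + as.integer(near_wrap)

  n_cycles <- max(cycle)
  if (n_cycles < 9L)
    stop(sprintf("insufficient data: %d respiratory cycles, need >= 9",
                 n_cycles), call. = FALSE)

  idx <- which(keep)
  if (length(idx) == 0L)
    stop("insufficient data: no end-expiratory beats in window",
         call. = FALSE)
  by_cycle <- split(idx, cycle_attr[idx])
  pick <- vapply(by_cycle, function(i) i[which.max(beats$vti_cm[i])], 0L)
  pick <- pick[order(as.integer(names(by_cycle)))]

  if (length(pick) < 9L)
    stop(sprintf(
      "insufficient data: only %d cycles carry an end-expiratory beat",
      length(pick)), call. = FALSE)
  if (length(pick) > max_readings)
    pick <- pick[(length(pick) - max_readings + 1L):length(pick)]

  reading_set(vti_cm = beats$vti_cm[pick], pv_cm_s = beats$pv_cm_s[pick],
              stage = stage)
}

#' Construct a set of accepted end-expiratory readings
#'
#' @param vti_cm Accepted end-expiratory VTImax readings, cm.
#' @param pv_cm_s Paired peak velocities, cm/s.
#' @param stage Optional stage label.
#' @param validate Enforce the 9-17 protocol range (default `TRUE`).
#' @return Object of class `reading_set`.
#' @export
reading_set <- function(vti_cm, pv_cm_s = NULL, stage = NA, validate = TRUE) {
  if (validate) {
    n <- length(vti_cm)
    if (n < 9L || n > 17L)
      stop(sprintf("protocol violation: %d readings, expected 9-17", n),
           call. = FALSE)
  }
  check_positive(vti_cm, "vti_cm")
  if (!is.null(pv_cm_s)) {
    check_positive(pv_cm_s, "pv_cm_s")
    stopifnot(length(pv_cm_s) == length(vti_cm))
  }
  structure(list(stage = stage, vti_cm = as.numeric(vti_cm),
                 pv_cm_s = if (is.null(pv_cm_s)) NULL else as.numeric(pv_cm_s),
                 n = length(vti_cm)),
            class = "reading_set")
}

#' @export
print.reading_set <- function(x, ...) {
  cat(sprintf("reading_set: stage %s, %d accepted end-expiratory readings\n",
              as.character(x$stage), x$n))
  cat("  VTI (cm):", paste(signif(x$vti_cm, 4), collapse = " "), "\n")
  invisible(x)
}

#' Mean of the central five order statistics
#'
#' The stage-level estimate of VTImax (or peak velocity): sort the 9-17
#' accepted readings, discard the k highest and k lowest with
#' k = (n - 5)/2, and average the surviving central five. The discarded
#' extremes correspond to readings taken with the Doppler gate too close
#' to or too far from the aortic valve; with up to k = (n-5)/2 corrupted
#' readings per side the surviving five are genuine.
#'
#' For an even number of readings (possible in user-supplied data, not
#' under the 9-17-with-five-survivors protocol arithmetic) a single
#' pre-discard step removes the reading farthest from the overall median
#' (ties resolved by discarding the larger value), after which the odd-n
#' rule applies.
#'
#' @param readings Numeric vector of 9-17 positive readings, or a
#'   `reading_set`.
#' @param what For a `reading_set`, which channel to estimate:
#'   `"vti"` (default) or `"pv"`.
#' @return A `median_estimate`: list with `value`, `n_total`,
#'   `n_trimmed_each_side`.
#' @examples
#' central_five_mean(c(10, 11, 12, 13, 14, 15, 16, 17, 18))  # 14
#' @export
central_five_mean <- function(readings, what = c("vti", "pv")) {
  if (inherits(readings, "reading_set")) {
    what <- match.arg(what)
    readings <- if (what == "pv") readings$pv_cm_s else readings$vti_cm
  }
  n0 <- length(readings)
  if (n0 < 9L || n0 > 17L)
    stop(sprintf("protocol violation: %d readings, expected 9-17", n0),
         call. = FALSE)
  check_positive(readings, "readings")

  x <- as.numeric(readings)
  if (n0 %% 2L == 0L) {
    med <- stats::median(x)
    d <- abs(x - med)
    cand <- which(d == max(d))
    if (length(cand) > 1L) cand <- cand[which.max(x[cand])]
    x <- x[-cand]
  }
  n <- length(x)
  k <- (n - 5L) %/% 2L
  xs <- sort(x)
  central <- xs[(k + 1L):(n - k)]
  structure(list(value = mean(central), n_total = n0,
                 n_trimmed_each_side = k),
            class = "median_estimate")
}

#' @export
print.median_estimate <- function(x, ...) {
  cat(sprintf("median_estimate: %.4g (n = %d, trimmed %d per side)\n",
              x$value, x$n_total, x$n_trimmed_each_side))
  invisible(x)
}

#' Conventional mean over consecutive cardiac cycles
#'
#' The comparator estimator: the arithmetic mean of the VTI over the first
#' `n_cycles` consecutive cardiac cycles, inspiratory beats included. It
#' carries the full respiratory modulation and any misalignment deflation
#' straight into the estimate, which is the imprecision the end-expiratory
#' trimmed estimator is designed to avoid.
#'
#' @param beats Data frame as in [select_end_expiratory_maxima()], or a
#'   numeric vector of per-beat VTI values.
#' @param n_cycles Number of consecutive cardiac cycles to average
#'   (default 5).
#' @return Numeric estimate.
#' @export
conventional_consecutive_mean <- function(beats, n_cycles = 5L) {
  vti <- if (is.data.frame(beats)) beats$vti_cm else as.numeric(beats)
  if (length(vti) < n_cycles)
    stop(sprintf("insufficient data: %d beats, need >= %d",
                 length(vti), n_cycles), call. = FALSE)
  mean(vti[seq_len(n_cycles)])
}

#' Consistency of repeated stage estimates
#'
#' The protocol measures each position twice; a subject whose two
#' same-position estimates disagree by more than `tol_pct` (absolute
#' symmetric change) is flagged inconsistent and excluded from the fluid
#' challenge. The default tolerance of 5% sits below the 7% screening
#' threshold so that measurement inconsistency cannot by itself mimic a
#' positive screen.
#'
#' @param est1,est2 `median_estimate` objects (or plain positive numbers)
#'   from the first and second measurement at the same position.
#' @param tol_pct Tolerance on the absolute symmetric change, percent.
#' @return `TRUE` when the two estimates agree within tolerance.
#' @export
repeat_consistency <- function(est1, est2, tol_pct = 5.0) {
  v1 <- if (inherits(est1, "median_estimate")) est1$value else est1
  v2 <- if (inherits(est2, "median_estimate")) est2$value else est2
  abs(symmetric_change_pct(v1, v2)) <= tol_pct
}

validate_beats <- function(beats) {
  req <- c("t_s", "vti_cm", "pv_cm_s", "resp_phase")
  if (!is.data.frame(beats) || !all(req %in% names(beats)))
    stop("beats must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (any(!is.finite(beats$vti_cm)) || any(beats$vti_cm <= 0) ||
      any(!is.finite(beats$pv_cm_s)) || any(beats$pv_cm_s <= 0))
    stop("vti_cm and pv_cm_s must be finite and positive", call. = FALSE)
  if (any(beats$resp_phase < 0) || any(beats$resp_phase >= 1))
    stop("resp_phase must lie in [0, 1)", call. = FALSE)
  invisible(beats)
}
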