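#' Symmetric percent change between two positive measurements
#'
#' The change between two stage estimates is normalised by the mean of the
#' two values rather than by the baseline alone:
#' \deqn{100 \cdot (x_{to} - x_{from}) / \{(x_{to} + x_{from})/2\}.}
#' This symmetric form is antisymmetric in its arguments and bounded in
#' (-200, 200), so a change and its reverse always cancel, and neither
#' direction of a stage transition is privileged as "baseline".
#'
#' @param x_from Positive measurement at the starting stage (e.g. median
#'   VTImax in the 60-degree upper-body elevation position, in cm).
#' @param x_to Positive measurement at the ending stage (e.g. median VTImax
#'   supine, in cm).
#' @return Percent change in (-200, 200). Vectorised over both arguments.
#' @examples
#' symmetric_change_pct(16.9, 18.0)  # +6.30%
#' symmetric_change_pct(10, 30)      # +100%
#' @seealso [increase_ratio_pct()], [symmetric_to_ratio_pct()]
#' @export
symmetric_change_pct <- function(x_from, x_to) {
  check_positive(x_from, "x_from")
  check_positive(x_to, "x_to")
  100 * (x_to - x_from) / ((x_to + x_from) / 2)
}

#' Percent increase of the supine/elevated ratio
#'
#' The plain ratio form of the positional change: the percent by which the
#' supine estimate exceeds the upper-body-elevation estimate,
#' \eqn{100 (x_{sup}/x_{ube} - 1)}. Linked one-to-one with the symmetric
#' change by [symmetric_to_ratio_pct()].
#'
#' @param x_supine Positive supine-stage estimate.
#' @param x_ube Positive upper-body-elevation-stage estimate.
#' @return Percent increase (> -100). Vectorised.
#' @export
increase_ratio_pct <- function(x_supine, x_ube) {
  check_positive(x_supine, "x_supine")
  check_positive(x_ube, "x_ube")
  100 * (x_supine / x_ube - 1)
}

#' Convert between symmetric percent change and ratio percent increase
#'
#' For the same pair of positive measurements the symmetric change `c` and
#' the ratio increase `r` (both in percent) satisfy `r = 200 c / (200 - c)`
#' and `c = 200 r / (200 + r)`. The two functions are exact inverses, which
#' lets thresholds stated on one scale be restated on the other (a symmetric
#' cut-off of 11.8% corresponds to a ratio increase of 12.54%).
#'
#' @param c Symmetric percent change, |c| < 200.
#' @param r Ratio percent increase, r > -200.
#' @return The corresponding value on the other scale. Vectorised.
#' @export
symmetric_to_ratio_pct <- function(c) {
  if (any(!is.finite(c)) || any(abs(c) >= 200))
    stop("symmetric change must be finite with |c| < 200", call. = FALSE)
  200 * c / (200 - c)
}

#' @rdname symmetric_to_ratio_pct
#' @export
ratio_to_symmetric_pct <- function(r) {
  if (any(!is.finite(r)) || any(r <= -200))
    stop("ratio increase must be finite with r > -200", call. = FALSE)
  200 * r / (200 + r)
}

#' Respiratory collapsibility index of a vessel dimension
#'
#' Collapsibility of the internal jugular vein diameter or area over the
#' respiratory cycle, normalised by the mean of the extremes:
#' \deqn{100 \cdot (x_{max} - x_{min}) / \{(x_{max} + x_{min})/2\}.}
#' Ranges from 0 (no respiratory swing) to 200 (complete collapse,
#' \eqn{x_{min} = 0}). Scale-invariant, so diameters in mm and areas in
#' mm^2 are treated identically.
#'
#' @param x_max Maximum dimension over the respiratory cycle (> 0).
#' @param x_min Minimum dimension (>= 0, and <= `x_max`).
#' @return Collapsibility in percent, in \[0, 200\]. Vectorised.
#' @export
collapsibility_pct <- function(x_max, x_min) {
  check_positive(x_max, "x_max")
  if (any(!is.finite(x_min)) || any(x_min < 0))
    stop("x_min must be finite and non-negative", call. = FALSE)
  if (any(x_min > x_max))
    stop("x_min exceeds x_max; orient the arguments as (max, min)",
         call. = FALSE)
  100 * (x_max - x_min) / ((x_max + x_min) / 2)
}

#' Positional change of the internal jugular vein dimension
#'
#' Symmetric percent change of the maximal IJV dimension between the
#' upper-body-elevation and supine positions. Two sign conventions are
#' supported. `"table"` (the default) reports supine-minus-elevated, so the
#' value is positive when the vein distends on lying down — the orientation
#' under which published group values are large and positive. `"formula"`
#' reports elevated-minus-supine, the literal orientation of the defining
#' difference, which is negative for the same physiology. The two differ
#' only in sign.
#'
#' @param ijv_supine Maximal IJV dimension supine (> 0).
#' @param ijv_ube Maximal IJV dimension at 60-degree upper-body
#'   elevation (> 0).
#' @param sign_convention `"table"` (positive when larger supine) or
#'   `"formula"` (the literal elevated-minus-supine orientation).
#' @return Symmetric percent change. Vectorised over the measurements.
#' @export
ijv_positional_change_pct <- function(ijv_supine, ijv_ube,
                                      sign_convention = c("table", "formula")) {
  sign_convention <- match.arg(sign_convention)
  out <- symmetric_change_pct(ijv_ube, ijv_supine)
  if (sign_convention == "formula") -out else out
}

#' Threshold classification of a change index
#'
#' Inclusive threshold rule used throughout the protocol: a subject is
#' classified positive when the change index is greater than *or equal to*
#' the threshold, so ties at exactly the screening (7%) or responder (10%)
#' threshold classify positive.
#'
#' @param change_pct Change index in percent.
#' @param threshold_pct Threshold in percent.
#' @return Logical. Vectorised.
#' @export
classify_threshold <- function(change_pct, threshold_pct) {
  if (any(!is.finite(change_pct)) || any(!is.finite(threshold_pct)))
    stop("classification requires finite inputs", call. = FALSE)
  change_pct >= threshold_pct
}

#' Protocol thresholds
#'
#' The percent thresholds used by the screening and evaluation pipeline:
#' `screen_pct` (7) — an upper-body-elevation-induced or fluid-induced
#' median VTImax change at or above this level raises suspicion of mild
#' hypovolemia and gates the fluid challenge in patients; `responder_pct`
#' (10) — the fluid-induced change defining fluid responsiveness;
#' `cutoff_responder_pct` (11.8) and `cutoff_mild_pct` (7.98) — reported
#' cut-offs of the positional change for predicting a fluid-induced change
#' at or above 10% and 7% respectively.
#'
#' @return Named list of the four thresholds, in percent.
#' @export
default_thresholds <- function() {
  list(screen_pct = 7.0, responder_pct = 10.0,
       cutoff_responder_pct = 11.8, cutoff_mild_pct = 7.98)
}

# shared argument guard: strictly positive, finite
check_positive <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("%s must be finite and strictly positive", name),
         call. = FALSE)
  invisible(x)
}
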