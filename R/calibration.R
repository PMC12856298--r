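#' Estimate the conductance field factor alpha against thermodilution
#'
#' The field-inhomogeneity gain is the ratio of conductance-derived
#' (uncalibrated) stroke volume to thermodilution stroke volume,
#' `alpha = SV_uncal / (CO_TD * 1000 / HR)`. The parallel-conductance offset
#' `Vp` cancels out of any stroke volume by construction, so alpha can be
#' estimated before `Vp`.
#'
#' @param sv_uncal mean uncalibrated stroke volume (a.u., mL-equivalent).
#' @param co_thermodilution thermodilution cardiac output, L/min.
#' @param hr heart rate, bpm.
#' @return alpha (unitless gain).
#' @examples
#' estimate_alpha(87.5, 4.2, 96)   # 2
#' @export
estimate_alpha <- function(sv_uncal, co_thermodilution, hr) {
  if (co_thermodilution <= 0)
    stop("thermodilution CO must be > 0", call. = FALSE)
  if (sv_uncal <= 0 || hr <= 0)
    stop("inputs must be positive", call. = FALSE)
  sv_uncal / (co_thermodilution * 1000 / hr)
}

#' Estimate parallel conductance from a hypertonic-saline transient
#'
#' During saline wash-in the blood term of the conductance signal is scaled
#' while the parallel (tissue) term is not, so on alpha-corrected volumes the
#' per-beat end-systolic volume is linear in the end-diastolic volume:
#' `V_es = m V_ed + b` with `m = ESV/EDV`. The intersection with the identity
#' line, \deqn{Vp = b / (1 - m),} is the parallel-conductance volume;
#' subtracting it from all volumes yields the calibrated scale.
#'
#' @param saline_beats a [segment_beats()] table computed on alpha-corrected
#'   volumes (>= 4 beats spanning a detectable drift in ED volume).
#' @param min_drift ED-volume span (mL) below which the result is flagged
#'   low-confidence.
#' @return A list of class `calibration_result`: `Vp` (mL), `slope`,
#'   `intercept` of the saline regression, `r2`, `flags`.
#' @examples
#' # slope 0.6, intercept 10 -> Vp = 25 mL
#' @export
estimate_parallel_volume <- function(saline_beats, min_drift = 2) {
  b <- saline_beats
  if (nrow(b) < 4)
    stop("need >= 4 beats spanning the saline transient", call. = FALSE)
  flags <- character(0)
  if (diff(range(b$EDV)) < min_drift)
    flags <- c(flags, "low-confidence: ED-volume drift below detection floor")
  fit <- stats::lm(ESV ~ EDV, data = b)
  m <- unname(stats::coef(fit)[2])
  b0 <- unname(stats::coef(fit)[1])
  if (m >= 1)
    stop("non-convergent extrapolation: ES-on-ED slope >= 1", call. = FALSE)
  Vp <- b0 / (1 - m)
  if (!is.finite(Vp)) stop("parallel volume estimate is not finite",
                           call. = FALSE)
  structure(list(Vp = Vp, slope = m, intercept = b0,
                 r2 = r_squared(fit), flags = flags),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> Vp = %.2f mL (ES = %.3f ED + %.2f, r2 %.4f)\n",
              x$Vp, x$slope, x$intercept, x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Apply conductance calibration to a recording
#'
#' Inverts the conductance forward model: `V = U / alpha - Vp`. The original
#' uncalibrated channel is preserved.
#'
#' @param rec a [hemo_recording] with an uncalibrated volume channel.
#' @param alpha field factor (> 0).
#' @param Vp parallel-conductance volume, mL.
#' @param uncal,name uncalibrated and calibrated channel names.
#' @return The recording with an added calibrated volume channel (mL).
#' @export
apply_calibration <- function(rec, alpha, Vp, uncal = "U", name = "V") {
  stopifnot(inherits(rec, "hemo_recording"))
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!uncal %in% names(rec$data))
    stop("channel not found: ", uncal, call. = FALSE)
  rec$data[[name]] <- rec$data[[uncal]] / alpha - Vp
  rec$units[name] <- "mL"
  rec
}

#' Full conductance calibration on a synthetic or recorded session
#'
#' Convenience wrapper composing the two calibration steps: alpha from the
#' steady uncalibrated stroke volume against thermodilution CO, then Vp from
#' the saline transient after alpha-scaling.
#'
#' @param steady_rec recording with uncalibrated channel `U` under steady
#'   conditions.
#' @param saline_rec recording with uncalibrated channel `U` during the
#'   saline transient.
#' @param co_thermodilution thermodilution CO, L/min.
#' @param pressure,uncal channel names.
#' @return A list of class `calibration_result` with `alpha`, `Vp` and the
#'   saline regression diagnostics.
#' @export
calibrate_conductance <- function(steady_rec, saline_rec, co_thermodilution,
                                  pressure = "P", uncal = "U") {
  sb <- segment_beats(steady_rec, pressure = pressure, volume = uncal)
  hr <- 60000 / mean(sb$RR)
  alpha <- estimate_alpha(mean(sb$SV), co_thermodilution, hr)
  scaled <- apply_calibration(saline_rec, alpha, Vp = 0, uncal = uncal,
                              name = ".Vscaled")
  beats <- segment_beats(scaled, pressure = pressure, volume = ".Vscaled")
  res <- estimate_parallel_volume(beats)
  res$alpha <- alpha
  res
}
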