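#' @keywords internal
"_PACKAGE"

#' End-to-end analysis of one hemodynamic session
#'
#' Convenience pipeline over the module functions: segments the steady and
#' occlusion recordings, fits the relaxation constant on every steady beat,
#' selects and fits the occlusion family (ESPVR, EDPVR, PRSW) and assembles
#' the per-ventricle summary. Mirrors what an interactive analysis would do
#' step by step.
#'
#' @param steady_rec steady-state [hemo_recording] (channels `P`, `V`).
#' @param occlusion_rec occlusion [hemo_recording], or `NULL` to skip the
#'   occlusion-family fits.
#' @param thermo_co thermodilution CO, L/min (optional; otherwise SV x HR).
#' @param pa_mean mean PA pressure, mmHg (optional; defaults to the
#'   recording's metadata value when present).
#' @param lvedp LV end-diastolic pressure, mmHg (optional; defaults to
#'   metadata).
#' @param pressure,volume channel names.
#' @return A [ventricular_summary()] with the component fits attached as
#'   attribute `fits`.
#' @examples
#' p <- make_preset("cteph")
#' st <- simulate_steady(p, n_beats = 5)
#' oc <- simulate_occlusion(p, n_beats = 12, edv_end = 90)
#' s <- analyze_session(st$recording, oc$recording)
#' round(c(s$EF, s$Ees, s$tau), 2)
#' @export
analyze_session <- function(steady_rec, occlusion_rec = NULL,
                            thermo_co = NULL, pa_mean = NULL, lvedp = NULL,
                            pressure = "P", volume = "V") {
  sb <- segment_beats(steady_rec, pressure, volume)
  taus <- lapply(seq_len(nrow(sb)), function(k)
    fit_tau_logistic(steady_rec, sb[k, ], pressure))
  espvr <- edpvr <- prsw <- NULL
  if (!is.null(occlusion_rec)) {
    ob <- segment_beats(occlusion_rec, pressure, volume)
    run <- select_occlusion_beats(ob)
    espvr <- fit_espvr(run)
    edpvr <- fit_edpvr(run)
    prsw <- fit_prsw(run)
  }
  if (is.null(pa_mean)) pa_mean <- steady_rec$meta$pa_mean
  if (is.null(lvedp)) lvedp <- steady_rec$meta$LVEDP
  out <- ventricular_summary(sb, taus, espvr = espvr, edpvr = edpvr,
                             prsw = prsw, thermo_co = thermo_co,
                             pa_mean = pa_mean, lvedp = lvedp)
  attr(out, "fits") <- list(espvr = espvr, edpvr = edpvr, prsw = prsw,
                            tau = taus, beats = sb)
  out
}
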