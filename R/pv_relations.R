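#' Select and quality-control beats from a caval occlusion run
#'
#' Keeps the longest run of beats with monotonically non-increasing
#' end-diastolic volume (tolerance 2 mL) after excluding ectopic beats whose
#' RR interval deviates more than 20% from the running median. Exclusions are
#' logged with reasons.
#'
#' @param beats a [segment_beats()] table.
#' @param edv_tol per-beat tolerance on the EDV descent, mL.
#' @param rr_tol fractional RR deviation that marks a beat ectopic.
#' @param min_span minimum EDV span (mL) for a descent to count as an
#'   occlusion.
#' @return A list of class `occlusion_run`: `beats` (accepted rows),
#'   `excluded` (rows + reasons), `span` (mL of EDV covered).
#' @export
select_occlusion_beats <- function(beats, edv_tol = 2, rr_tol = 0.2,
                                   min_span = 5) {
  b <- as.data.frame(beats)
  med_rr <- stats::runmed(b$RR, k = min(nrow(b) - !(nrow(b) %% 2), 7))
  ectopic <- abs(b$RR - med_rr) / med_rr > rr_tol
  excluded <- b[ectopic, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "ectopic: RR deviates > 20% from running median"
  b <- b[!ectopic, , drop = FALSE]
  if (nrow(b) < 5) stop("fewer than 5 accepted beats", call. = FALSE)
  # longest contiguous non-increasing EDV run (with tolerance)
  ok <- c(TRUE, diff(b$EDV) <= edv_tol)
  run_id <- cumsum(!ok)
  runs <- split(seq_len(nrow(b)), run_id)
  spans <- vapply(runs, function(i) b$EDV[i[1]] - b$EDV[i[length(i)]],
                  numeric(1))
  lens <- lengths(runs)
  cand <- which(lens >= 5 & spans >= min_span)
  if (!length(cand))
    stop("no occlusion descent found", call. = FALSE)
  best <- cand[which.max(spans[cand])]
  acc <- b[runs[[best]], , drop = FALSE]
  structure(list(beats = acc, excluded = excluded,
                 span = acc$EDV[1] - acc$EDV[nrow(acc)]),
            class = "occlusion_run")
}

#' @export
print.occlusion_run <- function(x, ...) {
  cat(sprintf("<occlusion_run> %d accepted beats, EDV span %.1f mL (%d excluded)\n",
              nrow(x$beats), x$span, nrow(x$excluded)))
  invisible(x)
}

# R^2 without summary.lm (avoids its perfect-fit warning on exact data)
r_squared <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  ss <- sum((y - mean(y))^2)
  if (ss < .Machine$double.eps) return(1)
  1 - sum(stats::resid(fit)^2) / ss
}

run_beats <- function(run) {
  if (inherits(run, "occlusion_run")) run$beats else as.data.frame(run)
}

#' Fit the end-systolic pressure-volume relationship (ESPVR)
#'
#' Ordinary least squares of ESP on ESV, `ESP = Ees (ESV - V0)`. A quadratic
#' fit is computed alongside and its fractional curvature contribution,
#' `|c2| (range ESV)^2 / range(ESP)`, is always reported; the linear fit is
#' returned regardless, with a warning when the contribution exceeds 5%
#' (the operational reading of "quadratic terms negligible").
#'
#' @param run an [select_occlusion_beats()] result or a beat table with
#'   `ESP`/`ESV` columns (>= 5 beats).
#' @return A list of class `espvr_fit`: `Ees` (mmHg/mL), `V0` (mL), `r2`,
#'   `quadratic_check` (`c2`, `curvature_contribution`).
#' @export
fit_espvr <- function(run) {
  b <- run_beats(run)
  if (nrow(b) < 5) stop("ESPVR fit needs >= 5 end-systolic points",
                        call. = FALSE)
  if (diff(range(b$ESV)) < 3)
    stop("degenerate ESV spread (< 3 mL)", call. = FALSE)
  fit <- stats::lm(ESP ~ ESV, data = b)
  Ees <- unname(stats::coef(fit)[2])
  V0 <- -unname(stats::coef(fit)[1]) / Ees
  qfit <- stats::lm(ESP ~ ESV + I(ESV^2), data = b)
  c2 <- unname(stats::coef(qfit)[3])
  contrib <- abs(c2) * diff(range(b$ESV))^2 / diff(range(b$ESP))
  if (is.finite(contrib) && contrib > 0.05)
    warning(sprintf(
      "quadratic curvature contributes %.1f%% of the ESP range; linear ESPVR may be inadequate",
      100 * contrib))
  structure(list(Ees = Ees, V0 = V0, r2 = r_squared(fit),
                 quadratic_check = list(c2 = c2,
                                        curvature_contribution = contrib),
                 n = nrow(b)),
            class = "espvr_fit")
}

#' @export
print.espvr_fit <- function(x, ...) {
  cat(sprintf("<espvr_fit> Ees = %.3f mmHg/mL, V0 = %.2f mL (r2 %.5f, n %d)\n",
              x$Ees, x$V0, x$r2, x$n))
  cat(sprintf("  quadratic check: c2 = %.3g, curvature contribution %.3g%%\n",
              x$quadratic_check$c2,
              100 * x$quadratic_check$curvature_contribution))
  invisible(x)
}

#' Fit the end-diastolic pressure-volume relationship (EDPVR)
#'
#' Nonlinear least squares of \deqn{P_{ed} = P_{inf} + A e^{\beta V_{ed}}}
#' (exponential with asymptote). Initialization is deterministic:
#' `Pinf0 = min(P) - 0.5`, then `beta0`/`A0` from a log-linear regression of
#' `P - Pinf0` on `V`. The asymptote is unconstrained in sign but bounded
#' below at -20 mmHg to stabilize the fit.
#'
#' @param run an [select_occlusion_beats()] result or beat table with
#'   `EDP`/`EDV` columns (>= 5 points spanning >= 15 mL).
#' @return A list of class `edpvr_fit`: `P_inf`, `A` (mmHg), `beta` (/mL),
#'   `rmse`.
#' @export
fit_edpvr <- function(run) {
  b <- run_beats(run)
  if (nrow(b) < 5) stop("EDPVR fit needs >= 5 end-diastolic points",
                        call. = FALSE)
  if (diff(range(b$EDV)) < 15)
    stop("EDV span must be >= 15 mL for a stable EDPVR fit", call. = FALSE)
  if (diff(range(b$EDP)) < 1e-6)
    stop("all end-diastolic pressures equal: no curvature to fit",
         call. = FALSE)
  V <- b$EDV
  P <- b$EDP
  Pinf0 <- min(P) - 0.5
  ll <- stats::lm(log(P - Pinf0) ~ V)
  beta0 <- max(unname(stats::coef(ll)[2]), 1e-4)
  A0 <- exp(unname(stats::coef(ll)[1]))
  # direct Levenberg-Marquardt: the A/beta gradient columns are nearly
  # collinear on narrow volume spans, which trips nls()'s singularity check
  res_fn <- function(par) par[1] + par[2] * exp(par[3] * V) - P
  fit <- minpack.lm::nls.lm(
    par = c(P_inf = Pinf0, A = A0, beta = beta0), fn = res_fn,
    lower = c(P_inf = -20, A = 1e-12, beta = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0 || fit$info > 4)
    stop("EDPVR fit did not converge: ", fit$message, call. = FALSE)
  cf <- fit$par
  structure(list(P_inf = unname(cf["P_inf"]), A = unname(cf["A"]),
                 beta = unname(cf["beta"]),
                 rmse = sqrt(mean(res_fn(cf)^2)), n = nrow(b)),
            class = "edpvr_fit")
}

#' @export
print.edpvr_fit <- function(x, ...) {
  cat(sprintf("<edpvr_fit> P = %.3f + %.4g * exp(%.4f V)  (rmse %.3g, n %d)\n",
              x$P_inf, x$A, x$beta, x$rmse, x$n))
  invisible(x)
}

#' Fit preload recruitable stroke work (PRSW)
#'
#' OLS of per-beat stroke work on end-diastolic volume, `SW = Mw (EDV - Vw)`;
#' the slope `Mw` is in mmHg (mmHg.mL per mL).
#'
#' @param run an [select_occlusion_beats()] result or beat table with
#'   `SW`/`EDV` columns (>= 2 beats; >= 5 for a qualified run).
#' @return A list of class `prsw_fit`: `Mw` (mmHg), `Vw` (mL), `r2`.
#' @export
fit_prsw <- function(run) {
  b <- run_beats(run)
  if (nrow(b) < 2) stop("PRSW fit needs multiple beats", call. = FALSE)
  if (diff(range(b$EDV)) < 3)
    stop("degenerate EDV spread for PRSW", call. = FALSE)
  fit <- stats::lm(SW ~ EDV, data = b)
  Mw <- unname(stats::coef(fit)[2])
  structure(list(Mw = Mw, Vw = -unname(stats::coef(fit)[1]) / Mw,
                 r2 = r_squared(fit), n = nrow(b)),
            class = "prsw_fit")
}

#' @export
print.prsw_fit <- function(x, ...) {
  cat(sprintf("<prsw_fit> Mw = %.2f mmHg, Vw = %.1f mL (r2 %.4f, n %d)\n",
              x$Mw, x$Vw, x$r2, x$n))
  invisible(x)
}

#' Effective arterial elastance
#'
#' `Ea = ESP / SV`, averaged over steady beats; the lumped afterload of the
#' pulmonary circulation as seen by the right ventricle.
#'
#' @param steady_beats a [segment_beats()] table (>= 1 beat).
#' @return Ea, mmHg/mL.
#' @export
arterial_elastance <- function(steady_beats) {
  b <- as.data.frame(steady_beats)
  if (!nrow(b)) stop("no beats", call. = FALSE)
  if (any(b$SV <= 0)) stop("stroke volume must be positive", call. = FALSE)
  mean(b$ESP / b$SV)
}

#' Ventriculo-vascular coupling ratio
#'
#' `VVC = Ees / Ea`. Computed per animal (ratio first, averaged across
#' animals afterwards), matching how a group-mean VVC relates to the group
#' Ees and Ea summaries.
#'
#' @param Ees end-systolic elastance, mmHg/mL.
#' @param Ea arterial elastance, mmHg/mL (> 0).
#' @return The coupling ratio, unitless.
#' @export
coupling_ratio <- function(Ees, Ea) {
  if (any(Ea <= 0)) stop("Ea must be > 0", call. = FALSE)
  Ees / Ea
}

#' Pulmonary vascular resistance
#'
#' `PVR = (mPAP - LVEDP) / CO` in Wood units, using LV end-diastolic pressure
#' as the surrogate for wedge pressure (the study's stated convention when
#' wedge pressure cannot be obtained reliably). A negative gradient is
#' flagged by warning, not clipped.
#'
#' @param mpap mean pulmonary artery pressure, mmHg.
#' @param lvedp LV end-diastolic pressure, mmHg.
#' @param co cardiac output, L/min (> 0).
#' @return PVR, Wood units.
#' @examples
#' compute_pvr(51, 9, 4.2)   # 10
#' @export
compute_pvr <- function(mpap, lvedp, co) {
  if (co <= 0) stop("CO must be > 0", call. = FALSE)
  pvr <- (mpap - lvedp) / co
  if (pvr < 0) warning("negative PVR: downstream pressure exceeds mPAP")
  pvr
}

#' Assemble a per-ventricle hemodynamic summary
#'
#' Combines steady-beat scalars, occlusion-family fits, relaxation fits and
#' calibration-side measurements into one summary per ventricle per animal:
#' Pmax, EF, dP/dt_max, PRSW, Ea, Ees, VVC, EDP, EDV, tau, beta, CO and (when
#' PA pressures and LVEDP are available) PVR. CO is taken from thermodilution
#' when supplied, else computed as SV x HR from the analyzed beats.
#'
#' @param steady_beats a [segment_beats()] table (mandatory).
#' @param tau_fits list of [fit_tau_logistic()] results (mandatory).
#' @param espvr,edpvr,prsw occlusion-family fits (optional).
#' @param thermo_co thermodilution CO, L/min (optional).
#' @param pa_mean mean PA pressure, mmHg (optional; e.g. preset metadata or
#'   [pa_pressure_stats()]).
#' @param lvedp LV end-diastolic pressure, mmHg (optional).
#' @return A list of class `ventricular_summary`.
#' @export
ventricular_summary <- function(steady_beats, tau_fits, espvr = NULL,
                                edpvr = NULL, prsw = NULL, thermo_co = NULL,
                                pa_mean = NULL, lvedp = NULL) {
  gaps <- c(if (missing(steady_beats) || is.null(steady_beats)) "steady_beats",
            if (missing(tau_fits) || is.null(tau_fits) || !length(tau_fits))
              "tau_fits")
  if (length(gaps))
    stop("missing mandatory component(s): ", paste(gaps, collapse = ", "),
         call. = FALSE)
  b <- as.data.frame(steady_beats)
  if (inherits(tau_fits, "tau_fit")) tau_fits <- list(tau_fits)
  hr <- 60000 / mean(b$RR)
  ea <- arterial_elastance(b)
  ees <- if (!is.null(espvr)) espvr$Ees else NA_real_
  co <- if (!is.null(thermo_co)) thermo_co else mean(b$SV) * hr / 1000
  out <- list(
    Pmax = mean(b$Pmax), EF = mean(b$EF), dPdt_max = mean(b$dPdt_max),
    PRSW = if (!is.null(prsw)) prsw$Mw else NA_real_,
    Ea = ea, Ees = ees,
    VVC = if (is.na(ees)) NA_real_ else coupling_ratio(ees, ea),
    EDP = mean(b$EDP), EDV = mean(b$EDV),
    tau = mean(vapply(tau_fits, `[[`, numeric(1), "tau")),
    beta = if (!is.null(edpvr)) edpvr$beta else NA_real_,
    CO = co, HR = hr, SV = mean(b$SV),
    PVR = if (!is.null(pa_mean) && !is.null(lvedp))
      compute_pvr(pa_mean, lvedp, co) else NA_real_
  )
  class(out) <- "ventricular_summary"
  out
}

#' @export
print.ventricular_summary <- function(x, ...) {
  cat("<ventricular_summary>\n")
  cat(sprintf("  Pmax %.1f mmHg | EF %.1f%% | dP/dt_max %.0f mmHg/s\n",
              x$Pmax, 100 * x$EF, x$dPdt_max))
  cat(sprintf("  Ees %.2f, Ea %.2f mmHg/mL (VVC %.2f) | PRSW %.1f mmHg\n",
              x$Ees, x$Ea, x$VVC, x$PRSW))
  cat(sprintf("  EDP %.1f mmHg, EDV %.1f mL | tau %.1f ms | beta %.4f /mL\n",
              x$EDP, x$EDV, x$tau, x$beta))
  cat(sprintf("  CO %.2f L/min (HR %.0f) | PVR %.2f WU\n", x$CO, x$HR, x$PVR))
  invisible(x)
}
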