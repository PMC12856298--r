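#' Hemodynamic ground-truth presets
#'
#' A preset bundles every parameter the beat-level time-varying-elastance
#' renderer needs: end-systolic elastance `Ees` and its volume intercept `V0`,
#' effective pulmonary arterial elastance `Ea`, end-diastolic volume `EDV`,
#' the exponential end-diastolic PV relation (EDPVR)
#' \eqn{P = P_{inf} + A e^{\beta V}}, the logistic relaxation constant
#' \eqn{\tau}, heart rate, rendered peak pressure, pulmonary artery pressures
#' and the LV end-diastolic pressure used as the downstream pressure in PVR.
#'
#' The end-systolic volume is not a free parameter: it is the analytic
#' solution of the ventricular-arterial coupling at the beat level,
#' \deqn{ESV = (Ea \cdot EDV + Ees \cdot V0) / (Ea + Ees),}
#' which makes \eqn{ESP = Ees (ESV - V0) = Ea \cdot SV} hold exactly, so every
#' downstream recovery test has a closed-form truth.
#'
#' Two named presets are built in. `"cteph"` reproduces the group-level right
#' ventricular phenotype of a severe chronic thromboembolic pulmonary
#' hypertension swine cohort (EF 35%, Ees 2.0 mmHg/mL, Ea 1.2 mmHg/mL,
#' tau 20 ms, beta 0.038 /mL, PA 70/51/38 mmHg, CO 4.2 L/min, PVR 10 WU);
#' `"sham"` the corresponding control phenotype (EF 51%, tau 13 ms,
#' beta 0.015 /mL).
#'
#' @param name `"cteph"`, `"sham"`, or a named list of parameter overrides
#'   applied on top of `"cteph"` (must contain at least the overridden fields).
#' @param ... individual parameter overrides (e.g. `tau = 25`), applied last.
#'
#' @return An object of class `hemo_preset`: a list with fields `name`, `HR`
#'   (bpm), `EDV`, `V0` (mL), `Ees`, `Ea` (mmHg/mL), `tau` (ms), `edpvr_Pinf`,
#'   `edpvr_A` (mmHg), `edpvr_beta` (/mL), `Pmax`, `PA_sys`, `PA_mean`,
#'   `PA_dia`, `LVEDP` (mmHg), `phase_fractions`, `fs` (Hz), plus the derived
#'   quantities `ESV`, `SV` (mL), `EF` (fraction), `ESP`, `EDP` (mmHg) and
#'   `CO` (L/min).
#' @examples
#' p <- make_preset("cteph")
#' p$ESV          # 81.25 mL, coupling solution
#' p$EF           # 0.35
#' @export
make_preset <- function(name = "cteph", ...) {
  base <- list(
    cteph = list(
      name = "cteph", HR = 96, EDV = 125, V0 = 55, Ees = 2.0, Ea = 1.2,
      tau = 20, edpvr_Pinf = 0, edpvr_A = 0.10382, edpvr_beta = 0.038,
      Pmax = 63, PA_sys = 70, PA_mean = 51, PA_dia = 38, LVEDP = 9
    ),
    sham = list(
      name = "sham", HR = 103, EDV = 115, V0 = -6.0, Ees = 0.47, Ea = 0.5,
      tau = 13, edpvr_Pinf = 0, edpvr_A = 1.4263, edpvr_beta = 0.015,
      Pmax = 34, PA_sys = 32, PA_mean = 24, PA_dia = 14, LVEDP = 14
    )
  )
  if (is.character(name)) {
    if (!name %in% names(base)) {
      stop("unknown preset '", name, "'; available presets: ",
           paste(names(base), collapse = ", "), call. = FALSE)
    }
    p <- base[[name]]
  } else if (is.list(name)) {
    p <- utils::modifyList(base$cteph, name)
    if (is.null(name$name)) p$name <- "custom"
  } else {
    stop("'name' must be a preset name or a list of parameters", call. = FALSE)
  }
  dots <- list(...)
  if (length(dots)) p <- utils::modifyList(p, dots)
  if (is.null(p$phase_fractions)) {
    p$phase_fractions <- c(ivc = 0.08, ejection = 0.30, ivr = 0.12,
                           filling = 0.50)
  }
  if (is.null(p$fs)) p$fs <- 1000
  validate_preset(p)
}

validate_preset <- function(p) {
  stopifnot(p$Ees > 0, p$Ea > 0, p$EDV > 0, p$tau > 0, p$fs >= 250,
            p$edpvr_beta > 0, p$edpvr_A > 0)
  if (abs(sum(p$phase_fractions) - 1) > 1e-8)
    stop("phase fractions must sum to 1", call. = FALSE)
  p$ESV <- coupling_esv(p)
  if (!(p$EDV > p$ESV && p$ESV > 0))
    stop("preset is not internally consistent: requires EDV > ESV > 0 (ESV = ",
         signif(p$ESV, 4), ")", call. = FALSE)
  p$SV  <- p$EDV - p$ESV
  p$EF  <- p$SV / p$EDV
  p$ESP <- p$Ees * (p$ESV - p$V0)
  p$EDP <- edpvr_pressure(p$EDV, p)
  p$CO  <- p$SV * p$HR / 1000
  class(p) <- "hemo_preset"
  p
}

# analytic beat-level coupling solution: Ea*(EDV-ESV) = Ees*(ESV-V0)
coupling_esv <- function(p, EDV = p$EDV) {
  (p$Ea * EDV + p$Ees * p$V0) / (p$Ea + p$Ees)
}

# EDPVR: P = Pinf + A*exp(beta*V)
edpvr_pressure <- function(v, p) {
  p$edpvr_Pinf + p$edpvr_A * exp(p$edpvr_beta * v)
}

#' @export
print.hemo_preset <- function(x, ...) {
  cat("<hemo_preset '", x$name, "'>\n", sep = "")
  cat(sprintf("  HR %g bpm | EDV %g mL, ESV %.2f mL (EF %.2f)\n",
              x$HR, x$EDV, x$ESV, x$EF))
  cat(sprintf("  Ees %g, Ea %g mmHg/mL, V0 %g mL | ESP %.2f mmHg\n",
              x$Ees, x$Ea, x$V0, x$ESP))
  cat(sprintf("  EDPVR: Pinf %g + %g*exp(%g V) -> EDP %.2f mmHg\n",
              x$edpvr_Pinf, x$edpvr_A, x$edpvr_beta, x$EDP))
  cat(sprintf("  tau %g ms | Pmax %g | PA %g/%g/%g mmHg | LVEDP %g | CO %.2f L/min\n",
              x$tau, x$Pmax, x$PA_sys, x$PA_mean, x$PA_dia, x$LVEDP, x$CO))
  invisible(x)
}
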