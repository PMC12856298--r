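#' @title Beat-level time-varying-elastance renderer
#' @description Internal workhorse shared by [simulate_steady()],
#' [simulate_occlusion()] and [simulate_saline_transient()]. Each beat is
#' rendered as four phases over one cardiac cycle:
#' isovolumic contraction at `V = EDV` (half-cosine pressure ramp EDP -> ESP),
#' ejection `EDV -> ESV` (half-sine pressure through the rendered peak with
#' endpoint ESP), isovolumic relaxation at `V = ESV` following the logistic
#' decay `P(t) = P_A / (1 + exp(t/tau)) + P_B` with `P_B = 2` mmHg and
#' `P_A = 2 (ESP - P_B)`, and filling `ESV -> EDV` along the EDPVR (with a
#' quadratically vanishing continuity term joining the logistic tail, zero at
#' end-diastole). ESV per beat is the closed-form coupling solution, so all
#' end-systolic points are exactly collinear on `P = Ees (V - V0)` and all
#' end-diastolic points lie exactly on the EDPVR.
#' @noRd
render_beats <- function(preset, edv_seq, noise_sd = 0, seed = NULL,
                         gamma = NULL) {
  p <- preset
  fs <- p$fs
  dt <- 1 / fs
  n_cycle <- round(fs * 60 / p$HR)
  nf <- round(p$phase_fractions * n_cycle)
  nf[4] <- n_cycle - sum(nf[1:3])
  if (nf[3] < 10)
    stop("sampling rate too low to resolve tau: fewer than 10 samples in ",
         "the relaxation window", call. = FALSE)
  n_beats <- length(edv_seq)
  P_B <- 2
  # per-beat truth from the coupling solution
  esv <- coupling_esv(p, edv_seq)
  esp <- p$Ees * (esv - p$V0)
  edp <- edpvr_pressure(edv_seq, p)
  pk  <- esp + (p$Pmax - p$ESP)         # peak tracks afterload during occlusion
  edv_next <- c(edv_seq[-1], edv_seq[n_beats])

  P <- V <- PA <- numeric(0)
  beat_of <- integer(0)
  n_sys <- nf[1] + nf[2]
  n_dia <- n_cycle - n_sys
  for (k in seq_len(n_beats)) {
    s1 <- seq(0, length.out = nf[1], by = 1 / nf[1])
    p1 <- edp[k] + (esp[k] - edp[k]) * (1 - cos(pi * s1)) / 2
    v1 <- rep(edv_seq[k], nf[1])
    s2 <- seq(0, length.out = nf[2], by = 1 / nf[2])
    p2 <- esp[k] + (pk[k] - esp[k]) * sin(pi * s2)
    v2 <- esv[k] + (edv_seq[k] - esv[k]) * (1 + cos(pi * s2)) / 2
    t3 <- seq(0, length.out = nf[3], by = dt)
    P_A <- 2 * (esp[k] - P_B)
    p3 <- P_A / (1 + exp(t3 / (p$tau / 1000))) + P_B
    v3 <- rep(esv[k], nf[3])
    s4 <- seq(0, length.out = nf[4], by = 1 / nf[4])
    v4 <- esv[k] + (edv_next[k] - esv[k]) * (1 - cos(pi * s4)) / 2
    # continuity term: logistic value at the next tick minus EDPVR(ESV)
    resid0 <- P_A / (1 + exp(nf[3] * dt / (p$tau / 1000))) + P_B -
      edpvr_pressure(esv[k], p)
    p4 <- edpvr_pressure(v4, p) + resid0 * (1 - s4)^2
    # pulmonary artery channel: two-segment sinusoid hitting sys/dia exactly
    ss <- seq(0, length.out = n_sys, by = 1 / n_sys)
    sd_ <- seq(0, length.out = n_dia, by = 1 / n_dia)
    pa <- c(p$PA_dia + (p$PA_sys - p$PA_dia) * (1 - cos(pi * ss)) / 2,
            p$PA_dia + (p$PA_sys - p$PA_dia) * (1 + cos(pi * sd_)) / 2)
    P <- c(P, p1, p2, p3, p4)
    V <- c(V, v1, v2, v3, v4)
    PA <- c(PA, pa)
    beat_of <- c(beat_of, rep.int(k, n_cycle))
  }
  if (!is.null(gamma)) V <- V * gamma[beat_of]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    P <- P + stats::rnorm(length(P), 0, noise_sd)
    PA <- PA + stats::rnorm(length(PA), 0, noise_sd)
  }
  time <- (seq_along(P) - 1) * dt
  dat <- data.frame(time = time, P = P, V = V, PA = PA)
  truth <- list(
    preset = p,
    beats = data.frame(beat = seq_len(n_beats), EDV = edv_seq, ESV = esv,
                       ESP = esp, EDP = edp, SV = edv_seq - esv),
    seed = seed
  )
  list(data = dat, truth = truth, beat_of = beat_of, n_cycle = n_cycle)
}

wrap_recording <- function(rb, preset, kind, extra_meta = list()) {
  meta <- c(list(preset = preset$name, kind = kind, pa_mean = preset$PA_mean,
                 HR = preset$HR, LVEDP = preset$LVEDP), extra_meta)
  hemo_recording(rb$data, units = c(P = "mmHg", V = "mL", PA = "mmHg"),
                 fs = preset$fs, meta = meta)
}

#' Simulate a steady-state pressure-volume acquisition
#'
#' Renders `n_beats` identical four-phase PV loops from a [make_preset()]
#' ground truth (see the package vignette for the beat model). Optional
#' additive Gaussian noise is applied to the pressure channels only; the
#' volume channel is the mechanical truth.
#'
#' @param preset a [make_preset()] object.
#' @param n_beats number of beats (>= 1).
#' @param noise_sd pressure noise standard deviation, mmHg.
#' @param seed RNG seed for the noise (ignored when `noise_sd = 0`).
#' @return A list with `recording` (a [hemo_recording] with channels `P`
#'   (mmHg), `V` (mL) and `PA` (mmHg)) and `truth` (preset plus per-beat
#'   EDV/ESV/ESP/EDP/SV).
#' @examples
#' sim <- simulate_steady(make_preset("cteph"), n_beats = 3)
#' min(sim$recording$data$V)   # 81.25 mL = analytic ESV
#' @export
simulate_steady <- function(preset, n_beats = 5, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "hemo_preset"))
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  rb <- render_beats(preset, rep(preset$EDV, n_beats), noise_sd, seed)
  list(recording = wrap_recording(rb, preset, "steady",
                                  list(truth = rb$truth$beats)),
       truth = rb$truth)
}

#' Simulate an inferior-vena-cava occlusion run
#'
#' Preload falls linearly from `edv_start` to `edv_end` across `n_beats`
#' beats; each beat's ESV follows the analytic coupling solution with fixed
#' `Ees`, `Ea`, `V0`, so end-systolic points are exactly collinear on
#' `P = Ees (V - V0)` and end-diastolic points lie exactly on the EDPVR.
#'
#' @inheritParams simulate_steady
#' @param edv_start,edv_end first/last beat end-diastolic volume, mL
#'   (`edv_start > edv_end > V0`).
#' @return As [simulate_steady()].
#' @export
simulate_occlusion <- function(preset, n_beats = 12, edv_start = preset$EDV,
                               edv_end, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "hemo_preset"))
  if (n_beats < 5) stop("n_beats must be >= 5 for an occlusion run",
                        call. = FALSE)
  if (edv_end <= preset$V0)
    stop("edv_end must exceed the ESPVR volume intercept V0 (nonphysical)",
         call. = FALSE)
  if (edv_start <= edv_end) stop("edv_start must exceed edv_end", call. = FALSE)
  edv_seq <- seq(edv_start, edv_end, length.out = n_beats)
  rb <- render_beats(preset, edv_seq, noise_sd, seed)
  list(recording = wrap_recording(rb, preset, "occlusion",
                                  list(truth = rb$truth$beats)),
       truth = rb$truth)
}

#' Conductance-catheter forward model
#'
#' Maps a true volume series to the uncalibrated conductance-derived signal
#' `U(t) = alpha (V(t) + Vp)`, where `alpha` is the field-inhomogeneity gain
#' and `Vp` the parallel-conductance volume offset. [apply_calibration()]
#' inverts it exactly.
#'
#' @param volume true volume series, mL.
#' @param alpha field factor (> 0), unitless.
#' @param Vp parallel-conductance volume, mL.
#' @return Uncalibrated volume series (arbitrary units).
#' @export
simulate_conductance_channel <- function(volume, alpha, Vp) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  alpha * (volume + Vp)
}

#' Simulate a hypertonic-saline calibration transient
#'
#' Steady mechanical beats whose blood conductivity rises as the saline bolus
#' washes in: beat `k` carries a gain `gamma_k = 1 + drift_per_beat (k-1)/EDV`
#' on the blood-volume term, so the uncalibrated channel is
#' `U = alpha (gamma_k V + Vp)`. On the alpha-corrected scale the apparent
#' end-diastolic volume rises by `drift_per_beat` mL per beat while the true
#' stroke volume is constant; regressing apparent ESV on apparent EDV and
#' extrapolating to the identity line recovers `Vp` exactly
#' (see [estimate_parallel_volume()]).
#'
#' @inheritParams simulate_steady
#' @param Vp_true true parallel-conductance volume, mL.
#' @param alpha_true true field factor.
#' @param drift_per_beat wash-in drift: rise of apparent ED volume per beat on
#'   the alpha-corrected scale, mL (> 0).
#' @return A list with `recording` (channels `P` (mmHg), `U` (a.u.), `PA`) and
#'   `truth` (includes `alpha`, `Vp`, `drift_per_beat`, per-beat gains).
#' @export
simulate_saline_transient <- function(preset, n_beats = 8, Vp_true = 25,
                                      alpha_true = 2, drift_per_beat = 6,
                                      noise_sd = 0, seed = NULL) {
  stopifnot(inherits(preset, "hemo_preset"))
  if (n_beats < 4)
    stop("n_beats must be >= 4: insufficient points for extrapolation",
         call. = FALSE)
  if (drift_per_beat <= 0) stop("drift_per_beat must be > 0", call. = FALSE)
  if (alpha_true <= 0) stop("alpha_true must be > 0", call. = FALSE)
  gamma <- 1 + drift_per_beat * (seq_len(n_beats) - 1) / preset$EDV
  rb <- render_beats(preset, rep(preset$EDV, n_beats), noise_sd, seed,
                     gamma = gamma)
  dat <- rb$data
  dat$U <- alpha_true * (dat$V + Vp_true)
  dat$V <- NULL
  rec <- hemo_recording(dat, units = c(P = "mmHg", PA = "mmHg", U = "a.u."),
                        fs = preset$fs,
                        meta = list(preset = preset$name, kind = "saline",
                                    pa_mean = preset$PA_mean, HR = preset$HR))
  truth <- rb$truth
  truth$alpha <- alpha_true
  truth$Vp <- Vp_true
  truth$drift_per_beat <- drift_per_beat
  truth$gamma <- gamma
  list(recording = rec, truth = truth)
}

#' Simulate a thermodilution cardiac-output measurement
#'
#' `CO = SV * HR / 1000` from the preset's coupling solution, multiplied by
#' lognormal noise with the stated coefficient of variation (mean 1);
#' `noise_cv = 0` returns the exact value.
#'
#' @inheritParams simulate_steady
#' @param noise_cv coefficient of variation of the measurement (fraction).
#' @return Cardiac output, L/min.
#' @examples
#' simulate_thermodilution(make_preset("cteph"))   # 4.2
#' @export
simulate_thermodilution <- function(preset, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(preset, "hemo_preset"))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  co <- preset$SV * preset$HR / 1000
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    co <- co * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  co
}
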