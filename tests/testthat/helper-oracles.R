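# Independent oracles and shared fixtures for the test suite.
# The loop-area oracle integrates the continuous-time phase model directly
# (quadrature on the parametric forms), independent of sampling and of the
# package's shoelace implementation.

oracle_loop_area <- function(p, edv = p$EDV, edv_next = edv) {
  esv <- (p$Ea * edv + p$Ees * p$V0) / (p$Ea + p$Ees)
  esp <- p$Ees * (esv - p$V0)
  sv <- edv - esv
  pk <- esp + (p$Pmax - p$ESP)
  edpvr <- function(v) p$edpvr_Pinf + p$edpvr_A * exp(p$edpvr_beta * v)
  # ejection: V = esv + sv (1+cos pi s)/2, P = esp + (pk-esp) sin(pi s)
  ej <- stats::integrate(function(s) {
    (esp + (pk - esp) * sin(pi * s)) * sv * (pi / 2) * sin(pi * s)
  }, 0, 1, rel.tol = 1e-10)$value
  # filling: V = esv + (edv_next - esv)(1-cos pi s)/2,
  #          P = edpvr(V) + r (1-s)^2, r from the renderer's continuity rule
  n_cycle <- round(p$fs * 60 / p$HR)
  nf <- round(p$phase_fractions * n_cycle)
  P_B <- 2
  P_A <- 2 * (esp - P_B)
  r <- P_A / (1 + exp(nf[3] / p$fs / (p$tau / 1000))) + P_B - edpvr(esv)
  svf <- edv_next - esv
  fill <- stats::integrate(function(s) {
    v <- esv + svf * (1 - cos(pi * s)) / 2
    (edpvr(v) + r * (1 - s)^2) * svf * (pi / 2) * sin(pi * s)
  }, 0, 1, rel.tol = 1e-10)$value
  ej - fill
}

# polygon area by the surveyor formula written independently (signed sum over
# directed edges), used as the per-beat stroke-work oracle
oracle_polygon_area <- function(P, V) {
  n <- length(P)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + (V[i] - V[j]) * (P[i] + P[j]) / 2
  }
  abs(s)
}

cteph <- make_preset("cteph")
sham <- make_preset("sham")
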