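#' Myocyte cross-sectional area assuming an elliptical section
#'
#' `CSA = pi * width * depth / 4`.
#'
#' @param width,depth cell width and depth, um (> 0).
#' @return CSA, um^2.
#' @examples
#' myocyte_csa(20, 20)   # 314.16
#' @export
myocyte_csa <- function(width, depth) {
  if (any(width <= 0) || any(depth <= 0))
    stop("width and depth must be > 0", call. = FALSE)
  pi * width * depth / 4
}

#' Normalize force by cross-sectional area
#'
#' `tension = force / CSA`, with 1 uN/um^2 = 10^3 kN/m^2.
#'
#' @param force force, uN.
#' @param csa cross-sectional area, um^2 (> 0).
#' @return Tension, kN/m^2.
#' @examples
#' tension_from_force(3, 300)   # 10
#' @export
tension_from_force <- function(force, csa) {
  if (any(csa <= 0)) stop("CSA must be > 0", call. = FALSE)
  force / csa * 1000
}

#' Passive tension from a slack test
#'
#' The slack test shortens the cell to 80% of its initial length; passive
#' tension is the force drop normalized by CSA,
#' `PT = (total - post_slack) / CSA`. Negative values are flagged by warning,
#' not clipped.
#'
#' @param total_force,post_slack_force forces before/after the slack, uN.
#' @param csa cross-sectional area, um^2 (> 0).
#' @return PT, kN/m^2.
#' @export
slack_passive_tension <- function(total_force, post_slack_force, csa) {
  pt <- tension_from_force(total_force - post_slack_force, csa)
  if (any(pt < 0)) warning("negative passive tension (post-slack force exceeds total)")
  pt
}

#' Active tension
#'
#' `AT = total - passive`, both tensions on the same CSA basis.
#'
#' @param total_tension,passive_tension tensions, kN/m^2.
#' @return AT, kN/m^2.
#' @export
active_tension <- function(total_tension, passive_tension) {
  total_tension - passive_tension
}

hill_at <- function(pCa, ATmax, pCa50, nH) {
  ATmax / (1 + 10^(nH * (pCa - pCa50)))
}

#' Fit the force-pCa Hill relation
#'
#' Least-squares fit of
#' \deqn{AT = AT_{max} / (1 + (EC_{50}/[Ca])^{n_H})}
#' with \eqn{[Ca] = 10^{-pCa}}; internally parameterized in
#' \eqn{pCa_{50} = -\log_{10} EC_{50}} for numerical stability. The Hill
#' coefficient is fitted freely. Initialization is deterministic:
#' `ATmax0 = max(AT)`, `pCa50_0` at half-max by linear interpolation,
#' `nH0 = 2`.
#'
#' @param pCa pCa values (>= 4 distinct points).
#' @param AT active tensions, kN/m^2.
#' @return A list of class `hill_fit`: `ATmax` (kN/m^2), `EC50` (mol/L),
#'   `pCa50`, `nH`, `rmse`, `flags` (extrapolation flag when EC50 falls more
#'   than one decade outside the sampled range).
#' @examples
#' pca <- c(5.0, 5.2, 5.4, 5.6, 5.8, 6.0)
#' f <- fit_hill(pca, 20 / (1 + 10^(3 * (pca - 5.6))))
#' f$pCa50   # 5.6
#' @export
fit_hill <- function(pCa, AT) {
  stopifnot(length(pCa) == length(AT))
  if (length(unique(pCa)) < 4)
    stop("Hill fit needs >= 4 distinct pCa points", call. = FALSE)
  if (diff(range(AT)) < 1e-9)
    stop("all active tensions equal: Hill fit is degenerate", call. = FALSE)
  ATmax0 <- max(AT)
  o <- order(pCa)
  pCa50_0 <- tryCatch(
    stats::approx(AT[o], pCa[o], xout = ATmax0 / 2, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(pCa50_0)) pCa50_0 <- mean(range(pCa))
  fit <- minpack.lm::nlsLM(
    AT ~ ATmax / (1 + 10^(nH * (pCa - pCa50))),
    start = list(ATmax = ATmax0, pCa50 = pCa50_0, nH = 2),
    lower = c(ATmax = 1e-9, pCa50 = 2, nH = 0.1),
    upper = c(ATmax = Inf, pCa50 = 9, nH = 20),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  flags <- character(0)
  if (cf["pCa50"] > max(pCa) + 1 || cf["pCa50"] < min(pCa) - 1)
    flags <- "EC50 extrapolated more than one decade beyond the sampled range"
  structure(list(ATmax = unname(cf["ATmax"]), pCa50 = unname(cf["pCa50"]),
                 EC50 = 10^(-unname(cf["pCa50"])), nH = unname(cf["nH"]),
                 rmse = sqrt(mean(stats::resid(fit)^2)), flags = flags),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> ATmax = %.2f kN/m2, pCa50 = %.3f (EC50 %.3g M), nH = %.2f (rmse %.3g)\n",
              x$ATmax, x$pCa50, x$EC50, x$nH, x$rmse))
  if (length(x$flags)) cat("  flags:", x$flags, "\n")
  invisible(x)
}

#' Fit the exponential sarcomere-length / passive-tension relation
#'
#' Least-squares fit of `PT = a exp(b SL)` (no offset). Non-positive PT
#' values are excluded with a log; the predicted PT at SL 2.2 um — the
#' standard comparison point — is reported.
#'
#' @param SL sarcomere lengths, um (>= 4 points within 1.8-2.3 um).
#' @param PT passive tensions, kN/m^2.
#' @return A list of class `slpt_fit`: `a` (kN/m^2), `b` (/um), `pt_2.2`,
#'   `rmse`, `excluded` (count of non-positive points dropped), `flags`.
#' @export
fit_sl_pt <- function(SL, PT) {
  stopifnot(length(SL) == length(PT))
  drop <- PT <= 0
  SL <- SL[!drop]; PT <- PT[!drop]
  if (length(unique(SL)) < 4)
    stop("SL-PT fit needs >= 4 positive-tension points", call. = FALSE)
  ll <- stats::lm(log(PT) ~ SL)
  b0 <- unname(stats::coef(ll)[2])
  a0 <- exp(unname(stats::coef(ll)[1]))
  # direct Levenberg-Marquardt (tolerates the flat-curve b = 0 edge case)
  res_fn <- function(par) par[1] * exp(par[2] * SL) - PT
  fit <- minpack.lm::nls.lm(par = c(a = a0, b = b0), fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0 || fit$info > 4)
    stop("SL-PT fit did not converge: ", fit$message, call. = FALSE)
  cf <- fit$par
  flags <- if (cf["b"] < 1e-6)
    "exponent not positive: no passive stiffening with SL" else character(0)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 pt_2.2 = unname(cf["a"] * exp(cf["b"] * 2.2)),
                 rmse = sqrt(mean(res_fn(cf)^2)),
                 excluded = sum(drop), flags = flags),
            class = "slpt_fit")
}

#' @export
print.slpt_fit <- function(x, ...) {
  cat(sprintf("<slpt_fit> PT = %.4g * exp(%.3f SL); PT(2.2 um) = %.2f kN/m2 (rmse %.3g)\n",
              x$a, x$b, x$pt_2.2, x$rmse))
  if (length(x$flags)) cat("  flags:", x$flags, "\n")
  invisible(x)
}

#' Cluster-bootstrap confidence band for a group-level curve fit
#'
#' Resamples myocytes (not individual points) with replacement, refits the
#' Hill or exponential model on each resample, and returns the pointwise
#' percentile 2.5/97.5 band of the predicted curves on a fixed x grid.
#' Resampling whole myocytes respects the within-myocyte correlation of the
#' repeated measurements.
#'
#' @param data data.frame with columns `myocyte`, `x`, `y` (pooled points of
#'   one group).
#' @param fit_kind `"hill"` or `"exponential"`.
#' @param B number of resamples (>= 100).
#' @param seed RNG seed.
#' @param grid x grid for the band (default: 50 points over the data range).
#' @return A data.frame `x`, `lo`, `hi`, `fit` (the point-estimate curve),
#'   with attribute `B`.
#' @export
bootstrap_fit_band <- function(data, fit_kind = c("hill", "exponential"),
                               B = 5000, seed = NULL, grid = NULL) {
  fit_kind <- match.arg(fit_kind)
  stopifnot(all(c("myocyte", "x", "y") %in% names(data)))
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  ids <- unique(data$myocyte)
  if (length(ids) < 3) stop("cluster bootstrap needs >= 3 myocytes",
                            call. = FALSE)
  if (is.null(grid)) grid <- seq(min(data$x), max(data$x), length.out = 50)
  predfun <- switch(fit_kind,
    hill = function(d) {
      f <- fit_hill(d$x, d$y)
      hill_at(grid, f$ATmax, f$pCa50, f$nH)
    },
    exponential = function(d) {
      f <- fit_sl_pt(d$x, d$y)
      f$a * exp(f$b * grid)
    })
  point <- predfun(data)
  if (!is.null(seed)) set.seed(seed)
  by_id <- split(data, data$myocyte)
  preds <- matrix(NA_real_, B, length(grid))
  for (r in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    d <- do.call(rbind, by_id[as.character(take)])
    preds[r, ] <- tryCatch(predfun(d), error = function(e) rep(NA_real_,
                                                               length(grid)))
  }
  qs <- apply(preds, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(x = grid, lo = qs[1, ], hi = qs[2, ], fit = point)
  attr(out, "B") <- B
  out
}
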