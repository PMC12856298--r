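#' Simulate hierarchical skinned-myocyte mechanics data
#'
#' Generates a tidy table of per-myocyte measurements with a two-level random
#' structure (animal intercepts plus a per-myocyte component, plus residual
#' noise), emulating a two-group skinned-cardiomyocyte study design with at
#' least 5 cells per animal.
#'
#' For each myocyte, active tension is sampled on the standard activating
#' ladder pCa in \{5.0, 5.2, 5.4, 5.6, 5.8, 6.0\} from a Hill curve whose
#' `ATmax` carries the additive animal and myocyte effects, and passive
#' tension at SL in \{1.8, 1.9, ..., 2.3\} um from `PT = a exp(b SL)` whose
#' scale `a` carries the same effects multiplicatively (log-normal), so each
#' noise-free myocyte still lies exactly on its own curve family. Cell width
#' and depth are drawn uniformly from typical ranges for CSA computation.
#'
#' @param n_animals named integer vector: animals per group
#'   (default `c(sham = 6, cteph = 7)`).
#' @param n_myocytes myocytes per animal (>= 5).
#' @param ATmax,pCa50,nH named per-group Hill parameters (kN/m^2, -, -).
#' @param a,b named per-group SL-PT exponential parameters (kN/m^2, /um).
#' @param sd_animal,sd_myocyte SD of the animal/myocyte effects on ATmax
#'   (kN/m^2); applied on the log scale (as fractions of `a`) for PT.
#' @param sd_resid residual SD on each active-tension point, kN/m^2.
#' @param sd_resid_pt residual SD on each passive-tension point, kN/m^2;
#'   defaults to 2% of the myocyte's PT at 2.2 um (force-transducer noise is
#'   small relative to the between-myocyte spread).
#' @param width_range,depth_range uniform sampling ranges for cell size, um.
#' @param seed RNG seed.
#' @return A tidy data.frame: `group`, `animal`, `myocyte`, `width`, `depth`,
#'   `csa`, `kind` (`"at"` or `"pt"`), `x` (pCa or SL um), `value` (kN/m^2),
#'   with the per-myocyte true parameters as attribute `truth`.
#' @export
simulate_myocytes <- function(n_animals = c(sham = 6, cteph = 7),
                              n_myocytes = 5,
                              ATmax = c(sham = 16, cteph = 22),
                              pCa50 = c(sham = 5.55, cteph = 5.55),
                              nH = c(sham = 3, cteph = 3),
                              a = c(sham = 0.012, cteph = 0.024),
                              b = c(sham = 2.5, cteph = 2.5),
                              sd_animal = 1, sd_myocyte = 0.5, sd_resid = 0.5,
                              sd_resid_pt = NULL,
                              width_range = c(18, 32),
                              depth_range = c(12, 24),
                              seed = NULL) {
  if (n_myocytes < 5)
    stop("at least 5 myocytes per animal are required", call. = FALSE)
  if (sd_animal < 0 || sd_myocyte < 0 || sd_resid < 0 ||
      (!is.null(sd_resid_pt) && sd_resid_pt < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  groups <- names(n_animals)
  stopifnot(!is.null(groups), all(groups %in% names(ATmax)))
  if (!is.null(seed)) set.seed(seed)
  pca_grid <- c(5.0, 5.2, 5.4, 5.6, 5.8, 6.0)
  sl_grid <- seq(1.8, 2.3, by = 0.1)
  rows <- list()
  truth <- list()
  for (g in groups) {
    for (ai in seq_len(n_animals[[g]])) {
      animal <- sprintf("%s_%02d", g, ai)
      a_eff <- stats::rnorm(1, 0, sd_animal)
      for (mi in seq_len(n_myocytes)) {
        myocyte <- sprintf("%s_m%02d", animal, mi)
        m_eff <- stats::rnorm(1, 0, sd_myocyte)
        atmax_i <- ATmax[[g]] + a_eff + m_eff
        # same hierarchy on PT scale, multiplicative to keep PT positive
        a_i <- a[[g]] * exp((a_eff + m_eff) / ATmax[[g]])
        w <- stats::runif(1, width_range[1], width_range[2])
        d <- stats::runif(1, depth_range[1], depth_range[2])
        at <- hill_at(pca_grid, atmax_i, pCa50[[g]], nH[[g]]) +
          stats::rnorm(length(pca_grid), 0, sd_resid)
        sd_pt <- if (!is.null(sd_resid_pt)) sd_resid_pt
          else if (sd_resid == 0) 0 else 0.02 * a_i * exp(b[[g]] * 2.2)
        pt <- a_i * exp(b[[g]] * sl_grid) +
          stats::rnorm(length(sl_grid), 0, sd_pt)
        rows[[myocyte]] <- data.frame(
          group = g, animal = animal, myocyte = myocyte,
          width = w, depth = d, csa = myocyte_csa(w, d),
          kind = rep(c("at", "pt"), c(length(pca_grid), length(sl_grid))),
          x = c(pca_grid, sl_grid), value = c(at, pt)
        )
        truth[[myocyte]] <- data.frame(
          myocyte = myocyte, ATmax = atmax_i, pCa50 = pCa50[[g]],
          nH = nH[[g]], a = a_i, b = b[[g]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, c(truth, make.row.names = FALSE))
  out
}

#' Simulate a nested null/effect response for mixed-model calibration
#'
#' Draws `y = group_effect * 1(group 2) + animal + myocyte + residual` with
#' independent Gaussian components, the design used to calibrate the nested
#' mixed model's type-I error and power.
#'
#' @param n_animals animals per group (length-2 vector).
#' @param n_myocytes myocytes per animal.
#' @param n_obs observations per myocyte.
#' @param group_effect fixed difference between groups.
#' @param sd_animal,sd_myocyte,sd_resid variance-component SDs.
#' @param seed RNG seed.
#' @return data.frame `group`, `animal`, `myocyte`, `y`.
#' @export
simulate_nested_response <- function(n_animals = c(6, 7), n_myocytes = 5,
                                     n_obs = 3, group_effect = 0,
                                     sd_animal = 2, sd_myocyte = 1,
                                     sd_resid = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in 1:2) {
    for (ai in seq_len(n_animals[g])) {
      animal <- sprintf("g%d_a%02d", g, ai)
      a_eff <- stats::rnorm(1, 0, sd_animal)
      for (mi in seq_len(n_myocytes)) {
        myocyte <- sprintf("%s_m%02d", animal, mi)
        m_eff <- stats::rnorm(1, 0, sd_myocyte)
        y <- (g == 2) * group_effect + a_eff + m_eff +
          stats::rnorm(n_obs, 0, sd_resid)
        rows[[myocyte]] <- data.frame(group = paste0("g", g), animal = animal,
                                      myocyte = myocyte, y = y)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Ct table with dual housekeepers
#'
#' Ct values follow `Ct = baseline - log2FC * 1(group 2) + noise`, run in
#' duplicate per sample, for the standard right-ventricular remodeling gene
#' panel plus the two housekeeping genes GAPDH and RPL4 (whose fold change is
#' fixed at zero between groups). Default fold-change directions follow the
#' expected pressure-overload fetal-gene-program shift (MYH7, NPPB, TNF up;
#' MYH6, ATP2A2 down; RYR2, collagen chains and EDN1 unchanged) with
#' configurable magnitudes.
#'
#' @param n_per_group named integer vector of samples per group
#'   (reference group first).
#' @param log2fc named per-gene log2 fold change of group 2 vs group 1;
#'   genes absent from the vector default to 0. Housekeepers are forced to 0.
#' @param baseline named per-gene baseline Ct (defaults span 18-30 cycles).
#' @param noise_sd Ct noise SD (cycles).
#' @param replicates reactions per sample (default 2, run in duplicate).
#' @param efficiency per-gene amplification efficiency (fraction, 1 = 100%).
#' @param seed RNG seed.
#' @return A tidy data.frame `sample`, `group`, `gene`, `replicate`, `Ct`,
#'   `efficiency`.
#' @export
simulate_qpcr <- function(n_per_group = c(sham = 6, cteph = 7),
                          log2fc = c(MYH7 = 2, NPPB = 1.5, TNF = 1,
                                     MYH6 = -2, ATP2A2 = -1),
                          baseline = NULL, noise_sd = 0.2, replicates = 2,
                          efficiency = 1, seed = NULL) {
  genes <- c("ATP2A2", "COL1A1", "COL3A1", "EDN1", "GAPDH", "MYH6", "MYH7",
             "NPPB", "RPL4", "RYR2", "TNF")
  housekeepers <- c("GAPDH", "RPL4")
  if (is.null(baseline)) {
    baseline <- c(ATP2A2 = 22, COL1A1 = 24, COL3A1 = 24, EDN1 = 28,
                  GAPDH = 18, MYH6 = 23, MYH7 = 21, NPPB = 26, RPL4 = 20,
                  RYR2 = 25, TNF = 30)
  }
  fc <- stats::setNames(rep(0, length(genes)), genes)
  fc[names(log2fc)[names(log2fc) %in% genes]] <-
    log2fc[names(log2fc) %in% genes]
  fc[housekeepers] <- 0
  if (!all(housekeepers %in% genes) || !all(housekeepers %in% names(baseline)))
    stop("both housekeeping genes (GAPDH, RPL4) must be present",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eff <- if (length(efficiency) == 1)
    stats::setNames(rep(efficiency, length(genes)), genes) else efficiency
  groups <- names(n_per_group)
  rows <- list()
  for (gi in seq_along(groups)) {
    for (si in seq_len(n_per_group[[gi]])) {
      sample_id <- sprintf("%s_%02d", groups[gi], si)
      for (gene in genes) {
        ct <- baseline[[gene]] - fc[[gene]] * (gi == 2) +
          stats::rnorm(replicates, 0, noise_sd)
        ct <- pmin(pmax(ct, 5 + 1e-6), 40 - 1e-6)
        rows[[paste(sample_id, gene)]] <- data.frame(
          sample = sample_id, group = groups[gi], gene = gene,
          replicate = seq_len(replicates), Ct = ct,
          efficiency = eff[[gene]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
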