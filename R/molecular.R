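#' PCR amplification efficiency from a dilution series
#'
#' OLS slope of Ct on log10 input gives the efficiency
#' `E = 10^(-1/slope) - 1`; a slope of -3.3219 corresponds to perfect
#' doubling (100%). Target genes whose efficiency differs from the
#' housekeepers by more than 5 percentage points should be flagged before
#' 2^-ddCt quantification (see [relative_expression()]).
#'
#' @param log10_input log10 of template input for each dilution point.
#' @param ct observed Ct values (>= 4 points).
#' @return A list: `efficiency` (fraction), `slope`, `r2`.
#' @examples
#' check_efficiency(0:-3, 20 + 3.3219 * (0:3))$efficiency   # 1
#' @export
check_efficiency <- function(log10_input, ct) {
  stopifnot(length(log10_input) == length(ct))
  if (length(log10_input) < 4)
    stop("efficiency check needs >= 4 dilution points", call. = FALSE)
  fit <- stats::lm(ct ~ log10_input)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("positive dilution slope: Ct must fall with template input",
         call. = FALSE)
  list(efficiency = 10^(-1 / slope) - 1, slope = slope,
       r2 = r_squared(fit))
}

#' Relative gene expression by the 2^-ddCt method
#'
#' Replicate Cts are averaged per sample and gene; the target Ct is
#' normalized by the arithmetic mean of the two housekeeper Cts — exactly
#' the geometric mean of the linear housekeeper quantities when efficiencies
#' are equal — giving dCt; ddCt subtracts the reference-group mean dCt, and
#' `fold = 2^-ddCt`, so the reference group's geometric-mean fold is 1 for
#' every gene by construction.
#'
#' @param ct a tidy Ct table: `sample`, `group`, `gene`, `Ct` (one row per
#'   replicate), optionally `efficiency`.
#' @param housekeepers the two normalizer genes.
#' @param reference_group group used as the expression reference.
#' @param efficiency_tol maximum spread (fraction) between target and
#'   housekeeper efficiencies before a gene is flagged.
#' @return A data.frame `gene`, `sample`, `group`, `dCt`, `ddCt`, `fold`,
#'   `flag`.
#' @export
relative_expression <- function(ct, housekeepers = c("GAPDH", "RPL4"),
                                reference_group = "sham",
                                efficiency_tol = 0.05) {
  stopifnot(all(c("sample", "group", "gene", "Ct") %in% names(ct)))
  if (!all(housekeepers %in% ct$gene))
    stop("missing housekeeper gene(s): ",
         paste(setdiff(housekeepers, ct$gene), collapse = ", "),
         call. = FALSE)
  if (!reference_group %in% ct$group)
    stop("reference group '", reference_group, "' absent from table",
         call. = FALSE)
  rng_flag <- ct$Ct <= 5 | ct$Ct >= 40
  if (any(rng_flag))
    warning(sum(rng_flag), " Ct value(s) outside (5, 40) flagged")
  agg <- stats::aggregate(Ct ~ sample + group + gene, data = ct, FUN = mean)
  eff_flags <- character(0)
  if ("efficiency" %in% names(ct)) {
    eff <- stats::aggregate(efficiency ~ gene, data = ct, FUN = mean)
    hk_eff <- mean(eff$efficiency[eff$gene %in% housekeepers])
    bad <- eff$gene[abs(eff$efficiency - hk_eff) > efficiency_tol]
    eff_flags <- setdiff(bad, housekeepers)
    if (length(eff_flags))
      warning("efficiency differs from housekeepers by > ",
              100 * efficiency_tol, " points for: ",
              paste(eff_flags, collapse = ", "))
  }
  wide <- split(agg, agg$sample)
  rows <- lapply(wide, function(d) {
    hk <- mean(d$Ct[d$gene %in% housekeepers])
    tg <- d[!d$gene %in% housekeepers, , drop = FALSE]
    data.frame(gene = tg$gene, sample = tg$sample, group = tg$group,
               dCt = tg$Ct - hk)
  })
  out <- do.call(rbind, rows)
  ref_mean <- stats::aggregate(
    dCt ~ gene, data = out[out$group == reference_group, , drop = FALSE],
    FUN = mean)
  out$ddCt <- out$dCt - ref_mean$dCt[match(out$gene, ref_mean$gene)]
  out$fold <- 2^(-out$ddCt)
  out$flag <- out$gene %in% eff_flags
  rownames(out) <- NULL
  out[order(out$gene, out$sample), ]
}

#' Normalize densitometry band intensities
#'
#' Duplicate intensities are averaged, the target/normalizer ratio is formed
#' (e.g. SERCA2a over GAPDH, or phospho-PLB over total PLB), and ratios are
#' rescaled so that the reference-group mean equals 1.
#'
#' @param dens a data.frame with `sample`, `group` and replicate intensity
#'   columns: `target` and `normalizer` may each be a single column or
#'   duplicates (`target1`/`target2`, `normalizer1`/`normalizer2`).
#' @param reference_group group whose mean ratio is scaled to 1.
#' @return The input with added `ratio` (raw) and `level` (reference-scaled).
#' @export
densitometry_normalize <- function(dens, reference_group = "sham") {
  stopifnot(all(c("sample", "group") %in% names(dens)))
  pick <- function(stem) {
    cols <- grep(paste0("^", stem, "[0-9]*$"), names(dens), value = TRUE)
    if (!length(cols)) stop("no '", stem, "' column(s)", call. = FALSE)
    rowMeans(dens[cols])
  }
  tgt <- pick("target")
  nrm <- pick("normalizer")
  if (any(nrm <= 0)) stop("normalizer intensity must be > 0", call. = FALSE)
  if (any(tgt <= 0)) stop("band intensities must be > 0", call. = FALSE)
  dens$ratio <- tgt / nrm
  ref <- mean(dens$ratio[dens$group == reference_group])
  dens$level <- dens$ratio / ref
  dens
}

#' Percent wall thickness of an arteriole
#'
#' `%WT = 100 (external - lumen) / external`, the medial-wall fraction of
#' the external diameter, for distal arterioles (< 100 um).
#'
#' @param external_d external diameter, um.
#' @param lumen_d lumen diameter, um (`0 <= lumen_d < external_d`).
#' @return Percent wall thickness.
#' @examples
#' percent_wall_thickness(80, 60)   # 25
#' @export
percent_wall_thickness <- function(external_d, lumen_d) {
  if (any(lumen_d < 0)) stop("lumen diameter must be >= 0", call. = FALSE)
  if (any(lumen_d >= external_d))
    stop("lumen diameter must be smaller than external diameter",
         call. = FALSE)
  100 * (external_d - lumen_d) / external_d
}

#' Aggregate morphometry with the animal as the statistical unit
#'
#' Averages raw measurements (cardiomyocyte CSA, arteriolar percent wall
#' thickness, fibrosis fraction, ...) within animal first, then summarizes
#' per group as mean +/- SEM. Warns when an animal falls below the study's
#' minimum counts (60 cardiomyocytes for CSA, 10 arterioles for %WT, 10
#' sections for fibrosis).
#'
#' @param records data.frame with `animal`, `group`, `structure`
#'   (`"cardiomyocyte"`, `"arteriole"` or `"field"`) and `value`.
#' @param min_counts named minimum measurement counts per structure.
#' @return A list: `per_animal` (animal means + counts) and `per_group`
#'   (mean, SEM, n animals) per structure.
#' @export
aggregate_morphometry <- function(records,
                                  min_counts = c(cardiomyocyte = 60,
                                                 arteriole = 10,
                                                 field = 10)) {
  stopifnot(all(c("animal", "group", "structure", "value") %in%
                  names(records)))
  if (!nrow(records)) stop("empty morphometry input", call. = FALSE)
  per_animal <- stats::aggregate(value ~ group + animal + structure,
                                 data = records, FUN = mean)
  counts <- stats::aggregate(value ~ group + animal + structure,
                             data = records, FUN = length)
  per_animal$n <- counts$value
  low <- per_animal$n < min_counts[per_animal$structure]
  if (any(low, na.rm = TRUE)) {
    bad <- per_animal[which(low), , drop = FALSE]
    warning("below minimum count: ",
            paste(sprintf("%s %s (%d < %d)", bad$animal, bad$structure,
                          bad$n, min_counts[bad$structure]),
                  collapse = "; "))
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  grp <- do.call(rbind, lapply(
    split(per_animal, interaction(per_animal$group, per_animal$structure,
                                  drop = TRUE)),
    function(d) data.frame(group = d$group[1], structure = d$structure[1],
                           mean = mean(d$value), sem = sem(d$value),
                           n_animals = nrow(d))))
  rownames(grp) <- NULL
  list(per_animal = per_animal, per_group = grp)
}
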