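#' Normality-dispatched two-group comparison
#'
#' Implements the study-level test dispatcher: Shapiro-Wilk on each group at
#' alpha = 0.05; if both pass, an F-test of variance homogeneity decides
#' between Student's (homogeneous) and Welch's (non-homogeneous) t-test;
#' otherwise the Mann-Whitney U-test. Two-tailed throughout. The descriptive
#' summary style follows the normality decision: mean +/- SEM when both
#' groups are normal, median (range) otherwise.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha decision threshold for the Shapiro-Wilk and variance tests.
#' @return A list of class `group_comparison`: `test` (`"student"`,
#'   `"welch"` or `"mannwhitney"`), `statistic`, `p`, `summary_x`,
#'   `summary_y` (formatted descriptives), `style`, and `trace` (Shapiro p
#'   per group, variance-test p) making the decision path reproducible.
#' @export
two_group_compare <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  sw_x <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  sw_y <- tryCatch(stats::shapiro.test(y)$p.value, error = function(e) 0)
  normal <- sw_x >= alpha && sw_y >= alpha
  var_p <- NA_real_
  if (normal) {
    var_p <- stats::var.test(x, y)$p.value
    if (var_p >= alpha) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      test <- "student"
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      test <- "welch"
    }
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    test <- "mannwhitney"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  style <- if (normal) "mean_sem" else "median_range"
  structure(list(test = test, statistic = statistic, p = p,
                 summary_x = describe_group(x, style),
                 summary_y = describe_group(y, style),
                 style = style,
                 trace = list(shapiro_x = sw_x, shapiro_y = sw_y,
                              var_test = var_p, alpha = alpha)),
            class = "group_comparison")
}

describe_group <- function(x, style, digits = 3) {
  if (style == "mean_sem") {
    sprintf("%s ± %s", signif(mean(x), digits),
            signif(stats::sd(x) / sqrt(length(x)), digits))
  } else {
    sprintf("%s (%s–%s)", signif(stats::median(x), digits),
            signif(min(x), digits), signif(max(x), digits))
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s: %s test, p = %.4g\n",
              x$summary_x, x$summary_y, x$test, x$p))
  cat(sprintf("  trace: Shapiro p %.3g / %.3g; variance-test p %s\n",
              x$trace$shapiro_x, x$trace$shapiro_y,
              ifelse(is.na(x$trace$var_test), "-",
                     signif(x$trace$var_test, 3))))
  invisible(x)
}

#' ANCOVA on a fit-derived parameter
#'
#' Linear model `response ~ group + covariates`, the analysis used for
#' parameters that come out of linear or exponential PV fits: the co-fitted
#' parameters enter as covariates (V0 for Ees; A and the asymptote for the
#' EDPVR stiffness constant). The response is log-transformed when the
#' residual Shapiro-Wilk test fails at alpha = 0.05 and all values are
#' positive; the transformation is recorded.
#'
#' @param data data.frame with one row per animal.
#' @param response name of the fit parameter analyzed.
#' @param covariates names of its co-fitted parameters.
#' @param group name of the group column (two levels, >= 3 animals each).
#' @param alpha residual-normality threshold for the log transform.
#' @return A list of class `ancova_result`: `p_group`, `estimate` (group
#'   effect on the analyzed scale), `transformation` (`"none"` or `"log"`),
#'   `model`.
#' @export
ancova_fit_param <- function(data, response, covariates = character(0),
                             group = "group", alpha = 0.05) {
  stopifnot(response %in% names(data), group %in% names(data),
            all(covariates %in% names(data)))
  tab <- table(data[[group]])
  if (length(tab) != 2 || any(tab < 3))
    stop("ANCOVA needs two groups with >= 3 animals each", call. = FALSE)
  data[[group]] <- factor(data[[group]])
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  if (any(!is.finite(stats::coef(fit))))
    stop("singular ANCOVA design", call. = FALSE)
  transformation <- "none"
  res_p <- tryCatch(stats::shapiro.test(stats::resid(fit))$p.value,
                    error = function(e) 1)
  if (res_p < alpha && all(data[[response]] > 0)) {
    data$.logresp <- log(data[[response]])
    fit <- stats::lm(stats::as.formula(paste(".logresp ~", rhs)), data = data)
    transformation <- "log"
  }
  cf <- summary(fit)$coefficients
  grow <- grep(paste0("^", group), rownames(cf))
  structure(list(response = response, covariates = covariates,
                 p_group = cf[grow, "Pr(>|t|)"],
                 estimate = cf[grow, "Estimate"],
                 transformation = transformation, model = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> %s ~ group + %s: group p = %.4g (estimate %.3g%s)\n",
              x$response,
              if (length(x$covariates)) paste(x$covariates, collapse = " + ")
              else "1",
              x$p_group, x$estimate,
              if (x$transformation == "log") ", log scale" else ""))
  invisible(x)
}

#' Nested mixed model for myocyte-level responses
#'
#' Fits `response ~ group + (1 | animal) + (1 | animal:myocyte)` by REML —
#' a fixed group effect with random intercepts by animal plus a variance
#' component for each myocyte — the appropriate analysis when repeated
#' cell-level measurements are nested in animals. The group-effect p-value
#' uses the Satterthwaite degrees-of-freedom approximation, which keeps the
#' test calibrated at typical animal counts.
#'
#' @param table data.frame with `group`, `animal`, `myocyte` columns and the
#'   response (>= 3 animals per group, >= 2 myocytes per animal).
#' @param response name of the response column.
#' @return A list of class `mixed_model_result`: `estimate`, `se`, `p` for
#'   the group effect, `sd_animal`, `sd_myocyte`, `sd_resid`, `converged`,
#'   `model`.
#' @export
mixed_model_myocytes <- function(table, response = "y") {
  stopifnot(all(c("group", "animal", "myocyte", response) %in% names(table)))
  per_group <- tapply(table$animal, table$group,
                      function(a) length(unique(a)))
  if (length(per_group) < 2 || any(per_group < 3))
    stop("mixed model needs >= 3 animals in each of two groups",
         call. = FALSE)
  per_animal <- tapply(table$myocyte, table$animal,
                       function(m) length(unique(m)))
  if (any(per_animal < 2))
    stop("mixed model needs >= 2 myocytes per animal", call. = FALSE)
  table$group <- factor(table$group)
  fml <- stats::as.formula(
    paste(response, "~ group + (1 | animal) + (1 | animal:myocyte)"))
  fit <- lmerTest::lmer(fml, data = table, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged && !any(grepl("failed to converge", msgs)))
    converged <- TRUE   # singular fits are usable, report them converged
  cf <- stats::coef(summary(fit))
  grow <- grep("^group", rownames(cf))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(which) {
    i <- match(which, vc$grp)
    if (is.na(i)) 0 else vc$sdcor[i]
  }
  structure(list(estimate = cf[grow, "Estimate"],
                 se = cf[grow, "Std. Error"],
                 p = cf[grow, "Pr(>|t|)"],
                 sd_animal = sd_of("animal"),
                 sd_myocyte = sd_of("animal:myocyte"),
                 sd_resid = sd_of("Residual"),
                 converged = converged, model = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> group effect %.3g (SE %.3g), p = %.4g\n",
              x$estimate, x$se, x$p))
  cat(sprintf("  SD: animal %.3g, myocyte %.3g, residual %.3g%s\n",
              x$sd_animal, x$sd_myocyte, x$sd_resid,
              if (x$converged) "" else "  [non-converged]"))
  invisible(x)
}

#' Render a study-style hemodynamic comparison table
#'
#' Runs [two_group_compare()] on every requested variable of a per-animal
#' results table and renders a report shaped like a hemodynamic summary
#' table: one row per variable, formatted group descriptives, the test used
#' and its p-value, with significant rows (p < 0.05) marked. Decimal rules
#' are deterministic: pressures and volumes as integers, elastances and
#' coupling to one or two decimals, the EDPVR stiffness constant to three.
#'
#' @param data per-animal data.frame with a group column.
#' @param variables variable names (rows, in display order); defaults to all
#'   numeric columns.
#' @param group name of the group column (two levels).
#' @param digits named per-variable decimal counts overriding the defaults.
#' @param alpha significance threshold for the marker column.
#' @return A data.frame of class `study_report` with columns `variable`,
#'   one per group, `test`, `p`, `signif`; numeric p and per-group numeric
#'   means are kept as attributes for round-tripping.
#' @export
summary_table <- function(data, variables = NULL, group = "group",
                          digits = NULL, alpha = 0.05) {
  stopifnot(group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("report needs exactly two groups", call. = FALSE)
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  if (!length(variables)) stop("no variables to report", call. = FALSE)
  default_digits <- c(Pmax = 0, EDP = 0, EDV = 0, PA_sys = 0, PA_mean = 0,
                      PA_dia = 0, dPdt_max = 0, EF = 0, PRSW = 0, tau = 0,
                      Ea = 1, Ees = 1, VVC = 1, CO = 1, PVR = 1, beta = 3)
  rows <- lapply(variables, function(v) {
    x <- data[[v]][g == levels(g)[1]]
    y <- data[[v]][g == levels(g)[2]]
    cmp <- two_group_compare(x, y)
    d <- if (!is.null(digits) && v %in% names(digits)) digits[[v]]
         else if (v %in% names(default_digits)) default_digits[[v]] else 2
    fmt <- function(z) format_descriptive(z, cmp$style, d)
    data.frame(variable = v, g1 = fmt(x), g2 = fmt(y), test = cmp$test,
               p = formatC(cmp$p, digits = 3, format = "g"),
               signif = ifelse(cmp$p < alpha, "*", ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- levels(g)
  class(out) <- c("study_report", "data.frame")
  out
}

format_descriptive <- function(x, style, d) {
  f <- function(z) formatC(z, format = "f", digits = d)
  if (style == "mean_sem") {
    sprintf("%s ± %s", f(mean(x)), f(stats::sd(x) / sqrt(length(x))))
  } else {
    sprintf("%s (%s–%s)", f(stats::median(x)), f(min(x)), f(max(x)))
  }
}

#' Write / read a rendered study report as tab-separated text
#'
#' The rendered table round-trips: reading the file back recovers every cell
#' bit-exactly at the printed precision.
#'
#' @param report a [summary_table()] result.
#' @param path output path (TSV).
#' @return `path` (write) or the parsed data.frame (read).
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
}
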