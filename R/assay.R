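# Antioxidant assay analysis: percent radical scavenging, four-parameter
# logistic (4PL) dose-response fitting with analytic IC50, FRAP
# Trolox-equivalent calibration, and one-way ANOVA with Tukey HSD.

#' Percent radical-scavenging activity from absorbances
#'
#' `100 * (a_control - a_sample) / a_control`: the fractional loss of
#' radical absorbance caused by the test compound, as a percentage. The
#' control is the radical solution without compound.
#'
#' @param a_control,a_sample Absorbance values (vectorised; recycled).
#' @return Percent activity.
#' @examples
#' percent_activity(0.800, 0.200) # 75
#' @export
percent_activity <- function(a_control, a_sample) {
  if (any(a_control <= 0)) {
    abort("Control absorbance must be positive.")
  }
  100 * (a_control - a_sample) / a_control
}

four_pl_response <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

four_pl_starts <- function(conc, act) {
  a0 <- mean(act[conc == min(conc)])
  d0 <- mean(act[conc == max(conc)])
  # log-linear mid-segment: logit of the scaled response against log(conc)
  lo <- min(a0, d0) - 1; hi <- max(a0, d0) + 1
  mid <- act > lo + 0.05 * (hi - lo) & act < hi - 0.05 * (hi - lo)
  b0 <- 1; c0 <- exp(mean(log(range(conc))))
  if (sum(mid) >= 3) {
    u <- log((act[mid] - lo) / (hi - act[mid]))
    fit <- tryCatch(lm(u ~ log(conc[mid])), error = function(e) NULL)
    if (!is.null(fit) && is.finite(coef(fit)[2]) && coef(fit)[2] != 0) {
      sl <- unname(coef(fit)[2]); ic <- unname(coef(fit)[1])
      b0 <- abs(sl)
      c0 <- exp(-ic / sl)
    }
  }
  if (a0 > d0) b0 <- -abs(b0)  # decreasing curves
  list(a = a0, d = d0, b = max(min(abs(b0), 15), 0.2) * sign(b0 + (b0 == 0)),
    c = min(max(c0, min(conc) * 0.02), max(conc) * 50))
}

fit_four_pl_once <- function(conc, act, start, lower, upper) {
  df <- data.frame(x = conc, y = act)
  tryCatch(
    minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x / c)^b)` to pooled
#' replicate points: `a` is the response at vanishing concentration, `d`
#' the plateau at saturating concentration, `c` the inflection
#' concentration and `b` the Hill-type slope. Initial values are
#' self-started from the data range and a log-linear fit to the
#' mid-segment; the fit restarts from five deterministic initialisations
#' with `b` bounded to `[0.1, 20]` in magnitude and `c` to the observed
#' concentration range widened by a factor 100 either side.
#'
#' The IC50 is the 50%-activity crossing of the fitted curve (see
#' [estimate_ic50()]). When a `replicate` column is present, `ic50_sd` is
#' the standard deviation over per-replicate refits.
#'
#' @param data A data frame with columns `concentration` (positive) and
#'   `activity` (percent), optionally `replicate` and `compound` --
#'   e.g. from [gen_dose_response()].
#' @return An object of class `four_pl_fit` with components `coefficients`
#'   (named `a`, `b`, `c`, `d`), `ic50`, `ic50_sd`, `r_squared`, `data`,
#'   `compound`, `n_obs`. Supports [coef()], [predict()], [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_four_pl <- function(data) {
  stopifnot(all(c("concentration", "activity") %in% names(data)))
  conc <- data$concentration; act <- data$activity
  if (any(conc <= 0)) abort("Concentrations must be strictly positive.")
  if (length(unique(conc)) < 4) {
    abort("At least 4 distinct concentrations are required for a 4PL fit.")
  }
  if (diff(range(act)) < 1) {
    abort("Degenerate dose-response data: activity range below 1% activity.")
  }
  s0 <- four_pl_starts(conc, act)
  increasing <- s0$a <= s0$d
  lower <- c(a = -Inf, b = if (increasing) 0.1 else -20,
    c = min(conc) * 0.01, d = -Inf)
  upper <- c(a = Inf, b = if (increasing) 20 else -0.1,
    c = max(conc) * 100, d = Inf)
  gm <- exp(mean(log(conc)))
  starts <- list(
    s0,
    list(a = s0$a, d = s0$d, b = if (increasing) 1 else -1, c = gm),
    list(a = s0$a, d = s0$d, b = if (increasing) 2 else -2, c = median(conc)),
    list(a = s0$a, d = s0$d, b = if (increasing) 0.5 else -0.5, c = gm),
    list(a = min(act), d = max(act), b = if (increasing) 1.3 else -1.3, c = s0$c)
  )
  best <- NULL
  for (st in starts) {
    st$c <- min(max(st$c, lower["c"]), upper["c"])
    fit <- fit_four_pl_once(conc, act, st[c("a", "b", "c", "d")], lower, upper)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Four-parameter logistic fit failed to converge from all initialisations.")
  }
  cf <- coef(best$fit)[c("a", "b", "c", "d")]
  r2 <- 1 - best$rss / sum((act - mean(act))^2)
  ic50 <- tryCatch(estimate_ic50(cf), error = function(e) NA_real_)

  ic50_sd <- NA_real_
  replicate_ic50 <- NULL
  if ("replicate" %in% names(data) && dplyr::n_distinct(data$replicate) >= 2) {
    replicate_ic50 <- vapply(unique(data$replicate), function(r) {
      sub <- data[data$replicate == r, ]
      f <- tryCatch(fit_four_pl(sub[setdiff(names(sub), "replicate")]),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$ic50
    }, double(1))
    if (sum(!is.na(replicate_ic50)) >= 2) {
      ic50_sd <- sd(replicate_ic50, na.rm = TRUE)
    }
  }
  structure(
    list(
      coefficients = cf, ic50 = ic50, ic50_sd = ic50_sd,
      replicate_ic50 = replicate_ic50, r_squared = r2,
      data = tibble::as_tibble(data), n_obs = length(act),
      compound = if ("compound" %in% names(data)) data$compound[1] else NA_character_,
      fit = best$fit
    ),
    class = "four_pl_fit"
  )
}

#' @export
coef.four_pl_fit <- function(object, ...) object$coefficients

#' @export
predict.four_pl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else {
    if (is.data.frame(newdata)) newdata$concentration else as.numeric(newdata)
  }
  cf <- object$coefficients
  unname(four_pl_response(x, cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]]))
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("<four_pl_fit>", if (!is.na(x$compound)) x$compound else "", "\n")
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f uM, d = %.3f\n",
    cf["a"], cf["b"], cf["c"], cf["d"]))
  cat(sprintf("  IC50 = %.3f uM%s, r^2 = %.4f (n = %d)\n", x$ic50,
    if (!is.na(x$ic50_sd)) sprintf(" +/- %.3f", x$ic50_sd) else "",
    x$r_squared, x$n_obs))
  invisible(x)
}

#' @export
tidy.four_pl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "d"),
    description = c("lower asymptote (%)", "slope", "inflection (uM)",
      "upper asymptote (%)"),
    estimate = unname(x$coefficients[c("a", "b", "c", "d")])
  )
}

#' @export
glance.four_pl_fit <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, ic50 = x$ic50, ic50_sd = x$ic50_sd,
    r_squared = x$r_squared, n_obs = x$n_obs
  )
}

#' IC50 from a fitted four-parameter logistic curve
#'
#' Solves `y(x) = level` analytically:
#' `x = c * ((a - d) / (level - d) - 1)^(1/b)`. With asymptotes 0 and 100
#' and `level = 50` this coincides with the inflection concentration `c`.
#'
#' @param fit A `four_pl_fit`, or a named numeric vector with elements
#'   `a`, `b`, `c`, `d`.
#' @param level Response level to cross (default 50, i.e. IC50).
#' @return Concentration at the crossing (same units as `c`).
#' @export
estimate_ic50 <- function(fit, level = 50) {
  cf <- if (inherits(fit, "four_pl_fit")) fit$coefficients else fit
  stopifnot(all(c("a", "b", "c", "d") %in% names(cf)))
  a <- unname(cf["a"]); b <- unname(cf["b"])
  cc <- unname(cf["c"]); d <- unname(cf["d"])
  if (level <= min(a, d) || level >= max(a, d)) {
    abort(paste0("The fitted curve does not cross ", level,
      "% activity (asymptotes ", round(min(a, d), 2), " and ",
      round(max(a, d), 2), ")."))
  }
  ratio <- (a - d) / (level - d) - 1
  if (ratio <= 0) {
    abort("No admissible crossing: (a - d)/(level - d) - 1 must be positive.")
  }
  cc * ratio^(1 / b)
}

#' FRAP Trolox-equivalent antioxidant capacity
#'
#' Fits an ordinary least-squares calibration line through Trolox standards
#' and inverts it for the sample: the Trolox-equivalent concentration is
#' `(sample_abs - intercept) / slope`, normalised by `mass_factor` (grams
#' of sample per reaction) to micromol TE per gram.
#'
#' @param standards A data frame with columns `concentration` (micromolar
#'   Trolox) and `absorbance`, at least 3 rows.
#' @param sample_abs Sample absorbance(s).
#' @param mass_factor Grams of sample per reaction (explicit because the
#'   per-gram conversion depends on the assay's mass/dilution scheme).
#' @return An object of class `frap_result`: list with `te_per_gram`
#'   (numeric, per sample), `slope`, `intercept`, `r_squared`,
#'   `n_standards`. [glance()] gives a one-row summary.
#' @export
frap_trolox_equivalents <- function(standards, sample_abs, mass_factor = 1) {
  stopifnot(all(c("concentration", "absorbance") %in% names(standards)))
  if (nrow(standards) < 3) abort("At least 3 Trolox standards are required.")
  if (mass_factor <= 0) abort("mass_factor must be positive.")
  if (dplyr::n_distinct(standards$concentration) < 2) {
    abort("Singular calibration: standards span a single concentration.")
  }
  fit <- lm(absorbance ~ concentration, data = standards)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope == 0) abort("Calibration slope is zero.")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  te <- (sample_abs - intercept) / slope / mass_factor
  structure(
    list(te_per_gram = te, slope = slope, intercept = intercept,
      r_squared = r2, n_standards = nrow(standards)),
    class = "frap_result"
  )
}

#' @export
print.frap_result <- function(x, ...) {
  cat("<frap_result> calibration: abs =", signif(x$slope, 4), "* conc +",
    signif(x$intercept, 4), sprintf("(r^2 = %.4f, n = %d)\n", x$r_squared,
      x$n_standards))
  cat("  TE:", paste(signif(x$te_per_gram, 5), collapse = ", "),
    "umol TE/g\n")
  invisible(x)
}

#' @export
glance.frap_result <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_standards = x$n_standards,
    te_per_gram = if (length(x$te_per_gram) == 1) x$te_per_gram else NA_real_
  )
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Standard one-way analysis of variance across groups followed by Tukey's
#' honestly-significant-difference test on all pairs. Pairs are flagged at
#' the conventional p < 0.05 and p < 0.001 levels.
#'
#' @param data A data frame with a grouping column and a value column, or a
#'   named list of numeric vectors.
#' @param group,value Column names (when `data` is a data frame).
#' @return An object of class `anova_tukey`: list with `overall` (one-row
#'   tibble: `f_statistic`, `df_between`, `df_within`, `p_value`) and
#'   `pairwise` (tibble: `contrast`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significance`).
#' @export
anova_tukey <- function(data, group = "group", value = "value") {
  if (is.list(data) && !is.data.frame(data)) {
    data <- purrr::imap_dfr(data, function(v, nm) {
      tibble::tibble(group = nm, value = as.numeric(v))
    })
    group <- "group"; value <- "value"
  }
  df <- data.frame(g = factor(data[[group]]), y = as.numeric(data[[value]]))
  if (nlevels(df$g) < 2) abort("ANOVA requires at least 2 groups.")
  sizes <- table(df$g)
  if (any(sizes < 2)) abort("Each group needs at least 2 replicates.")
  wvar <- tapply(df$y, df$g, stats::var)
  if (all(wvar == 0)) {
    abort("Zero within-group variance in all groups: ANOVA undefined.")
  }
  fit <- aov(y ~ g, data = df)
  sm <- summary(fit)[[1]]
  overall <- tibble::tibble(
    f_statistic = sm$`F value`[1],
    df_between = sm$Df[1], df_within = sm$Df[2],
    p_value = sm$`Pr(>F)`[1]
  )
  tk <- TukeyHSD(fit)$g
  pairwise <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significance = dplyr::case_when(
      tk[, "p adj"] < 0.001 ~ "***",
      tk[, "p adj"] < 0.05 ~ "*",
      TRUE ~ ""
    )
  )
  structure(list(overall = overall, pairwise = pairwise), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<anova_tukey> F(%d, %d) = %.3f, p = %.4g\n",
    o$df_between, o$df_within, o$f_statistic, o$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' @export
glance.anova_tukey <- function(x, ...) x$overall
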