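# Agreement, repeatability, normative-range and covariate-model statistics.

#' Bland-Altman agreement
#'
#' Bias is the mean paired difference x - y; limits of agreement are
#' bias +/- 1.96 SD of the differences.
#'
#' @param x,y Paired measurements (equal length >= 2).
#' @return An object of class `srcse_bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("insufficient data: need paired vectors of length >= 2",
         call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  structure(list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, sd_diff = s,
                 n = length(d)),
            class = "srcse_bland_altman")
}

#' Within-subject scan-rescan coefficient of variation
#'
#' CV = 100 * (SD of paired differences / sqrt(2)) / grand mean, the
#' within-subject formulation for scan-rescan pairs of a positive-mean
#' metric.
#'
#' @param m1,m2 Paired scan and rescan values.
#' @return An object of class `srcse_cv`: `cv` (percent), `n_pairs`.
#' @export
repeatability_cv <- function(m1, m2) {
  if (length(m1) != length(m2) || length(m1) < 2L)
    stop("insufficient data: need >= 2 pairs", call. = FALSE)
  gm <- mean(c(m1, m2))
  if (gm <= 0) stop("grand mean must be positive", call. = FALSE)
  cv <- 100 * (stats::sd(m1 - m2) / sqrt(2)) / gm
  structure(list(cv = cv, n_pairs = length(m1)), class = "srcse_cv")
}

#' Normative table rows by group
#'
#' Mean, SD (n-1 denominator) and linear-interpolation 5th / 95th
#' percentiles of a metric, per group (typically sex).
#'
#' @param values Metric values.
#' @param group Grouping factor of the same length.
#' @param warn_n Warn when a group has fewer values than this (percentile
#'   stability).
#' @return Data.frame with `group`, `n`, `mean`, `sd`, `p5`, `p95`.
#' @export
normative_table <- function(values, group, warn_n = 20L) {
  group <- as.factor(group)
  if (any(tabulate(group) == 0L) || length(values) == 0L)
    stop("insufficient data: empty group", call. = FALSE)
  rows <- lapply(levels(group), function(g) {
    v <- values[group == g]
    if (length(v) == 0L) stop("insufficient data: empty group ", g,
                              call. = FALSE)
    if (length(v) < warn_n)
      warning("group ", g, " has fewer than ", warn_n,
              " values; percentiles unstable", call. = FALSE)
    q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               p5 = q[1L], p95 = q[2L])
  })
  do.call(rbind, rows)
}

#' Multivariable regression of a metric on age and sex
#'
#' Ordinary least squares with intercept; reports coefficients with
#' classical standard errors, 95% confidence intervals, standardized
#' coefficients (from z-scored outcome and regressors), two-sided t-test
#' p-values, and adjusted R-squared. BMI is deliberately not part of this
#' model (collinearity with the fat metrics); see
#' [group_compare_bonferroni()] for the BMI analysis.
#'
#' @param y Metric values.
#' @param age Age in years.
#' @param male 0/1 male indicator.
#' @return An object of class `srcse_regression`: `coefficients` data.frame
#'   (term, beta, se, ci_low, ci_high, std_beta, p), `adj_r_squared`, `n`,
#'   and the `lm` fit.
#' @export
fit_covariate_model <- function(y, age, male) {
  n <- length(y)
  if (n <= 3L) stop("need more than 3 observations", call. = FALSE)
  X <- cbind(age = age, male = male)
  if (qr(cbind(1, X))$rank < 3L)
    stop("rank error: design is rank deficient", call. = FALSE)
  fit <- stats::lm(y ~ age + male)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  std_fit <- stats::lm(zs(y) ~ zs(age) + zs(male))
  co <- data.frame(
    term = c("intercept", "age", "male"),
    beta = unname(stats::coef(fit)),
    se = unname(sm$coefficients[, "Std. Error"]),
    ci_low = unname(ci[, 1L]),
    ci_high = unname(ci[, 2L]),
    std_beta = c(NA_real_, unname(stats::coef(std_fit)[2:3])),
    p = unname(sm$coefficients[, "Pr(>|t|)"]))
  structure(list(coefficients = co, adj_r_squared = sm$adj.r.squared,
                 n = n, fit = fit),
            class = "srcse_regression")
}

#' Two-way fixed-factor comparison with Bonferroni correction
#'
#' Fits a general linear model of the metric on sex and an overweight
#' indicator (BMI >= 25 by default) as fixed factors and reports the
#' factor-contrast p-values multiplied by the number of contrasts (capped
#' at 1).
#'
#' @param y Metric values.
#' @param sex Factor or character ("male"/"female").
#' @param bmi BMI in kg/m^2, or a logical overweight indicator.
#' @param bmi_cut Threshold applied when `bmi` is numeric.
#' @param n_contrasts Bonferroni multiplier; defaults to the number of
#'   factor contrasts tested in this model (2). Set to the full family size
#'   when the model is one of several metrics tested together.
#' @return Data.frame with `term`, `estimate`, `p_raw`, `p_adjusted`.
#' @export
group_compare_bonferroni <- function(y, sex, bmi, bmi_cut = 25,
                                     n_contrasts = NULL) {
  sex <- droplevels(as.factor(sex))
  over <- if (is.logical(bmi)) bmi else bmi >= bmi_cut
  over <- factor(over, levels = c(FALSE, TRUE),
                 labels = c("normal", "overweight"))
  if (nlevels(sex) < 2L || any(table(sex, over) == 0L))
    stop("design error: empty sex x BMI cell", call. = FALSE)
  fit <- stats::lm(y ~ sex + over)
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1L]
  if (is.null(n_contrasts)) n_contrasts <- length(terms)
  data.frame(term = terms,
             estimate = unname(sm[-1L, "Estimate"]),
             p_raw = unname(sm[-1L, "Pr(>|t|)"]),
             p_adjusted = pmin(unname(sm[-1L, "Pr(>|t|)"]) * n_contrasts, 1))
}
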