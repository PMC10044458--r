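#' Classify a coefficient of variation
#'
#' Standard agronomic CV classes: low for CV < 12%, medium for
#' 12% <= CV <= 24% (both boundaries inclusive to medium), high above 24%.
#'
#' @param cv_pct Coefficient of variation in percent (>= 0).
#' @return `"low"`, `"medium"` or `"high"` (vectorized).
#' @export
classify_cv <- function(cv_pct) {
  if (any(cv_pct < 0)) stop("cv_pct must be >= 0")
  ifelse(cv_pct < 12, "low", ifelse(cv_pct <= 24, "medium", "high"))
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS test against a normal distribution whose mean and
#' standard deviation are estimated from the data, with the Lilliefors
#' correction for the estimated parameters (the uncorrected KS p-value
#' would be anti-conservative). A zero-variance sample has no defined
#' test; it is flagged and reported non-normal.
#'
#' @param values Numeric vector, n >= 5.
#' @param alpha Significance level (default 0.01); the sample is called
#'   normal when `p > alpha`.
#' @return List with `statistic`, `p_value`, `normal` (logical) and
#'   `degenerate` (TRUE when the sample variance is zero).
#' @export
ks_normality <- function(values, alpha = 0.01) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("need n >= 5 for the normality test")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                normal = FALSE, degenerate = TRUE))
  kt <- nortest::lillie.test(values)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       normal = kt$p.value > alpha, degenerate = FALSE)
}

#' Descriptive statistics of an annual THI sample
#'
#' Mean, median, extremes, sample (n-1) standard deviation, coefficient
#' of variation with its class, bias-corrected sample skewness and excess
#' kurtosis (the convention under which a normal sample scores ~0), and
#' the Lilliefors-corrected KS normality call at the 1% level.
#'
#' @param values Numeric vector, n >= 4.
#' @param year Year label carried into the output (default `NA`).
#' @param alpha Significance level for the normality call.
#' @return One-row data frame with columns `year`, `n`, `mean`, `median`,
#'   `min`, `max`, `sd`, `cv_pct`, `cv_class`, `skewness`,
#'   `kurtosis_excess`, `ks_p`, `normal_at_1pct`.
#' @export
summary_stats <- function(values, year = NA, alpha = 0.01) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) stop("need n >= 4 (kurtosis undefined below that)")
  m <- mean(values)
  s <- stats::sd(values)
  # CV is meaningful for positive-mean quantities (THI always is)
  cv <- if (m > 0) 100 * s / m else NA_real_
  if (s == 0) {
    skew <- 0; kurt <- 0            # degenerate: by convention
    ks <- list(p_value = NA_real_, normal = FALSE)
  } else {
    skew <- e1071::skewness(values, type = 2)
    kurt <- e1071::kurtosis(values, type = 2)
    ks <- if (n >= 5) ks_normality(values, alpha)
          else list(p_value = NA_real_, normal = NA)
  }
  data.frame(year = year, n = n, mean = m, median = stats::median(values),
             min = min(values), max = max(values), sd = s,
             cv_pct = cv,
             cv_class = if (is.na(cv)) NA_character_ else classify_cv(cv),
             skewness = skew, kurtosis_excess = kurt,
             ks_p = ks$p_value, normal_at_1pct = ks$normal,
             stringsAsFactors = FALSE)
}

#' Tukey five-number boxplot summary with outlier screening
#'
#' Quartiles by linear interpolation (quantile type 7), fences at
#' `q1 - 1.5 IQR` and `q3 + 1.5 IQR`, whiskers at the most extreme
#' non-outlying observations, outliers listed explicitly.
#'
#' @param values Numeric vector, n >= 5.
#' @param year Year label carried into the output.
#' @return List of class `boxplot_summary` with `year`, `min_whisker`,
#'   `q1`, `median`, `q3`, `max_whisker`, `outliers`.
#' @export
boxplot_summary <- function(values, year = NA) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("need n >= 5")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inl <- values[values >= lo & values <= hi]
  structure(list(year = year, min_whisker = min(inl), q1 = q[1],
                 median = q[2], q3 = q[3], max_whisker = max(inl),
                 outliers = sort(out)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat("boxplot summary (year ", x$year, "): [",
      format(x$min_whisker), " | ", format(x$q1), " ", format(x$median), " ",
      format(x$q3), " | ", format(x$max_whisker), "], ",
      length(x$outliers), " outlier(s)\n", sep = "")
  invisible(x)
}
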