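# Continuous-outcome validation statistics: Bland-Altman agreement with
# 2-sd limits, two-way mixed average-measures ICC, Ryan-Joiner normality
# screening, gap summaries, Spearman correlation with Fisher-z intervals,
# and ordinary least squares with the study's predictive equation for
# mandibular body length.

#' Bland-Altman agreement of two paired series
#'
#' Differences are `first - second`; the limits of agreement are placed at
#' the mean difference plus/minus `k` sample standard deviations, with
#' `k = 2` by convention here (not 1.96).
#'
#' @param first,second equal-length numeric vectors, n >= 2.
#' @param k limit multiplier (2 by default).
#' @return Object of class `"bland_altman"`: `mean_diff`, `sd`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
bland_altman <- function(first, second, k = 2) {
  if (length(first) != length(second)) stop("series lengths differ")
  n <- length(first)
  if (n < 2) stop("need at least two pairs")
  d <- first - second
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd = s, loa_low = m - k * s,
                 loa_high = m + k * s, k = k, n = n),
            class = "bland_altman")
}

#' Intraclass correlation, two-way mixed, average measures, consistency
#'
#' ICC(3,k): subjects are rows, the k repeated measurements (raters or
#' occasions) are columns. From the two-way decomposition,
#' `ICC = (MS_subject - MS_error) / MS_subject`, with a 95% confidence
#' interval from the F ratio `MS_subject / MS_error` on `(n-1)` and
#' `(n-1)(k-1)` degrees of freedom.
#'
#' @param data numeric matrix, `n >= 3` subjects by `k >= 2` measurements,
#'   no missing cells.
#' @param conf confidence level (0.95).
#' @return Object of class `"icc_result"`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k_raters`, `model`.
#' @export
icc_two_way_mixed_average <- function(data, conf = 0.95) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells are not supported")
  n <- nrow(data); k <- ncol(data)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 measurements")
  grand <- mean(data)
  row_m <- rowMeans(data); col_m <- colMeans(data)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0)
    stop("zero between-subject variance: ICC undefined for this design")
  icc <- (ms_rows - ms_err) / ms_rows
  alpha <- 1 - conf
  f <- ms_rows / ms_err
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  structure(list(icc = icc, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu,
                 n_subjects = n, k_raters = k,
                 model = "two-way mixed, average measures, consistency"),
            class = "icc_result")
}

# Ryan-Joiner critical-value approximation polynomials in 1/sqrt(n), 1/n
# at alpha = 0.10, 0.05, 0.01
.rj_critical <- function(n, alpha = 0.05) {
  co <- switch(as.character(alpha),
    "0.1"  = c(1.0071, -0.1371, -0.3682, 0.7780),
    "0.05" = c(1.0063, -0.1288, -0.6118, 1.3505),
    "0.01" = c(0.9963, -0.0211, -1.4106, 3.1791),
    stop("alpha must be one of 0.10, 0.05, 0.01"))
  co[1] + co[2] / sqrt(n) + co[3] / n + co[4] / n^2
}

#' Ryan-Joiner normality test
#'
#' The statistic is the correlation between the ordered sample and the
#' normal scores `qnorm((i - 3/8) / (n + 1/4))`; small values indicate
#' departure from normality. Rejection compares the statistic against the
#' published critical-value approximation at the requested alpha; a custom
#' critical value (e.g. from a Monte-Carlo table) may be supplied instead.
#'
#' @param x numeric vector, n >= 4, not constant.
#' @param alpha 0.10, 0.05 or 0.01 (only used for the shipped critical
#'   curve).
#' @param critical optional critical value overriding the approximation.
#' @return Object of class `"rj_result"`: `statistic`, `n`, `critical`,
#'   `reject` (TRUE when the statistic falls below the critical value).
#' @export
ryan_joiner <- function(x, alpha = 0.05, critical = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("Ryan-Joiner test needs n >= 4")
  if (stats::sd(x) == 0) stop("constant series: normality test undefined")
  scores <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  r <- stats::cor(sort(x), scores)
  cv <- if (is.null(critical)) .rj_critical(n, alpha) else critical
  structure(list(statistic = r, n = n, alpha = alpha, critical = cv,
                 reject = r < cv), class = "rj_result")
}

#' Summary of a Euclidean-gap distribution
#'
#' Mean plus first and third quartiles under the `(n+1)p` order-statistic
#' interpolation convention (type 6), the convention of the statistics
#' package used for the reference analysis; both mean and IQR are reported
#' because gap distributions are typically non-normal. A Ryan-Joiner result
#' is attached when `n >= 4`.
#'
#' @param gaps non-empty numeric vector of per-subject gaps (mm).
#' @param quartile_type quantile algorithm (see [stats::quantile()]); 6 is
#'   the `(n+1)p` convention.
#' @return Object of class `"gap_summary"`: `mean`, `q1`, `q3`, `median`,
#'   `n`, `normality` (an `rj_result` or `NULL`).
#' @export
gap_summary <- function(gaps, quartile_type = 6) {
  gaps <- as.numeric(gaps[!is.na(gaps)])
  if (!length(gaps)) stop("no gaps to summarize")
  q <- stats::quantile(gaps, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  rj <- if (length(gaps) >= 4 && stats::sd(gaps) > 0) ryan_joiner(gaps) else NULL
  structure(list(mean = mean(gaps), q1 = q[1], median = q[2], q3 = q[3],
                 n = length(gaps), normality = rj), class = "gap_summary")
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Rho is computed on average ranks; the interval uses the Fisher z
#' transform with the rank-correlation standard error `1.03 / sqrt(n - 3)`,
#' and the p-value the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y equal-length numeric vectors, n >= 5, not all tied.
#' @param conf confidence level.
#' @return Object of class `"correlation_result"`: `rho`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
spearman_with_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  if (n < 5) stop("need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("all-tied input: correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1.03 / sqrt(n - 3)
  crit <- stats::qnorm(1 - (1 - conf) / 2)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(rho = rho, ci_low = tanh(z - crit * se),
                 ci_high = tanh(z + crit * se), p = p, n = n),
            class = "correlation_result")
}

#' Simple ordinary least squares fit
#'
#' @param x,y numeric vectors, n >= 3, x not constant.
#' @return Object of class `"ols_result"`: `intercept`, `slope`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero x variance: slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  structure(list(intercept = mean(y) - slope * mean(x), slope = slope,
                 n = n), class = "ols_result")
}

#' Predict mandibular body length (Go-Me) from anterior cranial base (SN)
#'
#' Applies the study's predictive equation `Go-Me = 22.65 + 0.5426 * SN`
#' (both lengths in mm); alternative coefficients may be supplied, e.g.
#' from a fresh [ols_fit()].
#'
#' @param sn positive SN length(s), mm.
#' @param intercept,slope regression coefficients (study defaults).
#' @return Predicted Go-Me length(s), mm.
#' @export
predict_gome_from_sn <- function(sn, intercept = 22.65, slope = 0.5426) {
  if (any(sn <= 0)) stop("SN length must be positive")
  intercept + slope * sn
}

#' Per-measurement agreement table (Bland-Altman + ICC)
#'
#' Builds the repeatability table for a set of named measurement series
#' digitized twice: one column per measurement, rows mean / sd / 2sd / ICC.
#'
#' @param first,second data frames or matrices with identical column names,
#'   one row per subject; `first` is the initial digitization, `second` the
#'   repeat.
#' @return A data frame with rows `mean`, `sd`, `2sd`, `ICC` and one column
#'   per measurement.
#' @export
agreement_table <- function(first, second) {
  first <- as.data.frame(first); second <- as.data.frame(second)
  if (!identical(names(first), names(second)))
    stop("measurement names differ between digitizations")
  out <- sapply(names(first), function(nm) {
    ba <- bland_altman(first[[nm]], second[[nm]])
    icc <- tryCatch(
      icc_two_way_mixed_average(cbind(first[[nm]], second[[nm]]))$icc,
      error = function(e) NA_real_)
    c(mean = ba$mean_diff, sd = ba$sd, `2sd` = 2 * ba$sd, ICC = icc)
  })
  as.data.frame(out)
}
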