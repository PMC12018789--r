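#' @title Method agreement between cytometry and literature pollen sizes
#'
#' @description Bland-Altman analysis of paired species sizes (difference of
#'   the two methods against their mean, summarized by the mean difference
#'   and SD-based limit lines), per-family difference summaries, Pearson
#'   correlation and ordinary least squares fits with adjusted R-squared.
#'   The sign convention is cytometry minus literature, so a negative mean
#'   difference means the literature sizes run larger.
#'
#' @name agreement
NULL

#' Bland-Altman agreement of two size measurements
#'
#' @param size_ifc,size_lit paired size vectors (um); alternatively pass a
#'   data frame with columns `size_ifc` and `size_lit` as the first argument
#' @return object of class `ifc_agreement`: `n`, `mean_diff_um`,
#'   `sd_diff_um`, `lines` (zero, mean difference, mean +/- 1 SD and
#'   +/- 2 SD), and the per-record `diffs` and `means`
#' @export
#' @examples
#' ba <- bland_altman(c(20, 30, 40), c(22, 29, 43))
#' ba$mean_diff_um
bland_altman <- function(size_ifc, size_lit = NULL) {
  if (is.data.frame(size_ifc)) {
    size_lit <- size_ifc$size_lit
    size_ifc <- size_ifc$size_ifc
  }
  stopifnot(length(size_ifc) == length(size_lit))
  keep <- !is.na(size_ifc) & !is.na(size_lit)
  x <- size_ifc[keep]; y <- size_lit[keep]
  n <- length(x)
  if (n < 2) stop("at least 2 pairs required")
  diffs <- x - y
  means <- (x + y) / 2
  m <- mean(diffs); s <- sd(diffs)
  lines <- c(zero = 0, mean_diff = m,
             lower_1sd = m - s, upper_1sd = m + s,
             lower_2sd = m - 2 * s, upper_2sd = m + 2 * s)
  structure(list(n = n, mean_diff_um = m, sd_diff_um = s, lines = lines,
                 diffs = diffs, means = means), class = "ifc_agreement")
}

#' @export
print.ifc_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  mean diff: %.2f um, SD of diffs: %.2f um\n",
              x$mean_diff_um, x$sd_diff_um))
  cat(sprintf("  +/-2 SD limits: [%.2f, %.2f] um\n",
              x$lines["lower_2sd"], x$lines["upper_2sd"]))
  invisible(x)
}

#' Per-group mean difference summaries
#'
#' Mean and SD of the paired differences within each group (typically plant
#' family), with counts; groups of size 1 report `NA` SD.
#'
#' @param pairs data frame with columns `size_ifc`, `size_lit` and the
#'   grouping column
#' @param group name of the grouping column (default `"family_label"`)
#' @return data frame `(group, n, mean_diff_um, sd_diff_um)`
#' @export
group_diff_summary <- function(pairs, group = "family_label") {
  stopifnot(all(c("size_ifc", "size_lit", group) %in% names(pairs)))
  d <- pairs$size_ifc - pairs$size_lit
  out <- lapply(split(d, pairs[[group]]), function(v) {
    v <- v[!is.na(v)]
    data.frame(n = length(v), mean_diff_um = mean(v),
               sd_diff_um = if (length(v) > 1) sd(v) else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y numeric vectors, `n >= 3`, nonzero variance
#' @return list with `r`, `p_value`, `n`
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("at least 3 pairs required")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ordinary least-squares fit with adjusted R-squared
#'
#' Fits `y ~ x` (optionally `y ~ log10(x)`, the model form used to relate
#' cytometry sizes to literature sizes) and reports slope, intercept,
#' adjusted R-squared `1 - (1 - r^2)(n - 1)/(n - 2)`, residual degrees of
#' freedom `n - 2` and the slope's two-sided p-value.
#'
#' @param x predictor (e.g. literature size)
#' @param y response (e.g. cytometry size)
#' @param log10_x apply a log10 transform to `x` before fitting
#' @return object of class `ifc_fit`: list with `slope`, `intercept`,
#'   `r2_adj`, `df`, `p_value`, and the underlying `lm` fit
#' @export
ols_fit <- function(x, y, log10_x = FALSE) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("at least 3 pairs required")
  if (log10_x) x <- log10(x)
  if (var(x) == 0) stop("degenerate collinear input")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2_adj = sm$adj.r.squared, df = fit$df.residual,
                 p_value = sm$coefficients[2, 4], fit = fit,
                 log10_x = log10_x),
            class = "ifc_fit")
}

#' @export
print.ifc_fit <- function(x, ...) {
  form <- if (x$log10_x) "y = %.3g x log10(x) + %.3g" else "y = %.3g x + %.3g"
  cat(sprintf(paste0(form, "; adj R2 = %.3f; df = %d; p = %.3g\n"),
              x$slope, x$intercept, x$r2_adj, x$df, x$p_value))
  invisible(x)
}
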