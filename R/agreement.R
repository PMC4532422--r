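#' Substitute below-detection-limit measurements
#'
#' Measurements reported only as "below the limit of detection" are replaced
#' by a fixed fraction of the LOD before summary statistics: LOD/sqrt(2)
#' (default; 10/1.414 = 7.07 for a 10% limit) or LOD/2.  Observed values are
#' untouched, so the substitution is idempotent.
#'
#' @param values Numeric percentages; `NA` marks a below-LOD entry (see
#'   `below`).
#' @param lod Detection limit (> 0), default 10 (the Sanger limit; the
#'   mixture-series empirical limit of 7 can be supplied instead).
#' @param rule `"sqrt2"` (default) or `"half"`.
#' @param below Optional logical vector marking below-LOD entries explicitly;
#'   defaults to `is.na(values)`.
#' @return Numeric vector with substituted values.
#' @examples
#' lod_substitute(c(NA, 45.87), lod = 10)  # 7.07, 45.87
#' @export
lod_substitute <- function(values, lod = 10, rule = c("sqrt2", "half"),
                           below = NULL) {
  rule <- match.arg(rule)
  if (!is.numeric(lod) || lod <= 0) stop("lod must be a positive number")
  if (is.null(below)) below <- is.na(values)
  sub <- if (rule == "sqrt2") lod / sqrt(2) else lod / 2
  values[below] <- sub
  values
}

#' Bland-Altman agreement between two heteroplasmy quantification methods
#'
#' For paired measurements (method A, e.g. Sanger; method B, e.g. NGS) the
#' plot coordinates are the pair mean (abscissa) and the difference B - A
#' (ordinate).  The summary reports the mean difference (fixed bias), the SD
#' of differences, the 95% limits of agreement (mean +/- 1.96 SD), the
#' percentage of pairs inside the limits, a two-sided one-sample t-test of
#' the mean difference against 0, and Pearson's r between the two methods.
#'
#' @param value_a,value_b Paired percentage measurements (equal length >= 2).
#' @return A list of class `agreement_stats`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pct_within`, `bias_t`, `bias_p`, `bias_df`,
#'   `degenerate` (TRUE when differences have zero variance), `pearson_r`,
#'   and `points` (data.frame `mean`, `diff` for plotting).
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
#' ba$mean_diff  # 4/3
#' @export
bland_altman <- function(value_a, value_b) {
  if (length(value_a) != length(value_b)) stop("paired vectors must have equal length")
  keep <- !(is.na(value_a) | is.na(value_b))
  a <- value_a[keep]; b <- value_b[keep]
  n <- length(a)
  if (n < 2L) stop("Bland-Altman needs at least 2 complete pairs")
  d <- b - a
  md <- mean(d)
  sdd <- sd(d)
  loa <- md + c(-1, 1) * 1.96 * sdd
  within <- d >= loa[1] & d <= loa[2]
  bt <- fixed_bias_test(d)
  r <- if (sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
  structure(list(
    n = n, mean_diff = md, sd_diff = sdd,
    loa_low = loa[1], loa_high = loa[2],
    pct_within = 100 * mean(within),
    bias_t = bt$t, bias_p = bt$p, bias_df = bt$df, degenerate = bt$degenerate,
    pearson_r = r,
    points = data.frame(mean = (a + b) / 2, diff = d)
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference (B - A): %.2f (SD %.2f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: [%.2f, %.2f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  pairs within limits: %.1f%%\n", x$pct_within))
  if (isTRUE(x$degenerate)) {
    cat("  fixed-bias t-test: degenerate (zero variance)\n")
  } else {
    cat(sprintf("  fixed-bias t-test: t = %.3f (df %d), p = %.3g\n",
                x$bias_t, x$bias_df, x$bias_p))
  }
  cat(sprintf("  Pearson r: %.3f\n", x$pearson_r))
  invisible(x)
}

#' One-sample t-test of a fixed bias
#'
#' Two-sided test of whether the mean of the paired differences deviates from
#' zero.  With zero variance the statistic is undefined; the result is
#' flagged `degenerate` rather than reported as a spurious p-value.
#'
#' @param differences Numeric vector, length >= 2.
#' @return List with `t`, `df`, `p`, `mean`, `se`, `degenerate`.
#' @export
fixed_bias_test <- function(differences) {
  n <- length(differences)
  if (n < 2L) stop("need at least 2 differences")
  m <- mean(differences)
  s <- sd(differences)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, mean = m,
                se = 0, degenerate = TRUE))
  }
  tt <- t.test(differences, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = m, se = s / sqrt(n), degenerate = FALSE)
}

#' Pearson product-moment correlation with test
#'
#' @param x,y Numeric vectors (length >= 3, non-constant).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("Pearson correlation needs >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired Sanger/NGS measurements from a TSV
#'
#' Columns: `sample`, `pos`, `sanger_pct` (or `NA` when below the Sanger
#' detection limit) and `ngs_pct`.
#'
#' @param path File path.
#' @param lod,rule Passed to [lod_substitute()] for the Sanger column.
#' @return data.frame with columns `sample pos sanger_pct ngs_pct
#'   a_below_lod`, Sanger values substituted.
#' @export
read_pairs_tsv <- function(path, lod = 10, rule = "sqrt2") {
  p <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "n.d."))
  need <- c("sample", "pos", "sanger_pct", "ngs_pct")
  if (!all(need %in% names(p))) stop("pairs TSV needs columns: ",
                                     paste(need, collapse = ", "))
  p$a_below_lod <- is.na(p$sanger_pct)
  p$sanger_pct <- lod_substitute(p$sanger_pct, lod = lod, rule = rule)
  p
}
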