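#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z
#' into the omnibus statistic \eqn{K^2 = Z_{b1}^2 + Z_{b2}^2}, referred to
#' a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric sample, n >= 8.
#' @return list with `k2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("dagostino_pearson: need n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("dagostino_pearson: sample is constant")
  # skewness (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * asinh(Y / alpha)
  # kurtosis (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality-gated two-group comparison
#'
#' Implements the two-group comparison policy used throughout the
#' pipeline: both samples are first checked with the D'Agostino-Pearson
#' omnibus test (alpha 0.05). If both pass, an unpaired two-sided t-test is
#' used (Welch variant when the variance ratio exceeds `var_ratio_welch`);
#' otherwise a two-sided Mann-Whitney U test. Groups smaller than
#' `min_n_gate` skip the gate and go straight to Mann-Whitney (logged), as
#' do constant-valued groups.
#'
#' @param a,b numeric samples.
#' @param alpha_normality gate alpha (default 0.05).
#' @param var_ratio_welch variance ratio above which Welch's t replaces the
#'   pooled t (default 4).
#' @param min_n_gate minimum group size for the normality gate (default 8).
#' @param labels length-2 character vector of group labels.
#' @param metric metric name carried into the result.
#' @param summary_style `"mean_sem"`, `"mean_sd"` or `"median_iqr"`.
#' @return object of class `"group_comparison"`: list with `metric`,
#'   `labels`, `n`, `test_used` (`"t"`, `"welch"`, `"mann_whitney"`),
#'   `statistic`, `p`, `normality_p`, `gate_note`, `summary` (per group,
#'   in `summary_style`).
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, var_ratio_welch = 4,
                           min_n_gate = 8, labels = c("A", "B"),
                           metric = "metric", summary_style = "median_iqr") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("compare_groups: empty group")
  gate_note <- NA_character_
  norm_p <- c(NA_real_, NA_real_)
  constant <- (length(unique(a)) == 1) || (length(unique(b)) == 1)
  if (constant) {
    gate_note <- "constant_group_mann_whitney"
    warning("compare_groups: constant-valued group; falling back to Mann-Whitney")
    normal <- FALSE
  } else if (length(a) < min_n_gate || length(b) < min_n_gate) {
    gate_note <- "n_below_gate_mann_whitney"
    normal <- FALSE
  } else {
    norm_p <- c(dagostino_pearson(a)$p, dagostino_pearson(b)$p)
    normal <- all(norm_p > alpha_normality)
  }
  if (normal) {
    vr <- max(stats::var(a), stats::var(b)) / min(stats::var(a), stats::var(b))
    welch <- is.finite(vr) && vr > var_ratio_welch
    tt <- stats::t.test(a, b, var.equal = !welch)
    test_used <- if (welch) "welch" else "t"
    statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    test_used <- "mann_whitney"
    statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(metric = metric, labels = labels,
                 n = c(length(a), length(b)), test_used = test_used,
                 statistic = statistic, p = p, normality_p = norm_p,
                 gate_note = gate_note,
                 summary = list(summarize_values(a, summary_style),
                                summarize_values(b, summary_style))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s (n = %d, %d), %s, stat %.4g, p = %.4g\n",
              x$metric, x$labels[1], x$labels[2], x$n[1], x$n[2],
              x$test_used, x$statistic, x$p))
  invisible(x)
}

#' Summary statistics in a reporting convention
#'
#' @param values numeric sample, n >= 1.
#' @param style `"mean_sem"`, `"mean_sd"` or `"median_iqr"`; IQR is
#'   Q3 - Q1 with linear-interpolation quantiles.
#' @return list with `style`, `centre`, `spread`, `n`, and a formatted
#'   `label`.
#' @export
summarize_values <- function(values, style = c("mean_sem", "mean_sd", "median_iqr")) {
  style <- match.arg(style)
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) stop("summarize_values: no finite values")
  if (style == "median_iqr") {
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    centre <- qs[2]; spread <- qs[3] - qs[1]
    label <- sprintf("%.3g (%.3g)", centre, spread)
  } else {
    centre <- mean(values)
    sdv <- if (n > 1) stats::sd(values) else 0
    spread <- if (style == "mean_sem") sdv / sqrt(n) else sdv
    label <- sprintf("%.3g ± %.3g", centre, spread)
  }
  list(style = style, centre = centre, spread = spread, n = n, label = label)
}
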