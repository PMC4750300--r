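#' Two-way absolute-agreement intraclass correlation, single measures
#'
#' ICC(A,1): the agreement variant of the two-way single-measure ICC,
#' computed from the mean squares of the two-way layout (subjects x
#' methods). Unlike consistency variants, absolute agreement penalises a
#' systematic offset between methods, which is exactly the bias a
#' projection-based length measurement introduces; Pearson correlation of
#' the same data would not see it.
#'
#' For `n` subjects and `k` methods with row mean squares `MSR`, column
#' mean squares `MSC` and residual `MSE`:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#'
#' @param a,b Paired measurement vectors (method A and method B, aligned
#'   by subject), or `a` alone as an `n x k` matrix.
#' @return The ICC value. If the layout has zero total variance the ICC is
#'   defined as 1 with a warning.
#' @export
#' @examples
#' icc_absolute_agreement(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
icc_absolute_agreement <- function(a, b = NULL) {
  m <- if (is.null(b)) as.matrix(a) else cbind(a, b)
  if (any(!is.finite(m))) stop("non-finite values in ICC input", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("ICC needs at least 2 subjects and 2 methods", call. = FALSE)
  }
  grand <- mean(m)
  sst <- sum((m - grand)^2)
  if (sst < .Machine$double.eps * n * k) {
    warning("zero total variance; ICC defined as 1")
    return(1)
  }
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sst - k * sum((row_means - grand)^2) - n * sum((col_means - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Landis-Koch agreement band for an ICC / kappa value
#'
#' Bands: <=0.2 slight, (0.2, 0.4] fair, (0.4, 0.6] moderate,
#' (0.6, 0.8] substantial, >0.8 almost perfect. Boundaries fall in the
#' lower band, matching the strict inequalities of the conventional
#' wording ("<0.2 = slight; >0.2-0.4 = fair; ...").
#'
#' @param icc Finite ICC (or kappa) value(s).
#' @return Character vector of band labels.
#' @export
#' @examples
#' landis_koch_label(c(0.74, 0.91)) # "substantial", "almost perfect"
landis_koch_label <- function(icc) {
  if (any(!is.finite(icc))) stop("ICC must be finite", call. = FALSE)
  bands <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  # left-open intervals: exact boundary values fall in the lower band
  idx <- findInterval(icc, c(0.2, 0.4, 0.6, 0.8), left.open = TRUE) + 1L
  bands[idx]
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same subjects by two methods, computes
#' the per-subject differences `d = a - b`, the bias (mean difference),
#' the sample SD of the differences and the 95% limits of agreement
#' `bias +/- loa_mult * sd` (default multiplier 1.96). The per-subject
#' `(mean, difference)` pairs are kept for plotting.
#'
#' @param a,b Paired measurement vectors (um), n >= 2.
#' @param loa_mult Limits-of-agreement multiplier (default 1.96, the 95%
#'   interval).
#' @param ids Optional subject identifiers.
#' @return An object of class `bland_altman`: list with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `loa_mult`, `n` and a `data` tibble
#'   (`cilium_id`, `mean`, `diff`).
#' @export
#' @examples
#' bland_altman(c(3.0, 3.1, 2.9), c(2.9, 3.3, 2.8))
bland_altman <- function(a, b, loa_mult = 1.96, ids = NULL) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite values", call. = FALSE)
  }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      bias = bias, sd = s,
      loa_low = bias - loa_mult * s, loa_high = bias + loa_mult * s,
      loa_mult = loa_mult, n = length(d),
      data = tibble::tibble(
        cilium_id = ids %||% as.character(seq_along(d)),
        mean = (a + b) / 2, diff = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.3f um (SD %.3f), %g%% LoA [%.3f, %.3f]\n",
    x$n, x$bias, x$sd, 100 * (2 * stats::pnorm(x$loa_mult) - 1),
    x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd = x$sd,
    loa_low = x$loa_low, loa_high = x$loa_high,
    loa_mult = x$loa_mult, n = x$n
  )
}

#' Independent two-sample t-test for cilium lengths
#'
#' Student's pooled-variance two-sided t-test (Welch's correction behind
#' `var_equal = FALSE`), with group summaries formatted as `mean +/- SD`.
#'
#' @param group1,group2 Length vectors (um), each n >= 2.
#' @param var_equal Pool variances (default TRUE, Student's test).
#' @return A tibble: `t`, `df`, `p_value`, `mean1`, `sd1`, `mean2`, `sd2`,
#'   `label1`, `label2`.
#' @export
#' @examples
#' ttest_independent(c(3.3, 3.1, 3.5), c(2.2, 2.5, 2.4))
ttest_independent <- function(group1, group2, var_equal = TRUE) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(group1) == 0 && stats::var(group2) == 0) {
    if (isTRUE(all.equal(mean(group1), mean(group2)))) {
      # identical constant groups: no evidence of a difference
      ht <- list(statistic = c(t = 0), parameter = c(df = length(group1) +
        length(group2) - 2), p.value = 1)
    } else {
      stop("zero pooled variance with unequal means", call. = FALSE)
    }
  } else {
    ht <- stats::t.test(group1, group2, var.equal = var_equal)
  }
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean1 = mean(group1), sd1 = stats::sd(group1),
    mean2 = mean(group2), sd2 = stats::sd(group2),
    label1 = fmt(group1), label2 = fmt(group2)
  )
}

#' Agreement between two measurement methods
#'
#' Pairs per-cilium lengths of two methods from a long measurement table
#' and computes the full agreement summary: ICC(A,1) with its Landis-Koch
#' band and the Bland-Altman statistics.
#'
#' @param measurements Tibble with `cilium_id`, `method`, `length_um`
#'   (averaged over replicates, e.g. from [average_replicates()]).
#' @param method_a,method_b Method names to compare (difference is
#'   `method_a - method_b`).
#' @param loa_mult Limits-of-agreement multiplier.
#' @return An object of class `cilia_agreement`: `icc`, `icc_label`,
#'   `ba` (a [bland_altman()] object), `method_a`, `method_b`, `n`.
#' @export
method_agreement <- function(measurements, method_a, method_b,
                             loa_mult = 1.96) {
  m <- tibble::as_tibble(measurements)
  wide <- tidyr::pivot_wider(
    dplyr::filter(m, .data$method %in% c(method_a, method_b)),
    id_cols = "cilium_id", names_from = "method", values_from = "length_um"
  )
  if (!all(c(method_a, method_b) %in% names(wide))) {
    stop("both methods must be present in `measurements`", call. = FALSE)
  }
  wide <- tidyr::drop_na(wide, dplyr::all_of(c(method_a, method_b)))
  if (nrow(wide) < 2L) stop("need n >= 2 paired cilia", call. = FALSE)
  a <- wide[[method_a]]
  b <- wide[[method_b]]
  icc <- icc_absolute_agreement(a, b)
  structure(
    list(
      icc = icc, icc_label = landis_koch_label(icc),
      ba = bland_altman(a, b, loa_mult = loa_mult, ids = wide$cilium_id),
      method_a = method_a, method_b = method_b, n = nrow(wide)
    ),
    class = "cilia_agreement"
  )
}

#' @export
print.cilia_agreement <- function(x, ...) {
  cat(sprintf(
    "%s vs %s (n = %d): ICC = %.3f (%s); bias %.3f um, LoA [%.3f, %.3f]\n",
    x$method_a, x$method_b, x$n, x$icc, x$icc_label,
    x$ba$bias, x$ba$loa_low, x$ba$loa_high
  ))
  invisible(x)
}

#' @method tidy cilia_agreement
#' @export
tidy.cilia_agreement <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      method_a = x$method_a, method_b = x$method_b,
      icc = x$icc, icc_label = x$icc_label
    ),
    tidy(x$ba)
  )
}

#' @method glance cilia_agreement
#' @export
glance.cilia_agreement <- function(x, ...) tidy(x)
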