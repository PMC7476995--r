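#' Build a 12 x 12 confusion matrix
#'
#' Rows are truth, columns are predictions, both in fixed [cell_classes()]
#' order.
#'
#' @param truth,predicted character vectors of class labels.
#' @param classes class order (default the 12 cell classes).
#' @return integer matrix with dimnames.
#' @export
confusion_matrix <- function(truth, predicted, classes = cell_classes()) {
  stopifnot(length(truth) == length(predicted))
  as.matrix(table(factor(truth, levels = classes),
                  factor(predicted, levels = classes)))
}

#' Per-class and overall confusion-matrix metrics
#'
#' One-vs-rest accuracy, sensitivity and specificity per class, the overall
#' accuracy (trace / total), and its binomial confidence interval.  Classes
#' with an empty truth row get a flagged undefined sensitivity rather than
#' a division error.  All metrics are reported in percent.
#'
#' @param cm square count matrix, rows = truth, columns = predicted.
#' @param alpha significance level for the overall-accuracy CI.
#' @param ci_method `"normal"` or `"wilson"` (see [proportion_ci()]).
#' @return list with `per_class` (data.frame: class, accuracy, sensitivity,
#'   specificity), `overall_accuracy`, `overall_ci` (length-2), `n`.
#' @export
class_metrics <- function(cm, alpha = 0.05, ci_method = "normal") {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  if (n == 0) stop("class_metrics() needs a non-empty confusion matrix")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    data.frame(
      class = classes[i],
      accuracy = 100 * (tp + tn) / n,
      sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp))
  })
  overall <- sum(diag(cm)) / n
  ci <- proportion_ci(sum(diag(cm)), n, alpha = alpha, method = ci_method)
  list(per_class = do.call(rbind, per),
       overall_accuracy = 100 * overall,
       overall_ci = 100 * ci, n = n)
}

#' Binomial proportion confidence interval
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param alpha two-sided significance level.
#' @param method `"normal"` (Wald, the default) or `"wilson"` (score).
#' @return length-2 numeric `(lower, upper)`, clipped to [0, 1].
#' @export
proportion_ci <- function(successes, n, alpha = 0.05,
                          method = c("normal", "wilson")) {
  method <- match.arg(method)
  stopifnot(n > 0, successes >= 0, successes <= n)
  p <- successes / n
  z <- stats::qnorm(1 - alpha / 2)
  ci <- if (method == "normal") {
    se <- sqrt(p * (1 - p) / n)
    c(p - z * se, p + z * se)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(centre - half, centre + half)
  }
  clamp(ci, 0, 1)
}

icc_from_ms <- function(msr, mse, n, k, alpha) {
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  if (msr <= 0 && mse <= 0) {
    return(structure(list(icc = NA_real_, F = NA_real_, df1 = df1,
                          df2 = df2, p = NA_real_,
                          ci = c(NA_real_, NA_real_), n_subjects = n,
                          k_raters = k, undefined = TRUE),
                     class = "icc_result"))
  }
  if (mse <= 0) {
    # perfectly consistent raters (zero residual): ICC = 1 exactly
    return(structure(list(icc = 1, F = Inf, df1 = df1, df2 = df2, p = 0,
                          ci = c(1, 1), n_subjects = n, k_raters = k,
                          undefined = FALSE),
                     class = "icc_result"))
  }
  F <- msr / mse
  icc <- (F - 1) / (F + k - 1)
  fq <- stats::qf(1 - alpha / 2, df1, df2)
  fq_rev <- stats::qf(1 - alpha / 2, df2, df1)
  f_l <- F / fq
  f_u <- F * fq_rev
  ci <- c((f_l - 1) / (f_l + k - 1), (f_u - 1) / (f_u + k - 1))
  structure(list(icc = icc, F = F, df1 = df1, df2 = df2,
                 p = stats::pf(F, df1, df2, lower.tail = FALSE),
                 ci = ci, n_subjects = n, k_raters = k, undefined = FALSE),
            class = "icc_result")
}

#' Intraclass correlation (two-way, consistency, single measures)
#'
#' From the two-way ANOVA decomposition with subjects as rows and
#' raters/methods as columns: ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE),
#' where MSR is the between-subject mean square and MSE the residual mean
#' square after removing the rater effect.  The F statistic MSR/MSE with
#' df (n-1, (n-1)(k-1)) yields the confidence bounds
#' (F/F_u - 1)/(F/F_u + k - 1) and (F F_u' - 1)/(F F_u' + k - 1).  With
#' `model = "agreement"` the absolute-agreement form ICC(A,1) is returned
#' instead (its CI uses the consistency F bounds as an approximation).
#'
#' @param data numeric matrix or data.frame, n subjects x k raters, no
#'   missing cells.
#' @param alpha two-sided significance level for the CI.
#' @param model `"consistency"` (default) or `"agreement"`.
#' @return object of class `icc_result`: `icc`, `F`, `df1`, `df2`, `p`,
#'   `ci`, `n_subjects`, `k_raters`, `undefined`.
#' @export
icc_consistency <- function(data, alpha = 0.05,
                            model = c("consistency", "agreement")) {
  model <- match.arg(model)
  m <- as.matrix(data)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3, k >= 2, !anyNA(m))
  grand <- mean(m)
  rmeans <- rowMeans(m)
  cmeans <- colMeans(m)
  ssr <- k * sum((rmeans - grand)^2)
  ssc <- n * sum((cmeans - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  out <- icc_from_ms(msr, mse, n, k, alpha)
  if (model == "agreement" && !out$undefined) {
    out$icc <- (msr - mse) /
      (msr + (k - 1) * mse + k / n * (msc - mse))
  }
  out
}

#' Intraclass correlation from a printed F statistic
#'
#' Closed-form ICC(C,1) and its confidence bounds computed from the
#' published F ratio alone, without raw data: ICC = (F-1)/(F+k-1); bounds
#' from F_L = F / F_{1-a/2}(df1, df2) and F_U = F * F_{1-a/2}(df2, df1).
#'
#' @param F positive F ratio (MSR/MSE).
#' @param n_subjects,k_raters design dimensions (n >= 3, k >= 2).
#' @param alpha two-sided significance level.
#' @return an `icc_result` (see [icc_consistency()]).
#' @export
icc_from_f <- function(F, n_subjects, k_raters, alpha = 0.05) {
  stopifnot(F > 0, n_subjects >= 3, k_raters >= 2)
  df2 <- (n_subjects - 1) * (k_raters - 1)
  # reuse the mean-square path with MSE = 1, MSR = F
  icc_from_ms(F, 1, n_subjects, k_raters, alpha)
}

# Kolmogorov distribution upper tail, for the cusum linearity test
kolmogorov_sf <- function(h) {
  if (h <= 0) return(1)
  kk <- 1:100
  min(1, max(0, 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * h^2))))
}

#' Passing-Bablok method-comparison regression
#'
#' The nonparametric regression of the original procedure: the slope is the
#' shifted median of all pairwise slopes S_ij = (y_j - y_i)/(x_j - x_i)
#' (pairs with both differences zero are dropped, slopes exactly -1 are
#' dropped, vertical pairs contribute signed infinities to the ranking);
#' the shift K is the number of slopes below -1, which makes the estimate
#' invariant to swapping the axes.  Rank-based confidence bounds use the
#' normal approximation w = z * sqrt(n(n-1)(2n+5)/18).  The intercept is
#' the median of y - b x, with its CI from the slope bounds.  Linearity is
#' assessed by a cusum-of-residual-signs test against the Kolmogorov bound.
#'
#' @param x,y paired measurements (n >= 3; a warning below 30, where the
#'   rank CIs are crude).
#' @param alpha two-sided significance level.
#' @return object of class `pb_result`: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `n_pairs`, `n_slopes`, `K`, `linearity_stat`,
#'   `linearity_p`, `linear`.
#' @export
passing_bablok <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("passing_bablok() needs at least 3 pairs")
  if (length(unique(x)) == 1) {
    stop("all x values identical: no regression possible")
  }
  if (n < 30) warning("fewer than 30 pairs: confidence bounds are crude")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- !(dx == 0 & dy == 0)
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  s <- s[s != -1]
  s <- sort(s)  # sorts -Inf first, Inf last
  N <- length(s)
  if (N == 0) stop("no valid pairwise slopes")
  K <- sum(s < -1)

  at <- function(i) s[clamp(i, 1, N)]
  b <- if (N %% 2 == 1) {
    at((N + 1) / 2 + K)
  } else {
    mean(c(at(N / 2 + K), at(N / 2 + 1 + K)))
  }
  z <- stats::qnorm(1 - alpha / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- floor((N - w) / 2)
  M2 <- N - M1 + 1
  slope_ci <- c(at(M1 + K), at(M2 + K))
  intercept <- stats::median(y - b * x)
  intercept_ci <- c(stats::median(y - slope_ci[2] * x),
                    stats::median(y - slope_ci[1] * x))

  # cusum linearity test
  d <- y - (intercept + b * x)
  tol <- 1e-12 * max(1, max(abs(y)))
  pos <- d > tol; neg <- d < -tol
  l <- sum(pos); mneg <- sum(neg)
  if (l == 0 || mneg == 0) {
    stat <- 0; p <- 1
  } else {
    scores <- numeric(n)
    scores[pos] <- sqrt(mneg / l)
    scores[neg] <- -sqrt(l / mneg)
    ord <- order(x, y)
    cs <- cumsum(scores[ord])
    stat <- max(abs(cs)) / sqrt(l + 1)
    p <- kolmogorov_sf(stat)
  }
  structure(list(slope = b, intercept = intercept, slope_ci = slope_ci,
                 intercept_ci = intercept_ci, n_pairs = n, n_slopes = N,
                 K = K, linearity_stat = stat, linearity_p = p,
                 linear = p > alpha),
            class = "pb_result")
}

#' Bland-Altman agreement analysis
#'
#' Differences d = x - y are summarized by their mean (bias), sample
#' standard deviation, and the limits of agreement bias +/- multiplier *
#' sd.  The bias CI uses the t distribution; each limit's CI uses the
#' standard se(LoA) ~ sd * sqrt(3/n) approximation.
#'
#' @param x,y paired measurements (n >= 2).
#' @param multiplier LoA width in standard deviations (default 1.96).
#' @param alpha significance level for the CIs.
#' @return object of class `ba_result`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `bias_ci`, `loa_lower_ci`, `loa_upper_ci`, `multiplier`,
#'   `n`, plus `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x, y, multiplier = 1.96, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("bland_altman() needs at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  lo <- bias - multiplier * sdd
  hi <- bias + multiplier * sdd
  tq <- stats::qt(1 - alpha / 2, n - 1)
  bias_half <- tq * sdd / sqrt(n)
  loa_half <- tq * sdd * sqrt(3 / n)
  structure(list(bias = bias, sd_diff = sdd, loa_lower = lo, loa_upper = hi,
                 bias_ci = c(bias - bias_half, bias + bias_half),
                 loa_lower_ci = c(lo - loa_half, lo + loa_half),
                 loa_upper_ci = c(hi - loa_half, hi + loa_half),
                 multiplier = multiplier, n = n,
                 means = (x + y) / 2, diffs = d),
            class = "ba_result")
}
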