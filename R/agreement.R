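drop_pairwise_na <- function(x, y, what) {
  ok <- !(is.na(x) | is.na(y))
  if (!all(ok))
    message(sum(!ok), " incomplete pair(s) dropped from ", what)
  list(x = x[ok], y = y[ok])
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two continuous readings of the same quantity,
#' penalizing both poor correlation and location/scale shifts:
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' with population (1/n) moment estimators. Unlike Pearson's r, a constant
#' offset between raters lowers the CCC (`|CCC| <= |r|` always).
#'
#' The confidence interval uses Lin's asymptotic variance of the Fisher
#' z-transform of the coefficient, back-transformed (method recorded in the
#' result as `ci_method`).
#'
#' @param x,y paired readings (equal length, n >= 3); incomplete pairs are
#'   dropped with a message.
#' @param conf.level confidence level for the interval.
#' @return object of class `ccc`: list with `ccc`, `ci` (length 2), `n`,
#'   `pearson_r`, `ci_method`.
#' @references Lin, L. I-K. (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45, 255-268.
#' @export
lin_ccc <- function(x, y, conf.level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  p <- drop_pairwise_na(x, y, "lin_ccc")
  x <- p$x; y <- p$y
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 + sy2 == 0)
    stop("agreement undefined: both series are constant", call. = FALSE)
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (!is.na(r) && abs(ccc) < 1 && abs(r) > 0) {
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    q <- stats::qnorm(1 - (1 - conf.level) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(max(sz2, 0)))
  } else if (abs(ccc) >= 1) {
    ci <- c(ccc, ccc)
  }
  structure(list(ccc = ccc, ci = ci, n = n, pearson_r = r,
                 conf.level = conf.level,
                 ci_method = "Fisher z transform, Lin (1989) asymptotic variance"),
            class = "ccc")
}

#' @export
print.ccc <- function(x, ...) {
  cat(sprintf("Lin's concordance correlation: %.3f (%d%% CI %.3f-%.3f), n = %d\n",
              x$ccc, round(100 * x$conf.level), x$ci[1L], x$ci[2L], x$n))
  invisible(x)
}

#' Bland-Altman paired-difference summary
#'
#' Summarizes rater differences `d = x - y` (first-listed rater minus second):
#' the mean difference, the empirical 5th and 95th percentiles of the
#' differences (type-7 linear interpolation), and the classical limits of
#' agreement `mean +/- 1.96 sd` for plotting.
#'
#' @param x,y paired readings; incomplete pairs dropped with a message.
#' @return object of class `bland_altman`: list with `mean_diff`, `p05_diff`,
#'   `p95_diff`, `sd_diff`, `loa` (length 2), `n`, and the per-pair `means`
#'   and `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  p <- drop_pairwise_na(x, y, "bland_altman")
  x <- p$x; y <- p$y
  if (length(x) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  q <- stats::quantile(d, c(0.05, 0.95), names = FALSE, type = 7)
  sd_d <- stats::sd(d)
  structure(list(mean_diff = mean(d), p05_diff = q[1L], p95_diff = q[2L],
                 sd_diff = sd_d, loa = mean(d) + c(-1.96, 1.96) * sd_d,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %+.2f (P05 %+.2f to P95 %+.2f), n = %d\n",
              x$mean_diff, x$p05_diff, x$p95_diff, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of pair",
                 ylab = "difference (first - second)",
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2), col = "grey40")
  invisible(x)
}

#' Weighted kappa for ordered categories
#'
#' Chance-corrected agreement between two raters on an ordered k-category
#' scale with quadratic disagreement weights
#' `w_ij = 1 - (i - j)^2 / (k - 1)^2`. Kappa is
#' `(p_o - p_e) / (1 - p_e)` with weighted observed and expected agreement
#' from the k x k contingency table and its margins. The confidence interval
#' uses the large-sample standard error of Fleiss, Cohen & Everitt (1969).
#'
#' @param a,b paired category codes (integers, or factors with identical
#'   level sets); incomplete pairs dropped with a message.
#' @param k number of scale categories; inferred from factor levels or the
#'   observed code range when omitted.
#' @param conf.level confidence level.
#' @return object of class `weighted_kappa`: list with `kappa`, `se`, `ci`,
#'   `po`, `pe`, `n`, `k`. When both raters are constant on the same category
#'   (`p_e = 1`) kappa is undefined and returned as `NA` with a warning.
#' @export
weighted_kappa <- function(a, b, k = NULL, conf.level = 0.95) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (is.factor(a) || is.factor(b)) {
    if (!identical(levels(a), levels(b)))
      stop("factor inputs must share the same ordered level set", call. = FALSE)
    if (is.null(k)) k <- nlevels(a)
    a <- as.integer(a); b <- as.integer(b)
  } else {
    a <- as.integer(a) + 1L; b <- as.integer(b) + 1L  # 0-based codes
    if (is.null(k)) k <- max(a, b, na.rm = TRUE)
  }
  p <- drop_pairwise_na(a, b, "weighted_kappa")
  a <- p$x; b <- p$y
  n <- length(a)
  if (n < 1L) stop("no complete pairs", call. = FALSE)
  if (k < 2L) stop("need at least 2 categories", call. = FALSE)
  if (any(c(a, b) < 1L) || any(c(a, b) > k))
    stop("category codes outside 0..k-1", call. = FALSE)

  tab <- table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k)))
  pij <- tab / n
  w <- 1 - (outer(seq_len(k), seq_len(k), "-"))^2 / (k - 1)^2
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  po <- sum(w * pij)
  pe <- sum(w * outer(pi_, p_j))
  if (1 - pe < .Machine$double.eps * 8) {
    warning("expected agreement is 1 (both raters effectively constant); ",
            "kappa undefined")
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci = c(NA_real_, NA_real_), po = po, pe = pe,
                          n = n, k = k, conf.level = conf.level),
                     class = "weighted_kappa"))
  }
  kap <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt large-sample variance
  wbar_i <- as.vector(w %*% p_j)     # row-wise expected weight
  wbar_j <- as.vector(pi_ %*% w)     # column-wise expected weight
  dev <- w - outer(wbar_i, wbar_j, "+") * (1 - kap)
  var_k <- (sum(pij * dev^2) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  structure(list(kappa = kap, se = se, ci = kap + c(-1, 1) * q * se,
                 po = po, pe = pe, n = n, k = k, conf.level = conf.level,
                 ci_method = "Fleiss-Cohen-Everitt large-sample SE"),
            class = "weighted_kappa")
}

#' @export
print.weighted_kappa <- function(x, ...) {
  if (is.na(x$kappa)) cat("Weighted kappa: undefined (expected agreement = 1)\n")
  else cat(sprintf("Quadratic-weighted kappa: %.3f (%d%% CI %.3f-%.3f), n = %d, k = %d\n",
                   x$kappa, round(100 * x$conf.level), x$ci[1L], x$ci[2L],
                   x$n, x$k))
  invisible(x)
}

#' Per-category PD distribution summary
#'
#' For each category of a visual scale, summarizes the continuous PD readings
#' falling in it: n, mean, and empirical 5th/95th percentiles - the standard
#' shape for comparing a quantitative tool against visual classification.
#'
#' @param pd numeric PD values.
#' @param categories parallel factor (or vector coerced to factor) of visual
#'   categories.
#' @return data frame with columns `category`, `n`, `mean`, `p05`, `p95`
#'   (one row per factor level, in level order; empty categories get `n = 0`
#'   and `NA` summaries).
#' @export
per_category_summary <- function(pd, categories) {
  if (length(pd) != length(categories))
    stop("pd and categories must be aligned", call. = FALSE)
  categories <- as.factor(categories)
  rows <- lapply(levels(categories), function(lv) {
    v <- pd[categories == lv & !is.na(pd)]
    if (length(v) == 0L)
      data.frame(category = lv, n = 0L, mean = NA_real_, p05 = NA_real_,
                 p95 = NA_real_)
    else {
      q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
      data.frame(category = lv, n = length(v), mean = mean(v), p05 = q[1L],
                 p95 = q[2L])
    }
  })
  do.call(rbind, rows)
}
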