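#' Ordinary least squares fit of y on x
#'
#' Simple linear regression with the conventions used throughout the
#' analysis: r^2 is the squared Pearson correlation and the p value is the
#' two-sided t test on the slope with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite.
#' @return A list of class \code{"reg_result"} with elements \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_value}, \code{method}
#'   (\code{"OLS"}) and \code{n}.
#' @export
ols_fit <- function(x, y) {
  check_xy(x, y)
  if (stats::sd(x) == 0) {
    stop("degenerate fit: x has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # perfect fits trip summary.lm's noise-floor warning; they are legitimate here
  cf <- suppressWarnings(summary(fit)$coefficients)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  p <- if (nrow(cf) < 2L || stats::sd(y) == 0) 1 else cf["x", "Pr(>|t|)"]
  reg_result(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r_squared = r^2, p_value = p, method = "OLS", n = length(x))
}

#' Standardized major axis (SMA) regression
#'
#' Symmetric model-II line fit appropriate when both variables are measured
#' with error and neither is a natural predictor — here, bulk-melt nutrient
#' concentrations against independently estimated bottom-ice intracellular
#' concentrations. The slope is \eqn{sign(r)\, s_y / s_x}, the intercept
#' passes through the centroid, r^2 is the squared Pearson correlation, and
#' the p value is that of the correlation test (the standard inference for
#' SMA). When r is exactly zero the slope sign is undefined; the positive
#' root is returned with attribute \code{"sign_undefined"} set.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both with positive
#'   variance.
#' @return A \code{"reg_result"} list with \code{method = "SMA"}.
#' @export
sma_fit <- function(x, y) {
  check_xy(x, y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("SMA undefined when either variable has zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  s <- if (r == 0) 1 else sign(r)
  slope <- s * sy / sx
  ct <- stats::cor.test(x, y)
  out <- reg_result(slope = slope,
                    intercept = mean(y) - slope * mean(x),
                    r_squared = r^2, p_value = ct$p.value,
                    method = "SMA", n = length(x))
  if (r == 0) attr(out, "sign_undefined") <- TRUE
  out
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param lag Integer bookkeeping field recorded in the result (used by
#'   [lagged_residual_correlation()]); default 0.
#' @return A list of class \code{"cor_result"} with \code{r},
#'   \code{p_value}, \code{lag}, \code{n}.
#' @export
pearson_cor <- function(x, y, lag = 0L) {
  check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined when a variable has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 lag = as.integer(lag), n = length(x)),
            class = "cor_result")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of group locations for data with non-uniform
#' distributions. For larger samples the p value comes from the chi-square
#' approximation (df = k - 1); when the total sample size is at most
#' \code{exact_n_max} the exact permutation p value is computed by complete
#' enumeration of all assignments of the observations to the group sizes.
#' The H statistic uses the standard tie correction in both paths.
#'
#' @param groups A list of numeric vectors, each nonempty, at least two
#'   groups.
#' @param exact_n_max Total-n threshold at or below which the exact
#'   permutation p value is used; default 10.
#' @return A list with \code{H}, \code{p_value}, \code{df}, \code{n},
#'   \code{exact} (logical).
#' @export
kruskal_wallis <- function(groups, exact_n_max = 10L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two numeric vectors", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("every group must be nonempty", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 1L)
  n <- length(values)
  k <- length(groups)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p_value = 1, df = k - 1L, n = n, exact = FALSE))
  }
  H <- kw_statistic(values, rep.int(seq_len(k), sizes))
  if (n <= exact_n_max) {
    p <- kw_exact_p(values, sizes, H)
    list(H = H, p_value = p, df = k - 1L, n = n, exact = TRUE)
  } else {
    g <- factor(rep.int(seq_len(k), sizes))
    kt <- stats::kruskal.test(values, g)
    list(H = unname(kt$statistic), p_value = kt$p.value, df = k - 1L,
         n = n, exact = FALSE)
  }
}

# Tie-corrected H for a given assignment of values to groups.
kw_statistic <- function(values, group_index) {
  n <- length(values)
  rk <- rank(values)
  ssq <- tapply(rk, group_index, sum)^2 / tabulate(group_index)
  H <- 12 / (n * (n + 1)) * sum(ssq) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / correction
}

# Exact permutation p: enumerate all distinct assignments of the pooled
# observations to the given group sizes and count H >= observed.
kw_exact_p <- function(values, sizes, H_obs) {
  n <- length(values)
  assignments <- enumerate_assignments(seq_len(n), sizes)
  group_index <- rep.int(seq_along(sizes), sizes)
  hs <- vapply(assignments, function(idx) {
    kw_statistic(values[idx], group_index)
  }, numeric(1))
  mean(hs >= H_obs - 1e-12)
}

# All ways to deal the elements of `idx` into ordered groups of the given
# sizes; returns a list of index vectors (group 1 first, then group 2, ...).
enumerate_assignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(idx))
  first <- utils::combn(idx, sizes[1L], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_assignments(setdiff(idx, f), sizes[-1L])
    out <- c(out, lapply(rest, function(r) c(f, r)))
  }
  out
}

#' Linear detrending
#'
#' Removes the OLS linear trend of y against t and returns the residuals,
#' which by construction sum to zero and are orthogonal to t.
#'
#' @param t Numeric vector of times (e.g. fractional days from campaign
#'   start).
#' @param y Numeric vector of the same length, n >= 3.
#' @return Numeric vector of residuals.
#' @export
detrend_linear <- function(t, y) {
  fit <- ols_fit(t, y)
  y - (fit$intercept + fit$slope * t)
}

#' Lagged correlation of detrended residuals against a forcing series
#'
#' Correlates a residual series against a forcing series sampled on the same
#' grid, with the residual response lagging the forcing by \code{lag}
#' sampling cycles: \code{residuals[(lag+1):n]} is paired with
#' \code{forcing[1:(n-lag)]}. This is the convention for a biological signal
#' responding to an environmental driver.
#'
#' @param residuals Numeric residual vector (e.g. from [detrend_linear()]).
#' @param forcing Numeric forcing vector of the same length (e.g. daily
#'   maximum under-ice current speed on the sampling days).
#' @param lag Non-negative integer lag in sampling cycles.
#' @return A \code{"cor_result"} list; \code{n} is the number of pairs after
#'   trimming.
#' @export
lagged_residual_correlation <- function(residuals, forcing, lag = 0L) {
  stopifnot(length(residuals) == length(forcing))
  lag <- as.integer(lag)
  if (lag < 0L) stop("`lag` must be >= 0", call. = FALSE)
  n <- length(residuals)
  if (n - lag < 3L) {
    stop("too few pairs after lag trimming (need at least 3)", call. = FALSE)
  }
  pearson_cor(residuals[(lag + 1L):n], forcing[1L:(n - lag)], lag = lag)
}

#' Log-linear (exponential) decay fit
#'
#' Fits ln(ratio) = intercept + rate * t by OLS. A negative rate is an
#' exponential decay of the ratio (per day when t is in days); used for the
#' seasonal decline of the intracellular N:Si ratio.
#'
#' @param t Numeric times.
#' @param ratio Strictly positive numeric vector of the same length.
#' @return A list with \code{rate}, \code{intercept}, \code{r_squared},
#'   \code{p_value}, \code{n}.
#' @export
loglinear_decay_fit <- function(t, ratio) {
  if (any(ratio <= 0)) {
    stop("log-linear fit requires strictly positive ratios", call. = FALSE)
  }
  fit <- ols_fit(t, log(ratio))
  list(rate = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n)
}

#' Significance labelling convention
#'
#' The reporting convention used throughout: p < 0.01 is
#' \code{"significant"}; 0.01 <= p <= 0.1 is a \code{"weak"} association;
#' larger p is \code{"ns"}.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param strict_alpha,weak_alpha Thresholds; defaults 0.01 and 0.1.
#' @return Character vector in \code{c("significant", "weak", "ns")}.
#' @export
significance_label <- function(p, strict_alpha = 0.01, weak_alpha = 0.1) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  ifelse(p < strict_alpha, "significant",
         ifelse(p <= weak_alpha, "weak", "ns"))
}

reg_result <- function(slope, intercept, r_squared, p_value, method, n) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = min(max(r_squared, 0), 1),
                 p_value = min(max(p_value, 0), 1),
                 method = method, n = n),
            class = "reg_result")
}

#' @export
print.reg_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): slope = %.4g, intercept = %.4g, r^2 = %.3f, p = %.3g [%s]\n",
              x$method, x$n, x$slope, x$intercept, x$r_squared, x$p_value,
              significance_label(x$p_value)))
  invisible(x)
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, lag = %d, p = %.3g) [%s]\n",
              x$r, x$n, x$lag, x$p_value, significance_label(x$p_value)))
  invisible(x)
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
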