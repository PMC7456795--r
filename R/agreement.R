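# Method-agreement statistics: Box-Cox transformation, D'Agostino-Pearson
# omnibus normality test, Bland-Altman analysis with limits of agreement and
# their confidence intervals, Wilcoxon signed-rank and Mann-Whitney U tests
# (exact by enumeration at small n, normal approximation with tie and
# continuity corrections otherwise), and Pearson correlation with ordinary
# least-squares regression. Two-sided p-values throughout; no multiple-testing
# correction is applied.

#' Box-Cox power transformation
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `y = log(x)` at
#' `lambda = 0`. When `lambda` is omitted it is chosen to maximize the profile
#' log-likelihood over `[-5, 5]`. Inputs must be positive after the shift;
#' with `shift = "auto"` a shift of `-min(x) + epsilon` is applied when needed
#' (differences between two methods are frequently negative) and recorded in
#' the result.
#'
#' @param x numeric vector, length >= 4.
#' @param lambda optional fixed exponent.
#' @param shift `"auto"`, or a numeric shift added to `x` before transforming;
#'   use `0` to disable shifting (nonpositive values then error).
#' @return List of class `box_cox_fit`: `lambda`, `shift`, `transformed`,
#'   `loglik`.
#' @export
box_cox <- function(x, lambda = NULL, shift = "auto") {
  x <- as.numeric(x)
  if (length(x) < 4L || !all(is.finite(x)))
    stop("box_cox needs >= 4 finite values")
  if (identical(shift, "auto")) {
    shift <- if (min(x) > 0) 0 else -min(x) + 1e-6 * max(1, diff(range(x)))
  }
  shift <- as.numeric(shift)
  xs <- x + shift
  if (any(xs <= 0))
    stop("values must be strictly positive after the shift")
  bc <- function(l) if (abs(l) < 1e-12) log(xs) else (xs^l - 1) / l
  loglik <- function(l) {
    y <- bc(l)
    n <- length(y)
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(log(xs))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(loglik, c(-5, 5), maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    ll <- opt$objective
  } else {
    lambda <- as.numeric(lambda)
    ll <- loglik(lambda)
  }
  structure(list(lambda = lambda, shift = shift, transformed = bc(lambda),
                 loglik = ll),
            class = "box_cox_fit")
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (Z1) and kurtosis (Z2) into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-square distribution with 2 degrees of
#' freedom. Uses the D'Agostino (1970) skewness and Anscombe-Glynn (1983)
#' kurtosis transformations.
#'
#' @param x numeric vector; n >= 20 recommended (a warning is issued for
#'   8 <= n < 20, an error below 8).
#' @return List of class `seeg_test`: `statistic` (K2), `z_skewness`,
#'   `z_kurtosis`, `p_value`, `n`, `method`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("dagostino_pearson needs at least 8 values")
  if (n < 20L)
    warning("D'Agostino-Pearson is unreliable for n < 20 (n = ", n, ")")
  if (stats::sd(x) == 0) stop("constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  structure(list(statistic = k2, z_skewness = z1, z_kurtosis = z2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 n = n, method = "D'Agostino-Pearson K2"),
            class = "seeg_test")
}

#' @export
print.seeg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g, n = %s\n", x$method,
              x$statistic, x$p_value,
              paste(unlist(x[grep("^n", names(x))]), collapse = "/")))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two measurement methods via the differences `d = a - b`:
#' bias `mu = mean(d)`, `sigma = sd(d)` (n-1 denominator), limits of agreement
#' `mu +/- loa_factor * sigma`, and confidence intervals following the
#' classical large-sample approach: `mu +/- t * sigma / sqrt(n)` for the bias
#' and `limit +/- t * sigma * sqrt(3 / n)` for each limit (the variance of an
#' estimated limit is approximately `3 sigma^2 / n`).
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @param loa_factor multiple of sigma defining the limits (default 1.96).
#' @param ci_level confidence level for the intervals (default 0.95).
#' @return List of class `bland_altman_result`: `n`, `bias`, `sd`, `loa_low`,
#'   `loa_high`, `ci_bias`, `ci_loa_low`, `ci_loa_high`, `differences`.
#' @export
bland_altman <- function(a, b, loa_factor = 1.96, ci_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) stop("bland_altman needs at least 3 pairs")
  d <- a - b
  mu <- mean(d)
  sdd <- stats::sd(d)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  lo <- mu - loa_factor * sdd
  hi <- mu + loa_factor * sdd
  se_bias <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  structure(list(n = n, bias = mu, sd = sdd, loa_low = lo, loa_high = hi,
                 ci_bias = c(mu - tq * se_bias, mu + tq * se_bias),
                 ci_loa_low = c(lo - tq * se_loa, lo + tq * se_loa),
                 ci_loa_high = c(hi - tq * se_loa, hi + tq * se_loa),
                 loa_factor = loa_factor, ci_level = ci_level,
                 differences = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman (n = %d): bias = %.4f [%.4f, %.4f], ",
                     "LoA = [%.4f, %.4f]\n"),
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_low, x$loa_high))
  invisible(x)
}

# distribution of the positive-rank sum over all 2^n sign assignments
.signrank_sums <- function(r) {
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  sums
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded (classical treatment); ties among absolute
#' differences share average ranks. The reported statistic `W` is the smaller
#' of the positive- and negative-rank sums. The two-sided p-value is exact by
#' enumeration of all sign assignments when the effective n is at most
#' `exact_max` (default 15), otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @param exact_max largest effective n for exact enumeration.
#' @return List of class `seeg_test`: `statistic` (W), `p_value`, `n`
#'   (effective, zeros removed), `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 15L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  tot <- sum(r)
  w <- min(v, tot - v)
  if (n <= exact_max) {
    sums <- .signrank_sums(r)
    p <- (sum(sums <= w + 1e-9) + sum(sums >= tot - w - 1e-9)) / length(sums)
    p <- min(1, p)
    exact <- TRUE
  } else {
    tie_sizes <- table(abs(d))
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    exact <- FALSE
  }
  structure(list(statistic = w, p_value = p, n = n, exact = exact,
                 method = "Wilcoxon signed-rank W"),
            class = "seeg_test")
}

#' Mann-Whitney U test for two independent groups
#'
#' `U` is reported for the first group (`x`). The two-sided p-value is exact
#' by enumeration of all rank assignments when `length(x) + length(y) <=
#' exact_max` (default 12) and there are no ties, otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact_max largest pooled n for exact enumeration.
#' @return List of class `seeg_test`: `statistic` (U for `x`), `p_value`,
#'   `n_x`, `n_y`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  nn <- nx + ny
  ties <- any(duplicated(pooled))
  if (nn <= exact_max && !ties) {
    combs <- utils::combn(nn, nx)
    rs <- colSums(matrix(r[combs], nrow = nx))
    us <- rs - nx * (nx + 1) / 2
    lo <- min(u, nx * ny - u)
    hi <- nx * ny - lo
    p <- (sum(us <= lo + 1e-9) + sum(us >= hi - 1e-9)) / ncol(combs)
    p <- min(1, p)
    exact <- TRUE
  } else {
    tie_sizes <- table(pooled)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 *
      ((nn + 1) - sum(tie_sizes^3 - tie_sizes) / (nn * (nn - 1)))
    z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    exact <- FALSE
  }
  structure(list(statistic = u, p_value = p, n_x = nx, n_y = ny,
                 exact = exact, method = "Mann-Whitney U"),
            class = "seeg_test")
}

#' Pearson correlation and least-squares regression
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @return List with `rho` (Pearson correlation), `slope`, `intercept`, `n`
#'   for the ordinary least-squares fit of `y` on `x`.
#' @export
correlation_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  list(rho = stats::cor(x, y), slope = slope, intercept = intercept, n = n)
}
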