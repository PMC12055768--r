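#' One-sample Kolmogorov-Smirnov statistic against a fitted reference
#'
#' Computes the sup-distance D between the empirical CDF of a small sample
#' and a reference distribution fitted to that same sample:
#' `"normal_fitted"` uses the sample mean and the n-1 (unbiased-variance)
#' standard deviation; `"exponential_fitted"` uses rate `1/mean(x)`, i.e.
#' `F(x) = 1 - exp(-x/mean)`.  Ties are handled through the left limit of
#' the empirical CDF, so repeated zeros against an exponential reference
#' contribute their full jump (a sample with four of six values at zero has
#' `D >= 4/6` since `F(0) = 0`).
#'
#' @param values Numeric sample, `n >= 2`.  For the exponential reference
#'   all values must be non-negative with a positive mean; for the normal
#'   reference the sample must not be constant.
#' @param reference `"normal_fitted"` or `"exponential_fitted"`.
#' @return A `ks_result` list: `D`, `n`, `reference`, and `p_value`/`method`
#'   slots (filled by [ks_pvalue()], `NA` here).
#' @examples
#' ks_D(c(0, 0, 0, 1, 0, 0), "normal_fitted")$D  # 0.492
#' @export
ks_D <- function(values, reference = c("normal_fitted", "exponential_fitted")) {
  reference <- match.arg(reference)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  if (anyNA(x)) stop("missing values in sample")
  cdf <- fitted_reference_cdf(x, reference)
  xs <- sort(x)
  Fx <- cdf(xs)
  i <- seq_len(n)
  D <- max(pmax(i / n - Fx, Fx - (i - 1) / n))
  structure(list(D = D, n = n, reference = reference,
                 p_value = NA_real_, method = NA_character_),
            class = "ks_result")
}

fitted_reference_cdf <- function(x, reference) {
  if (reference == "normal_fitted") {
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0)
      stop("constant sample: normal reference has zero SD")
    m <- mean(x)
    function(q) stats::pnorm(q, mean = m, sd = s)
  } else {
    if (any(x < 0)) stop("negative value under exponential reference")
    m <- mean(x)
    if (m <= 0) stop("exponential reference needs a positive mean")
    function(q) stats::pexp(q, rate = 1 / m)
  }
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS D = %.4f (n = %d, %s)", x$D, x$n, x$reference))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4f [%s]", x$p_value, x$method))
  cat("\n")
  invisible(x)
}

#' P-value for a one-sample KS statistic at small n
#'
#' Two nulls are available.  `"exact_kolmogorov"` is the classical exact
#' distribution of D for a fully specified continuous reference,
#' `P(D_n >= D)`, computed with the Marsaglia-Tsang-Wang matrix method; it
#' ignores the fact that the reference parameters were estimated from the
#' sample and is therefore conservative.  `"monte_carlo"` is a parametric
#' bootstrap (fit-then-simulate): `reps` samples of size `n` are drawn from
#' the reference family, the parameters are re-estimated on each draw and
#' D recomputed, which yields the estimated-parameters (Lilliefors-type)
#' null.  Because both reference families are closed under location-scale /
#' scale changes, the bootstrap can simulate from the standard member.
#'
#' @param D Observed statistic in `[0, 1]`.
#' @param n Sample size.
#' @param reference `"normal_fitted"` or `"exponential_fitted"` (used by the
#'   Monte Carlo method only).
#' @param method `"exact_kolmogorov"` or `"monte_carlo"`.
#' @param reps Bootstrap draws (Monte Carlo only), at least 100.
#' @param seed Integer seed (Monte Carlo only); same seed, same p.
#' @return P-value in `[0, 1]`.
#' @examples
#' ks_pvalue(0.492, 6, method = "exact_kolmogorov")
#' @export
ks_pvalue <- function(D, n, reference = c("normal_fitted", "exponential_fitted"),
                      method = c("exact_kolmogorov", "monte_carlo"),
                      reps = 2000L, seed = 1L) {
  reference <- match.arg(reference)
  method <- match.arg(method)
  stopifnot(is.finite(D), D >= 0, D <= 1, n >= 1)
  if (method == "exact_kolmogorov")
    return(1 - pkolmogorov_cdf(D, n))
  if (reps < 100L) stop("monte_carlo needs reps >= 100")
  Dstar <- withr::with_seed(seed, vapply(seq_len(reps), function(i) {
    x <- if (reference == "normal_fitted") stats::rnorm(n) else stats::rexp(n)
    ks_D(x, reference)$D
  }, numeric(1)))
  mean(Dstar >= D - 1e-12)
}

#' Exact CDF of the one-sample KS statistic
#'
#' `P(D_n < d)` for a fully specified continuous null, via the
#' Marsaglia-Tsang-Wang matrix-power representation (adequate without
#' log-scaling at the small n used here).
#'
#' @param d Statistic value.
#' @param n Sample size.
#' @return `P(D_n < d)`.
#' @export
pkolmogorov_cdf <- function(d, n) {
  stopifnot(n >= 1, is.finite(d))
  if (d <= 1 / (2 * n)) return(0)   # D_n >= 1/(2n) always
  if (d >= 1) return(1)
  k <- ceiling(n * d)
  h <- k - n * d
  m <- 2L * k - 1L
  H <- matrix(0, m, m)
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i - j + 1L >= 0L) H[i, j] <- 1
  for (i in seq_len(m)) {
    H[i, 1] <- H[i, 1] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1L)
  }
  H[m, 1] <- H[m, 1] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i - j + 1L > 0L) H[i, j] <- H[i, j] / factorial(i - j + 1L)
  Hn <- matrix_power(H, n)
  p <- Hn[k, k] * exp(lfactorial(n) - n * log(n))
  min(max(p, 0), 1)
}

matrix_power <- function(A, n) {
  out <- diag(nrow(A))
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% A
    A <- A %*% A
    n <- n %/% 2
  }
  out
}

#' KS scan of per-session percentages
#'
#' Runs [ks_D()] for each row (code or meta-state) of a matrix of
#' per-session percentage values, the across-session comparison used to ask
#' which affect codes change over a course of therapy.  Rows that are zero
#' in every session carry no distributional information and are flagged
#' `"degenerate (all zero)"`; constant non-zero rows are degenerate under
#' the normal reference for the same reason (zero SD).
#'
#' @param percent Numeric matrix or data.frame, rows = codes/meta-states
#'   (rownames used as labels), columns = sessions (>= 2).
#' @param reference Reference family passed to [ks_D()].
#' @param pvalue `"none"`, `"exact_kolmogorov"` or `"monte_carlo"`.
#' @param reps,seed Monte Carlo settings (see [ks_pvalue()]).
#' @return data.frame with columns `item`, `n`, `D`, `p_value`, `flag`.
#' @export
ks_scan <- function(percent, reference = c("normal_fitted", "exponential_fitted"),
                    pvalue = c("none", "exact_kolmogorov", "monte_carlo"),
                    reps = 2000L, seed = 1L) {
  reference <- match.arg(reference)
  pvalue <- match.arg(pvalue)
  percent <- as.matrix(percent)
  if (ncol(percent) < 2L) stop("need at least 2 sessions")
  items <- rownames(percent)
  if (is.null(items)) items <- paste0("row", seq_len(nrow(percent)))
  rows <- lapply(seq_len(nrow(percent)), function(i) {
    x <- as.numeric(percent[i, ])
    if (all(x == 0))
      return(data.frame(item = items[i], n = length(x), D = NA_real_,
                        p_value = NA_real_, flag = "degenerate (all zero)"))
    if (reference == "normal_fitted" && stats::sd(x) == 0)
      return(data.frame(item = items[i], n = length(x), D = NA_real_,
                        p_value = NA_real_, flag = "degenerate (constant)"))
    r <- ks_D(x, reference)
    p <- if (pvalue == "none") NA_real_ else
      ks_pvalue(r$D, r$n, reference, method = pvalue, reps = reps, seed = seed)
    data.frame(item = items[i], n = r$n, D = r$D, p_value = p, flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
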