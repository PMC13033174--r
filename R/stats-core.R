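#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity. Ties and the
#' original ordering of `pvals` are preserved in the returned vector.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order as `pvals`.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
fdr_bh <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) == 0)
    stop("`pvals` must be a non-empty numeric vector")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Mann-Whitney U test (exact enumeration or tie-corrected normal)
#'
#' Two-sided rank-sum test. For small samples (combined n at most 16,
#' or `mode = "exact"`) the null distribution of U is obtained by
#' complete enumeration over all group assignments of the pooled
#' sample, which remains valid under ties. Otherwise a normal
#' approximation with tie-corrected variance and a clamped continuity
#' correction is used (the clamp keeps p = 1 for identical samples).
#'
#' @param x,y numeric vectors, one per group.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return a `stat_result` list: `statistic` (U for `x`), `p`, `n`,
#'   `direction` (sign of the mean-rank difference, x minus y) and
#'   `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  use_exact <- mode == "exact" || (mode == "auto" && N <= 16)
  if (use_exact) {
    sets <- utils::combn(N, n1)
    rs <- colSums(matrix(rk[sets], nrow = n1))
    Uall <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    tie <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      # continuity correction, clamped so identical groups give p = 1
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal approximation, tie- and continuity-corrected"
  }
  dir <- sign(mean(rk[seq_len(n1)]) - mean(rk[n1 + seq_len(n2)]))
  structure(list(statistic = U, value = U, p = p, n = c(n1 = n1, n2 = n2),
                 direction = dir, method = method, name = "Mann-Whitney U"),
            class = "stat_result")
}

#' Spearman rank correlation with t-distributed p-value
#'
#' Rank correlation using average ranks for ties; the p-value is from
#' the t approximation on the rank-Pearson coefficient.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return a `stat_result` list with `statistic` (rho), `p` and `n`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(statistic = rho, value = rho, p = p, n = n,
                 direction = sign(rho), method = "t approximation",
                 name = "Spearman rho"),
            class = "stat_result")
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r sample correlation.
#' @param n sample size (n > 3).
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  if (n <= 3) stop("need n > 3 for a Fisher-z interval")
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Pearson correlation test with Fisher-z interval
#'
#' Convenience wrapper around [stats::cor.test()] returning the pieces
#' the reporting layer uses.
#'
#' @param x,y numeric vectors of equal length.
#' @param level confidence level for the Fisher-z interval.
#' @return list with `r`, `p`, `ci95`, `n`.
#' @keywords internal
pearson_test <- function(x, y, level = 0.95) {
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci95 = fisher_z_ci(unname(ct$estimate), length(x), level),
       n = length(x))
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (%s, n = %s)\n",
              x$name, x$statistic, x$p, x$method,
              paste(x$n, collapse = "/")))
  invisible(x)
}
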