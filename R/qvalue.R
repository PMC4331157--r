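#' Estimate the null proportion pi0 (Storey)
#'
#' For each tuning value lambda, pi0_hat(lambda) = #\{p > lambda\} /
#' (m * (1 - lambda)).  The estimates over the lambda grid are smoothed with
#' a cubic smoothing spline and the smoother is evaluated at the largest
#' lambda; the result is clamped to (0, 1].  For small collections
#' (m < 100) the grid estimate is unstable, so the single fixed value
#' lambda = 0.5 is used instead.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda grid of tuning values in [0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return Estimated null proportion in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (m < 1L) stop("no p-values supplied")
  if (length(unique(p)) == 1L) {
    warning("all p-values identical; falling back to pi0 = 1")
    return(1)
  }
  if (m < 100L) {
    lam <- 0.5
    pi0 <- sum(p > lam) / (m * (1 - lam))
    return(min(max(pi0, .Machine$double.eps), 1))
  }
  pi0_lam <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                    numeric(1L))
  fit <- stats::smooth.spline(lambda, pi0_lam, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Storey q-values
#'
#' Converts p-values into q-values: the minimum positive false discovery
#' rate at which each test would be called significant.  With order
#' statistics p(1) <= ... <= p(m):
#' q(m) = pi0 * p(m) and q(i) = min(pi0 * m * p(i) / i, q(i+1)).
#' With `pi0 = 1` this reduces exactly to the Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 null proportion; `NULL` (default) estimates it with
#'   [estimate_pi0()].
#' @param lambda lambda grid passed to [estimate_pi0()].
#' @return An object of class `qvalue_fit`: list with `p_values`,
#'   `q_values` (aligned to input order), `pi0` and `lambda`.
#' @examples
#' fit <- qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
#' fit$q_values  # all 0.04: the BH step-up collapses this ladder
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda)
  if (pi0 <= 0 || pi0 > 1) stop("'pi0' must be in (0, 1]")
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  q[m] <- pi0 * ps[m]
  if (m > 1L)
    for (i in (m - 1L):1L)
      q[i] <- min(pi0 * m * ps[i] / i, q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  structure(list(p_values = p, q_values = out, pi0 = pi0, lambda = lambda),
            class = "qvalue_fit")
}

#' @export
print.qvalue_fit <- function(x, ...) {
  cat("Storey q-values: m = ", length(x$p_values),
      ", pi0 = ", signif(x$pi0, 4),
      ", q < 0.05: ", sum(x$q_values < 0.05), "\n", sep = "")
  invisible(x)
}

# Vectorized two-sample t-test over matrix rows (case/ref column indices).
# Pooled-variance Student by default, Welch optional; two-sided p-values.
# Returns list(stat, df, p, mean_case, mean_ref, sd_case, sd_ref).
.row_t_test <- function(m, idx_case, idx_ref, welch = FALSE) {
  n1 <- length(idx_case); n2 <- length(idx_ref)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  x1 <- m[, idx_case, drop = FALSE]
  x2 <- m[, idx_ref, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    stat <- (m1 - m2) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    df <- rep.int(n1 + n2 - 2L, nrow(m))
    stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  # identical groups: zero variance and zero difference -> no evidence
  p[is.nan(stat)] <- 1
  list(stat = stat, df = df, p = p, mean_case = m1, mean_ref = m2,
       sd_case = sqrt(v1), sd_ref = sqrt(v2))
}
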