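# Replicate-level statistics: median with error range (replicate min/max)
# or median absolute deviation, and the exact two-sided Mann-Whitney test
# for the tiny group sizes (n = 3-4) typical of barrier studies.

#' Summarise replicate values
#'
#' Median with error range (replicate minimum and maximum) and the
#' unscaled median absolute deviation MAD = median(|x_i - median|).
#'
#' @param values Numeric vector, length >= 1, no NAs.
#' @return An object of class `condition_summary`: list with `median`,
#'   `lower`, `upper`, `mad`, `n`.
#' @export
#' @examples
#' summarize_replicates(c(1, 2, 3, 10)) # median 2.5, range 1..10, MAD 1
summarize_replicates <- function(values) {
  x <- as.numeric(values)
  if (!length(x) || anyNA(x)) stop("values must be non-empty and NA-free", call. = FALSE)
  med <- stats::median(x)
  structure(list(median = med, lower = min(x), upper = max(x),
                 mad = stats::median(abs(x - med)), n = length(x)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("median %.4g (range %.4g..%.4g, MAD %.4g, n = %d)\n",
              x$median, x$lower, x$upper, x$mad, x$n))
  invisible(x)
}

#' Exact two-sided Mann-Whitney test
#'
#' Rank-sum test with the U statistic computed from midranks (ties
#' allowed). For small samples (n1 + n2 <= `exact_limit`) the null
#' distribution of U is obtained by full enumeration of all
#' choose(n1 + n2, n1) assignments of the pooled midranks to the first
#' group, and the two-sided p-value is twice the smaller one-sided tail
#' probability (including the observed value), capped at 1 -- the
#' convention under which a 4-vs-4 complete separation gives
#' p = 2/70 = 0.029 and the next-most-extreme ordering 4/70 = 0.057. For
#' larger samples a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (each length >= 1).
#' @param exact Force exact enumeration (`TRUE`), the normal approximation
#'   (`FALSE`), or decide by sample size (`NULL`, the default).
#' @param exact_limit Largest n1 + n2 for which enumeration is the
#'   default (12, covering 3-4 replicates per arm).
#' @return An object of class `pairwise_test`: list with `u_statistic`
#'   (U for the first group, in 0..n1*n2), `p_two_sided`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
mann_whitney_exact <- function(x, y, exact = NULL, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y)) {
    stop("both groups must be non-empty and NA-free", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y)) # midranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  use_exact <- if (is.null(exact)) n <= exact_limit else isTRUE(exact)
  if (use_exact) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(u_statistic = u_obs, p_two_sided = p,
                 n1 = n1, n2 = n2, method = method),
            class = "pairwise_test")
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, n = %d vs %d, two-sided p = %.4g\n",
              x$method, x$u_statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}
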