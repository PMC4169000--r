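#' MA statistics for a pair of tag-count libraries
#'
#' Computes, per gene, the log2 expression difference M and the average
#' log2 expression A between two count libraries:
#' \deqn{M = \log_2(c_1 + pc) - \log_2(c_2 + pc)}
#' \deqn{A = (\log_2(c_1 + pc) + \log_2(c_2 + pc)) / 2}
#' A pseudocount \code{pc} is added to both counts before any logarithm so
#' that genes with zero counts remain finite.
#'
#' @param c1,c2 Non-negative integer count vectors (same length).
#' @param pseudocount Positive value added to both counts (default 0.5).
#' @return A data.frame with columns \code{M} and \code{A}.
#' @examples
#' compute_ma(c(100, 200), c(100, 100))
#' @export
compute_ma <- function(c1, c2, pseudocount = 0.5) {
  stopifnot(length(c1) == length(c2), pseudocount > 0)
  if (any(c1 < 0) || any(c2 < 0)) {
    stop("counts must be non-negative")
  }
  l1 <- log2(c1 + pseudocount)
  l2 <- log2(c2 + pseudocount)
  data.frame(M = l1 - l2, A = (l1 + l2) / 2)
}

#' Null moments of M under the binomial random-sampling model
#'
#' Under the random-sampling null, the combined count K of a gene is
#' partitioned between two libraries as Binomial(K, p0) with
#' p0 = n1 / (n1 + n2), the relative library size. The delta-method
#' moments of M are
#' \deqn{E[M] = \log_2(p_0 / (1 - p_0))}
#' \deqn{Var(M) = 1 / ((\ln 2)^2 \cdot K \cdot p_0 (1 - p_0))}
#'
#' @param K Combined count (c1 + c2), vectorized, K >= 1.
#' @param p0 Null proportion in (0, 1), vectorized.
#' @return A data.frame with columns \code{muM} and \code{varM}.
#' @seealso [rsm_null_moments_exact()] for the exact enumeration.
#' @export
rsm_null_moments <- function(K, p0) {
  stopifnot(all(K >= 1), all(p0 > 0 & p0 < 1))
  data.frame(
    muM  = log2(p0 / (1 - p0)),
    varM = 1 / (log(2)^2 * K * p0 * (1 - p0))
  )
}

#' Exact null moments of M by binomial enumeration
#'
#' Enumerates every outcome x in 0..K of the Binomial(K, p0) split, applies
#' the same pseudocount rule as [compute_ma()], and returns the exact mean
#' and variance of M. Used to validate the delta-method approximation; at
#' screening depths (K >= 100) the two agree to within a few percent.
#'
#' @param K Scalar combined count, K >= 1.
#' @param p0 Scalar null proportion in (0, 1).
#' @param pseudocount Pseudocount applied to both counts.
#' @return A data.frame with columns \code{muM} and \code{varM}.
#' @export
rsm_null_moments_exact <- function(K, p0, pseudocount = 0.5) {
  stopifnot(length(K) == 1, K >= 1, p0 > 0, p0 < 1)
  x <- 0:K
  w <- stats::dbinom(x, K, p0)
  m <- log2(x + pseudocount) - log2(K - x + pseudocount)
  mu <- sum(w * m)
  data.frame(muM = mu, varM = sum(w * (m - mu)^2))
}

#' Random-sampling-model z-score for one gene between two libraries
#'
#' The deviation of the observed M from its random-sampling expectation,
#' in units of the null standard deviation:
#' \deqn{z = (M - E[M]) / \sqrt{Var(M)}}
#' with K = c1 + c2 and p0 = n1 / (n1 + n2). Library-size differences
#' enter through p0 only, keeping counts integral.
#'
#' @param c1,c2 Count vectors.
#' @param n1,n2 Library totals (scalars or vectors), strictly positive.
#' @param pseudocount Pseudocount for the M computation.
#' @return Numeric z vector; \code{NA} where K = 0 (no information).
#' @export
rsm_zscore <- function(c1, c2, n1, n2, pseudocount = 0.5) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  if (any(c1 < 0) || any(c2 < 0)) stop("counts must be non-negative")
  K <- c1 + c2
  p0 <- n1 / (n1 + n2)
  M <- compute_ma(c1, c2, pseudocount)$M
  z <- rep(NA_real_, length(M))
  ok <- K > 0
  if (any(ok)) {
    mom <- rsm_null_moments(K[ok], if (length(p0) > 1) p0[ok] else p0)
    z[ok] <- (M[ok] - mom$muM) / sqrt(mom$varM)
  }
  z
}

#' Two-sided normal tail probability for a z-score
#'
#' @param z Finite numeric vector.
#' @return p = 2 (1 - Phi(|z|)).
#' @export
two_sided_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Normal quantile-quantile pairing and normality index
#'
#' Orders the values and pairs them with standard-normal quantiles at
#' plotting positions (i - 0.5) / n; the Pearson correlation of the pairs
#' is returned as a normality index (1 for exactly normal spacing).
#'
#' @param values At least 3 finite values.
#' @return List with \code{theoretical}, \code{sample} (ordered pairs) and
#'   \code{correlation}.
#' @export
qq_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 finite values")
  if (stats::sd(values) == 0) {
    stop("values are constant; normality index undefined")
  }
  s <- sort(values)
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  list(theoretical = q, sample = s,
       correlation = stats::cor(q, s))
}
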