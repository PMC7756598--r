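#' Exact null distribution of the weighted prediction statistic
#'
#' Under the null the m prediction outcomes are independent Bernoulli(phi0),
#' so the statistic \eqn{T_m = \sum_i p_i w_i} is a weighted sum of Bernoulli
#' indicators. Its exact distribution is obtained by enumerating all
#' \eqn{2^m} outcome vectors, each contributing probability
#' \eqn{\phi_0^{\sum p_i} (1-\phi_0)^{m - \sum p_i}} at the value
#' \eqn{p^T w}; the enumeration is carried out as an iterative convolution
#' over endpoints, merging statistic values that coincide within
#' `tie_tolerance`.
#'
#' @param w endpoint weights ([compute_weights()] object or numeric vector).
#' @param phi0 null predictive ability, in (0, 1).
#' @param tie_tolerance absolute tolerance for merging equal statistic
#'   values (and for tail inclusion in [exact_pvalue()]).
#' @param max_m enumeration cap; beyond this many endpoints use
#'   [normal_pvalue()].
#'
#' @return An object of class `"exact_null_distribution"`: list with sorted
#'   `support`, matching `probs`, `phi0`, `tie_tolerance`, and the weight
#'   summaries `W` and `sumsq`. The probabilities sum to 1; the mean and
#'   variance equal \eqn{\phi_0 W} and \eqn{\phi_0(1-\phi_0)\sum w_i^2}.
#'
#' @examples
#' w <- compute_weights(diag(4))
#' d <- exact_null_distribution(w, 0.5)   # Binomial(4, .5) on {0,...,4}
#' cbind(d$support, d$probs)
#' @export
exact_null_distribution <- function(w, phi0, tie_tolerance = 1e-9, max_m = 25) {
  w <- .as_weights(w)
  .check_phi0(phi0)
  if (w$m > max_m)
    stop("m = ", w$m, " exceeds the enumeration cap (", max_m,
         "); use the normal approximation (normal_pvalue) or a Monte-Carlo p-value")
  support <- 0
  probs <- 1
  for (wi in w$w) {
    v <- c(support, support + wi)
    p <- c(probs * (1 - phi0), probs * phi0)
    o <- order(v)
    v <- v[o]
    p <- p[o]
    grp <- cumsum(c(TRUE, diff(v) > tie_tolerance))
    support <- v[!duplicated(grp)]
    probs <- as.vector(rowsum(p, grp))
  }
  structure(
    list(support = support, probs = probs, phi0 = phi0,
         tie_tolerance = tie_tolerance, W = w$W, sumsq = w$sumsq, m = w$m),
    class = "exact_null_distribution"
  )
}

#' @export
print.exact_null_distribution <- function(x, ...) {
  cat("Exact null distribution of the weighted prediction statistic\n")
  cat("  m =", x$m, " phi0 =", x$phi0, " support size =", length(x$support), "\n")
  cat("  mean =", format(sum(x$support * x$probs)),
      " (phi0 * W =", format(x$phi0 * x$W), ")\n")
  invisible(x)
}

#' Exact upper-tail p-value
#'
#' \eqn{P(T \ge t_{obs})} under the enumerated null distribution, with the
#' observed value included in the tail ("as or more extreme"); values within
#' the distribution's tie tolerance of `t_obs` count as equal.
#'
#' @param t_obs observed statistic.
#' @param dist an [exact_null_distribution()] object.
#'
#' @return the p-value.
#' @export
exact_pvalue <- function(t_obs, dist) {
  stopifnot(inherits(dist, "exact_null_distribution"))
  if (!is.finite(t_obs)) stop("t_obs must be finite")
  sum(dist$probs[dist$support >= t_obs - dist$tie_tolerance])
}

## Meet-in-the-middle tail probability for the weighted Bernoulli sum:
## P(T >= t) (upper = TRUE) or P(T <= t) (upper = FALSE) without building
## the full 2^m support. Splits the weights into two halves, enumerates
## 2^(m/2) partial sums each, and combines by a sorted scan. Used in the
## simulation loops where the full pmf is not needed.
.enum_half <- function(w, phi0) {
  s <- 0
  p <- 1
  for (wi in w) {
    s <- c(s, s + wi)
    p <- c(p * (1 - phi0), p * phi0)
  }
  o <- order(s)
  list(s = s[o], p = p[o])
}

.mitm_halves <- function(w, phi0) {
  w <- .as_weights(w)
  h <- w$m %/% 2
  A <- .enum_half(w$w[seq_len(h)], phi0)
  B <- .enum_half(w$w[-seq_len(h)], phi0)
  list(A = A, B = B,
       suffixB = rev(cumsum(rev(B$p))),   # P(B >= B$s[i])
       prefixB = cumsum(B$p))             # P(B <= B$s[i])
}

## single evaluation point against precomputed halves
.mitm_prob <- function(halves, t, tie_tolerance = 1e-9, upper = TRUE) {
  A <- halves$A
  B <- halves$B
  nB <- length(B$s)
  if (upper) {
    ## P(A + B >= t - tol) = sum_a pA(a) * P(B >= t - tol - a)
    thr <- (t - tie_tolerance) - A$s
    idx <- findInterval(thr - 1e-12, B$s) + 1L  # first B >= thr
    pv <- c(halves$suffixB, 0)[pmin(idx, nB + 1L)]
  } else {
    ## P(A + B <= t + tol)
    thr <- (t + tie_tolerance) - A$s
    idx <- findInterval(thr + 1e-12, B$s)       # last B <= thr
    pv <- c(0, halves$prefixB)[idx + 1L]
  }
  sum(A$p * pv)
}

.tail_prob <- function(w, phi0, t, tie_tolerance = 1e-9, upper = TRUE) {
  .mitm_prob(.mitm_halves(w, phi0), t, tie_tolerance = tie_tolerance,
             upper = upper)
}

#' Normal-approximation p-value
#'
#' For many endpoints the statistic is approximately
#' \eqn{Normal(\mu, \sigma)} with \eqn{\mu = \phi_0 W} and
#' \eqn{\sigma = \sqrt{\phi_0 (1-\phi_0) \sum_i w_i^2}}. Returns the
#' upper-tail probability \eqn{1 - \Phi((t_{obs} - \mu)/\sigma)}. No
#' continuity correction is applied: the support of the statistic is
#' irregular, so no half-width is well defined.
#'
#' @param t_obs observed statistic.
#' @param w endpoint weights.
#' @param phi0 null predictive ability, in (0, 1).
#'
#' @return the approximate p-value.
#' @export
normal_pvalue <- function(t_obs, w, phi0) {
  w <- .as_weights(w)
  .check_phi0(phi0)
  if (!is.finite(t_obs)) stop("t_obs must be finite")
  sigma <- sqrt(phi0 * (1 - phi0) * w$sumsq)
  if (sigma == 0) stop("degenerate null distribution: sigma = 0")
  stats::pnorm(t_obs, mean = phi0 * w$W, sd = sigma, lower.tail = FALSE)
}

.check_phi0 <- function(phi0) {
  if (!is.numeric(phi0) || length(phi0) != 1 || !is.finite(phi0) ||
      phi0 <= 0 || phi0 >= 1)
    stop("phi0 must be a single number strictly between 0 and 1")
  invisible(phi0)
}
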