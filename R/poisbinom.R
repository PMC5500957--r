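#' Exact Poisson-binomial distribution via probability generating functions
#'
#' The cohort-level test statistic -- the number of samples carrying a
#' breakpoint at a given feature or gene -- is, under the null, a sum of S
#' independent Bernoulli variables with heterogeneous success probabilities
#' p_1..p_S.  Its exact distribution (the Poisson-binomial) is obtained by
#' expanding the probability generating function
#' \deqn{G(x) = \prod_{s=1}^{S} (1 - p_s + p_s x)}
#' one factor at a time: the coefficient of \eqn{x^t} in the expanded
#' polynomial is \eqn{P(T = t)}.  The expansion costs O(S^2) and is exact up
#' to floating point, so no normal approximation is needed at any cohort
#' size this package targets (hundreds of samples).
#'
#' Upper-tail probabilities are accumulated from the top of the support
#' downwards to limit cancellation, and clamped into [0, 1].
#'
#' @param probs numeric vector of per-trial success probabilities, all in
#'   [0, 1].
#' @return an object of class \code{"poisson_binomial"}: a list with
#'   \describe{
#'     \item{probs}{the input probabilities.}
#'     \item{pmf}{numeric vector of length S + 1; \code{pmf[t + 1]} is
#'       P(T = t).}
#'     \item{tail}{numeric vector of length S + 1; \code{tail[t + 1]} is
#'       P(T >= t), with \code{tail[1] = 1}.}
#'   }
#' @examples
#' pb <- poisson_binomial(c(0.1, 0.2, 0.3))
#' pb$tail[3]  # P(T >= 2) = 0.098
#' @export
poisson_binomial <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) == 0L)
    stop("at least one probability is required")
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("all success probabilities must lie in [0, 1]")
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(pmax(tail, 0), 1)
  tail[1L] <- 1
  structure(list(probs = probs, pmf = pmf, tail = tail),
            class = "poisson_binomial")
}

#' @export
print.poisson_binomial <- function(x, ...) {
  s <- length(x$probs)
  cat("Poisson-binomial null over ", s, " trials (mean ",
      format(sum(x$probs), digits = 4), ")\n", sep = "")
  invisible(x)
}

## P(T >= t) for integer t (vectorized); exact-test p-value convention is
## inclusive of the observed value.
pb_upper_tail <- function(pb, t) {
  t <- as.integer(t)
  out <- numeric(length(t))
  out[t <= 0L] <- 1
  inside <- t > 0L & t <= length(pb$probs)
  out[inside] <- pb$tail[t[inside] + 1L]
  out
}
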