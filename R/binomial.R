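#' Binomial upper-tail probability
#'
#' Probability of observing at least `k` successes in `n` independent trials
#' with per-trial success probability `p0`. This is the null distribution of
#' the vote-counting rule for stable DEGs: under the null, a gene is called a
#' (directional) DEG in each experiment independently with probability `p0`,
#' and the tail measures how surprising `k` concordant calls are.
#'
#' @param k Integer (vectorised), number of successes, `0 <= k <= n`.
#' @param n Integer, number of trials (experiments in which the gene was
#'   measured).
#' @param p0 Per-trial null success probability in `[0, 1)`.
#' @return `P(X >= k)` for `X ~ Binomial(n, p0)`, exact.
#' @seealso [min_consistent_experiments()], [call_stable_degs()]
#' @export
#' @examples
#' binomial_tail(2, 5, 0.05) # < 0.05: two concordant calls out of five suffice
binomial_tail <- function(k, n, p0) {
  stopifnot(all(k >= 0), all(k <= n), n >= 1, p0 >= 0, p0 <= 1)
  pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Minimal number of concordant experiments for a stable DEG
#'
#' The smallest count `k` of concordant per-experiment DEG calls (out of `n`
#' experiments) whose binomial upper-tail probability under the null rate `p0`
#' falls strictly below `alpha`. A gene called a DEG with the same sign in at
#' least this many experiments is declared a stable unidirectional DEG. With
#' the defaults used throughout the package (`n = 5`, `p0 = 0.05`,
#' `alpha = 0.05`) the cutoff is 2: concordant differential expression in two
#' or more of five experiments is already unlikely by chance.
#'
#' @param n Number of experiments in which the gene was measured (`>= 1`).
#' @param p0 Null probability that a single experiment calls the gene a
#'   directional DEG, in `[0, 1)`.
#' @param alpha Significance level in `(0, 1]`; the tail must be `< alpha`
#'   (strict).
#' @return The smallest `k` in `1..n` with `binomial_tail(k, n, p0) < alpha`,
#'   or `n + 1L` if no such `k` exists.
#' @export
#' @examples
#' min_consistent_experiments(5, 0.05, 0.05) # 2
#' min_consistent_experiments(5, 0.10, 0.05) # 3
min_consistent_experiments <- function(n, p0, alpha) {
  stopifnot(length(n) == 1, length(p0) == 1, length(alpha) == 1)
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  if (p0 < 0 || p0 >= 1) abort("`p0` must lie in [0, 1).")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  k <- seq_len(n)
  ok <- binomial_tail(k, n, p0) < alpha
  if (!any(ok)) return(as.integer(n) + 1L)
  as.integer(k[which(ok)[1]])
}
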