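#' Fisher's exact test on a 2x2 table of counts
#'
#' Exact hypergeometric test used throughout the enrichment machinery.
#' The right-sided p-value is the probability, conditional on the table
#' margins, of observing `a` or more successes; the two-sided p-value sums
#' the probabilities of all tables at most as likely as the observed one
#' (the usual conditional convention). The odds ratio reported is the
#' sample odds ratio `a*d / (b*c)`.
#'
#' @param a,b,c,d Cell counts: `a` = in both sets, `b` = first set only,
#'   `c` = second set only, `d` = neither.
#' @param alternative `"greater"` (enrichment, the default) or
#'   `"two.sided"`.
#' @return A list with `odds_ratio`, `p` and the input `table`.
#' @examples
#' fisher_exact(5, 0, 0, 5)$p          # 1/choose(10, 5)
#' fisher_exact(1, 9, 9, 81)$odds_ratio # exactly 1
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # size of first margin
  n <- c + d
  k <- a + c          # size of second margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margin in 2x2 table; p set to 1")
    return(list(odds_ratio = NA_real_, p = 1,
                table = c(a = a, b = b, c = c, d = d)))
  }
  if (alternative == "greater") {
    p <- stats::phyper(a - 1L, m, n, k, lower.tail = FALSE)
  } else {
    # sum over the support of all outcomes no more likely than observed
    support <- max(0L, k - n):min(k, m)
    dens <- stats::dhyper(support, m, n, k)
    p <- sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
    p <- min(p, 1)
  }
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p, table = c(a = a, b = b, c = c, d = d))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around [stats::p.adjust()] kept as a single choke point so
#' every stage of the pipeline adjusts identically.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (step-up, ties share the larger rank).
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Clamp p-values away from zero so BH and log-scale reporting behave;
# values below the smallest normal positive double are not meaningful.
clamp_p <- function(p) pmax(p, .Machine$double.xmin)

# Quartiles under the linear-interpolation ("type 7") convention, stated
# explicitly because extreme-outlier counts depend on it.
quartiles_type7 <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE,
                  na.rm = TRUE)
}

# Derive a child RNG seed from a master seed, stable and < 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
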