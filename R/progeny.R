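#' Progeny distribution of an amplifying progenitor
#'
#' A newborn amplifying neuroprogenitor (ANP) must divide at least \code{a}
#' times and may divide at most \code{b} times; after each division beyond the
#' minimum it keeps proliferating with renewal probability \code{p}. The total
#' number of terminal progeny is \eqn{X = 2^N} where \eqn{N} is the number of
#' divisions, giving
#' \deqn{P(X = 2^a) = 1 - p, \quad P(X = 2^{a+i}) = p^i (1 - p)
#'   \ (1 \le i \le b - a - 1), \quad P(X = 2^b) = p^{b-a}.}
#' The same law, read on \eqn{N} rather than \eqn{2^N}, governs the number of
#' sequential asymmetric divisions of an activated neural stem cell.
#'
#' @param a minimum number of divisions (integer \eqn{\ge 1})
#' @param b maximum number of divisions (integer \eqn{\ge a})
#' @param p renewal probability in \eqn{[0, 1]}
#' @return A data.frame with columns \code{divisions}, \code{progeny}
#'   (\eqn{2^{divisions}}) and \code{prob}; probabilities sum to one.
#' @examples
#' progeny_distribution(1, 4, 0.1)
#' @export
progeny_distribution <- function(a, b, p) {
  check_division_law(a, b, p)
  n <- a:b
  if (a == b) {
    prob <- 1
  } else {
    i <- 0:(b - a)
    prob <- p^i * (1 - p)
    prob[length(prob)] <- p^(b - a)   # terminal mass, not p^(b-a)(1-p)
  }
  data.frame(divisions = n, progeny = 2^n, prob = prob)
}

check_division_law <- function(a, b, p) {
  if (length(a) != 1L || length(b) != 1L || a != round(a) || b != round(b))
    stop("invalid parameter: a and b must be single integers")
  if (a < 1) stop("invalid parameter: minimum number of divisions a must be >= 1")
  if (b < a) stop("invalid parameter: maximum number of divisions b must be >= a")
  if (!is.finite(p) || p < 0 || p > 1)
    stop("invalid parameter: renewal probability p must lie in [0, 1]")
  invisible(TRUE)
}

#' Expected number of divisions
#'
#' Defined as \eqn{\log_2 E[X]} where \eqn{X} is the progeny count from
#' \code{\link{progeny_distribution}}; exactly \code{a} when \code{a == b}.
#'
#' @inheritParams progeny_distribution
#' @return A single number.
#' @examples
#' expected_divisions(1, 4, 0.1)   # 1.17 to two decimals
#' @export
expected_divisions <- function(a, b, p) {
  check_division_law(a, b, p)
  if (a == b) return(as.numeric(a))
  pmf <- progeny_distribution(a, b, p)
  log2(sum(pmf$progeny * pmf$prob))
}

#' Expected number of sequential (asymmetric) divisions
#'
#' The mean of \eqn{N} under the division-number law: the expected number of
#' ANPs emitted by one activated neural stem cell when each division releases
#' a single daughter ANP.
#'
#' @inheritParams progeny_distribution
#' @export
expected_division_count <- function(a, b, p) {
  pmf <- progeny_distribution(a, b, p)
  sum(pmf$divisions * pmf$prob)
}
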