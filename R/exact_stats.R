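# Exact small-sample statistics built on explicit enumeration of the binomial
# and hypergeometric laws. Point probabilities are computed from log binomial
# coefficients; no approximations and no continuity corrections.

#' 2x2 contingency table
#'
#' Rows are groups, columns are outcome present/absent.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` and `b` form the first
#'   row, `c` and `d` the second.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(7, 3, 0, 5)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  a <- check_count(a, "a"); b <- check_count(b, "b")
  c <- check_count(c, "c"); d <- check_count(d, "d")
  if (a + b + c + d == 0L) abort_arg("a..d", "must have at least one positive margin")
  structure(list(a = a, b = b, c = c, d = d), class = "contingency_2x2")
}

as_contingency_2x2 <- function(x) {
  if (inherits(x, "contingency_2x2")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2L, 2L))) {
    return(contingency_2x2(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  }
  abort_arg("table", "must be a contingency_2x2 or a 2x2 matrix")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(group = c("1", "2"), outcome = c("yes", "no")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)` of proportions.
#' @examples
#' wilson_ci(12, 24) # c(0.314, 0.686) to 3 decimals
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  n <- check_count(n, "n", lower = 1L)
  k <- check_count(k, "k")
  if (k > n) abort_arg("k", "must not exceed `n`")
  conf <- check_number(conf, "conf", 0, 1, allow_boundary = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (k + z^2 / 2) / (n + z^2)
  half <- z / (n + z^2) * sqrt(k * (n - k) / n + z^2 / 4)
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# log point probability of the binomial law, from log binomial coefficients
log_dbinom_enum <- function(k, n, p) {
  if (p == 0) return(ifelse(k == 0, 0, -Inf))
  if (p == 1) return(ifelse(k == n, 0, -Inf))
  lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
}

#' Exact binomial test
#'
#' Tail sums of the exact binomial law. The two-sided p-value sums all
#' outcomes whose point probability does not exceed that of the observed
#' count (the minimum-likelihood convention).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`.
#' @return The p-value.
#' @examples
#' binomial_test(12, 24, 0.915) # ~1.4e-7
#' @export
binomial_test <- function(k, n, p0,
                          alternative = c("two.sided", "less", "greater")) {
  n <- check_count(n, "n", lower = 1L)
  k <- check_count(k, "k")
  if (k > n) abort_arg("k", "must not exceed `n`")
  p0 <- check_number(p0, "p0", 0, 1, allow_boundary = FALSE)
  alternative <- match.arg(alternative)
  lp <- vapply(0:n, log_dbinom_enum, numeric(1), n = n, p = p0)
  pr <- exp(lp)
  p <- switch(alternative,
    less = sum(pr[seq_len(k + 1L)]),
    greater = sum(pr[(k + 1L):(n + 1L)]),
    two.sided = sum(pr[pr <= pr[k + 1L] * (1 + 1e-7)])
  )
  min(1, p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Enumerates every table compatible with the observed margins; point
#' probabilities follow the hypergeometric law computed from log binomial
#' coefficients. One-tailed p-values take the tail in the first cell
#' (`"greater"`: enrichment of the outcome in row 1); the two-tailed p-value
#' sums all tables whose point probability does not exceed the observed one.
#'
#' @param table A `contingency_2x2` or 2x2 matrix.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`.
#' @return The p-value. Tables with a zero row or column margin carry no
#'   information about association; these return 1 with attribute
#'   `degenerate = TRUE`.
#' @examples
#' fisher_exact(contingency_2x2(7, 3, 0, 5))             # 0.026
#' fisher_exact(contingency_2x2(7, 0, 4, 8), "greater")  # 0.007
#' @export
fisher_exact <- function(table,
                         alternative = c("two.sided", "less", "greater")) {
  tab <- as_contingency_2x2(table)
  alternative <- match.arg(alternative)
  r1 <- tab$a + tab$b; r2 <- tab$c + tab$d
  c1 <- tab$a + tab$c; c2 <- tab$b + tab$d
  n <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  pr <- exp(lp)
  p_obs <- pr[match(tab$a, support)]
  p <- switch(alternative,
    greater = sum(pr[support >= tab$a]),
    less = sum(pr[support <= tab$a]),
    two.sided = sum(pr[pr <= p_obs * (1 + 1e-7)])
  )
  min(1, p)
}
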