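# Fluctuation-test mutation-rate estimation. Mutant-count distributions follow
# the Luria-Delbruck law under the Lea-Coulson formulation: mutations arrive
# as a Poisson process (expectation m per culture) during exponential
# expansion, and each mutant clone's final size has pmf 1/(j(j+1)). The count
# pmf is computed by the Ma-Sandri-Sarkar recursion
#   p_0 = e^(-m),  p_r = (m/r) * sum_{j=0}^{r-1} p_j / (r - j + 1)
# and m is estimated by maximum likelihood. Partial plating of a culture
# (volume fraction z < 1) binomially thins each mutant's chance of being
# plated; the thinned pmf is obtained by convolving the whole-culture pmf with
# the binomial thinning kernel. Counts above a cap are treated as
# right-censored so jackpot cultures do not force an unbounded pmf support.

#' Fluctuation assay record
#'
#' @param counts Integer vector of mutant colony counts, one parallel culture
#'   per entry (all >= 0).
#' @param n_final Viable cells per culture in the plated sample (>= 1).
#' @param volume_fraction Fraction of each culture that was plated, in (0, 1];
#'   default 1.
#' @return An object of class `fluctuation_assay`.
#' @export
fluctuation_assay <- function(counts, n_final, volume_fraction = 1) {
  if (!is.numeric(counts) || length(counts) < 1L || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    abort_arg("counts", "must be non-negative integers")
  }
  n_final <- check_number(n_final, "n_final", lower = 1)
  volume_fraction <- check_number(volume_fraction, "volume_fraction", 0, 1,
                                  allow_boundary = TRUE)
  if (volume_fraction <= 0) abort_arg("volume_fraction", "must be in (0, 1]")
  structure(list(counts = as.integer(counts), n_final = n_final,
                 volume_fraction = volume_fraction),
            class = "fluctuation_assay")
}

#' Plating efficiency from a co-plating calibration
#'
#' `p_eff = m_c / m_e`, where `m_c` is the number of mutants forming visible
#' colonies on selective medium in combination with an excess
#' non-revertible strain, and `m_e` the number forming colonies when plated
#' alone on permissive medium.
#'
#' @param m_c Colonies in selective co-plating (>= 1; zero efficiency would
#'   make counts uncorrectable and is rejected).
#' @param m_e Colonies on permissive medium (>= 1).
#' @return A list of class `plating_efficiency` with `m_c`, `m_e`, `p_eff`.
#'   Values of `m_c > m_e` are clamped to efficiency 1 with a warning.
#' @export
plating_efficiency <- function(m_c, m_e) {
  m_e <- check_count(m_e, "m_e", lower = 1L)
  m_c <- check_count(m_c, "m_c")
  if (m_c == 0L) {
    stop("`m_c` is zero: a plating efficiency of 0 makes counts ",
         "uncorrectable", call. = FALSE)
  }
  if (m_c > m_e) {
    warning("m_c > m_e; clamping plating efficiency to 1", call. = FALSE)
    m_c <- m_e
  }
  structure(list(m_c = m_c, m_e = m_e, p_eff = m_c / m_e),
            class = "plating_efficiency")
}

#' Correct mutant colony counts for plating efficiency
#'
#' Each count is scaled by `1/p_eff` and rounded to the nearest integer
#' (ties to even), mirroring correction of observed counts to the number of
#' mutants that would have formed colonies at full efficiency.
#'
#' @param counts Non-negative integer counts.
#' @param p_eff Plating efficiency in (0, 1], or a [plating_efficiency()]
#'   object.
#' @return Integer vector of corrected counts.
#' @examples
#' correct_counts(c(2, 4), 0.5) # c(4, 8)
#' @export
correct_counts <- function(counts, p_eff) {
  if (inherits(p_eff, "plating_efficiency")) p_eff <- p_eff$p_eff
  p_eff <- check_number(p_eff, "p_eff", 0, 1)
  if (p_eff <= 0) abort_arg("p_eff", "must be in (0, 1]")
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    abort_arg("counts", "must be non-negative")
  }
  as.integer(round(counts / p_eff))
}

#' Luria-Delbruck mutant-count pmf (Ma-Sandri-Sarkar recursion)
#'
#' @param m Expected mutation events per culture (>= 0).
#' @param max_n Largest count to evaluate.
#' @return Numeric vector of probabilities for counts `0:max_n`.
#' @export
ld_pmf <- function(m, max_n) {
  m <- check_number(m, "m", lower = 0)
  max_n <- check_count(max_n, "max_n")
  p <- numeric(max_n + 1L)
  p[1] <- exp(-m)
  if (max_n >= 1L) {
    for (r in seq_len(max_n)) {
      j <- 0:(r - 1L)
      p[r + 1L] <- (m / r) * sum(p[j + 1L] / (r - j + 1))
    }
  }
  p
}

# pmf of observed (plated) counts 0..max_k when a fraction z of each culture
# is plated: binomial thinning of the whole-culture mutant number. The
# whole-culture pmf is truncated where the thinning kernel has negligible
# mass on counts <= max_k.
ld_pmf_thinned <- function(m, max_k, z) {
  if (z >= 1) return(ld_pmf(m, max_k))
  r_max <- ceiling((max_k + 10 * sqrt(max_k + 25) + 25) / z)
  p_full <- ld_pmf(m, r_max)
  q <- numeric(max_k + 1L)
  r <- 0:r_max
  for (k in 0:max_k) {
    q[k + 1L] <- sum(p_full * stats::dbinom(k, r, z))
  }
  q
}

#' Maximum-likelihood mutation-rate estimate from a fluctuation assay
#'
#' Maximizes the Luria-Delbruck likelihood of the observed counts in the
#' expected-mutations parameter `m`, then divides by the effective number of
#' cells per whole culture (`n_final / volume_fraction`) to obtain a per-cell
#' per-generation rate. The published pipeline order is mirrored: correct
#' counts by `1/p_eff` first (see [correct_counts()]), then estimate; folding
#' the plating efficiency into the likelihood as extra thinning is available
#' via `method = "thin-likelihood"` but off by default.
#'
#' @param assay A [fluctuation_assay()].
#' @param p_eff Plating efficiency in (0, 1] (or [plating_efficiency()]);
#'   default 1 (already-corrected counts).
#' @param method `"correct-first"` (default: scale counts by `1/p_eff`, then
#'   fit) or `"thin-likelihood"` (leave counts as observed and thin the
#'   likelihood by `volume_fraction * p_eff`).
#' @param ci Compute a 95% profile-likelihood interval (1.92 log-likelihood
#'   unit drop)? Default `TRUE`.
#' @param cap Counts above `cap` enter the likelihood as right-censored
#'   (`P(count >= cap)`); default 1000.
#' @return A list of class `rate_estimate`: `m_hat`, `rate`, `ci_low`,
#'   `ci_high`, `boundary` (`TRUE` when all counts are zero, in which case the
#'   rate is 0 and only an upper bound is reported), `n_cultures`.
#' @export
estimate_rate <- function(assay, p_eff = 1,
                          method = c("correct-first", "thin-likelihood"),
                          ci = TRUE, cap = 1000L) {
  if (!inherits(assay, "fluctuation_assay")) {
    abort_arg("assay", "must be a fluctuation_assay")
  }
  method <- match.arg(method)
  if (inherits(p_eff, "plating_efficiency")) p_eff <- p_eff$p_eff
  p_eff <- check_number(p_eff, "p_eff", 0, 1)
  if (p_eff <= 0) abort_arg("p_eff", "must be in (0, 1]")
  cap <- check_count(cap, "cap", lower = 10L)
  counts <- assay$counts
  if (length(counts) < 2L) abort_arg("assay", "needs at least 2 cultures")

  z <- assay$volume_fraction
  if (method == "correct-first") {
    if (p_eff < 1) counts <- correct_counts(counts, p_eff)
  } else {
    z <- z * p_eff
  }
  n_eff <- assay$n_final / assay$volume_fraction # cells per whole culture

  censored <- counts > cap
  obs <- pmin(counts, cap)
  max_k <- max(obs)

  loglik <- function(m) {
    if (m <= 0) return(if (all(obs == 0)) 0 else -Inf)
    q <- ld_pmf_thinned(m, max_k, z)
    q <- pmax(q, 1e-300)
    ll <- sum(log(q[obs[!censored] + 1L]))
    if (any(censored)) {
      tail_p <- pmax(1 - cumsum(q)[max_k], 1e-300)
      ll <- ll + sum(censored) * log(tail_p)
    }
    ll
  }

  if (all(counts == 0)) {
    # likelihood is exp(-n * m * z-ish); only an upper bound is available
    n <- length(counts)
    m_upper <- stats::uniroot(function(m) loglik(m) + 1.92,
                              c(1e-9, 200))$root
    return(structure(list(m_hat = 0, rate = 0, ci_low = 0,
                          ci_high = m_upper / n_eff, boundary = TRUE,
                          n_cultures = n), class = "rate_estimate"))
  }

  # bracket the MLE: p0 method where zeros exist, else mean-based guess
  n_zero <- sum(obs == 0)
  m_guess <- if (n_zero > 0) -log(n_zero / length(obs)) else max(1, log(mean(obs)))
  opt <- stats::optimize(loglik, c(m_guess / 50, m_guess * 50), maximum = TRUE,
                         tol = 1e-7)
  m_hat <- opt$maximum
  ll_max <- opt$objective

  ci_low <- ci_high <- NA_real_
  if (ci) {
    drop_fun <- function(m) loglik(m) - (ll_max - 1.92)
    ci_low <- tryCatch(
      stats::uniroot(drop_fun, c(m_hat / 100, m_hat), tol = 1e-7)$root,
      error = function(e) 0)
    ci_high <- tryCatch(
      stats::uniroot(drop_fun, c(m_hat, m_hat * 100), tol = 1e-7)$root,
      error = function(e) NA_real_)
  }
  structure(list(m_hat = m_hat, rate = m_hat / n_eff,
                 ci_low = ci_low / n_eff, ci_high = ci_high / n_eff,
                 boundary = FALSE, n_cultures = length(counts)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  if (x$boundary) {
    cat(sprintf("rate = 0 (boundary: all %d cultures mutant-free); 95%% upper bound %.3g\n",
                x$n_cultures, x$ci_high))
  } else {
    cat(sprintf("m_hat = %.4g; rate = %.4g per cell per generation (95%% CI %.3g-%.3g; %d cultures)\n",
                x$m_hat, x$rate, x$ci_low, x$ci_high, x$n_cultures))
  }
  invisible(x)
}
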