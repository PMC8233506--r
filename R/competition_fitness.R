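# Serial-transfer competition fitness. Each competition day the mixed culture
# is diluted `dilution`-fold (default 100) into fresh medium and regrows;
# absolute (Malthusian) fitness of a competitor is the natural log of its net
# fold-growth across the assay, including the regrown dilution factor.

#' Construct a serial-transfer competition assay record
#'
#' @param n_a_initial,n_a_final,n_b_initial,n_b_final Colony-forming-unit
#'   counts (or densities in any common unit) for competitors a and b at the
#'   initial and final time points. Only within-competitor ratios enter the
#'   fitness calculus, so any consistent unit works.
#' @param d Competition duration in days (>= 1).
#' @param dilution Fold-dilution applied at each daily transfer; default 100.
#' @return An object of class `competition_assay`.
#' @export
competition_assay <- function(n_a_initial, n_a_final, n_b_initial, n_b_final,
                              d, dilution = 100) {
  for (nm in c("n_a_initial", "n_a_final", "n_b_initial", "n_b_final")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      abort_arg(nm, "must be a single non-negative number")
    }
  }
  d <- check_count(d, "d", lower = 1L)
  dilution <- check_number(dilution, "dilution", lower = 1, allow_boundary = FALSE)
  structure(list(n_a_initial = n_a_initial, n_a_final = n_a_final,
                 n_b_initial = n_b_initial, n_b_final = n_b_final,
                 d = d, dilution = dilution),
            class = "competition_assay")
}

#' Absolute (Malthusian) fitness over a serial-transfer competition
#'
#' Computes `ln(dilution^d * n_f / n_i)`: the log net fold-growth needed to
#' offset `d` days of dilution and produce the observed count change.
#'
#' @param n_i,n_f Initial and final counts (> 0).
#' @param d Days of competition (>= 1).
#' @param dilution Daily fold-dilution; default 100.
#' @return Malthusian fitness (dimensionless log units per assay).
#' @examples
#' absolute_fitness(100, 100, d = 1) # ln(100) = 4.605
#' @export
absolute_fitness <- function(n_i, n_f, d, dilution = 100) {
  d <- check_count(d, "d", lower = 1L)
  dilution <- check_number(dilution, "dilution", lower = 1, allow_boundary = FALSE)
  if (!is.numeric(n_f) || length(n_f) != 1L || !is.finite(n_f) || n_f <= 0) {
    if (is.numeric(n_f) && length(n_f) == 1L && is.finite(n_f) && n_f == 0) {
      stop("final count is zero: competitor went extinct during the assay, ",
           "Malthusian fitness is undefined (-Inf)", call. = FALSE)
    }
    abort_arg("n_f", "must be a single positive count")
  }
  if (!is.numeric(n_i) || length(n_i) != 1L || !is.finite(n_i) || n_i <= 0) {
    abort_arg("n_i", "must be a single positive count")
  }
  d * log(dilution) + log(n_f / n_i)
}

#' Relative fitness and selection coefficient from one competition
#'
#' `w_rel = w_a / w_b` and `s = w_rel - 1`, where `w_a`, `w_b` are the
#' competitors' absolute Malthusian fitnesses.
#'
#' @param assay A [competition_assay()].
#' @return A list of class `fitness_result` with elements `w_a`, `w_b`,
#'   `w_rel`, `s`.
#' @export
relative_fitness <- function(assay) {
  if (!inherits(assay, "competition_assay")) {
    abort_arg("assay", "must be a competition_assay")
  }
  w_a <- absolute_fitness(assay$n_a_initial, assay$n_a_final, assay$d, assay$dilution)
  w_b <- absolute_fitness(assay$n_b_initial, assay$n_b_final, assay$d, assay$dilution)
  if (w_b == 0) {
    stop("competitor b has zero Malthusian fitness; relative fitness is ",
         "undefined", call. = FALSE)
  }
  structure(list(w_a = w_a, w_b = w_b, w_rel = w_a / w_b, s = w_a / w_b - 1),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("w_a = %.4f, w_b = %.4f, w_rel = %.4f, s = %+.4f\n",
              x$w_a, x$w_b, x$w_rel, x$s))
  invisible(x)
}

#' Summarize replicate competitions per strain pair
#'
#' Computes per-replicate relative fitness, then the per-pair mean and
#' t-based 95% confidence interval. Replicates in which a competitor went
#' extinct (a zero final count) are flagged and excluded, with a message.
#'
#' @param assays Data frame with one replicate per row and columns `pair`,
#'   `n_a_initial`, `n_a_final`, `n_b_initial`, `n_b_final`, `d` and
#'   optionally `dilution`.
#' @param conf Confidence level; default 0.95.
#' @return Data frame with one row per pair: `pair`, `n_reps`, `n_excluded`,
#'   `mean_w_rel`, `ci_low`, `ci_high` (CI is `NA` with a warning when only a
#'   single usable replicate exists).
#' @export
batch_fitness <- function(assays, conf = 0.95) {
  need <- c("pair", "n_a_initial", "n_a_final", "n_b_initial", "n_b_final", "d")
  if (!is.data.frame(assays) || !all(need %in% names(assays))) {
    abort_arg("assays", paste("must be a data frame with columns",
                              paste(need, collapse = ", ")))
  }
  if (is.null(assays$dilution)) assays$dilution <- 100
  conf <- check_number(conf, "conf", 0, 1, allow_boundary = FALSE)

  out <- lapply(split(assays, assays$pair), function(rows) {
    extinct <- rows$n_a_final == 0 | rows$n_b_final == 0
    if (any(extinct)) {
      message(sprintf("pair %s: excluding %d replicate(s) with an extinct competitor",
                      rows$pair[1], sum(extinct)))
      rows <- rows[!extinct, , drop = FALSE]
    }
    w <- vapply(seq_len(nrow(rows)), function(i) {
      relative_fitness(competition_assay(
        rows$n_a_initial[i], rows$n_a_final[i],
        rows$n_b_initial[i], rows$n_b_final[i],
        rows$d[i], rows$dilution[i]))$w_rel
    }, numeric(1))
    n <- length(w)
    if (n == 0L) {
      return(data.frame(pair = rows$pair[1], n_reps = 0L,
                        n_excluded = sum(extinct),
                        mean_w_rel = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_))
    }
    if (n == 1L) {
      warning(sprintf("pair %s: single replicate, no confidence interval",
                      rows$pair[1]), call. = FALSE)
      ci <- c(NA_real_, NA_real_)
    } else {
      half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(w) / sqrt(n)
      ci <- mean(w) + c(-half, half)
    }
    data.frame(pair = rows$pair[1], n_reps = n, n_excluded = sum(extinct),
               mean_w_rel = mean(w), ci_low = ci[1], ci_high = ci[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
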