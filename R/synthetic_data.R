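# Generators for every laboratory-shaped input the analysis consumes:
# plate-reader OD time series, Luria-Delbruck fluctuation-assay colony counts,
# two-strain competition plate counts, and clone-by-locus mutation incidence
# tables. All generators take an explicit seed and are bit-reproducible.

#' Measurement-noise model for synthetic data
#'
#' @param od_sd Additive standard deviation on optical-density readings
#'   (OD units, >= 0). Noise is Gaussian truncated at zero so readings stay
#'   physical.
#' @param count_sampling Plating-noise family for count data:
#'   `"multinomial"` (default), `"poisson"`, or `"none"` (deterministic
#'   expected counts).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(od_sd = 0.005,
                        count_sampling = c("multinomial", "poisson", "none")) {
  od_sd <- check_number(od_sd, "od_sd", lower = 0)
  count_sampling <- match.arg(count_sampling)
  structure(list(od_sd = od_sd, count_sampling = count_sampling),
            class = "noise_model")
}

#' Generate a synthetic plate-reader growth curve
#'
#' Readings at `t = 0, interval, 2*interval, ... <= horizon` follow the exact
#' Baranyi-Roberts trajectory plus additive Gaussian noise truncated at zero.
#'
#' @param params [growth_params()] of the simulated strain.
#' @param horizon Duration in hours (> 0); default 24.
#' @param interval Reading interval in minutes (> 0); default 5, the usual
#'   plate-reader cadence.
#' @param noise A [noise_model()]; default `noise_model()`.
#' @param seed Integer seed.
#' @return Data frame with columns `time` (hours) and `od`.
#' @export
gen_growth_curve <- function(params, horizon = 24, interval = 5,
                             noise = noise_model(), seed = 1) {
  if (!inherits(params, "growth_params")) {
    abort_arg("params", "must be a growth_params object")
  }
  horizon <- check_number(horizon, "horizon", lower = 0, allow_boundary = FALSE)
  interval <- check_number(interval, "interval", lower = 0, allow_boundary = FALSE)
  if (!inherits(noise, "noise_model")) abort_arg("noise", "must be a noise_model")
  times <- seq(0, horizon, by = interval / 60)
  clean <- br_trajectory(params, times)
  od <- local_seed(seed, {
    if (noise$od_sd > 0) pmax(0, clean + stats::rnorm(length(clean), 0, noise$od_sd))
    else clean
  })
  data.frame(time = times, od = od)
}

#' Generate Luria-Delbruck-distributed mutant counts
#'
#' Simulates mutation occurrence per doubling generation of an expanding
#' culture: at each doubling, every newborn cell mutates with probability
#' `rate`, and each mutant clone then doubles deterministically with the rest
#' of the culture, so a mutation arising `g` doublings before the end
#' contributes `2^g` mutants. The expected number of mutation events per
#' culture is `m = rate * n_final` (one mutation opportunity per cell
#' division).
#'
#' @param rate Mutation rate per cell per generation, in [0, 1).
#' @param n_final Final cells per culture (>= 1).
#' @param n_cultures Number of parallel cultures (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of mutant counts, one per culture.
#' @export
gen_fluctuation_counts <- function(rate, n_final, n_cultures, seed = 1) {
  rate <- check_number(rate, "rate", lower = 0, upper = 1)
  if (rate >= 1) abort_arg("rate", "must be in [0, 1)")
  n_final <- check_number(n_final, "n_final", lower = 1)
  n_cultures <- check_count(n_cultures, "n_cultures", lower = 1L)
  if (rate == 0) return(rep.int(0L, n_cultures))

  n_gen <- ceiling(log2(n_final))
  sizes <- round(n_final / 2^(n_gen:0)) # population size after each doubling
  newborn <- pmax(diff(sizes), 0)
  clone_size <- 2^((n_gen - 1):0) # final descendants of a mutation per epoch

  local_seed(seed, {
    vapply(seq_len(n_cultures), function(i) {
      events <- stats::rbinom(length(newborn), newborn, rate)
      sum(events * clone_size)
    }, numeric(1))
  })
}

#' Generate plate counts from a synthetic two-strain competition
#'
#' Inverts the serial-transfer fitness calculus: given a target relative
#' fitness `w_ratio` of competitor a over b, a 1:1 initial mix, and `d` days
#' of `dilution`-fold transfers with the total density returning to the same
#' stationary level each day, the final frequency `f_a` solves
#' `ln(dilution^d * f_a / 0.5) = w_ratio * ln(dilution^d * (1 - f_a) / 0.5)`.
#' Plated counts are then drawn around the initial and final frequencies.
#'
#' @param w_ratio Target relative fitness (> 0).
#' @param n_plated_initial,n_plated_final Total colonies counted at the
#'   initial and final platings (>= 1).
#' @param d Competition days (>= 1).
#' @param dilution Daily fold-dilution; default 100.
#' @param noise A [noise_model()]; `count_sampling` selects multinomial
#'   (default), Poisson, or deterministic plating.
#' @param seed Integer seed.
#' @return A [competition_assay()]; the attribute `truth` records the target
#'   `w_ratio` and the noiseless final frequency.
#' @export
gen_competition_counts <- function(w_ratio, n_plated_initial, n_plated_final,
                                   d, dilution = 100, noise = noise_model(),
                                   seed = 1) {
  w_ratio <- check_number(w_ratio, "w_ratio", lower = 0, allow_boundary = FALSE)
  n_plated_initial <- check_count(n_plated_initial, "n_plated_initial", lower = 1L)
  n_plated_final <- check_count(n_plated_final, "n_plated_final", lower = 1L)
  d <- check_count(d, "d", lower = 1L)
  if (!inherits(noise, "noise_model")) abort_arg("noise", "must be a noise_model")

  x <- 0.5
  gap <- function(f) {
    log(dilution^d * f / x) - w_ratio * log(dilution^d * (1 - f) / (1 - x))
  }
  f_a <- stats::uniroot(gap, c(1e-12, 1 - 1e-12), tol = 1e-14)$root

  draw <- function(n_total, freq) {
    switch(noise$count_sampling,
      none = {
        a <- round(n_total * freq)
        c(a, n_total - a)
      },
      multinomial = as.vector(stats::rmultinom(1L, n_total, c(freq, 1 - freq))),
      poisson = c(stats::rpois(1L, n_total * freq),
                  stats::rpois(1L, n_total * (1 - freq)))
    )
  }
  counts <- local_seed(seed, list(initial = draw(n_plated_initial, x),
                                  final = draw(n_plated_final, f_a)))
  assay <- competition_assay(
    n_a_initial = counts$initial[1], n_a_final = counts$final[1],
    n_b_initial = counts$initial[2], n_b_final = counts$final[2],
    d = d, dilution = dilution)
  attr(assay, "truth") <- list(w_ratio = w_ratio, f_a_final = f_a)
  assay
}

#' Generate clone-by-locus mutation profiles with tunable sharing
#'
#' The locus pool is split into a group-a signature half and a group-b
#' signature half. A clone carries each locus of its own group's signature
#' with probability `p_within` and each locus of the other group's signature
#' with probability `p_shared`, plus `n_private` loci unique to the clone.
#' Expected pairwise Dice similarity is then higher within groups than
#' between exactly when `p_within != p_shared` (the shared-intersection rate
#' is `p_within^2 + p_shared^2` within versus `2 p_within p_shared` between,
#' and the difference is `(p_within - p_shared)^2`); at
#' `p_within == p_shared` the groups are exchangeable, giving a null
#' generator for permutation tests.
#'
#' @param n_group_a,n_group_b Clones per group (>= 1).
#' @param pool_size Total loci in the shared pool (>= 2; split evenly between
#'   the two signatures).
#' @param p_within Probability of carrying an own-signature locus, in [0, 1].
#' @param p_shared Probability of carrying an other-signature locus, in [0, 1].
#' @param n_private Private loci per clone (default 0).
#' @param seed Integer seed.
#' @return List of [mutation_profile()] objects, groups labelled `"a"`/`"b"`.
#' @export
gen_mutation_profiles <- function(n_group_a, n_group_b, pool_size,
                                  p_within, p_shared, n_private = 0L,
                                  seed = 1) {
  n_group_a <- check_count(n_group_a, "n_group_a", lower = 1L)
  n_group_b <- check_count(n_group_b, "n_group_b", lower = 1L)
  pool_size <- check_count(pool_size, "pool_size", lower = 2L)
  p_within <- check_probability(p_within, "p_within")
  p_shared <- check_probability(p_shared, "p_shared")
  n_private <- check_count(n_private, "n_private")

  half <- pool_size %/% 2L
  sig_a <- sprintf("locusA%03d", seq_len(half))
  sig_b <- sprintf("locusB%03d", seq_len(pool_size - half))

  local_seed(seed, {
    make_clone <- function(id, group) {
      own <- if (group == "a") sig_a else sig_b
      other <- if (group == "a") sig_b else sig_a
      loci <- c(own[stats::runif(length(own)) < p_within],
                other[stats::runif(length(other)) < p_shared])
      if (n_private > 0L) {
        loci <- c(loci, sprintf("private_%s_%02d", id, seq_len(n_private)))
      }
      mutation_profile(clone_id = id, group = group, loci = loci)
    }
    c(lapply(seq_len(n_group_a), function(i) make_clone(sprintf("a%02d", i), "a")),
      lapply(seq_len(n_group_b), function(i) make_clone(sprintf("b%02d", i), "b")))
  })
}

#' Write a generated table with a JSON parameter sidecar
#'
#' Writes tidy CSV plus `<path>.json` recording the generator parameters and
#' seed, so every synthetic dataset is traceable.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param params Named list of generator parameters (include the seed).
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(x, path, params = list()) {
  utils::write.csv(x, path, row.names = FALSE)
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
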