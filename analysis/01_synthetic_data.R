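#!/usr/bin/env Rscript
# Generate one example of every laboratory-shaped input the analysis consumes
# (plate-reader OD curves, fluctuation-assay counts, competition plate counts,
# clone-by-locus mutation tables) and write them, with JSON parameter
# sidecars, under results/synthetic/.

library(epistasim)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923L

## plate-reader growth curves: an ancestral-like strain (5.00 h lag) and a
## focal-mutant-like strain (3.87 h lag), read every 5 min for 24 h
strain <- function(lag) growth_params(y0 = 0.01, r = 0.8, k = 1.2, nu = 1.3,
                                      q0 = 1 / expm1(0.9 * lag), v = 0.9)
for (s in c(5.00, 3.87)) {
  curve <- gen_growth_curve(strain(s), horizon = 24, interval = 5,
                            noise = noise_model(od_sd = 0.005), seed = seed)
  write_synthetic(curve, file.path(out, sprintf("od_curve_lag%.2fh.csv", s)),
                  params = list(lag_h = s, od_sd = 0.005, interval_min = 5,
                                seed = seed))
}
message("wrote two 289-reading OD curves (lag 5.00 h and 3.87 h)")

## fluctuation assay at the ancestral mutation-rate scale (m ~ 5 per culture)
counts <- gen_fluctuation_counts(rate = 1.72e-7, n_final = 2.9e7,
                                 n_cultures = 10, seed = seed)
write_synthetic(data.frame(culture = seq_along(counts), mutants = counts),
                file.path(out, "fluctuation_counts.csv"),
                params = list(rate = 1.72e-7, n_final = 2.9e7, seed = seed))
message("fluctuation counts (10 cultures): ", paste(counts, collapse = ", "),
        " - note the jackpot skew")

## competition plate counts engineered around an 8.31% focal benefit
assay <- gen_competition_counts(w_ratio = 1.0831, n_plated_initial = 500,
                                n_plated_final = 500, d = 1, seed = seed)
write_synthetic(data.frame(time = c("initial", "final"),
                           n_a = c(assay$n_a_initial, assay$n_a_final),
                           n_b = c(assay$n_b_initial, assay$n_b_final)),
                file.path(out, "competition_counts.csv"),
                params = list(w_ratio = 1.0831, d = 1, seed = seed))
message(sprintf("competition assay at 500 colonies/plate estimates s = %+.3f (truth +0.0831)",
                relative_fitness(assay)$s))

## clone-by-locus mutation incidence, contingent scenario (asymmetric sharing)
profiles <- gen_mutation_profiles(n_group_a = 8, n_group_b = 8,
                                  pool_size = 60, p_within = 0.3,
                                  p_shared = 0.1, n_private = 2, seed = seed)
long <- do.call(rbind, lapply(profiles, function(p) {
  data.frame(clone_id = p$clone_id, group = p$group, locus = p$loci)
}))
write_synthetic(long, file.path(out, "mutation_profiles.csv"),
                params = list(p_within = 0.3, p_shared = 0.1, pool_size = 60,
                              n_private = 2, seed = seed))
message("wrote mutation profiles for 8 + 8 clones")
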