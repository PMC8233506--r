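#!/usr/bin/env Rscript
# Mutation-set parallelism and the exact statistics behind the contingency
# claims: Dice similarity within and between clone groups against a
# label-permutation null, plus the Wilson interval, exact binomial test and
# Fisher tests on the published contingency tables.

library(epistasim)

dir.create("results", showWarnings = FALSE)
seed <- 20260923L

## similarity under a contingent scenario (groups share less across than within)
contingent <- gen_mutation_profiles(8, 8, 60, p_within = 0.3, p_shared = 0.1,
                                    n_private = 2, seed = seed)
res_c <- permutation_test(contingent, n_perm = 1000, seed = seed + 1L)
print(res_c)

## and under the exchangeable null
null <- gen_mutation_profiles(8, 8, 60, p_within = 0.2, p_shared = 0.2,
                              n_private = 2, seed = seed + 2L)
res_n <- permutation_test(null, n_perm = 1000, seed = seed + 3L)
print(res_n)

simil <- data.frame(
  scenario = c("contingent", "null"),
  within_a = c(res_c$within["a"], res_n$within["a"]),
  within_b = c(res_c$within["b"], res_n$within["b"]),
  between = c(res_c$between, res_n$between),
  p_between = c(res_c$p_between, res_n$p_between))
write.csv(simil, "results/similarity.csv", row.names = FALSE)

## exact statistics on the published contingency tables
ci <- wilson_ci(12, 24, 0.95)
stats_tbl <- data.frame(
  statistic = c("wilson_low_pct", "wilson_high_pct",
                "binomial_p_12_24_vs_0.915",
                "fisher_env_7_3_vs_0_5_two_tailed",
                "fisher_uspb_7_0_vs_4_8_one_tailed",
                "fisher_regime_1_4_vs_7_3_two_tailed"),
  value = c(100 * ci[["low"]], 100 * ci[["high"]],
            binomial_test(12, 24, 0.915),
            as.numeric(fisher_exact(contingency_2x2(7, 3, 0, 5))),
            as.numeric(fisher_exact(contingency_2x2(7, 0, 4, 8), "greater")),
            as.numeric(fisher_exact(contingency_2x2(1, 4, 7, 3)))))
print(stats_tbl, row.names = FALSE)
write.csv(stats_tbl, "results/exact_statistics.csv", row.names = FALSE)
message("12/24 observed substitutions sit well below any >91% simulated expectation (binomial p < 0.001)")
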