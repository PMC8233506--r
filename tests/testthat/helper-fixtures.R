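# Shared fixtures, built in code.

# ancestor-like Baranyi-Roberts parameter set: ~5 h lag, saturation near
# 1.2 OD within 24 h
ancestor_growth <- function(lag = 5, v = 0.9) {
  growth_params(y0 = 0.01, r = 0.8, k = 1.2, nu = 1.3,
                q0 = 1 / expm1(v * lag), v = v)
}

# small Wright-Fisher configuration for fast unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_pop = 200, u_genome = 0, mu_focal = 1e-5, s_focal = 0.08,
         horizon = 100, fix_threshold = 0.95),
    list(...))
  do.call(sim_config, args)
}

# brute-force Luria-Delbruck pmf: compound Poisson of clone sizes with
# pmf 1/(j(j+1)), by direct convolution (independent of the MSS recursion)
brute_ld_pmf <- function(m, kmax, n_mut_max = 80) {
  clone <- c(0, 1 / ((1:kmax) * (2:(kmax + 1))))
  cur <- c(1, rep(0, kmax))
  total <- dpois(0, m) * cur
  for (k in seq_len(n_mut_max)) {
    new <- numeric(kmax + 1)
    for (n in 0:kmax) {
      j <- 0:n
      new[n + 1] <- sum(cur[j + 1] * clone[n - j + 1])
    }
    cur <- new
    total <- total + dpois(k, m) * cur
  }
  total
}

# exhaustive mean pairwise Dice over explicit pair enumeration
brute_group_means <- function(profiles) {
  groups <- vapply(profiles, function(p) p$group, character(1))
  labels <- sort(unique(groups))
  vals <- list(within = setNames(numeric(0), character(0)), between = NULL)
  for (g in labels) {
    idx <- which(groups == g)
    sims <- c()
    if (length(idx) >= 2) {
      for (i in idx) for (j in idx) if (i < j) {
        sims <- c(sims, dice(profiles[[i]], profiles[[j]]))
      }
      vals$within[g] <- mean(sims)
    } else {
      vals$within[g] <- NA_real_
    }
  }
  sims <- c()
  for (i in which(groups == labels[1])) {
    for (j in which(groups == labels[2])) {
      sims <- c(sims, dice(profiles[[i]], profiles[[j]]))
    }
  }
  vals$between <- mean(sims)
  vals
}
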