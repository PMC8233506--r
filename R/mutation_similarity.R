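# Parallelism of mutation sets between sequenced clones: Sorensen-Dice
# similarity on sets of mutated loci, within- versus between-group means, and
# a label-permutation null. Locus identity is whatever granularity the
# profiles carry (typically gene-level labels, so two different substitutions
# in the same gene count as shared; pass position-level identifiers for
# position-level matching).

#' Mutation profile of one sequenced clone
#'
#' @param clone_id Clone label.
#' @param group Group label (e.g. focal-allele fixed vs. not).
#' @param loci Character vector of mutated locus identifiers; duplicates are
#'   collapsed (the profile is a set). May be empty.
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(clone_id, group, loci) {
  if (!is.character(clone_id) || length(clone_id) != 1L) {
    abort_arg("clone_id", "must be a single string")
  }
  if (!is.character(group) || length(group) != 1L) {
    abort_arg("group", "must be a single string")
  }
  loci <- unique(as.character(loci))
  structure(list(clone_id = clone_id, group = group, loci = loci),
            class = "mutation_profile")
}

#' Read mutation profiles from a long-format table
#'
#' @param x Data frame with columns `clone_id`, `group`, `locus` (one row per
#'   mutated locus per clone), or a path to such a CSV file.
#' @return List of [mutation_profile()] objects.
#' @export
read_mutation_profiles <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- utils::read.csv(x)
  need <- c("clone_id", "group", "locus")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort_arg("x", "must be a data frame (or CSV) with columns clone_id, group, locus")
  }
  ids <- unique(x$clone_id)
  lapply(ids, function(id) {
    rows <- x[x$clone_id == id, , drop = FALSE]
    mutation_profile(as.character(id), as.character(rows$group[1]),
                     as.character(rows$locus))
  })
}

#' Sorensen-Dice similarity between two locus sets
#'
#' `2 |a intersect b| / (|a| + |b|)`, bounded between 0 (disjoint) and 1
#' (identical).
#'
#' @param a,b Character vectors of locus identifiers (treated as sets), or
#'   [mutation_profile()] objects.
#' @return Similarity in [0, 1]; `NA` with a warning when both sets are empty
#'   (the coefficient is undefined there, neither 0 nor 1).
#' @examples
#' dice(c("g1", "g2"), c("g2", "g3")) # 0.5
#' @export
dice <- function(a, b) {
  if (inherits(a, "mutation_profile")) a <- a$loci
  if (inherits(b, "mutation_profile")) b <- b$loci
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) {
    warning("both locus sets are empty: Dice similarity undefined", call. = FALSE)
    return(NA_real_)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# all pairwise similarities plus pair metadata; the workhorse shared by the
# group means and the permutation test
pairwise_dice <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  n <- length(profiles)
  pairs <- utils::combn(n, 2)
  sim <- vapply(seq_len(ncol(pairs)), function(j) {
    dice(profiles[[pairs[1, j]]], profiles[[pairs[2, j]]])
  }, numeric(1))
  list(i = pairs[1, ], j = pairs[2, ], sim = sim,
       group = vapply(profiles, function(p) p$group, character(1)))
}

group_means_from_pairs <- function(pw, groups) {
  labels <- sort(unique(groups))
  gi <- groups[pw$i]; gj <- groups[pw$j]
  within <- vapply(labels, function(g) {
    sel <- gi == g & gj == g
    if (!any(sel)) NA_real_ else mean(pw$sim[sel], na.rm = TRUE)
  }, numeric(1))
  between <- mean(pw$sim[gi != gj], na.rm = TRUE)
  list(within = within, between = between)
}

#' Within- and between-group mean Dice similarity
#'
#' Means over all unordered clone pairs: one within-group mean per group and
#' one cross-group mean.
#'
#' @param profiles List of [mutation_profile()] objects spanning exactly two
#'   groups (>= 2 clones overall; a group with a single clone has no within
#'   pairs and gets an `NA` mean with a warning).
#' @return A list: `within` (named numeric, one entry per group), `between`.
#' @export
group_mean_similarity <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    abort_arg("profiles", "must list at least two mutation profiles")
  }
  pw <- pairwise_dice(profiles)
  res <- group_means_from_pairs(pw, pw$group)
  singletons <- names(res$within)[is.na(res$within)]
  if (length(singletons)) {
    warning("group(s) with a single clone have no within-group mean: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  res
}

#' Permutation test of group structure in mutation-set similarity
#'
#' Reassigns clones to group labels uniformly at random (preserving group
#' sizes) and compares each observed statistic (within-group means and the
#' between-group mean) with its permutation distribution. p-values are
#' two-sided by absolute deviation from the permutation mean:
#' `p = (1 + #\{|t_perm - c| >= |t_obs - c|\}) / (1 + n_perm)` with `c` the
#' mean of the permuted statistics.
#'
#' @param profiles List of [mutation_profile()] objects spanning two groups,
#'   with at least two clones per group.
#' @param n_perm Number of permutations (>= 100); default 1000.
#' @param seed Integer seed; identical seed gives identical p-values.
#' @return A list of class `similarity_result`: `within` and `between`
#'   observed means, `p_within` (named per group), `p_between`, `n_perm`.
#' @export
permutation_test <- function(profiles, n_perm = 1000, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm", lower = 100L)
  if (!is.list(profiles) || length(profiles) < 4L) {
    abort_arg("profiles", "needs at least two clones in each of two groups")
  }
  pw <- pairwise_dice(profiles)
  groups <- pw$group
  labels <- sort(unique(groups))
  if (length(labels) != 2L || any(table(groups) < 2L)) {
    abort_arg("profiles", "needs at least two clones in each of two groups")
  }
  obs <- group_means_from_pairs(pw, groups)
  n <- length(profiles)

  perm_stats <- local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      g <- groups[sample.int(n)]
      res <- group_means_from_pairs(pw, g)
      c(res$within, between = res$between)
    }, numeric(length(labels) + 1L))
  })

  p_value <- function(observed, perms) {
    centre <- mean(perms)
    (1 + sum(abs(perms - centre) >= abs(observed - centre) - 1e-12)) / (1 + n_perm)
  }
  p_within <- vapply(seq_along(labels), function(i) {
    p_value(obs$within[i], perm_stats[i, ])
  }, numeric(1))
  names(p_within) <- labels
  structure(list(within = obs$within, between = obs$between,
                 p_within = p_within,
                 p_between = p_value(obs$between, perm_stats[length(labels) + 1L, ]),
                 n_perm = n_perm),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  for (g in names(x$within)) {
    cat(sprintf("within %s: mean Dice = %.3f (p = %.3g)\n",
                g, x$within[g], x$p_within[g]))
  }
  cat(sprintf("between: mean Dice = %.3f (p = %.3g) [%d permutations]\n",
              x$between, x$p_between, x$n_perm))
  invisible(x)
}
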