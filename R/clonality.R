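# Pairwise clonality testing. Two biopsies from the same clone share trunk
# variants; two independent tumors share variants only through chance
# recurrence of (mostly common) variants. The score therefore up-weights
# rare shared variants, and significance comes from a cohort-frequency-
# matched permutation null.

#' Variant weight from cohort frequency
#'
#' `w(v) = -log10(max(freq, f_min))`: a variant seen in half the cohort
#' carries ~0.3 units of evidence, a 1-in-44-patients variant ~1.6. The floor
#' keeps weights finite.
#'
#' @param freq Cohort frequencies in `(0, 1]`.
#' @param f_min Positive frequency floor.
#' @return Non-negative weights.
#' @export
variant_weight <- function(freq, f_min = min(freq)) {
  stopifnot(f_min > 0)
  -log10(pmax(freq, f_min))
}

#' Frequency-weighted clonality score of two variant profiles
#'
#' A cosine-type overlap on rarity weights:
#' `S(A, B) = sum_{v in A&B} w(v) / sqrt(sum_{v in A} w(v) * sum_{v in B} w(v))`.
#' It is symmetric, 0 exactly when the profiles share no variant, and 1
#' exactly when they are identical.
#'
#' @param keys_a,keys_b Character vectors of variant keys
#'   (`chrom:pos:ref:alt`), one per profile; must be non-empty.
#' @param weights Named numeric vector of variant weights covering both
#'   profiles (see [variant_weight()]).
#' @return A score in `[0, 1]`.
#' @export
clonality_score <- function(keys_a, keys_b, weights) {
  keys_a <- unique(keys_a)
  keys_b <- unique(keys_b)
  if (length(keys_a) == 0 || length(keys_b) == 0) {
    abort("clonality score is undefined for an empty variant profile")
  }
  missing <- setdiff(c(keys_a, keys_b), names(weights))
  if (length(missing) > 0) {
    abort(sprintf("no weight for variant(s): %s", paste(head(missing, 3), collapse = ", ")))
  }
  wa <- sum(weights[keys_a])
  wb <- sum(weights[keys_b])
  shared <- sum(weights[intersect(keys_a, keys_b)])
  if (shared == 0) return(0)
  shared / sqrt(wa * wb)
}

#' Permutation p-value for the clonality score of one biopsy pair
#'
#' Under the null that the two profiles are unrelated draws from the cohort
#' variant pool, each permutation redraws variant sets of the observed sizes
#' with probability proportional to cohort frequency (without replacement
#' within a replicate) and rescores. The p-value is
#' `(1 + #\{S_perm >= S_obs\}) / (n_perm + 1)`, so it is never below
#' `1/(n_perm+1)`. A pair sharing no variant has `S_obs = 0` and every null
#' score is `>= 0`, so `p = 1` exactly and no permutations are spent on it.
#'
#' @inheritParams clonality_score
#' @param pool Data frame of the cohort variant pool with columns
#'   `variant_key` and `cohort_freq` (every cohort variant, each once).
#' @param n_perm Number of permutations (at least 99; default 999).
#' @param seed Integer seed for the permutation stream.
#' @param f_min Frequency floor for the weights; defaults to the smallest
#'   pool frequency.
#' @return List with `score`, `p_value`, `n_perm`, `n_shared`, `seed` and
#'   the vector of `null_scores` (empty when permutations were skipped).
#' @export
permutation_pvalue <- function(keys_a, keys_b, pool, n_perm = 999, seed = 1,
                               f_min = NULL) {
  stopifnot(n_perm >= 99)
  keys_a <- unique(keys_a)
  keys_b <- unique(keys_b)
  pool <- distinct(as_tibble(pool), .data$variant_key, .keep_all = TRUE) %>%
    arrange(.data$variant_key) # results must not depend on input row order
  if (max(length(keys_a), length(keys_b)) > nrow(pool)) {
    abort("pool smaller than a profile: cannot draw without replacement")
  }
  if (is.null(f_min)) f_min <- min(pool$cohort_freq)
  w_pool <- variant_weight(pool$cohort_freq, f_min)
  weights <- setNames(w_pool, pool$variant_key)
  s_obs <- clonality_score(keys_a, keys_b, weights)
  n_shared <- length(intersect(keys_a, keys_b))
  if (s_obs == 0) {
    return(list(score = 0, p_value = 1, n_perm = n_perm, n_shared = n_shared,
      seed = seed, null_scores = numeric(0)))
  }
  null_scores <- with_seed(seed, perm_null_scores_cpp(
    length(keys_a), length(keys_b), pool$cohort_freq, w_pool, as.integer(n_perm)
  ))
  p <- (1 + sum(null_scores >= s_obs)) / (n_perm + 1)
  list(score = s_obs, p_value = p, n_perm = n_perm, n_shared = n_shared,
    seed = seed, null_scores = null_scores)
}

#' Binary clonality call from a permutation p-value
#'
#' A pair is called clonal when `p <= alpha_clonal` (boundary inclusive,
#' matching the "p <= 0.05 is significant" convention).
#'
#' @param p_value Permutation p-value(s).
#' @param alpha_clonal Significance level (default 0.05).
#' @return Character vector, `"clonal"` or `"non_clonal"`.
#' @export
call_pair <- function(p_value, alpha_clonal = 0.05) {
  stopifnot(all(p_value > 0 & p_value <= 1), alpha_clonal > 0, alpha_clonal < 1)
  if_else(p_value <= alpha_clonal, "clonal", "non_clonal")
}

#' Score every intra-patient, inter-nodule biopsy pair of a cohort
#'
#' Enumerates all pairs of tumor biopsies that belong to the same patient but
#' to different nodules (pairs within one nodule carry no information about
#' relatedness between tumors and are excluded), scores each against the
#' cohort pool, and calls it clonal or non-clonal. Each pair gets its own RNG
#' stream derived from `(seed, biopsy_a, biopsy_b)`, so results do not depend
#' on iteration order.
#'
#' @param mutations Mutation tibble (from [read_mutations()] or
#'   [simulate_cohort()]): `biopsy_id`, `variant_key`, `cohort_freq`.
#' @param samples Sample sheet tibble.
#' @inheritParams permutation_pvalue
#' @param alpha_clonal Significance level for the clonal call.
#' @param pool Optional explicit cohort pool (defaults to the distinct
#'   variants of `mutations`).
#' @return A tibble of class `mf_pair_calls`, one row per pair: biopsy and
#'   nodule ids, profile sizes, `n_shared`, `score`, `p_value`, `call`,
#'   `seed`.
#' @export
score_all_pairs <- function(mutations, samples, n_perm = 999,
                            alpha_clonal = 0.05, seed = 1, pool = NULL,
                            f_min = NULL) {
  if (is.null(pool)) {
    pool <- distinct(mutations, .data$variant_key, .data$cohort_freq)
  }
  if (is.null(f_min)) f_min <- attr(mutations, "f_min") %||% min(pool$cohort_freq)
  pairs <- enumerate_intra_patient_pairs(samples)
  profiled <- unique(mutations$biopsy_id)
  unprofiled <- setdiff(unique(c(pairs$biopsy_a, pairs$biopsy_b)), profiled)
  if (length(unprofiled) > 0) {
    warn(sprintf("%d tumor biopsy(ies) without variant calls excluded from pairing",
      length(unprofiled)))
    pairs <- filter(pairs, .data$biopsy_a %in% profiled, .data$biopsy_b %in% profiled)
  }
  profiles <- split(mutations$variant_key, mutations$biopsy_id)

  res <- purrr::pmap_dfr(pairs, function(biopsy_a, biopsy_b, ...) {
    pair_seed <- derive_seed(seed, paste(biopsy_a, biopsy_b, sep = "|"))
    r <- permutation_pvalue(profiles[[biopsy_a]], profiles[[biopsy_b]],
      pool = pool, n_perm = n_perm, seed = pair_seed, f_min = f_min)
    tibble(
      biopsy_a = biopsy_a, biopsy_b = biopsy_b,
      n_a = length(unique(profiles[[biopsy_a]])),
      n_b = length(unique(profiles[[biopsy_b]])),
      n_shared = r$n_shared, score = r$score, p_value = r$p_value,
      seed = pair_seed
    )
  })
  out <- pairs %>%
    inner_join(res, by = c("biopsy_a", "biopsy_b")) %>%
    mutate(call = call_pair(.data$p_value, alpha_clonal))
  class(out) <- c("mf_pair_calls", class(out))
  attr(out, "alpha_clonal") <- alpha_clonal
  attr(out, "n_perm") <- n_perm
  out
}

# All canonical intra-patient, inter-nodule tumor biopsy pairs.
enumerate_intra_patient_pairs <- function(samples) {
  tum <- filter(samples, .data$tissue == "tumor")
  if (nrow(tum) == 0) {
    return(tibble(patient_id = character(), biopsy_a = character(),
      biopsy_b = character(), nodule_a = character(), nodule_b = character()))
  }
  pairs <- tum %>%
    inner_join(tum, by = "patient_id", suffix = c("_a", "_b"),
      relationship = "many-to-many") %>%
    filter(.data$biopsy_id_a < .data$biopsy_id_b,
      .data$nodule_id_a != .data$nodule_id_b) %>%
    select(
      patient_id = "patient_id",
      biopsy_a = "biopsy_id_a", biopsy_b = "biopsy_id_b",
      nodule_a = "nodule_id_a", nodule_b = "nodule_id_b"
    ) %>%
    arrange(.data$patient_id, .data$biopsy_a, .data$biopsy_b)
  pairs
}
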