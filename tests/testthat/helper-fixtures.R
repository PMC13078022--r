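# Fixtures and independent oracles shared by the test files. Everything is
# built in code; nothing is read from stored data.

# A minimal hand-written cohort: 2 patients, 3 nodules, 5 tumor biopsies,
# one NTL biopsy.
tiny_samples <- function() {
  validate_samples(tibble::tribble(
    ~patient_id, ~nodule_id, ~biopsy_id, ~timepoint, ~tissue, ~liver_segment, ~grade,
    "PA", "N1", "PA_N1_B1", 0, "tumor", 5L, "II",
    "PA", "N1", "PA_N1_B2", 1, "tumor", 5L, "II",
    "PA", "N2", "PA_N2_B1", 0, "tumor", 6L, "III",
    "PB", "N1", "PB_N1_B1", 0, "tumor", 2L, "II",
    "PB", "N2", "PB_N2_B1", 0, "tumor", 8L, NA,
    "PB", NA, "PB_NTL1", 0, "NTL", NA, NA
  ))
}

# Mutation tibble from a named list biopsy_id -> character vector of
# variant keys "chrom:pos:ref:alt"; frequencies computed per patient.
mutations_from_keys <- function(keys_by_biopsy, samples, f_min = NULL,
                                driver_genes = character(), genes = NULL) {
  rows <- purrr::imap_dfr(keys_by_biopsy, function(keys, b) {
    parts <- stringr::str_split_fixed(keys, ":", 4)
    tibble::tibble(
      biopsy_id = b, chrom = parts[, 1], pos = as.integer(parts[, 2]),
      ref = parts[, 3], alt = parts[, 4],
      gene = if (is.null(genes)) NA_character_ else unname(genes[keys])
    )
  })
  mfclone:::build_mutation_table(rows, samples, driver_genes, f_min)
}

# Synthetic cohort variant pool with the default power-law spectrum.
toy_pool <- function(n = 10000, f_max = 0.5, alpha = 0.5) {
  tibble::tibble(
    variant_key = sprintf("chr1:%d:A:T", seq_len(n)),
    cohort_freq = f_max * seq_len(n)^(-alpha)
  )
}

# Pair-call rows for a patient given nodule structure and calls; used to
# drive classification without running the permutation test.
calls_from_relations <- function(patient_id, relations) {
  purrr::pmap_dfr(relations, function(nodule_a, nodule_b, call) {
    tibble::tibble(
      patient_id = patient_id,
      biopsy_a = paste0(patient_id, "_", nodule_a, "_B1"),
      biopsy_b = paste0(patient_id, "_", nodule_b, "_B1"),
      nodule_a = nodule_a, nodule_b = nodule_b,
      n_a = 10L, n_b = 10L, n_shared = 5L, score = 0.5,
      p_value = if (call == "clonal") 0.001 else 0.5,
      seed = 1L, call = call
    )
  })
}

samples_from_nodules <- function(patient_id, nodules, biopsies_per_nodule = 1) {
  purrr::map_dfr(seq_along(nodules), function(i) {
    tibble::tibble(
      patient_id = patient_id, nodule_id = nodules[i],
      biopsy_id = sprintf("%s_%s_B%d", patient_id, nodules[i],
        seq_len(biopsies_per_nodule)),
      timepoint = as.numeric(seq_len(biopsies_per_nodule) - 1),
      tissue = "tumor"
    )
  })
}

## ---- independent oracles -------------------------------------------------

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_exact_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  mid <- length(x) * length(y) / 2
  combos <- utils::combn(n, m)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mid) >= abs(obs - mid) - 1e-9)
}

# Two-sided Fisher p for a 2x2 table by hypergeometric probability-mass rule.
fisher_closed_form <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  a_all <- max(0, k - n):min(k, m)
  p_all <- stats::dhyper(a_all, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

# Brute-force per-bin maximum-deviation aggregation.
brute_cn_aggregate <- function(states, neutral = 2) {
  dev <- abs(states - neutral)
  cand <- states[dev == max(dev)]
  if (any(cand > neutral)) max(cand) else min(cand)
}

# Pure-R reference for the permutation null (same sampling scheme as the
# compiled kernel, via base R's weighted without-replacement sampler).
r_null_scores <- function(n_a, n_b, freq, w, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    ia <- sample.int(length(freq), n_a, prob = freq)
    ib <- sample.int(length(freq), n_b, prob = freq)
    sh <- intersect(ia, ib)
    s <- sum(w[sh])
    if (s == 0) 0 else s / sqrt(sum(w[ia]) * sum(w[ib]))
  }, numeric(1))
}
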