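# The pair-class similarity framework: every intra-patient inter-nodule
# biopsy pair is labeled clonal or non-clonal by the clonality test, and a
# random sample of inter-patient pairs provides the between-individuals
# yardstick. If non-clonal pairs are no more similar than inter-patient
# pairs, independent tumors in one liver are as heterogeneous as tumors from
# different people.

#' Label biopsy pairs by class (clonal / non-clonal / inter-patient)
#'
#' Intra-patient inter-nodule pairs take their class from the clonality
#' call; `n_inter` inter-patient pairs are sampled uniformly without
#' replacement from all cross-patient tumor biopsy pairs.
#'
#' @param pair_calls Pair-call tibble from [score_all_pairs()].
#' @param samples Sample sheet tibble.
#' @param n_inter Number of inter-patient pairs to sample (default 50).
#' @param seed Integer seed for the inter-patient draw.
#' @return A tibble `biopsy_a`, `biopsy_b`, `patient_a`, `patient_b`,
#'   `pair_class`.
#' @export
enumerate_pair_classes <- function(pair_calls, samples, n_inter = 50, seed = 1) {
  stopifnot(n_inter >= 1)
  intra <- pair_calls %>%
    dplyr::transmute(
      biopsy_a = .data$biopsy_a, biopsy_b = .data$biopsy_b,
      patient_a = .data$patient_id, patient_b = .data$patient_id,
      pair_class = .data$call
    )
  tum <- filter(samples, .data$tissue == "tumor")
  cross <- tum %>%
    dplyr::cross_join(tum, suffix = c("_a", "_b")) %>%
    filter(.data$patient_id_a < .data$patient_id_b) %>%
    select(biopsy_a = "biopsy_id_a", biopsy_b = "biopsy_id_b",
      patient_a = "patient_id_a", patient_b = "patient_id_b")
  # canonical biopsy ordering within the pair
  swap <- cross$biopsy_a > cross$biopsy_b
  cross <- mutate(cross,
    b_lo = ifelse(swap, .data$biopsy_b, .data$biopsy_a),
    b_hi = ifelse(swap, .data$biopsy_a, .data$biopsy_b),
    p_lo = ifelse(swap, .data$patient_b, .data$patient_a),
    p_hi = ifelse(swap, .data$patient_a, .data$patient_b)
  ) %>%
    dplyr::transmute(biopsy_a = .data$b_lo, biopsy_b = .data$b_hi,
      patient_a = .data$p_lo, patient_b = .data$p_hi) %>%
    arrange(.data$biopsy_a, .data$biopsy_b)
  if (n_inter > nrow(cross)) {
    abort(sprintf("n_inter = %d exceeds the %d available inter-patient pairs",
      n_inter, nrow(cross)))
  }
  picked <- with_seed(derive_seed(seed, "inter_pairs"),
    sort(sample.int(nrow(cross), n_inter)))
  inter <- mutate(cross[picked, ], pair_class = "inter_patient")
  bind_rows(intra, inter)
}

#' Keep only pairs of first-timepoint biopsies
#'
#' Re-analysis guard against multiply-biopsied nodules dominating pair-level
#' statistics: retains pairs in which both members are the earliest biopsy of
#' their nodule. For inter-patient pairs and single-biopsy nodules the filter
#' is the identity.
#'
#' @param records Pair records (any tibble with `biopsy_a`, `biopsy_b`).
#' @param samples Sample sheet tibble.
#' @return The filtered records.
#' @export
first_biopsy_filter <- function(records, samples) {
  firsts <- samples %>%
    filter(.data$tissue == "tumor") %>%
    group_by(.data$patient_id, .data$nodule_id) %>%
    arrange(.data$timepoint, .data$biopsy_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    pull("biopsy_id")
  filter(records, .data$biopsy_a %in% firsts, .data$biopsy_b %in% firsts)
}

#' Correlation between two molecular profiles
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) over a shared coordinate universe. A constant profile has no
#' defined correlation and yields `NA` with a warning.
#'
#' @param x,y Numeric vectors over the same coordinates (length >= 3).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
profile_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("profile correlation needs at least 3 positions")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance profile: correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = method)
}

#' Convert a binned copy-number table to a feature-by-biopsy matrix tibble
#'
#' @param copy_number Binned copy-number tibble.
#' @return Wide tibble with `bin` (chrom:start) plus one column per biopsy.
#' @export
cn_matrix <- function(copy_number) {
  copy_number %>%
    mutate(bin = paste(.data$chrom, .data$start, sep = ":")) %>%
    select("bin", "biopsy_id", "cn") %>%
    tidyr::pivot_wider(names_from = "biopsy_id", values_from = "cn") %>%
    arrange(.data$bin)
}

#' Per-pair profile correlations
#'
#' Computes, for each biopsy pair, the correlation of a molecular layer
#' (copy-number states, signature activities, expression) between the two
#' members. Pairs with a member missing from the layer get `NA`.
#'
#' @param records Pair records with `biopsy_a`, `biopsy_b`.
#' @param features Wide feature matrix tibble: first column is the feature
#'   id, remaining columns are biopsies (see [cn_matrix()],
#'   [read_expression_matrix()], [read_signature_matrix()]).
#' @inheritParams profile_correlation
#' @param name Name of the added correlation column.
#' @return `records` with the correlation column added.
#' @export
pair_correlations <- function(records, features, method = c("spearman", "pearson"),
                              name = "correlation") {
  method <- match.arg(method)
  mat <- as.matrix(features[, -1])
  rownames(mat) <- as.character(features[[1]])
  vals <- purrr::map2_dbl(records$biopsy_a, records$biopsy_b, function(a, b) {
    if (!a %in% colnames(mat) || !b %in% colnames(mat)) return(NA_real_)
    if (sd(mat[, a]) == 0 || sd(mat[, b]) == 0) return(NA_real_)
    cor(mat[, a], mat[, b], method = method)
  })
  records[[name]] <- vals
  records
}

#' Concordance of a categorical annotation within biopsy pairs
#'
#' `same` when both members carry equal non-missing values, `different` when
#' both are non-missing and unequal, `missing` otherwise. For
#' `liver_segment`, values in the same or a neighboring Couinaud segment
#' (under `neighbors`) count as `same`.
#'
#' @param records Pair records with `biopsy_a`, `biopsy_b`.
#' @param samples Sample sheet carrying the annotation.
#' @param feature Annotation column name (e.g. `"grade"`,
#'   `"growth_pattern"`, `"liver_segment"`).
#' @param neighbors Adjacency list for `liver_segment` (default
#'   [couinaud_adjacency()]).
#' @return `records` with an added `concordance` column.
#' @export
categorical_concordance <- function(records, samples, feature,
                                    neighbors = couinaud_adjacency()) {
  if (!feature %in% names(samples)) {
    abort(sprintf("unknown feature '%s' in sample sheet", feature))
  }
  look <- setNames(samples[[feature]], samples$biopsy_id)
  va <- look[records$biopsy_a]
  vb <- look[records$biopsy_b]
  same <- if (feature == "liver_segment") {
    purrr::map2_lgl(va, vb, function(a, b) {
      if (is.na(a) || is.na(b)) return(NA)
      a == b || b %in% neighbors[[as.character(a)]]
    })
  } else {
    ifelse(is.na(va) | is.na(vb), NA, as.character(va) == as.character(vb))
  }
  records$concordance <- case_when(
    is.na(same) ~ "missing",
    same ~ "same",
    TRUE ~ "different"
  )
  records
}

#' Fraction of genome altered by copy number
#'
#' Length-weighted fraction of the genome in a non-neutral copy-number
#' state; the standard summary of overall genomic instability.
#'
#' @param copy_number Binned copy-number tibble.
#' @param ploidy_neutral Neutral state (default from the profile attribute,
#'   else 2).
#' @return A tibble `biopsy_id`, `fga` with values in `[0, 1]`.
#' @export
fraction_genome_altered <- function(copy_number, ploidy_neutral = NULL) {
  if (nrow(copy_number) == 0) abort("empty copy-number profile")
  if (is.null(ploidy_neutral)) {
    ploidy_neutral <- attr(copy_number, "ploidy_neutral") %||% 2L
  }
  copy_number %>%
    mutate(len = .data$end - .data$start) %>%
    group_by(.data$biopsy_id) %>%
    summarise(
      fga = sum(.data$len * (.data$cn != .env$ploidy_neutral)) / sum(.data$len),
      .groups = "drop"
    )
}

#' Tumor mutational burden (mutations per callable megabase)
#'
#' @param mutations Mutation tibble.
#' @param callable_mb Callable genome size in Mb (default 35, a typical
#'   whole-exome footprint).
#' @param samples Optional sample sheet; when given, tumor biopsies with no
#'   variant calls are included with a TMB of 0.
#' @return A tibble `biopsy_id`, `n_variants`, `tmb`.
#' @export
tumor_mutational_burden <- function(mutations, callable_mb = 35, samples = NULL) {
  if (callable_mb <= 0) abort("callable_mb must be positive")
  counts <- mutations %>%
    distinct(.data$biopsy_id, .data$variant_key) %>%
    dplyr::count(.data$biopsy_id, name = "n_variants")
  if (!is.null(samples)) {
    counts <- samples %>%
      filter(.data$tissue == "tumor") %>%
      dplyr::transmute(biopsy_id = .data$biopsy_id) %>%
      left_join(counts, by = "biopsy_id") %>%
      mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L))
  }
  mutate(counts, tmb = .data$n_variants / callable_mb)
}

#' Number of altered driver genes in a variant set
#'
#' A gene counts once no matter how many of its variants are present; for
#' tumor units, apply to the aggregated (union) mutation set.
#'
#' @param genes Character vector of gene symbols, one per variant occurrence
#'   (e.g. the `gene` column of a mutation or unit-mutation tibble).
#' @param driver_genes Non-empty driver panel.
#' @return Integer count of distinct driver genes altered.
#' @export
driver_alteration_count <- function(genes, driver_genes) {
  if (length(driver_genes) == 0) abort("driver gene list is empty")
  length(intersect(unique(genes[!is.na(genes)]), driver_genes))
}

#' Driver alteration counts per tumor unit
#'
#' @param unit_mutations Aggregated unit mutation tibble from
#'   [aggregate_unit_mutations()].
#' @inheritParams driver_alteration_count
#' @return A tibble `unit_id`, `n_driver_genes`.
#' @export
unit_driver_counts <- function(unit_mutations, driver_genes) {
  if (length(driver_genes) == 0) abort("driver gene list is empty")
  unit_mutations %>%
    group_by(.data$unit_id) %>%
    summarise(
      n_driver_genes = driver_alteration_count(.data$gene, driver_genes),
      .groups = "drop"
    )
}

#' Sharing of driver-gene mutations within biopsy pairs
#'
#' For clonal pairs, measures how often driver-gene variant occurrences are
#' present in both members (shared) versus one (private). The primary
#' statistic pools occurrences over all clonal pairs; the mean of per-pair
#' fractions is reported alongside. For non-clonal and inter-patient pairs,
#' reports how often a pair has driver mutations in one or both members and
#' how often both members carry different variants of the same driver gene
#' (convergent, non-clonal evidence).
#'
#' @param records Pair-class records from [enumerate_pair_classes()].
#' @param mutations Mutation tibble (needs `gene`, `is_driver`).
#' @param driver_genes Non-empty driver panel.
#' @return A list of class `mf_shared_fraction`: `overall` (pooled and mean
#'   per-pair shared fractions over clonal pairs), `per_gene`, `per_pair`,
#'   and `co_occurrence` (per pair class).
#' @export
shared_mutation_fraction <- function(records, mutations, driver_genes) {
  if (length(driver_genes) == 0) abort("driver gene list is empty")
  if (!any(records$pair_class == "clonal")) {
    abort("no clonal pairs: shared-mutation fraction undefined")
  }
  drv <- mutations %>%
    filter(.data$gene %in% driver_genes) %>%
    distinct(.data$biopsy_id, .data$variant_key, .data$gene)
  by_biopsy <- split(drv[, c("variant_key", "gene")], drv$biopsy_id)
  empty <- tibble(variant_key = character(), gene = character())

  per_pair <- purrr::pmap_dfr(
    records[, c("biopsy_a", "biopsy_b", "pair_class")],
    function(biopsy_a, biopsy_b, pair_class) {
      a <- by_biopsy[[biopsy_a]] %||% empty
      b <- by_biopsy[[biopsy_b]] %||% empty
      shared_keys <- intersect(a$variant_key, b$variant_key)
      union_keys <- union(a$variant_key, b$variant_key)
      shared_genes_ident <- unique(a$gene[a$variant_key %in% shared_keys])
      common_genes <- intersect(unique(a$gene), unique(b$gene))
      tibble(
        biopsy_a = biopsy_a, biopsy_b = biopsy_b, pair_class = pair_class,
        n_driver_occurrences = length(union_keys),
        n_shared = length(shared_keys),
        shared_fraction = if (length(union_keys) == 0) NA_real_ else
          length(shared_keys) / length(union_keys),
        any_hit = length(union_keys) > 0,
        both_hit = nrow(a) > 0 && nrow(b) > 0,
        same_gene_diff_variant =
          length(setdiff(common_genes, shared_genes_ident)) > 0
      )
    }
  )

  clonal <- filter(per_pair, .data$pair_class == "clonal")
  overall <- tibble(
    n_clonal_pairs = nrow(clonal),
    pooled_shared_fraction = sum(clonal$n_shared) /
      max(sum(clonal$n_driver_occurrences), 1L),
    mean_pair_shared_fraction = mean(clonal$shared_fraction, na.rm = TRUE)
  )

  clonal_ids <- unique(c(clonal$biopsy_a, clonal$biopsy_b))
  per_gene <- purrr::pmap_dfr(clonal[, c("biopsy_a", "biopsy_b")],
    function(biopsy_a, biopsy_b) {
      a <- by_biopsy[[biopsy_a]] %||% empty
      b <- by_biopsy[[biopsy_b]] %||% empty
      keys <- union(a$variant_key, b$variant_key)
      if (length(keys) == 0) return(tibble())
      tibble(
        gene = c(a$gene, b$gene)[match(keys, c(a$variant_key, b$variant_key))],
        variant_key = keys,
        shared = keys %in% intersect(a$variant_key, b$variant_key)
      )
    }) %>%
    group_by(.data$gene) %>%
    summarise(
      n_occurrences = n(), n_shared = sum(.data$shared),
      shared_fraction = mean(.data$shared), .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$n_occurrences))

  co_occurrence <- per_pair %>%
    group_by(.data$pair_class) %>%
    summarise(
      n_pairs = n(),
      frac_any_driver_hit = mean(.data$any_hit),
      frac_both_hit = mean(.data$both_hit),
      frac_same_gene_diff_variant = mean(.data$same_gene_diff_variant),
      .groups = "drop"
    )

  structure(
    list(overall = overall, per_gene = per_gene, per_pair = per_pair,
      co_occurrence = co_occurrence),
    class = "mf_shared_fraction"
  )
}

#' @export
print.mf_shared_fraction <- function(x, ...) {
  cat("<mf_shared_fraction>\n")
  cat(sprintf("  %d clonal pairs: %.1f%% of driver-gene variant occurrences shared (pooled)\n",
    x$overall$n_clonal_pairs, 100 * x$overall$pooled_shared_fraction))
  invisible(x)
}

#' Mean z-score of a gene set against a reference collection
#'
#' Each gene is z-scored against its mean and standard deviation in the
#' reference biopsies; a profile's score is the mean z over the set genes.
#' A generic stand-in for published single-sample signature indices
#' (exhaustion scores, fibroblast scores and the like).
#'
#' @param expression Wide expression tibble (`gene_id` + biopsy columns).
#' @param gene_set Character vector of gene ids (at least one must be
#'   present in the matrix).
#' @param reference Biopsy ids forming the reference collection (non-empty;
#'   genes with zero reference SD are excluded with a warning).
#' @return A tibble `biopsy_id`, `score` covering every biopsy column.
#' @export
gene_set_score <- function(expression, gene_set, reference) {
  stopifnot(length(reference) >= 1)
  mat <- as.matrix(expression[, -1])
  rownames(mat) <- expression[[1]]
  missing_ref <- setdiff(reference, colnames(mat))
  if (length(missing_ref) > 0) {
    abort(sprintf("reference biopsy not in matrix: %s", missing_ref[1]))
  }
  genes <- intersect(gene_set, rownames(mat))
  if (length(genes) == 0) abort("no gene of the set is in the expression matrix")
  ref <- mat[genes, reference, drop = FALSE]
  mu <- rowMeans(ref)
  sdev <- apply(ref, 1, sd)
  keep <- sdev > 0
  if (any(!keep)) {
    warn(sprintf("%d gene(s) with zero reference SD excluded from the score",
      sum(!keep)))
  }
  if (!any(keep)) abort("all set genes have zero reference SD")
  z <- (mat[genes[keep], , drop = FALSE] - mu[keep]) / sdev[keep]
  tibble(biopsy_id = colnames(mat), score = unname(colMeans(z)))
}
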