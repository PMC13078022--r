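test_that("pair-class enumeration labels intra pairs and samples inter pairs", {
  smp <- tiny_samples()
  mut <- mutations_from_keys(list(
    PA_N1_B1 = c("chr1:1:A:T"), PA_N1_B2 = c("chr1:1:A:T"),
    PA_N2_B1 = c("chr1:1:A:T"),
    PB_N1_B1 = c("chr1:2:A:T"), PB_N2_B1 = c("chr1:3:A:T")
  ), smp)
  calls <- score_all_pairs(mut, smp, n_perm = 99, seed = 1)
  rec <- enumerate_pair_classes(calls, smp, n_inter = 3, seed = 1)
  intra <- dplyr::filter(rec, pair_class != "inter_patient")
  expect_equal(nrow(intra), nrow(calls))
  expect_true(all(intra$patient_a == intra$patient_b))
  inter <- dplyr::filter(rec, pair_class == "inter_patient")
  expect_equal(nrow(inter), 3)
  expect_true(all(inter$patient_a != inter$patient_b))

  # deterministic under the seed; capped by the available cross pairs
  rec2 <- enumerate_pair_classes(calls, smp, n_inter = 3, seed = 1)
  expect_identical(rec, rec2)
  expect_error(enumerate_pair_classes(calls, smp, n_inter = 1000, seed = 1),
    regexp = "exceeds")
})

test_that("first-biopsy filter keeps only earliest-per-nodule pairs", {
  smp <- tiny_samples() # PA_N1 has biopsies at t=0 and t=1
  rec <- tibble::tibble(
    biopsy_a = c("PA_N1_B1", "PA_N1_B2", "PB_N1_B1"),
    biopsy_b = c("PA_N2_B1", "PA_N2_B1", "PB_N2_B1")
  )
  kept <- first_biopsy_filter(rec, smp)
  expect_equal(kept$biopsy_a, c("PA_N1_B1", "PB_N1_B1"))

  # all-single-biopsy nodules: identity
  single <- dplyr::filter(smp, biopsy_id != "PA_N1_B2")
  rec2 <- tibble::tibble(biopsy_a = "PA_N1_B1", biopsy_b = "PA_N2_B1")
  expect_identical(first_biopsy_filter(rec2, single), rec2)
})

test_that("profile correlations match hand-ranked cases and invariances", {
  expect_equal(profile_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1.0)
  expect_equal(profile_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4), "pearson"), 1.0)
  # ranks (1,2,3) vs (3,1,2): 1 - 6*6/(3*8) = -0.5
  expect_equal(profile_correlation(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_warning(r <- profile_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(r))
  expect_error(profile_correlation(c(1, 2), c(1, 2)))

  withr::with_seed(5, {
    x <- rnorm(30)
    y <- rnorm(30)
    expect_equal(profile_correlation(2 * x + 3, y, "pearson"),
      profile_correlation(x, y, "pearson"))
    expect_equal(profile_correlation(exp(x), y), profile_correlation(x, y))
  })
})

test_that("per-pair layer correlations use the shared coordinate universe", {
  co <- simulate_cohort(simulation_config(n_IM = 2, n_MO = 1, n_mixed = 0,
    pool_size = 500, expr_genes = 150, n_cn_bins = 44), seed = 23)
  rec <- tibble::tibble(
    biopsy_a = co$samples$biopsy_id[co$samples$tissue == "tumor"][1],
    biopsy_b = co$samples$biopsy_id[co$samples$tissue == "tumor"][2]
  )
  out <- pair_correlations(rec, co$expression, name = "cor_expr")
  expect_true(out$cor_expr >= -1 && out$cor_expr <= 1)
  # a pair with a member missing from the layer yields NA
  rec_na <- tibble::tibble(biopsy_a = "ghost", biopsy_b = rec$biopsy_b)
  expect_true(is.na(pair_correlations(rec_na, co$expression,
    name = "c")$c))
})

test_that("categorical concordance handles equality, difference, missing and segments", {
  smp <- tiny_samples()
  rec <- tibble::tibble(
    biopsy_a = c("PA_N1_B1", "PA_N1_B1", "PB_N1_B1", "PA_N1_B1"),
    biopsy_b = c("PA_N1_B2", "PA_N2_B1", "PB_N2_B1", "PB_N1_B1")
  )
  grade <- categorical_concordance(rec, smp, "grade")
  expect_equal(grade$concordance, c("same", "different", "missing", "same"))

  # segments 5 and 6 are neighbors under the default adjacency; 2 and 8 not
  seg <- categorical_concordance(rec, smp, "liver_segment")
  expect_equal(seg$concordance[2], "same")
  expect_equal(seg$concordance[3], "different")
  expect_error(categorical_concordance(rec, smp, "nope"))
})

test_that("Mann-Whitney routing matches exact enumeration at small n", {
  cmp <- compare_numeric_groups(
    tibble::tibble(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b")), "v", "g")
  expect_equal(cmp$p_value, 1 / 3) # U = 0, all C(4,2)=6 labelings
  expect_equal(cmp$test, "mann_whitney")

  sym <- compare_numeric_groups(
    tibble::tibble(v = c(1, 2, 3, 10, 20, 30), g = rep(c("a", "b"), 3)),
    "v", "g")
  expect_lte(sym$p_value, 1)

  kw <- compare_numeric_groups(
    tibble::tibble(v = rnorm(9), g = rep(c("a", "b", "c"), 3)), "v", "g")
  expect_equal(kw$test, "kruskal_wallis")

  expect_error(compare_numeric_groups(
    tibble::tibble(v = 1, g = "a"), "v", "g"), regexp = "two groups")

  # randomized agreement with the full-enumeration oracle (tie-free, n <= 8)
  withr::with_seed(77, {
    for (i in 1:15) {
      n1 <- sample(2:4, 1)
      n2 <- sample(2:4, 1)
      vals <- sample(1000, n1 + n2) / 7
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      got <- compare_numeric_groups(
        tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(n1, n2))), "v", "g")
      expect_equal(got$p_value, mw_exact_enumeration(x, y), tolerance = 1e-12)
    }
  })

  # glance/tidy surfaces
  g <- glance(cmp)
  expect_equal(g$p.value, 1 / 3)
  expect_equal(sort(tidy(cmp)$group), c("a", "b"))
})

test_that("categorical tests route Fisher for 2x2 and chi-squared beyond", {
  f <- compare_categorical_groups(matrix(c(2, 0, 0, 2), 2))
  expect_equal(f$p_value, 1 / 3)
  expect_equal(f$test, "fisher")
  expect_equal(compare_categorical_groups(matrix(c(1, 1, 1, 1), 2))$p_value, 1)

  chi <- compare_categorical_groups(matrix(c(5, 1, 2, 4, 3, 3), nrow = 3))
  expect_equal(chi$test, "chi_squared")
  expect_error(compare_categorical_groups(matrix(c(-1, 1, 1, 1), 2)))

  # random 2x2 tables against the hypergeometric closed form
  withr::with_seed(101, {
    for (i in 1:25) {
      tab <- matrix(rpois(4, 4), 2)
      expect_equal(compare_categorical_groups(tab, test = "fisher")$p_value,
        fisher_closed_form(tab), tolerance = 1e-9)
    }
  })
})

test_that("fraction of genome altered is length-weighted and refinement-invariant", {
  cn <- tibble::tibble(biopsy_id = "b", chrom = "chr1",
    start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6), cn = c(2L, 2L, 2L))
  expect_equal(fraction_genome_altered(cn)$fga, 0)
  cn$cn <- c(3L, 1L, 0L)
  expect_equal(fraction_genome_altered(cn)$fga, 1)
  # half the genome by length: one 2 Mb neutral bin + two 1 Mb altered bins
  cn2 <- tibble::tibble(biopsy_id = "b", chrom = "chr1",
    start = c(0, 2e6, 3e6), end = c(2e6, 3e6, 4e6), cn = c(2L, 3L, 0L))
  expect_equal(fraction_genome_altered(cn2)$fga, 0.5)
  # splitting a bin leaves the value unchanged
  cn3 <- tibble::tibble(biopsy_id = "b", chrom = "chr1",
    start = c(0, 1e6, 2e6, 3e6), end = c(1e6, 2e6, 3e6, 4e6),
    cn = c(2L, 2L, 3L, 0L))
  expect_equal(fraction_genome_altered(cn3)$fga,
    fraction_genome_altered(cn2)$fga)
  expect_error(fraction_genome_altered(cn[0, ]))
})

test_that("TMB and driver counts follow their definitions", {
  smp <- tiny_samples()
  mut <- mutations_from_keys(
    setNames(list(sprintf("chr1:%d:A:T", 1:70)), "PA_N1_B1"), smp)
  tmb <- tumor_mutational_burden(mut, callable_mb = 35, samples = smp)
  expect_equal(tmb$tmb[tmb$biopsy_id == "PA_N1_B1"], 2.0)
  expect_equal(tmb$tmb[tmb$biopsy_id == "PA_N2_B1"], 0.0) # no calls -> 0
  expect_error(tumor_mutational_burden(mut, callable_mb = 0))

  expect_equal(
    driver_alteration_count(c("CTNNB1", "CTNNB1", "TP53"), hcc_driver_genes()),
    2)
  expect_equal(driver_alteration_count(c("GENE1", "GENE2"), hcc_driver_genes()),
    0)
  expect_error(driver_alteration_count("TP53", character()))

  # union of two biopsies with one distinct driver each -> 2 for the unit
  rel <- nodule_relations(calls_from_relations("PA", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal")))
  units <- build_tumor_units(rel, smp)
  mut2 <- mutations_from_keys(list(
    PA_N1_B1 = "chr1:1:A:T", PA_N1_B2 = "chr1:1:A:T", PA_N2_B1 = "chr2:2:C:G"
  ), smp, driver_genes = hcc_driver_genes(),
  genes = c("chr1:1:A:T" = "TP53", "chr2:2:C:G" = "CTNNB1"))
  agg <- aggregate_unit_mutations(units[units$patient_id == "PA", ], mut2)
  counts <- unit_driver_counts(agg, hcc_driver_genes())
  expect_equal(counts$n_driver_genes, 2L)
})

test_that("driver-mutation sharing distinguishes identical from same-gene variants", {
  smp <- tiny_samples()
  drivers <- hcc_driver_genes()
  genes <- c("chr1:1:A:T" = "CTNNB1", "chr1:2:A:T" = "CTNNB1",
    "chr2:5:C:G" = "TP53")
  mut <- mutations_from_keys(list(
    PA_N1_B1 = c("chr1:1:A:T", "chr2:5:C:G"), # d1 + d3
    PA_N1_B2 = c("chr1:1:A:T"),
    PA_N2_B1 = c("chr1:1:A:T"),               # shares d1 with N1
    PB_N1_B1 = c("chr1:1:A:T"),               # CTNNB1 variant 1
    PB_N2_B1 = c("chr1:2:A:T")                # CTNNB1 variant 2 (distinct)
  ), smp, driver_genes = drivers, genes = genes)
  rec <- tibble::tibble(
    biopsy_a = c("PA_N1_B1", "PB_N1_B1"),
    biopsy_b = c("PA_N2_B1", "PB_N2_B1"),
    pair_class = c("clonal", "non_clonal")
  )
  sf <- shared_mutation_fraction(rec, mut, drivers)
  # clonal pair: occurrences {d1 shared, d3 private} -> pooled 1/2
  expect_equal(sf$overall$pooled_shared_fraction, 0.5)
  pp <- sf$per_pair
  expect_equal(pp$shared_fraction[pp$pair_class == "clonal"], 0.5)
  # non-clonal pair: no identical variant, but same gene different variants
  nc <- pp[pp$pair_class == "non_clonal", ]
  expect_equal(nc$n_shared, 0L)
  expect_true(nc$same_gene_diff_variant)
  co <- sf$co_occurrence
  expect_equal(co$frac_same_gene_diff_variant[co$pair_class == "non_clonal"], 1)

  # a fully shared pair gives fraction 1
  mut_full <- mutations_from_keys(list(
    PA_N1_B1 = "chr1:1:A:T", PA_N1_B2 = "chr1:1:A:T", PA_N2_B1 = "chr1:1:A:T",
    PB_N1_B1 = "chr1:1:A:T", PB_N2_B1 = "chr1:1:A:T"
  ), smp, driver_genes = drivers, genes = genes)
  sf1 <- shared_mutation_fraction(rec[1, ], mut_full, drivers)
  expect_equal(sf1$overall$pooled_shared_fraction, 1.0)

  expect_error(shared_mutation_fraction(
    dplyr::mutate(rec, pair_class = "non_clonal"), mut, drivers))
})

test_that("gene-set scores are mean z-scores against the reference", {
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    r1 = c(0, 0, 5), r2 = c(2, 2, 5), r3 = c(4, 4, 5),
    probe = c(4, 2, 5)
  )
  ref <- c("r1", "r2", "r3")
  # g1: mean 2 sd 2 -> probe z = +1; g2: z = 0; score over {g1,g2} = 0.5
  s <- gene_set_score(expr, c("g1", "g2"), ref)
  expect_equal(s$score[s$biopsy_id == "probe"], 0.5)
  expect_equal(s$score[s$biopsy_id == "r2"], 0) # the reference centroid
  # a zero-variance gene is excluded with a warning
  expect_warning(s2 <- gene_set_score(expr, c("g1", "g3"), ref), "zero")
  expect_equal(s2$score[s2$biopsy_id == "probe"], 1)
  expect_error(gene_set_score(expr, "absent", ref))
  expect_error(suppressWarnings(gene_set_score(expr, "g3", ref)))
})
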