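test_that("nodule relations follow the any-clonal rule with conflict flags", {
  one <- calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal"))
  r1 <- nodule_relations(one)
  expect_equal(r1$call, "clonal")
  expect_false(r1$conflict)

  # two biopsy pairs with conflicting calls -> clonal, flagged
  mixed_calls <- dplyr::bind_rows(
    calls_from_relations("P1", tibble::tribble(
      ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal")),
    dplyr::mutate(calls_from_relations("P1", tibble::tribble(
      ~nodule_a, ~nodule_b, ~call, "N1", "N2", "non_clonal")),
      biopsy_a = "P1_N1_B2")
  )
  r2 <- nodule_relations(mixed_calls)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$call, "clonal")
  expect_true(r2$conflict)

  both_non <- dplyr::bind_rows(
    calls_from_relations("P1", tibble::tribble(
      ~nodule_a, ~nodule_b, ~call, "N1", "N2", "non_clonal")),
    dplyr::mutate(calls_from_relations("P1", tibble::tribble(
      ~nodule_a, ~nodule_b, ~call, "N1", "N2", "non_clonal")),
      biopsy_a = "P1_N1_B2")
  )
  r3 <- nodule_relations(both_non)
  expect_equal(r3$call, "non_clonal")
  expect_false(r3$conflict)
})

test_that("patient classification matches the IM / MO / mixed definitions", {
  im <- nodule_relations(calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call,
    "N1", "N2", "clonal", "N1", "N3", "clonal", "N2", "N3", "clonal")))
  expect_equal(classify_patients(im)$label, "IM")

  mo <- nodule_relations(calls_from_relations("P2", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "non_clonal")))
  expect_equal(classify_patients(mo)$label, "MO")

  mx_rel <- nodule_relations(calls_from_relations("P3", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call,
    "N1", "N2", "clonal", "N1", "N3", "non_clonal", "N2", "N3", "non_clonal")))
  mx <- classify_patients(mx_rel)
  expect_equal(mx$label, "mixed")
  expect_equal(mx$n_clonal_pairs, 1)
  expect_equal(mx$n_nonclonal_pairs, 2)

  # incomplete relation graph is an error when the inventory is known
  smp <- samples_from_nodules("P1", c("N1", "N2", "N3"))
  incomplete <- nodule_relations(calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal")))
  expect_error(classify_patients(incomplete, validate_samples(smp)),
    class = "mfclone_validation_error", regexp = "incomplete")
})

test_that("tumor units are the connected components of the clonal graph", {
  smp3 <- validate_samples(samples_from_nodules("P1", c("N1", "N2", "N3")))
  im <- nodule_relations(calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call,
    "N1", "N2", "clonal", "N1", "N3", "clonal", "N2", "N3", "clonal")))
  u_im <- build_tumor_units(im, smp3)
  expect_equal(u_im$kind, "TMP")
  expect_equal(u_im$n_nodules, 3)

  smp2 <- validate_samples(samples_from_nodules("P2", c("N1", "N2")))
  mo <- nodule_relations(calls_from_relations("P2", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "non_clonal")))
  u_mo <- build_tumor_units(mo, smp2)
  expect_equal(u_mo$kind, c("TNEM", "TNEM"))

  smp_mx <- validate_samples(samples_from_nodules("P3", c("NA1", "NB1", "NC1")))
  mx <- nodule_relations(calls_from_relations("P3", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call,
    "NA1", "NB1", "clonal", "NA1", "NC1", "non_clonal", "NB1", "NC1", "non_clonal")))
  u_mx <- build_tumor_units(mx, smp_mx)
  expect_setequal(u_mx$kind, c("TMP", "TNEM"))
  expect_equal(sort(u_mx$nodules[[which(u_mx$kind == "TMP")]]), c("NA1", "NB1"))

  # intransitive triangle: one component of 3, warned and flagged
  intr <- nodule_relations(calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call,
    "N1", "N2", "clonal", "N2", "N3", "clonal", "N1", "N3", "non_clonal")))
  expect_warning(u_intr <- build_tumor_units(intr, smp3), "intransitive")
  expect_equal(u_intr$n_nodules, 3)
  expect_true(u_intr$intransitive)
})

test_that("classification and unit construction stay mutually consistent on every graph up to 4 nodules", {
  for (n_nod in 2:4) {
    nodules <- sprintf("N%d", seq_len(n_nod))
    smp <- validate_samples(samples_from_nodules("PX", nodules))
    pairs <- t(utils::combn(nodules, 2))
    n_pairs <- nrow(pairs)
    for (mask in 0:(2^n_pairs - 1)) {
      calls <- ifelse(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)) > 0,
        "clonal", "non_clonal")
      rel <- nodule_relations(calls_from_relations("PX", tibble::tibble(
        nodule_a = pairs[, 1], nodule_b = pairs[, 2], call = calls)))
      cls <- classify_patients(rel, smp)
      units <- suppressWarnings(build_tumor_units(rel, smp))
      # partition property holds for every graph
      expect_setequal(unlist(units$nodules), nodules)
      expect_equal(sum(units$n_nodules), n_nod)
      if (!any(units$intransitive)) {
        # transitively consistent graphs: the label is exactly
        # reconstructible from the units
        expected <- if (nrow(units) == 1 && units$kind[1] == "TMP") {
          "IM"
        } else if (all(units$kind == "TNEM")) {
          "MO"
        } else {
          "mixed"
        }
        expect_equal(cls$label, expected)
      } else {
        # an intransitive component implies both clonal and non-clonal
        # pairs, so the pair-count definition must say mixed, and the
        # anomaly must be flagged on the unit
        expect_equal(cls$label, "mixed")
      }
    }
  }
})

test_that("unit mutation aggregation is the exact union", {
  smp <- tiny_samples()
  mut <- mutations_from_keys(list(
    PA_N1_B1 = c("chr1:1:A:T", "chr1:2:A:T"),
    PA_N1_B2 = c("chr1:2:A:T", "chr1:3:A:T"),
    PA_N2_B1 = c("chr1:9:A:T"),
    PB_N1_B1 = c("chr1:1:A:T"), PB_N2_B1 = c("chr1:5:A:T")
  ), smp)
  rel <- nodule_relations(calls_from_relations("PA", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "non_clonal")))
  rel_b <- nodule_relations(calls_from_relations("PB", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal")))
  units <- build_tumor_units(dplyr::bind_rows(rel, rel_b), smp)
  agg <- aggregate_unit_mutations(units, mut)
  # PA_U1 = nodule N1 with two biopsies -> union {1,2,3}
  pa_n1 <- units$unit_id[purrr::map_lgl(units$nodules, ~ identical(.x, "N1")) &
    units$patient_id == "PA"]
  expect_setequal(agg$variant_key[agg$unit_id == pa_n1],
    c("chr1:1:A:T", "chr1:2:A:T", "chr1:3:A:T"))
  # single-biopsy TNEM: unchanged set
  pa_n2 <- units$unit_id[purrr::map_lgl(units$nodules, ~ identical(.x, "N2")) &
    units$patient_id == "PA"]
  expect_equal(agg$variant_key[agg$unit_id == pa_n2], "chr1:9:A:T")

  expect_error(aggregate_unit_mutations(units, mut[mut$biopsy_id != "PA_N2_B1", ]),
    class = "mfclone_validation_error")

  # random instances against an independent union oracle
  withr::with_seed(99, {
    for (i in 1:20) {
      keys <- list(
        PA_N1_B1 = sprintf("chr1:%d:A:T", sample(50, sample(1:10, 1))),
        PA_N1_B2 = sprintf("chr1:%d:A:T", sample(50, sample(1:10, 1)))
      )
      m <- mutations_from_keys(keys, smp)
      a <- aggregate_unit_mutations(units[units$unit_id == pa_n1, ], m)
      expect_setequal(a$variant_key, Reduce(union, keys))
    }
  })
})

test_that("unit copy-number aggregation keeps the most extreme deviation", {
  smp <- validate_samples(samples_from_nodules("P1", c("N1", "N2")))
  rel <- nodule_relations(calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal")))
  units <- build_tumor_units(rel, smp)
  mk_cn <- function(states) {
    tidyr::expand_grid(biopsy_id = c("P1_N1_B1", "P1_N2_B1"),
      tibble::tibble(chrom = "chr1", start = (seq_along(states[[1]]) - 1) * 1e6,
        end = seq_along(states[[1]]) * 1e6)) %>%
      dplyr::mutate(cn = as.integer(c(states[[1]], states[[2]])))
  }
  cn <- mk_cn(list(c(2L, 0L, 1L, 4L), c(5L, 2L, 5L, 0L)))
  agg <- aggregate_unit_copy_number(units, cn)
  # per bin: {2,5}->5, {0,2}->0, {1,5}->5, {4,0} tie -> gain 4 flagged
  expect_equal(agg$cn, c(5L, 0L, 5L, 4L))
  expect_equal(agg$tie_flag, c(FALSE, FALSE, FALSE, TRUE))

  bad <- cn[-1, ]
  expect_error(aggregate_unit_copy_number(units, bad),
    class = "mfclone_validation_error")

  # random instances against the brute-force argmax-deviation oracle
  withr::with_seed(123, {
    for (i in 1:20) {
      s1 <- sample(0:6, 5, replace = TRUE)
      s2 <- sample(0:6, 5, replace = TRUE)
      agg_i <- aggregate_unit_copy_number(units, mk_cn(list(s1, s2)))
      expect_equal(agg_i$cn,
        purrr::map_int(1:5, ~ as.integer(brute_cn_aggregate(c(s1[.x], s2[.x])))))
    }
  })
})

test_that("representative biopsies are the earliest per nodule with tie flags", {
  smp <- validate_samples(tibble::tibble(
    patient_id = "P1", nodule_id = c("N1", "N1", "N2", "N2"),
    biopsy_id = c("b_late", "b_early", "c1", "c2"),
    timepoint = c(3, 0, 1, 1), tissue = "tumor"
  ))
  rel <- nodule_relations(calls_from_relations("P1", tibble::tribble(
    ~nodule_a, ~nodule_b, ~call, "N1", "N2", "clonal")))
  units <- build_tumor_units(rel, smp)
  reps <- representative_biopsies(units, smp)
  expect_equal(nrow(reps), 2) # one per member nodule
  expect_equal(reps$biopsy_id[reps$nodule_id == "N1"], "b_early")
  expect_false(reps$tie_flag[reps$nodule_id == "N1"])
  # N2 tie at t=1: smallest id wins, flagged
  expect_equal(reps$biopsy_id[reps$nodule_id == "N2"], "c1")
  expect_true(reps$tie_flag[reps$nodule_id == "N2"])

  # unit clinical status comes from the first-biopsied nodule
  smp$grade <- unname(c(b_late = "III", b_early = "II", c1 = "IV",
    c2 = "IV")[smp$biopsy_id])
  status <- unit_clinical_status(units, smp, "grade")
  expect_equal(status$nodule_id, "N1")
  expect_equal(status$grade, "II")
})

test_that("unit summaries report counts, means and ranges per kind", {
  units <- tibble::tibble(
    unit_id = c("u1", "u2", "u3"), patient_id = "P",
    kind = c("TMP", "TMP", "TNEM"),
    n_nodules = c(2L, 3L, 1L), n_biopsies = c(3L, 4L, 1L),
    nodules = list("a", "b", "c"), biopsies = list("a", "b", "c"),
    intransitive = FALSE
  )
  s <- unit_summaries(units)
  tmp <- s[s$kind == "TMP", ]
  expect_equal(tmp$n_units, 2L)
  expect_equal(tmp$mean_nodules, 2.5)
  expect_equal(c(tmp$min_nodules, tmp$max_nodules), c(2L, 3L))

  s0 <- unit_summaries(units[units$kind == "TNEM", ])
  expect_equal(s0$n_units[s0$kind == "TMP"], 0L)
  expect_true(is.na(s0$mean_nodules[s0$kind == "TMP"])) # absent, not zero
})
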