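# Patient-level lineage classification. Biopsy-pair calls are aggregated to
# nodule-pair relations, nodule relations to a patient class (IM / MO /
# mixed), and the clonal relation graph to tumor units: TMPs (multi-nodule
# clonal components, i.e. tumors that demonstrably metastasized within the
# liver) and TNEMs (solitary tumors with no evidence of metastasis).

#' Aggregate biopsy-pair calls to nodule-pair relations
#'
#' A nodule pair is called clonal if any supporting biopsy pair is clonal:
#' one confident clonal match is positive evidence of shared origin, whereas
#' dropout can mask sharing in other biopsy combinations. Conflicting
#' biopsy-level calls are flagged, never silently resolved.
#'
#' @param pair_calls Pair-call tibble from [score_all_pairs()].
#' @return A tibble with one row per (patient, nodule pair): `n_biopsy_pairs`,
#'   `n_clonal_biopsy_pairs`, `call`, `conflict`.
#' @export
nodule_relations <- function(pair_calls) {
  stopifnot(nrow(pair_calls) > 0)
  swap <- pair_calls$nodule_a > pair_calls$nodule_b
  pair_calls %>%
    mutate(
      nodule_lo = ifelse(swap, .data$nodule_b, .data$nodule_a),
      nodule_hi = ifelse(swap, .data$nodule_a, .data$nodule_b)
    ) %>%
    group_by(.data$patient_id, nodule_a = .data$nodule_lo,
      nodule_b = .data$nodule_hi) %>%
    summarise(
      n_biopsy_pairs = n(),
      n_clonal_biopsy_pairs = sum(.data$call == "clonal"),
      .groups = "drop"
    ) %>%
    mutate(
      call = if_else(.data$n_clonal_biopsy_pairs > 0, "clonal", "non_clonal"),
      conflict = .data$n_clonal_biopsy_pairs > 0 &
        .data$n_clonal_biopsy_pairs < .data$n_biopsy_pairs
    ) %>%
    arrange(.data$patient_id, .data$nodule_a, .data$nodule_b)
}

#' Classify patients as IM, MO or mixed
#'
#' A patient whose nodule pairs are all clonal is IM (one disseminating
#' clone), all non-clonal is MO (independent tumors), and both kinds present
#' is mixed. Requires the complete relation graph: every pair of the
#' patient's nodules must have a call.
#'
#' @param relations Nodule-relation tibble from [nodule_relations()].
#' @param samples Optional sample sheet; when given, the completeness of each
#'   patient's relation graph is checked against the nodule inventory and
#'   missing pairs are an error.
#' @return A tibble `patient_id`, `label`, `n_clonal_pairs`,
#'   `n_nonclonal_pairs`.
#' @export
classify_patients <- function(relations, samples = NULL) {
  if (!is.null(samples)) {
    expected <- samples %>%
      filter(.data$tissue == "tumor") %>%
      distinct(.data$patient_id, .data$nodule_id) %>%
      group_by(.data$patient_id) %>%
      summarise(n_nodules = n(), .groups = "drop") %>%
      filter(.data$n_nodules >= 2) %>%
      mutate(n_expected = .data$n_nodules * (.data$n_nodules - 1) / 2)
    got <- dplyr::count(relations, .data$patient_id, name = "n_got")
    chk <- left_join(expected, got, by = "patient_id") %>%
      mutate(n_got = dplyr::coalesce(.data$n_got, 0L)) %>%
      filter(.data$n_got < .data$n_expected)
    if (nrow(chk) > 0) {
      validation_error(
        "incomplete nodule relation graph for patient(s): %s",
        paste(sprintf("%s (%d of %d pairs)", chk$patient_id, chk$n_got,
          chk$n_expected), collapse = ", ")
      )
    }
  }
  relations %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_clonal_pairs = sum(.data$call == "clonal"),
      n_nonclonal_pairs = sum(.data$call == "non_clonal"),
      .groups = "drop"
    ) %>%
    mutate(label = case_when(
      .data$n_nonclonal_pairs == 0 & .data$n_clonal_pairs >= 1 ~ "IM",
      .data$n_clonal_pairs == 0 & .data$n_nonclonal_pairs >= 1 ~ "MO",
      TRUE ~ "mixed"
    )) %>%
    select("patient_id", "label", "n_clonal_pairs", "n_nonclonal_pairs")
}

#' Build tumor units (TMP / TNEM) from the clonal relation graph
#'
#' Units are the connected components of the per-patient graph whose edges
#' are clonal nodule relations: components with two or more nodules are TMPs
#' (the clone demonstrably spread), singleton components are TNEMs. The
#' component rule treats clonality as transitive; intransitive triangles
#' (A~B, B~C but A and C called unrelated) are permitted but reported via the
#' `intransitive` flag and a warning.
#'
#' @param relations Nodule-relation tibble from [nodule_relations()].
#' @param samples Sample sheet tibble (supplies each unit's member biopsies
#'   and nodules without any pair, e.g. single-nodule patients).
#' @return A tibble of class `mf_units`, one row per unit: `unit_id`,
#'   `patient_id`, `kind` (`"TMP"`/`"TNEM"`), `n_nodules`, `n_biopsies`,
#'   list-columns `nodules` and `biopsies`, and `intransitive`.
#' @export
build_tumor_units <- function(relations, samples) {
  nodule_inventory <- samples %>%
    filter(.data$tissue == "tumor") %>%
    distinct(.data$patient_id, .data$nodule_id)
  biopsies_by_nodule <- samples %>%
    filter(.data$tissue == "tumor") %>%
    group_by(.data$patient_id, .data$nodule_id) %>%
    summarise(biopsies = list(.data$biopsy_id), .groups = "drop")

  units <- purrr::map_dfr(unique(nodule_inventory$patient_id), function(pid) {
    nodes <- filter(nodule_inventory, .data$patient_id == pid)$nodule_id
    rel <- filter(relations, .data$patient_id == pid)
    edges <- filter(rel, .data$call == "clonal")
    gr <- igraph::graph_from_data_frame(
      d = select(edges, "nodule_a", "nodule_b"),
      vertices = data.frame(name = nodes), directed = FALSE
    )
    comp <- igraph::components(gr)
    membership <- comp$membership[nodes]
    purrr::map_dfr(seq_len(comp$no), function(k) {
      members <- sort(nodes[membership == k])
      # a component is intransitive when some member pair was called non-clonal
      intrans <- nrow(filter(rel, .data$nodule_a %in% members &
        .data$nodule_b %in% members & .data$call == "non_clonal")) > 0
      tibble(
        patient_id = pid,
        kind = if (length(members) >= 2) "TMP" else "TNEM",
        nodules = list(members),
        n_nodules = length(members),
        intransitive = intrans
      )
    })
  })
  if (any(units$intransitive)) {
    warn(sprintf("%d unit(s) built from an intransitive clonal relation",
      sum(units$intransitive)))
  }
  units <- units %>%
    group_by(.data$patient_id) %>%
    mutate(unit_id = sprintf("%s_U%d", .data$patient_id, row_number())) %>%
    ungroup() %>%
    mutate(biopsies = purrr::map2(.data$patient_id, .data$nodules, function(pid, nods) {
      sort(unlist(filter(biopsies_by_nodule, .data$patient_id == pid,
        .data$nodule_id %in% nods)$biopsies))
    }), n_biopsies = purrr::map_int(.data$biopsies, length)) %>%
    select("unit_id", "patient_id", "kind", "n_nodules", "n_biopsies",
      "nodules", "biopsies", "intransitive")
  class(units) <- c("mf_units", class(units))
  units
}

#' Aggregated mutation set of a tumor unit
#'
#' The mutation profile of a TMP/TNEM is the exact union of the variant sets
#' of its member biopsies.
#'
#' @param units Unit tibble from [build_tumor_units()].
#' @param mutations Mutation tibble.
#' @return A tibble `unit_id`, `variant_key`, `gene`, `is_driver` with one
#'   row per (unit, variant).
#' @export
aggregate_unit_mutations <- function(units, mutations) {
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    members <- units$biopsies[[i]]
    missing <- setdiff(members, unique(mutations$biopsy_id))
    if (length(missing) > 0) {
      validation_error("no mutation profile for biopsy %s (unit %s)",
        missing[1], units$unit_id[i])
    }
    mutations %>%
      filter(.data$biopsy_id %in% members) %>%
      distinct(.data$variant_key, .keep_all = TRUE) %>%
      dplyr::transmute(unit_id = units$unit_id[i], variant_key = .data$variant_key,
        gene = .data$gene, is_driver = .data$is_driver)
  })
}

#' Aggregated copy-number profile of a tumor unit
#'
#' Per bin, the unit takes the member state with the maximum absolute
#' deviation from neutral ploidy, so a deep loss in one biopsy is preserved
#' even when other biopsies are neutral. A tie between a gain and a loss of
#' equal deviation resolves to the gain and is flagged.
#'
#' @param units Unit tibble from [build_tumor_units()].
#' @param copy_number Binned copy-number tibble (identical binning across
#'   biopsies).
#' @param ploidy_neutral Neutral state (default taken from the profile
#'   attribute, else 2).
#' @return A tibble `unit_id`, `chrom`, `start`, `end`, `cn`, `tie_flag`.
#' @export
aggregate_unit_copy_number <- function(units, copy_number,
                                       ploidy_neutral = NULL) {
  if (is.null(ploidy_neutral)) {
    ploidy_neutral <- attr(copy_number, "ploidy_neutral") %||% 2L
  }
  n_bins <- dplyr::count(copy_number, .data$biopsy_id)
  if (n_distinct(n_bins$n) > 1) {
    validation_error("inconsistent copy-number binning across biopsies")
  }
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    members <- units$biopsies[[i]]
    prof <- filter(copy_number, .data$biopsy_id %in% members)
    missing <- setdiff(members, unique(prof$biopsy_id))
    if (length(missing) > 0) {
      validation_error("no copy-number profile for biopsy %s (unit %s)",
        missing[1], units$unit_id[i])
    }
    prof %>%
      group_by(.data$chrom, .data$start, .data$end) %>%
      summarise(
        # tie_flag first: later expressions in summarise() would see the
        # aggregated cn, not the per-biopsy states
        tie_flag = {
          dev <- abs(.data$cn - ploidy_neutral)
          cand <- unique(.data$cn[dev == max(dev)])
          any(cand > ploidy_neutral) && any(cand < ploidy_neutral)
        },
        cn = {
          dev <- abs(.data$cn - ploidy_neutral)
          cand <- .data$cn[dev == max(dev)]
          if (any(cand > ploidy_neutral)) max(cand) else min(cand)
        },
        .groups = "drop"
      ) %>%
      mutate(unit_id = units$unit_id[i]) %>%
      select("unit_id", "chrom", "start", "end", "cn", "tie_flag") %>%
      arrange(.data$chrom, .data$start)
  })
}

#' Representative (first) biopsy of each nodule in each unit
#'
#' Per-nodule summaries of a unit use the earliest biopsy of each member
#' nodule; a timepoint tie resolves to the lexicographically smallest biopsy
#' id and is flagged.
#'
#' @param units Unit tibble from [build_tumor_units()].
#' @param samples Sample sheet tibble.
#' @return A tibble `unit_id`, `patient_id`, `nodule_id`, `biopsy_id`,
#'   `timepoint`, `tie_flag`.
#' @export
representative_biopsies <- function(units, samples) {
  members <- units %>%
    select("unit_id", "patient_id", "nodules") %>%
    tidyr::unnest(cols = "nodules") %>%
    rename(nodule_id = "nodules")
  samples %>%
    filter(.data$tissue == "tumor") %>%
    inner_join(members, by = c("patient_id", "nodule_id")) %>%
    group_by(.data$unit_id, .data$patient_id, .data$nodule_id) %>%
    arrange(.data$timepoint, .data$biopsy_id, .by_group = TRUE) %>%
    summarise(
      tie_flag = sum(.data$timepoint == min(.data$timepoint)) > 1,
      biopsy_id = first(.data$biopsy_id),
      timepoint = first(.data$timepoint),
      .groups = "drop"
    ) %>%
    arrange(.data$unit_id, .data$nodule_id)
}

#' Clinical status of a unit
#'
#' A clinicopathological variable of a TMP/TNEM is the value of the nodule
#' containing the globally earliest biopsy of the unit.
#'
#' @param units Unit tibble.
#' @param samples Sample sheet tibble.
#' @param feature Column of `samples` to look up (e.g. `"grade"`).
#' @return A tibble `unit_id`, `nodule_id` (first-biopsied nodule), and the
#'   requested feature.
#' @export
unit_clinical_status <- function(units, samples, feature) {
  if (!feature %in% names(samples)) {
    abort(sprintf("unknown clinical feature '%s'", feature))
  }
  members <- units %>%
    select("unit_id", "patient_id", "nodules") %>%
    tidyr::unnest(cols = "nodules") %>%
    rename(nodule_id = "nodules")
  samples %>%
    filter(.data$tissue == "tumor") %>%
    inner_join(members, by = c("patient_id", "nodule_id")) %>%
    group_by(.data$unit_id) %>%
    arrange(.data$timepoint, .data$biopsy_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("unit_id", "nodule_id", all_of(feature))
}

#' Per-kind summary of tumor units
#'
#' @param units Unit tibble from [build_tumor_units()].
#' @return One row per unit kind with `n_units`, the mean and range of
#'   nodules per unit and the mean biopsies per unit; statistics are `NA`
#'   (not zero) for a kind with no units.
#' @export
unit_summaries <- function(units) {
  purrr::map_dfr(c("TMP", "TNEM"), function(kd) {
    sub <- filter(units, .data$kind == kd)
    if (nrow(sub) == 0) {
      return(tibble(kind = kd, n_units = 0L, mean_nodules = NA_real_,
        min_nodules = NA_integer_, max_nodules = NA_integer_,
        mean_biopsies = NA_real_))
    }
    tibble(
      kind = kd, n_units = nrow(sub),
      mean_nodules = mean(sub$n_nodules),
      min_nodules = min(sub$n_nodules), max_nodules = max(sub$n_nodules),
      mean_biopsies = mean(sub$n_biopsies)
    )
  })
}
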