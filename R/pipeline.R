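# End-to-end orchestration: one config, one master seed, a manifest that
# records what ran. All randomness (simulation, per-pair permutation
# streams, inter-patient sampling) flows from the master seed through named
# substreams, so a rerun with the same config reproduces identical outputs.

#' Pipeline configuration
#'
#' Provide either a simulation config (the cohort is generated) or a set of
#' input paths (the cohort is read from disk); exactly one of the two.
#'
#' @param simulation A [simulation_config()], or `NULL`.
#' @param paths Named list of input files (`samples`, `mutations`,
#'   `copy_number`, `expression`, `signatures`, optionally `drivers`), or
#'   `NULL`.
#' @param n_perm Permutations per pair (default 999).
#' @param alpha_clonal Significance level for the clonal call (default 0.05).
#' @param n_inter Inter-patient pairs to sample (default 50).
#' @param correlation `"spearman"` (default) or `"pearson"`.
#' @param callable_mb Callable megabases for TMB (default 35).
#' @param driver_genes Driver panel (default [hcc_driver_genes()]; for
#'   simulated cohorts the cohort's own panel is used).
#' @param seed Master seed.
#' @return A `mf_pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(), paths = NULL,
                            n_perm = 999, alpha_clonal = 0.05, n_inter = 50,
                            correlation = c("spearman", "pearson"),
                            callable_mb = 35,
                            driver_genes = hcc_driver_genes(), seed = 1) {
  if (is.null(simulation) == is.null(paths)) {
    abort("provide exactly one of `simulation` or `paths`")
  }
  if (!is.null(paths)) {
    required <- c("samples", "mutations")
    missing <- setdiff(required, names(paths))
    if (length(missing) > 0) {
      abort(sprintf("paths must include: %s", paste(missing, collapse = ", ")))
    }
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent) > 0) {
      abort(sprintf("input file does not exist: %s", absent[1]))
    }
  }
  structure(
    list(simulation = simulation, paths = paths, n_perm = n_perm,
      alpha_clonal = alpha_clonal, n_inter = n_inter,
      correlation = match.arg(correlation), callable_mb = callable_mb,
      driver_genes = driver_genes, seed = seed),
    class = "mf_pipeline_config"
  )
}

#' Run the full clonality analysis
#'
#' Stages: cohort acquisition (simulate or read) -> pairwise clonality
#' scoring -> nodule relations -> patient classification -> tumor units with
#' aggregated mutation/copy-number profiles -> pair-class similarity records
#' with per-layer correlations -> unit-level summaries (FGA, TMB, driver
#' counts). Returns everything as tibbles plus a manifest of row counts and
#' seeds.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `mf_analysis`: list with `cohort`,
#'   `pair_calls`, `relations`, `patients`, `units`, `unit_mutations`,
#'   `unit_cn`, `records`, `unit_metrics`, `summaries`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "mf_pipeline_config"))
  t0 <- Sys.time()
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  say("[cohort] %s", if (is.null(config$paths)) "simulating" else "reading")
  cohort <- acquire_cohort(config)

  say("[clonality] scoring pairs (n_perm = %d)", config$n_perm)
  pair_calls <- score_all_pairs(cohort$mutations, cohort$samples,
    n_perm = config$n_perm, alpha_clonal = config$alpha_clonal,
    seed = derive_seed(config$seed, "clonality"))

  say("[classify] nodule relations and patient labels")
  relations <- nodule_relations(pair_calls)
  patients <- classify_patients(relations, cohort$samples)
  units <- build_tumor_units(relations, cohort$samples)
  unit_mutations <- aggregate_unit_mutations(units, cohort$mutations)
  unit_cn <- if (!is.null(cohort$copy_number)) {
    aggregate_unit_copy_number(units, cohort$copy_number)
  }

  say("[similarity] pair classes and correlations (n_inter = %d)", config$n_inter)
  records <- enumerate_pair_classes(pair_calls, cohort$samples,
    n_inter = config$n_inter, seed = derive_seed(config$seed, "similarity"))
  if (!is.null(cohort$copy_number)) {
    records <- pair_correlations(records, cn_matrix(cohort$copy_number),
      method = config$correlation, name = "cor_cn")
  }
  if (!is.null(cohort$expression)) {
    records <- pair_correlations(records, cohort$expression,
      method = config$correlation, name = "cor_expr")
  }
  if (!is.null(cohort$signatures)) {
    records <- pair_correlations(records, cohort$signatures,
      method = config$correlation, name = "cor_sig")
  }

  say("[metrics] unit-level FGA / TMB / driver counts")
  unit_metrics <- units %>%
    select("unit_id", "patient_id", "kind", "n_nodules", "n_biopsies") %>%
    left_join(unit_driver_counts(unit_mutations, cohort$driver_genes),
      by = "unit_id")
  if (!is.null(unit_cn)) {
    unit_fga <- unit_cn %>%
      rename(biopsy_id = "unit_id") %>%
      fraction_genome_altered() %>%
      rename(unit_id = "biopsy_id")
    unit_metrics <- left_join(unit_metrics, unit_fga, by = "unit_id")
  }
  tmb <- tumor_mutational_burden(cohort$mutations, config$callable_mb,
    cohort$samples)
  reps <- representative_biopsies(units, cohort$samples)
  unit_tmb <- reps %>%
    left_join(tmb, by = "biopsy_id") %>%
    group_by(.data$unit_id) %>%
    summarise(tmb = mean(.data$tmb), .groups = "drop")
  unit_metrics <- left_join(unit_metrics, unit_tmb, by = "unit_id")

  summaries <- unit_summaries(units)
  manifest <- tibble(
    stage = c("samples", "pair_calls", "relations", "patients", "units",
      "records"),
    n_rows = c(nrow(cohort$samples), nrow(pair_calls), nrow(relations),
      nrow(patients), nrow(units), nrow(records)),
    seed = config$seed,
    n_perm = config$n_perm,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  say("[done] %d patients, %d pairs, %d units in %.1fs",
    nrow(patients), nrow(pair_calls), nrow(units), manifest$elapsed_s[1])

  structure(
    list(cohort = cohort, pair_calls = pair_calls, relations = relations,
      patients = patients, units = units, unit_mutations = unit_mutations,
      unit_cn = unit_cn, records = records, unit_metrics = unit_metrics,
      summaries = summaries, manifest = manifest, config = config),
    class = "mf_analysis"
  )
}

acquire_cohort <- function(config) {
  if (is.null(config$paths)) {
    return(simulate_cohort(config$simulation, seed = config$seed))
  }
  p <- config$paths
  samples <- read_sample_sheet(p$samples)
  drivers <- if (!is.null(p$drivers)) readLines(p$drivers) else config$driver_genes
  structure(
    list(
      samples = samples,
      mutations = read_mutations(p$mutations, samples, driver_genes = drivers),
      copy_number = if (!is.null(p$copy_number)) read_copy_number(p$copy_number),
      expression = if (!is.null(p$expression)) read_expression_matrix(p$expression),
      signatures = if (!is.null(p$signatures)) read_signature_matrix(p$signatures),
      driver_genes = drivers, gene_sets = NULL, ground_truth = NULL,
      config = NULL, seed = config$seed
    ),
    class = "mf_cohort"
  )
}

#' @export
print.mf_analysis <- function(x, ...) {
  lab <- table(x$patients$label)
  cat("<mf_analysis>\n")
  cat(sprintf("  %d patients (%s); %d biopsy pairs (%d clonal, %d non-clonal)\n",
    nrow(x$patients),
    paste(sprintf("%s=%d", names(lab), as.integer(lab)), collapse = ", "),
    nrow(x$pair_calls), sum(x$pair_calls$call == "clonal"),
    sum(x$pair_calls$call == "non_clonal")))
  cat(sprintf("  units: %d TMP, %d TNEM\n",
    sum(x$units$kind == "TMP"), sum(x$units$kind == "TNEM")))
  invisible(x)
}

#' Tidy an analysis: one row per scored biopsy pair
#'
#' @param x An `mf_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return The pair-call tibble.
#' @export
tidy.mf_analysis <- function(x, ...) {
  as_tibble(x$pair_calls)
}

#' One-row summary of an analysis
#'
#' @param x An `mf_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with patient, pair and unit counts.
#' @export
glance.mf_analysis <- function(x, ...) {
  tibble(
    n_patients = nrow(x$patients),
    n_pairs = nrow(x$pair_calls),
    n_clonal_pairs = sum(x$pair_calls$call == "clonal"),
    n_nonclonal_pairs = sum(x$pair_calls$call == "non_clonal"),
    n_im = sum(x$patients$label == "IM"),
    n_mo = sum(x$patients$label == "MO"),
    n_mixed = sum(x$patients$label == "mixed"),
    n_tmp = sum(x$units$kind == "TMP"),
    n_tnem = sum(x$units$kind == "TNEM")
  )
}
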