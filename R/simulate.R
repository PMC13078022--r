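# Synthetic multifocal-cohort generator. Every downstream stage is validated
# against cohorts produced here, because the real study data are
# controlled-access: the generator encodes the cohort structure the pipeline
# is designed for (multi-nodule patients, clonal sets sharing trunk variants
# drawn from a rare-heavy cohort pool, co-segregating copy-number events,
# class-dependent expression programs) with full ground truth.

#' Default driver gene panel used by the simulator
#'
#' Twenty genes recurrently altered in hepatocellular carcinoma; the panel is
#' a fixture of the simulator, not a curated resource.
#' @return Character vector of 20 gene symbols.
#' @export
hcc_driver_genes <- function() {
  c(
    "TP53", "CTNNB1", "TERT", "ALB", "AXIN1", "ARID1A", "ARID2", "RB1",
    "CDKN2A", "KEAP1", "NFE2L2", "TSC2", "RPS6KA3", "BAP1", "PTEN",
    "PIK3CA", "SMARCA4", "APOB", "IL6ST", "ACVR2A"
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror a realistic multifocal-HCC study: 22 patients
#' (10 IM, 9 MO, 3 mixed), 2-4 tumor nodules each with 1-2 biopsies per
#' nodule, clonal sets sharing a Poisson-sized trunk of variants drawn
#' frequency-proportionally from a cohort pool with a power-law frequency
#' spectrum (a few hotspot-like common variants, a long rare tail; under the
#' default exponent the most common pool variant ends up in roughly a fifth
#' of nodules and the expected chance overlap between two independent
#' profiles stays below about one variant).
#'
#' @param n_IM,n_MO,n_mixed Patients per class. Mixed patients need at least
#'   3 nodules (at least one clonal pair and one independent nodule).
#' @param nodules_per_patient,biopsies_per_nodule Inclusive integer ranges.
#' @param pool_size Number of variants in the cohort pool.
#' @param freq_spectrum Power-law exponent of the pool frequency spectrum
#'   (frequency of rank-r variant is `freq_max * r^-freq_spectrum`).
#' @param freq_max Population frequency of the most common pool variant.
#' @param lambda_trunk Expected trunk variants per clone (shared by all
#'   nodules of a clonal set).
#' @param lambda_private Expected private variants per nodule.
#' @param dropout Per-biopsy probability of missing each nodule variant
#'   (models sampling and calling dropout).
#' @param n_cn_bins Copy-number bins genome-wide (spread over 22 chromosomes,
#'   1 Mb bins).
#' @param p_shared_cn_event,p_private_cn_event Per-chromosome probability of
#'   a clone-shared / nodule-private copy-number event.
#' @param expr_genes Genes in the expression layer (includes a 50-gene
#'   cell-cycle set and a 50-gene fibrosis set).
#' @param cellcycle_effect Log2 shift added to the cell-cycle set in tumors
#'   belonging to multi-nodule clonal sets (metastasizing clones).
#' @param fibrosis_effect Log2 shift added to the fibrosis set in the
#'   non-tumor liver of MO patients (field-effect surrogate).
#' @param noise_sd,component_expr_sd,nodule_expr_sd Expression noise scales
#'   (biopsy, clone and nodule level).
#' @param n_signatures Mutational signatures per activity profile.
#' @param signature_conc Dirichlet concentration of per-clone signature
#'   weights.
#' @param driver_genes Driver panel used to flag pool variants.
#' @param driver_pool_fraction Fraction of pool variants assigned to driver
#'   genes.
#' @return A validated config list of class `mf_sim_config`.
#' @export
simulation_config <- function(n_IM = 10, n_MO = 9, n_mixed = 3,
                              nodules_per_patient = c(2, 4),
                              biopsies_per_nodule = c(1, 2),
                              pool_size = 10000,
                              freq_spectrum = 0.5,
                              freq_max = 0.5,
                              lambda_trunk = 20,
                              lambda_private = 30,
                              dropout = 0.05,
                              n_cn_bins = 440,
                              p_shared_cn_event = 0.25,
                              p_private_cn_event = 0.1,
                              expr_genes = 1000,
                              cellcycle_effect = 1.0,
                              fibrosis_effect = 1.0,
                              noise_sd = 0.5,
                              component_expr_sd = 0.5,
                              nodule_expr_sd = 0.3,
                              n_signatures = 5,
                              signature_conc = 1.0,
                              driver_genes = hcc_driver_genes(),
                              driver_pool_fraction = 0.02) {
  cfg <- as.list(environment())
  counts <- c(n_IM, n_MO, n_mixed)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("need a non-negative class mix with at least one patient")
  }
  stopifnot(
    length(nodules_per_patient) == 2, nodules_per_patient[1] >= 1,
    diff(nodules_per_patient) >= 0,
    length(biopsies_per_nodule) == 2, biopsies_per_nodule[1] >= 1,
    diff(biopsies_per_nodule) >= 0,
    pool_size >= 100, freq_spectrum > 0, freq_max > 0, freq_max <= 1,
    lambda_trunk >= 0, lambda_private >= 0,
    dropout >= 0, dropout < 1,
    p_shared_cn_event >= 0, p_shared_cn_event <= 1,
    p_private_cn_event >= 0, p_private_cn_event <= 1,
    n_cn_bins >= 22, expr_genes >= 120, noise_sd >= 0
  )
  if (n_mixed > 0 && nodules_per_patient[2] < 3) {
    abort("mixed patients need at least 3 nodules; raise nodules_per_patient")
  }
  if (n_IM + n_mixed > 0 && nodules_per_patient[2] < 2) {
    abort("clonal sets need at least 2 nodules; raise nodules_per_patient")
  }
  structure(cfg, class = "mf_sim_config")
}

rdirichlet1 <- function(n, conc) {
  g <- rgamma(n, shape = conc)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

# Draw k pool variants with probability proportional to pool frequency,
# without replacement, optionally excluding indices.
draw_pool <- function(pool, k, exclude = integer()) {
  if (k == 0) return(integer())
  idx <- setdiff(seq_len(nrow(pool)), exclude)
  idx[sample.int(length(idx), k, prob = pool$freq[idx])]
}

#' Simulate a multifocal tumor cohort with known ground truth
#'
#' Produces every data layer the pipeline ingests (sample sheet, mutation
#' table with cohort frequencies, binned copy number, expression, signature
#' activities) plus the generating truth (patient class, clonal partition of
#' nodules, trunk variants). Fully deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @return An object of class `mf_cohort`: a list with elements `samples`,
#'   `mutations`, `copy_number`, `expression`, `signatures`, `pool`,
#'   `driver_genes`, `gene_sets`, `ground_truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "mf_sim_config"))
  with_seed(derive_seed(seed, "simulate"), simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(cfg, seed) {
  n_chrom <- 22L
  bins_per_chrom <- ceiling(cfg$n_cn_bins / n_chrom)
  chrom_len <- bins_per_chrom * 1e6
  chroms <- paste0("chr", seq_len(n_chrom))

  ## --- variant pool -------------------------------------------------------
  pool_n <- cfg$pool_size
  pool <- tibble(
    chrom = sample(chroms, pool_n, replace = TRUE),
    pos = sample.int(chrom_len - 1e6, pool_n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), pool_n, replace = TRUE)
  )
  pool$alt <- purrr::map_chr(pool$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  })
  pool$variant_key <- make_variant_key(pool$chrom, pool$pos, pool$ref, pool$alt)
  # resolve the rare duplicate key by shifting position
  while (anyDuplicated(pool$variant_key) > 0) {
    d <- which(duplicated(pool$variant_key))
    pool$pos[d] <- pool$pos[d] + sample.int(1e5, length(d), replace = TRUE)
    pool$variant_key <- make_variant_key(pool$chrom, pool$pos, pool$ref, pool$alt)
  }
  pool$freq <- cfg$freq_max * seq_len(pool_n)^(-cfg$freq_spectrum)
  n_driver_var <- max(length(cfg$driver_genes), round(cfg$driver_pool_fraction * pool_n))
  driver_idx <- sample.int(pool_n, n_driver_var)
  pool$gene <- paste0("G", sprintf("%05d", sample.int(3000, pool_n, replace = TRUE)))
  pool$gene[driver_idx] <- sample(cfg$driver_genes, n_driver_var, replace = TRUE)

  ## --- patients, nodules, clonal partition --------------------------------
  labels <- c(
    rep("IM", cfg$n_IM), rep("MO", cfg$n_MO), rep("mixed", cfg$n_mixed)
  )
  n_pat <- length(labels)
  patient_ids <- sprintf("P%02d", seq_len(n_pat))
  lo <- cfg$nodules_per_patient[1]
  hi <- cfg$nodules_per_patient[2]

  patients <- purrr::map2_dfr(patient_ids, labels, function(pid, lab) {
    n_nod <- if (lab == "mixed") {
      sample1(seq(max(lo, 3), hi))
    } else {
      sample1(seq(max(lo, if (lab == "IM") 2 else lo), hi))
    }
    nodules <- sprintf("N%d", seq_len(n_nod))
    comp <- switch(lab,
      IM = rep(1L, n_nod),
      MO = seq_len(n_nod),
      mixed = {
        s <- if (n_nod == 3) 2L else sample1(seq(2L, n_nod - 1L))
        c(rep(1L, s), seq(2L, 1L + n_nod - s))
      }
    )
    tibble(patient_id = pid, label = lab, nodule_id = nodules,
      component_id = sprintf("%s_C%d", pid, comp))
  })

  components <- distinct(patients, .data$patient_id, .data$component_id) %>%
    left_join(
      dplyr::count(patients, .data$component_id, name = "n_nodules"),
      by = "component_id"
    )

  ## --- mutations: trunk per component, private per nodule, dropout --------
  trunk <- purrr::map(components$component_id, function(cid) {
    draw_pool(pool, rpois(1, cfg$lambda_trunk))
  })
  names(trunk) <- components$component_id

  nodule_variants <- purrr::pmap(patients, function(patient_id, label,
                                                    nodule_id, component_id) {
    tr <- trunk[[component_id]]
    priv <- draw_pool(pool, rpois(1, cfg$lambda_private), exclude = tr)
    v <- union(tr, priv)
    if (length(v) == 0) v <- draw_pool(pool, 1)
    v
  })
  names(nodule_variants) <- paste(patients$patient_id, patients$nodule_id, sep = "/")

  ## --- sample sheet + per-biopsy variant calls ----------------------------
  seg_base <- setNames(sample(1:8, nrow(components), replace = TRUE),
    components$component_id)
  grades <- c("I", "II", "III", "IV")
  grade_base <- setNames(sample(grades, nrow(components), replace = TRUE,
    prob = c(0.15, 0.35, 0.35, 0.15)), components$component_id)
  patterns <- c("trabecular", "solid", "pseudoglandular", "macrotrabecular")
  pattern_base <- setNames(sample(patterns, nrow(components), replace = TRUE),
    components$component_id)

  nodule_meta <- patients %>% mutate(
    liver_segment = purrr::map_int(.data$component_id, function(cid) {
      base <- seg_base[[cid]]
      if (runif(1) < 0.7) base else couinaud_neighbor(base)
    }),
    grade = purrr::map_chr(.data$component_id, function(cid) {
      if (runif(1) < 0.85) grade_base[[cid]] else sample(grades, 1)
    }),
    growth_pattern = purrr::map_chr(.data$component_id, function(cid) {
      if (runif(1) < 0.85) pattern_base[[cid]] else sample(patterns, 1)
    }),
    n_biopsies = purrr::map_int(seq_len(n()), function(i) {
      as.integer(sample1(seq(cfg$biopsies_per_nodule[1],
        cfg$biopsies_per_nodule[2])))
    })
  )

  tumor_samples <- nodule_meta %>%
    purrr::pmap_dfr(function(patient_id, label, nodule_id, component_id,
                             liver_segment, grade, growth_pattern, n_biopsies) {
      tibble(
        patient_id = patient_id,
        nodule_id = nodule_id,
        biopsy_id = sprintf("%s_%s_B%d", patient_id, nodule_id, seq_len(n_biopsies)),
        timepoint = as.numeric(seq_len(n_biopsies) - 1),
        tissue = "tumor",
        liver_segment = as.integer(liver_segment),
        grade = grade,
        growth_pattern = growth_pattern
      )
    })

  ntl_samples <- purrr::map_dfr(patient_ids, function(pid) {
    k <- sample(1:2, 1)
    tibble(
      patient_id = pid, nodule_id = NA_character_,
      biopsy_id = sprintf("%s_NTL%d", pid, seq_len(k)),
      timepoint = as.numeric(seq_len(k) - 1), tissue = "NTL",
      liver_segment = NA_integer_, grade = NA_character_,
      growth_pattern = NA_character_
    )
  })
  samples <- validate_samples(bind_rows(tumor_samples, ntl_samples))

  variant_rows <- tumor_samples %>%
    purrr::pmap_dfr(function(patient_id, nodule_id, biopsy_id, ...) {
      v <- nodule_variants[[paste(patient_id, nodule_id, sep = "/")]]
      keep <- runif(length(v)) >= cfg$dropout
      if (!any(keep)) keep[sample.int(length(v), 1)] <- TRUE
      idx <- v[keep]
      tibble(
        biopsy_id = biopsy_id,
        chrom = pool$chrom[idx], pos = pool$pos[idx],
        ref = pool$ref[idx], alt = pool$alt[idx], gene = pool$gene[idx]
      )
    })
  mutations <- build_mutation_table(variant_rows, samples, cfg$driver_genes)

  ## --- copy number: clone-shared + nodule-private events ------------------
  bins <- tibble(
    chrom = rep(chroms, each = bins_per_chrom),
    start = rep((seq_len(bins_per_chrom) - 1) * 1e6, n_chrom),
    end = rep(seq_len(bins_per_chrom) * 1e6, n_chrom)
  )
  event_states <- c(0L, 1L, 3L, 4L)
  random_events <- function(p_event) {
    purrr::map_dfr(seq_len(n_chrom), function(ci) {
      if (runif(1) >= p_event) return(tibble())
      a <- sample.int(bins_per_chrom, 1)
      b <- min(bins_per_chrom, a + sample.int(ceiling(bins_per_chrom / 2), 1) - 1)
      tibble(chrom = chroms[ci], from = a, to = b,
        state = sample(event_states, 1))
    })
  }
  comp_events <- purrr::map(components$component_id, function(cid) {
    random_events(cfg$p_shared_cn_event)
  })
  names(comp_events) <- components$component_id
  apply_events <- function(cn, events) {
    if (nrow(events) == 0) return(cn)
    for (i in seq_len(nrow(events))) {
      sel <- bins$chrom == events$chrom[i]
      pos <- which(sel)[events$from[i]:events$to[i]]
      cn[pos] <- events$state[i]
    }
    cn
  }
  nodule_cn <- purrr::pmap(patients, function(patient_id, label, nodule_id,
                                              component_id) {
    cn <- rep(2L, nrow(bins))
    cn <- apply_events(cn, comp_events[[component_id]])
    apply_events(cn, random_events(cfg$p_private_cn_event))
  })
  names(nodule_cn) <- names(nodule_variants)
  copy_number <- tumor_samples %>%
    purrr::pmap_dfr(function(patient_id, nodule_id, biopsy_id, ...) {
      tibble(biopsy_id = biopsy_id, bins,
        cn = nodule_cn[[paste(patient_id, nodule_id, sep = "/")]])
    }) %>%
    arrange(.data$biopsy_id, .data$chrom, .data$start)
  attr(copy_number, "ploidy_neutral") <- 2L

  ## --- expression: clone/nodule/biopsy variance + class programs ----------
  gene_ids <- c(
    sprintf("CC_%03d", 1:50), sprintf("FIB_%03d", 1:50),
    sprintf("G_%04d", seq_len(cfg$expr_genes - 100))
  )
  gene_sets <- list(cell_cycle = gene_ids[1:50], fibrosis = gene_ids[51:100])
  g <- length(gene_ids)
  gene_mean <- rnorm(g, mean = 6, sd = 1.2)
  comp_eff <- matrix(rnorm(g * nrow(components), 0, cfg$component_expr_sd),
    nrow = g, dimnames = list(NULL, components$component_id))
  nod_eff <- matrix(rnorm(g * nrow(patients), 0, cfg$nodule_expr_sd),
    nrow = g, dimnames = list(NULL, names(nodule_variants)))
  multi <- components$component_id[components$n_nodules >= 2]
  cc_idx <- 1:50
  fib_idx <- 51:100

  tumor_expr <- purrr::pmap(tumor_samples[, c("patient_id", "nodule_id", "biopsy_id")],
    function(patient_id, nodule_id, biopsy_id) {
      key <- paste(patient_id, nodule_id, sep = "/")
      cid <- patients$component_id[match(key, names(nodule_variants))]
      val <- gene_mean + comp_eff[, cid] + nod_eff[, key] + rnorm(g, 0, cfg$noise_sd)
      if (cid %in% multi) val[cc_idx] <- val[cc_idx] + cfg$cellcycle_effect
      val
    })
  ntl_eff <- matrix(rnorm(g * n_pat, 0, cfg$nodule_expr_sd),
    nrow = g, dimnames = list(NULL, patient_ids))
  ntl_expr <- purrr::pmap(ntl_samples[, c("patient_id", "biopsy_id")],
    function(patient_id, biopsy_id) {
      val <- gene_mean + ntl_eff[, patient_id] + rnorm(g, 0, cfg$noise_sd)
      if (labels[match(patient_id, patient_ids)] == "MO") {
        val[fib_idx] <- val[fib_idx] + cfg$fibrosis_effect
      }
      val
    })
  expr_mat <- do.call(cbind, c(tumor_expr, ntl_expr))
  colnames(expr_mat) <- c(tumor_samples$biopsy_id, ntl_samples$biopsy_id)
  expression <- dplyr::bind_cols(tibble(gene_id = gene_ids), as_tibble(expr_mat))

  ## --- mutational signature activities (tumor biopsies) -------------------
  sig_ids <- c("SBS1", "SBS4", "SBS5", "SBS16", "SBS22")[seq_len(cfg$n_signatures)]
  if (cfg$n_signatures > 5) {
    sig_ids <- c(sig_ids, sprintf("SBS_X%d", seq_len(cfg$n_signatures - 5)))
  }
  comp_sig <- purrr::map(components$component_id, function(cid) {
    rdirichlet1(cfg$n_signatures, cfg$signature_conc)
  })
  names(comp_sig) <- components$component_id
  n_var_per_biopsy <- dplyr::count(mutations, .data$biopsy_id)
  sig_mat <- purrr::pmap(tumor_samples[, c("patient_id", "nodule_id", "biopsy_id")],
    function(patient_id, nodule_id, biopsy_id) {
      key <- paste(patient_id, nodule_id, sep = "/")
      cid <- patients$component_id[match(key, names(nodule_variants))]
      nv <- n_var_per_biopsy$n[match(biopsy_id, n_var_per_biopsy$biopsy_id)]
      comp_sig[[cid]] * nv * exp(rnorm(cfg$n_signatures, 0, 0.1))
    })
  sig_mat <- do.call(cbind, sig_mat)
  colnames(sig_mat) <- tumor_samples$biopsy_id
  signatures <- dplyr::bind_cols(tibble(signature_id = sig_ids), as_tibble(sig_mat))

  ## --- ground truth -------------------------------------------------------
  ground_truth <- list(
    patient_label = distinct(patients, .data$patient_id, .data$label),
    components = select(patients, "patient_id", "nodule_id", "component_id"),
    trunk_variants = purrr::imap_dfr(trunk, function(idx, cid) {
      if (length(idx) == 0) return(tibble())
      tibble(component_id = cid, variant_key = pool$variant_key[idx])
    })
  )

  structure(
    list(
      samples = samples, mutations = mutations, copy_number = copy_number,
      expression = expression, signatures = signatures,
      pool = select(pool, "variant_key", "chrom", "pos", "ref", "alt",
        "gene", "freq"),
      driver_genes = cfg$driver_genes, gene_sets = gene_sets,
      ground_truth = ground_truth, config = cfg, seed = seed
    ),
    class = "mf_cohort"
  )
}

# A neighboring Couinaud segment under the package's default adjacency.
couinaud_neighbor <- function(seg) {
  nb <- couinaud_adjacency()[[as.character(seg)]]
  nb[sample.int(length(nb), 1)]
}

#' Default Couinaud segment adjacency
#'
#' Approximate anatomical adjacency of the 8 Couinaud liver segments
#' (segments sharing a hepatic vein or portal boundary). Used to decide
#' whether two biopsies arose in the "same or neighboring" segment; pass a
#' custom list to override.
#' @return Named list: segment -> integer vector of neighboring segments.
#' @export
couinaud_adjacency <- function() {
  list(
    `1` = c(2L, 4L, 7L, 8L), `2` = c(1L, 3L, 4L), `3` = c(2L, 4L, 5L),
    `4` = c(1L, 2L, 3L, 5L, 8L), `5` = c(3L, 4L, 6L, 8L),
    `6` = c(5L, 7L), `7` = c(1L, 6L, 8L), `8` = c(1L, 4L, 5L, 7L)
  )
}

#' @export
print.mf_cohort <- function(x, ...) {
  lab <- table(x$ground_truth$patient_label$label)
  cat("<mf_cohort> ", n_distinct(x$samples$patient_id), " patients (",
    paste(sprintf("%s=%d", names(lab), as.integer(lab)), collapse = ", "),
    "); ", sum(x$samples$tissue == "tumor"), " tumor + ",
    sum(x$samples$tissue != "tumor"), " non-tumor biopsies; ",
    nrow(x$mutations), " variant calls\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits exactly the formats the readers consume: `sample_sheet.tsv`,
#' `mutations.maf.tsv` (MAF-like), `copy_number.seg` (SEG), `expression.tsv`
#' and `signatures.tsv` (feature x biopsy matrices), `driver_genes.txt`, and
#' `ground_truth.json`.
#'
#' @param cohort An `mf_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "sample_sheet.tsv"),
    mutations = file.path(dir, "mutations.maf.tsv"),
    copy_number = file.path(dir, "copy_number.seg"),
    expression = file.path(dir, "expression.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    drivers = file.path(dir, "driver_genes.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(cohort$samples, paths["samples"], progress = FALSE)
  maf <- cohort$mutations %>%
    dplyr::transmute(
      Hugo_Symbol = .data$gene, Chromosome = .data$chrom,
      Start_Position = .data$pos, Reference_Allele = .data$ref,
      Tumor_Seq_Allele2 = .data$alt, Tumor_Sample_Barcode = .data$biopsy_id
    )
  readr::write_tsv(maf, paths["mutations"], progress = FALSE)
  seg <- cohort$copy_number %>%
    group_by(.data$biopsy_id, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(run = cumsum(c(1L, diff(.data$cn)) != 0L)) %>%
    group_by(.data$biopsy_id, .data$chrom, .data$run) %>%
    summarise(loc.start = min(.data$start), loc.end = max(.data$end),
      cn = first(.data$cn), .groups = "drop") %>%
    dplyr::transmute(ID = .data$biopsy_id, chrom = .data$chrom,
      loc.start = .data$loc.start, loc.end = .data$loc.end, cn = .data$cn) %>%
    arrange(.data$ID, .data$chrom, .data$loc.start)
  readr::write_tsv(seg, paths["copy_number"], progress = FALSE)
  readr::write_tsv(cohort$expression, paths["expression"], progress = FALSE)
  readr::write_tsv(cohort$signatures, paths["signatures"], progress = FALSE)
  writeLines(cohort$driver_genes, paths["drivers"])
  truth <- cohort$ground_truth
  jsonlite::write_json(
    list(
      patient_label = truth$patient_label,
      components = truth$components,
      trunk_variants = truth$trunk_variants
    ),
    paths["truth"], dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Insert distinct driver-gene variants into independent nodules
#'
#' Models the situation where two clonally unrelated tumors each acquire
#' their own mutation in the same driver gene (convergent evolution): the
#' pair then counts downstream as "same gene, different variants", never as a
#' shared mutation.
#'
#' @param cohort An `mf_cohort`.
#' @param gene A gene from the cohort's driver panel.
#' @param patients Patient ids to spike; each receives two distinct variants
#'   of `gene` in two nodules, preferring clonally unrelated nodules.
#' @return The modified cohort (cohort frequencies recomputed).
#' @export
spike_shared_driver <- function(cohort, gene, patients) {
  stopifnot(inherits(cohort, "mf_cohort"))
  if (!gene %in% cohort$driver_genes) {
    abort(sprintf("'%s' is not in the cohort driver panel", gene))
  }
  if (length(patients) == 0) return(cohort)
  unknown <- setdiff(patients, cohort$ground_truth$patient_label$patient_id)
  if (length(unknown) > 0) {
    validation_error("unknown patient: %s", paste(unknown, collapse = ", "))
  }
  comp <- cohort$ground_truth$components
  counter <- 0L
  new_rows <- purrr::map_dfr(patients, function(pid) {
    pc <- filter(comp, .data$patient_id == pid)
    if (nrow(pc) < 2) validation_error("patient %s has fewer than 2 nodules", pid)
    # prefer nodules from different clonal components
    pick <- pc %>%
      group_by(.data$component_id) %>%
      slice(1) %>%
      ungroup()
    if (nrow(pick) < 2) pick <- pc
    pick <- pick[1:2, ]
    purrr::map_dfr(seq_len(2), function(i) {
      counter <<- counter + 1L
      bx <- cohort$samples %>%
        filter(.data$patient_id == pid, .data$nodule_id == pick$nodule_id[i],
          .data$tissue == "tumor")
      tibble(
        biopsy_id = bx$biopsy_id, chrom = "chrS",
        pos = 1000L + counter, ref = "A",
        alt = if (i == 1) "T" else "G", gene = gene
      )
    })
  })
  raw <- bind_rows(
    select(cohort$mutations, "biopsy_id", "chrom", "pos", "ref", "alt", "gene"),
    new_rows
  )
  cohort$mutations <- build_mutation_table(raw, cohort$samples, cohort$driver_genes)
  cohort
}
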