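#' Read and validate a cohort sample sheet
#'
#' The sample sheet is the backbone of the analysis: one row per biopsy with
#' its patient, tumor nodule, timepoint and tissue identity plus optional
#' clinicopathological annotations.
#'
#' @param path Path to a tab-separated sheet with columns `patient_id`,
#'   `biopsy_id`, `tissue` (one of `tumor`, `NTL`, `normal`) and, for tumor
#'   rows, `nodule_id` and `timepoint`. Optional columns `liver_segment`
#'   (integer 1-8), `grade` (Edmondson I-IV) and `growth_pattern` are carried
#'   through, as is anything else present.
#' @return A tibble of biopsies in canonical order
#'   (patient, nodule, timepoint, biopsy id).
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_samples(as_tibble(sheet))
}

#' @rdname read_sample_sheet
#' @param samples A data frame of biopsies to validate against the sample
#'   sheet invariants.
#' @export
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  assert_columns(samples, c("patient_id", "biopsy_id", "tissue"), "sample sheet")
  if (!"nodule_id" %in% names(samples)) samples$nodule_id <- NA_character_
  if (!"timepoint" %in% names(samples)) samples$timepoint <- NA_real_
  samples <- mutate(samples,
    patient_id = as.character(.data$patient_id),
    biopsy_id = as.character(.data$biopsy_id),
    nodule_id = as.character(.data$nodule_id),
    timepoint = as.numeric(.data$timepoint),
    tissue = as.character(.data$tissue)
  )

  dup <- samples$biopsy_id[duplicated(samples$biopsy_id)]
  if (length(dup) > 0) {
    validation_error("duplicated biopsy_id: %s", paste(unique(dup), collapse = ", "))
  }
  bad_tissue <- setdiff(unique(samples$tissue), c("tumor", "NTL", "normal"))
  if (length(bad_tissue) > 0) {
    validation_error("unknown tissue value: %s", paste(bad_tissue, collapse = ", "))
  }
  no_nodule <- samples$tissue == "tumor" & (is.na(samples$nodule_id) | samples$nodule_id == "")
  if (any(no_nodule)) {
    validation_error(
      "tumor biopsies lacking nodule_id: %s",
      paste(samples$biopsy_id[no_nodule], collapse = ", ")
    )
  }
  has_nodule <- samples$tissue != "tumor" & !is.na(samples$nodule_id)
  if (any(has_nodule)) {
    validation_error(
      "non-tumor biopsies must not carry a nodule_id: %s",
      paste(samples$biopsy_id[has_nodule], collapse = ", ")
    )
  }
  if ("liver_segment" %in% names(samples)) {
    seg <- samples$liver_segment
    if (any(!is.na(seg) & !(seg %in% 1:8))) {
      validation_error("liver_segment must be an integer in 1..8")
    }
  }
  arrange(samples, .data$patient_id, .data$nodule_id, .data$timepoint, .data$biopsy_id)
}

#' Read somatic variant calls for a cohort
#'
#' Reads a MAF-like tab-separated table of somatic SNVs/indels, checks every
#' record against the sample sheet, deduplicates per biopsy, and attaches the
#' patient-level cohort frequency of every variant (the fraction of patients
#' in which the variant was called in at least one biopsy, floored at
#' `f_min`). Rare shared variants are the evidence the clonality test weighs,
#' so the frequency column is part of the mutation table from the start.
#'
#' @param path Path to a MAF-like TSV with columns `Tumor_Sample_Barcode`,
#'   `Chromosome`, `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`
#'   and optionally `Hugo_Symbol`.
#' @param samples Sample sheet tibble from [read_sample_sheet()].
#' @param driver_genes Character vector of driver gene symbols used to set
#'   the `is_driver` flag.
#' @param f_min Frequency floor; defaults to `1 / (2 * n_patients)` so that
#'   no variant weight is infinite.
#' @return A tibble with one row per (biopsy, variant): `biopsy_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `is_driver`, `variant_key`, `cohort_freq`.
#' @export
read_mutations <- function(path, samples, driver_genes = character(), f_min = NULL) {
  maf <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(
    maf,
    c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
      "Reference_Allele", "Tumor_Seq_Allele2"),
    "mutation table"
  )
  variants <- tibble(
    biopsy_id = as.character(maf$Tumor_Sample_Barcode),
    chrom = as.character(maf$Chromosome),
    pos = as.integer(maf$Start_Position),
    ref = as.character(maf$Reference_Allele),
    alt = as.character(maf$Tumor_Seq_Allele2),
    gene = if ("Hugo_Symbol" %in% names(maf)) as.character(maf$Hugo_Symbol) else NA_character_
  )
  bad <- which(is.na(variants$pos) | is.na(variants$ref) | is.na(variants$alt) |
    variants$ref == variants$alt)
  if (length(bad) > 0) {
    format_error("malformed variant fields at line%s %s",
      if (length(bad) > 1) "s" else "", paste(head(bad + 1L, 5), collapse = ", "))
  }
  build_mutation_table(variants, samples, driver_genes, f_min)
}

# Shared finishing step for all mutation ingest routes: validate biopsy ids,
# dedupe, attach keys, driver flags and cohort frequencies.
build_mutation_table <- function(variants, samples, driver_genes = character(),
                                 f_min = NULL) {
  unknown <- setdiff(unique(variants$biopsy_id), samples$biopsy_id)
  if (length(unknown) > 0) {
    validation_error("mutations reference unknown biopsy_id: %s",
      paste(unknown, collapse = ", "))
  }
  variants <- variants %>%
    mutate(
      variant_key = make_variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      is_driver = !is.na(.data$gene) & .data$gene %in% driver_genes
    ) %>%
    distinct(.data$biopsy_id, .data$variant_key, .keep_all = TRUE) %>%
    arrange(.data$biopsy_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  freq <- cohort_variant_freq(variants, samples, f_min = f_min)
  variants <- left_join(select(variants, -dplyr::any_of("cohort_freq")),
    select(freq, "variant_key", "cohort_freq"),
    by = "variant_key"
  )
  attr(variants, "f_min") <- attr(freq, "f_min")
  variants
}

#' Patient-level cohort frequency of every variant
#'
#' A variant is counted once per patient no matter how many of the patient's
#' biopsies carry it, so multiply-biopsied clones do not inflate frequencies.
#'
#' @param variants Mutation tibble (needs `biopsy_id`, `variant_key`).
#' @param samples Sample sheet tibble.
#' @inheritParams read_mutations
#' @return Tibble `variant_key`, `n_patients`, `cohort_freq` with the floor
#'   stored in attribute `f_min`. Frequencies lie in `[f_min, 1]`.
#' @export
cohort_variant_freq <- function(variants, samples, f_min = NULL) {
  n_patients <- n_distinct(samples$patient_id)
  if (is.null(f_min)) f_min <- 1 / (2 * n_patients)
  stopifnot(f_min > 0)
  freq <- variants %>%
    left_join(select(samples, "biopsy_id", "patient_id"), by = "biopsy_id") %>%
    distinct(.data$variant_key, .data$patient_id) %>%
    dplyr::count(.data$variant_key, name = "n_patients") %>%
    mutate(cohort_freq = pmax(.data$n_patients / .env$n_patients, .env$f_min))
  attr(freq, "f_min") <- f_min
  freq
}

#' Read copy-number segments and rebin to fixed windows
#'
#' Consumes SEG-format segment calls (one row per contiguous segment per
#' biopsy) and projects them onto a fixed genome-wide binning shared by the
#' whole cohort: a bin takes the integer copy-number state of the segment
#' covering its midpoint; bins covered by no segment are set to
#' `ploidy_neutral` and counted in a warning.
#'
#' @param path Path to a tab-separated SEG file with columns `ID` (biopsy),
#'   `chrom`, `loc.start`, `loc.end` and a copy-number column (`cn` or
#'   `seg.mean`, rounded to integer states).
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param ploidy_neutral Neutral copy-number state (default 2).
#' @return A tibble `biopsy_id`, `chrom`, `start`, `end`, `cn` (0-based
#'   half-open bins, identical binning for every biopsy).
#' @export
read_copy_number <- function(path, bin_size = 1e6, ploidy_neutral = 2L) {
  stopifnot(bin_size > 0)
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(seg, c("ID", "chrom", "loc.start", "loc.end"), "SEG file")
  cn_col <- intersect(c("cn", "seg.mean"), names(seg))
  if (length(cn_col) == 0) format_error("SEG file needs a 'cn' or 'seg.mean' column")
  seg <- tibble(
    biopsy_id = as.character(seg$ID),
    chrom = as.character(seg$chrom),
    start = as.numeric(seg$loc.start),
    end = as.numeric(seg$loc.end),
    cn = as.integer(round(seg[[cn_col[1]]]))
  )
  if (any(seg$cn < 0) || any(seg$end <= seg$start)) {
    format_error("SEG segments must have end > start and non-negative states")
  }
  # overlapping segments within one biopsy+chrom are ambiguous
  ov <- seg %>%
    arrange(.data$biopsy_id, .data$chrom, .data$start) %>%
    group_by(.data$biopsy_id, .data$chrom) %>%
    filter(row_number() > 1 & .data$start < dplyr::lag(.data$end)) %>%
    ungroup()
  if (nrow(ov) > 0) {
    validation_error("overlapping segments for biopsy %s on %s",
      ov$biopsy_id[1], ov$chrom[1])
  }
  bins <- genome_bins(seg, bin_size)
  bin_segments(seg, bins, ploidy_neutral)
}

# Cohort-wide fixed binning: per chromosome, windows of bin_size covering
# [0, max segment end) rounded up to a whole bin.
genome_bins <- function(seg, bin_size) {
  seg %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$end), .groups = "drop") %>%
    mutate(n_bins = ceiling(.data$len / .env$bin_size)) %>%
    purrr::pmap_dfr(function(chrom, len, n_bins) {
      tibble(
        chrom = chrom,
        start = (seq_len(n_bins) - 1) * bin_size,
        end = seq_len(n_bins) * bin_size
      )
    }) %>%
    arrange(.data$chrom, .data$start)
}

bin_segments <- function(seg, bins, ploidy_neutral) {
  seg_split <- split(seg, list(seg$biopsy_id, seg$chrom), drop = TRUE)
  out <- purrr::map_dfr(unique(seg$biopsy_id), function(b) {
    cn <- purrr::map_int(seq_len(nrow(bins)), function(i) {
      s <- seg_split[[paste(b, bins$chrom[i], sep = ".")]]
      if (is.null(s)) return(NA_integer_)
      s <- s[order(s$start), ]
      mid <- (bins$start[i] + bins$end[i]) / 2
      k <- findInterval(mid, s$start)
      if (k >= 1 && mid < s$end[k]) s$cn[k] else NA_integer_
    })
    tibble(biopsy_id = b, bins, cn = cn)
  })
  n_uncovered <- sum(is.na(out$cn))
  if (n_uncovered > 0) {
    warn(sprintf("%d bin(s) covered by no segment set to neutral state %d",
      n_uncovered, as.integer(ploidy_neutral)))
    out$cn[is.na(out$cn)] <- as.integer(ploidy_neutral)
  }
  out <- arrange(out, .data$biopsy_id, .data$chrom, .data$start)
  attr(out, "ploidy_neutral") <- as.integer(ploidy_neutral)
  out
}

# Shared reader for genes-or-signatures x samples numeric matrices.
read_feature_matrix <- function(path, id_col, what) {
  mat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(mat) < 2) format_error("%s matrix needs an id column plus samples", what)
  names(mat)[1] <- id_col
  ids <- as.character(mat[[1]])
  if (anyDuplicated(ids)) {
    validation_error("duplicated %s row id: %s", what, ids[duplicated(ids)][1])
  }
  for (j in seq(2, ncol(mat))) {
    col <- mat[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      format_error("non-numeric %s value at row %d, column '%s'",
        what, if (is.na(bad)) 1L else bad, names(mat)[j])
    }
    if (anyNA(col) || any(!is.finite(col))) {
      format_error("missing or non-finite %s value in column '%s' (row %d)",
        what, names(mat)[j], which(!is.finite(col))[1])
    }
  }
  mat[[1]] <- ids
  as_tibble(mat)
}

#' Read an expression matrix (genes x biopsies, log2 scale)
#'
#' @param path TSV with gene ids in the first column and one numeric column
#'   per biopsy (log2(TPM+1) or comparable).
#' @return A wide tibble with column `gene_id` plus one column per biopsy.
#' @export
read_expression_matrix <- function(path) {
  read_feature_matrix(path, "gene_id", "expression")
}

#' Read a mutational-signature activity matrix (signatures x biopsies)
#'
#' @param path TSV with signature ids in the first column and one column of
#'   non-negative activities per biopsy.
#' @return A wide tibble with column `signature_id` plus one column per biopsy.
#' @export
read_signature_matrix <- function(path) {
  mat <- read_feature_matrix(path, "signature_id", "signature activity")
  vals <- as.matrix(mat[, -1])
  if (any(vals < 0)) validation_error("signature activities must be non-negative")
  mat
}

#' Cross-layer cohort validation report
#'
#' Reports, without failing, which biopsies are covered by which data layer
#' (partial layers are a feature of multi-omic designs, not an error) and
#' flags as hard errors any profile that references a biopsy absent from the
#' sample sheet.
#'
#' @param samples Sample sheet tibble.
#' @param mutations,copy_number,expression,signatures Optional data layers.
#' @return A tibble `layer`, `biopsy_id`, `issue`, `severity`
#'   (`"coverage"` or `"error"`); zero rows means fully consistent and
#'   complete.
#' @export
validate_cohort <- function(samples, mutations = NULL, copy_number = NULL,
                            expression = NULL, signatures = NULL) {
  tumor_ids <- samples$biopsy_id[samples$tissue == "tumor"]
  all_ids <- samples$biopsy_id
  layer_ids <- list(
    mutations = if (!is.null(mutations)) unique(mutations$biopsy_id),
    copy_number = if (!is.null(copy_number)) unique(copy_number$biopsy_id),
    expression = if (!is.null(expression)) setdiff(names(expression), "gene_id"),
    signatures = if (!is.null(signatures)) setdiff(names(signatures), "signature_id")
  )
  report <- purrr::imap_dfr(layer_ids, function(ids, layer) {
    if (is.null(ids)) return(tibble())
    expected <- if (layer == "expression") all_ids else tumor_ids
    bind_rows(
      tibble(
        layer = layer, biopsy_id = setdiff(expected, ids),
        issue = "biopsy not covered by this layer", severity = "coverage"
      ),
      tibble(
        layer = layer, biopsy_id = setdiff(ids, all_ids),
        issue = "profile references unknown biopsy_id", severity = "error"
      )
    )
  })
  if (nrow(report) == 0) {
    report <- tibble(layer = character(), biopsy_id = character(),
      issue = character(), severity = character())
  }
  report
}
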