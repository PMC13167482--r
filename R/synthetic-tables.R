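# Seeded generators for annotated variant tables (filter-cascade inputs) and
# paired tissue/plasma cohorts (concordance inputs).

FILTER_STRATA <- c("pass_all", "fail_vaf", "fail_status", "fail_pon",
                   "fail_popfreq", "fail_clinvar", "fail_noncoding")

PANEL_GENES <- c("APC", "KRAS", "TP53", "PIK3CA", "BRAF", "EGFR", "NRAS",
                 "SMAD4", "PTEN", "ATM", "FBXW7", "TCF7L2")

#' Simulate an annotated somatic-variant table with known filter strata
#'
#' Each requested stratum contributes rows that fail exactly one filter
#' criterion (or none, for `pass_all`), so the expected output of the filter
#' cascade is known by construction.
#'
#' @param seed integer seed.
#' @param stratum_counts named list/vector of non-negative counts; names from
#'   `pass_all`, `fail_vaf`, `fail_status`, `fail_pon`, `fail_popfreq`,
#'   `fail_clinvar`, `fail_noncoding`. Omitted strata default to 0.
#' @param sample_type "tissue" or "plasma" (sets which VAF threshold applies).
#' @param cfg a [filter_config()] supplying the thresholds the strata are
#'   built against.
#' @return list with `table` (annotated variant data.frame, shuffled row
#'   order, plus hidden column `true_stratum`) and `expected_pass` (the
#'   `pass_all` count).
#' @export
simulate_variant_table <- function(seed, stratum_counts,
                                   sample_type = c("tissue", "plasma"),
                                   cfg = filter_config()) {
  sample_type <- match.arg(sample_type)
  counts <- stats::setNames(rep(0L, length(FILTER_STRATA)), FILTER_STRATA)
  sc <- unlist(stratum_counts)
  if (length(sc)) {
    bad <- setdiff(names(sc), FILTER_STRATA)
    if (length(bad)) stop_config("unknown strata: %s", paste(bad, collapse = ", "))
    if (any(sc < 0) || any(sc != floor(sc))) {
      stop_config("stratum counts must be non-negative integers")
    }
    counts[names(sc)] <- as.integer(sc)
  }
  n <- sum(counts)
  vaf_min <- if (sample_type == "tissue") cfg$tissue_vaf_min else cfg$plasma_vaf_min

  cols <- c("patient_id", "sample_type", "chrom", "start", "end", "gene",
            "ref_allele", "alt_allele", "variant_classification", "hgvs_c",
            "tumor_vaf", "filter_status", "pon_flag", "gnomad_exome_af",
            "gnomad_genome_af", "clinvar_significance", "clinvar_origin",
            "true_stratum")
  if (n == 0L) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(empty) <- cols
    empty$start <- empty$end <- empty$tumor_vaf <- numeric(0)
    empty$pon_flag <- logical(0)
    empty$gnomad_exome_af <- empty$gnomad_genome_af <- numeric(0)
    return(list(table = empty, expected_pass = 0L))
  }
  local_seed(seed, {
    stratum <- rep(names(counts), counts)
    base <- data.frame(
      patient_id = "sim_patient",
      sample_type = sample_type,
      chrom = sample(paste0("chr", c(1:22, "X")), n, replace = TRUE),
      start = sample.int(2e6L, n, replace = TRUE) + 1e6L,
      gene = sample(PANEL_GENES, n, replace = TRUE),
      ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      variant_classification = sample(cfg$coding_classes, n, replace = TRUE),
      tumor_vaf = stats::runif(n, min = vaf_min, max = 0.9),
      filter_status = "PASS",
      pon_flag = FALSE,
      gnomad_exome_af = NA_real_,
      gnomad_genome_af = NA_real_,
      clinvar_significance = sample(c(NA, "pathogenic", "likely_pathogenic"),
                                    n, replace = TRUE),
      clinvar_origin = sample(c(NA, "somatic"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    base$end <- base$start
    base$alt_allele <- vapply(base$ref_allele, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    base$hgvs_c <- sprintf("c.%d%s>%s", seq_len(n) + 100L,
                           base$ref_allele, base$alt_allele)
    # a subset of clean rows carry a rare (passing) population frequency
    rare <- stats::runif(n) < 0.3
    base$gnomad_exome_af[rare] <- stats::runif(sum(rare), 0, cfg$popfreq_max * 0.5)

    i <- stratum == "fail_vaf"
    base$tumor_vaf[i] <- stats::runif(sum(i), 0, vaf_min * 0.99)
    i <- stratum == "fail_status"
    base$filter_status[i] <- sample(c("weak_evidence", "base_quality",
                                      "panel_of_normals"), sum(i), replace = TRUE)
    i <- stratum == "fail_pon"
    base$pon_flag[i] <- TRUE
    i <- stratum == "fail_popfreq"
    base$gnomad_exome_af[i] <- stats::runif(sum(i), cfg$popfreq_max, 0.1)
    i <- stratum == "fail_clinvar"
    # fails under both the OR and AND readings of the ClinVar rule
    base$clinvar_significance[i] <- sample(cfg$excluded_clinvar, sum(i),
                                           replace = TRUE)
    base$clinvar_origin[i] <- "germline"
    i <- stratum == "fail_noncoding"
    base$variant_classification[i] <- sample(c("Intron", "3'UTR", "5'UTR",
                                               "IGR", "RNA"), sum(i),
                                             replace = TRUE)
    base$true_stratum <- stratum
    ord <- sample.int(n)
    tab <- base[ord, , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab[cols], expected_pass = unname(counts["pass_all"]))
  })
}

#' Configure the paired tissue/plasma cohort simulator
#'
#' Defaults mirror a 16-patient colorectal-cancer cohort in which each tumor
#' mutation is independently re-detected in plasma with probability 0.734 (the
#' overall tumor-mutation detection rate the pipeline estimates).
#'
#' @param seed integer seed.
#' @param n_patients number of patients.
#' @param mutations_per_patient a single count or a length-2 range sampled
#'   uniformly per patient.
#' @param plasma_detection_prob per-mutation probability a tissue mutation is
#'   detected in plasma.
#' @param plasma_only_rate expected number of plasma-exclusive calls per
#'   tissue mutation (binomial per patient).
#' @param tissue_vaf_range,plasma_vaf_range VAF sampling intervals.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(seed = 1L, n_patients = 16L,
                            mutations_per_patient = c(11L, 24L),
                            plasma_detection_prob = 0.734,
                            plasma_only_rate = 0.05,
                            tissue_vaf_range = c(0.05, 0.9),
                            plasma_vaf_range = c(0.001, 0.5)) {
  if (!is_count(n_patients) || n_patients < 1) {
    stop_config("n_patients must be a positive count")
  }
  if (!is_prob(plasma_detection_prob) || !is_prob(plasma_only_rate)) {
    stop_config("probabilities must lie in [0, 1]")
  }
  m <- as.integer(mutations_per_patient)
  if (!length(m) %in% 1:2 || any(m < 1) || (length(m) == 2 && m[1] > m[2])) {
    stop_config("mutations_per_patient must be a count or an increasing range")
  }
  chk_rng <- function(r) length(r) == 2 && all(r >= 0 & r <= 1) && r[1] <= r[2]
  if (!chk_rng(tissue_vaf_range) || !chk_rng(plasma_vaf_range)) {
    stop_config("VAF ranges must be increasing intervals within [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 mutations_per_patient = m,
                 plasma_detection_prob = plasma_detection_prob,
                 plasma_only_rate = plasma_only_rate,
                 tissue_vaf_range = tissue_vaf_range,
                 plasma_vaf_range = plasma_vaf_range),
            class = "cohort_sim_spec")
}

#' Simulate a paired tissue/plasma mutation cohort
#'
#' Per patient, tissue mutations are generated with unique identity keys;
#' each appears in the matched plasma sample with `plasma_detection_prob`
#' (sharing its key), and extra plasma-exclusive calls are added at
#' `plasma_only_rate`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `tissue` and `plasma` call data.frames (patient_id, gene,
#'   chrom, start, end, ref_allele, alt_allele, hgvs_c, tumor_vaf,
#'   sample_type) and `truth` (per-patient tissue_n, matched_n, plasma_only_n).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  local_seed(spec$seed, {
    tissue <- list(); plasma <- list(); truth <- list()
    for (i in seq_len(spec$n_patients)) {
      pid <- sprintf("P%03d", i)
      m <- if (length(spec$mutations_per_patient) == 1L) {
        spec$mutations_per_patient
      } else {
        sample(seq.int(spec$mutations_per_patient[1],
                       spec$mutations_per_patient[2]), 1L)
      }
      n_extra <- stats::rbinom(1L, m, spec$plasma_only_rate)
      tot <- m + n_extra
      pos <- sample.int(5e7L, tot) + 1e6L   # unique within patient
      ref <- sample(c("A", "C", "G", "T"), tot, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
      muts <- data.frame(
        patient_id = pid,
        gene = sample(PANEL_GENES, tot, replace = TRUE),
        chrom = sample(paste0("chr", 1:22), tot, replace = TRUE),
        start = pos, end = pos, ref_allele = ref, alt_allele = alt,
        hgvs_c = sprintf("c.%d%s>%s", pos %% 9000L + 1L, ref, alt),
        stringsAsFactors = FALSE)
      tis <- muts[seq_len(m), , drop = FALSE]
      tis$tumor_vaf <- stats::runif(m, spec$tissue_vaf_range[1],
                                    spec$tissue_vaf_range[2])
      tis$sample_type <- "tissue"
      det <- stats::runif(m) < spec$plasma_detection_prob
      pl <- rbind(tis[det, names(muts), drop = FALSE],
                  muts[m + seq_len(n_extra), , drop = FALSE])
      if (nrow(pl)) {
        pl$tumor_vaf <- stats::runif(nrow(pl), spec$plasma_vaf_range[1],
                                     spec$plasma_vaf_range[2])
        pl$sample_type <- "plasma"
      } else {
        pl$tumor_vaf <- numeric(0); pl$sample_type <- character(0)
      }
      tissue[[i]] <- tis
      plasma[[i]] <- pl
      truth[[i]] <- data.frame(patient_id = pid, tissue_n = m,
                               matched_n = sum(det), plasma_only_n = n_extra,
                               stringsAsFactors = FALSE)
    }
    list(tissue = do.call(rbind, tissue),
         plasma = do.call(rbind, plasma),
         truth = do.call(rbind, truth))
  })
}

#' Write an annotated variant table as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
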