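# Tissue-plasma concordance metrics: within-patient mutation matching,
# detection rates with binomial confidence intervals, patient-level per-gene
# positive-detection rates, reference-material panel evaluation, and
# reporting-style rounding.

mutation_key <- function(calls, key_mode = c("hgvs", "coordinate")) {
  key_mode <- match.arg(key_mode)
  if (key_mode == "hgvs") {
    needed <- c("patient_id", "gene", "hgvs_c")
  } else {
    needed <- c("patient_id", "chrom", "start", "ref_allele", "alt_allele")
  }
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols)) {
    stop_config("calls lack column(s) needed for %s keys: %s", key_mode,
                paste(missing_cols, collapse = ", "))
  }
  do.call(paste, c(calls[needed], sep = "\r"))
}

#' Match mutation calls between paired tissue and plasma samples
#'
#' Matching is within-patient and by exact identity key: gene + HGVS-c string
#' (`key_mode = "hgvs"`) or chrom/start/ref/alt (`key_mode = "coordinate"`).
#' No HGVS normalisation is attempted; keys must agree verbatim.
#'
#' @param tissue_calls,plasma_calls data.frames of calls carrying
#'   `patient_id` and the key columns.
#' @param key_mode "hgvs" or "coordinate".
#' @return list with `matched` (tissue rows also seen in plasma),
#'   `tissue_only`, `plasma_only` (data.frames), and `counts` (named integer
#'   vector). `matched` + `tissue_only` partition the tissue calls;
#'   plasma-only calls never enter a detection-rate denominator.
#' @export
match_variants <- function(tissue_calls, plasma_calls,
                           key_mode = c("hgvs", "coordinate")) {
  key_mode <- match.arg(key_mode)
  tk <- mutation_key(tissue_calls, key_mode)
  pk <- mutation_key(plasma_calls, key_mode)
  if (anyDuplicated(tk)) {
    stop_config("duplicate mutation key within tissue calls: %s",
                gsub("\r", " ", tk[duplicated(tk)][1]))
  }
  if (anyDuplicated(pk)) {
    stop_config("duplicate mutation key within plasma calls: %s",
                gsub("\r", " ", pk[duplicated(pk)][1]))
  }
  in_plasma <- tk %in% pk
  matched <- tissue_calls[in_plasma, , drop = FALSE]
  tissue_only <- tissue_calls[!in_plasma, , drop = FALSE]
  plasma_only <- plasma_calls[!pk %in% tk, , drop = FALSE]
  rownames(matched) <- rownames(tissue_only) <- rownames(plasma_only) <- NULL
  list(matched = matched, tissue_only = tissue_only, plasma_only = plasma_only,
       counts = c(matched = nrow(matched), tissue_only = nrow(tissue_only),
                  plasma_only = nrow(plasma_only)))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The closed-form score interval; bounds are clipped to \[0, 1\] and the
#' lower bound is exactly 0 at k = 0. With `(262, 357, 0.95)` it reproduces
#' the interval (0.6857, 0.7771) to four decimals.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param conf confidence level.
#' @return numeric vector `c(low, high)` of proportions.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (!is_count(n) || n < 1) stop_config("wilson_interval needs n >= 1")
  if (!is_count(k) || k > n) stop_config("need 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z / (1 + z^2 / n) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' @rdname wilson_interval
#' @export
wald_interval <- function(k, n, conf = 0.95) {
  if (!is_count(n) || n < 1) stop_config("wald_interval needs n >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - half), high = min(1, p + half))
}

#' @rdname wilson_interval
#' @export
clopper_pearson_interval <- function(k, n, conf = 0.95) {
  if (!is_count(n) || n < 1) stop_config("clopper_pearson_interval needs n >= 1")
  a <- 1 - conf
  low <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Detection rate with confidence interval
#'
#' @param matched_count detected mutations (numerator).
#' @param total_count mutations assayed (denominator).
#' @param conf confidence level for the interval.
#' @param ci_method "wilson" (default), "wald" or "clopper-pearson".
#' @param places decimal places for the reported percentage (round half away
#'   from zero).
#' @return object of class `detection_rate`: list with `numerator`,
#'   `denominator`, `rate_percent` (rounded numeric), `percent_label`
#'   (string), `ci_low`, `ci_high` (proportions), `conf`, `undefined`
#'   (TRUE when the denominator is 0; no division is attempted).
#' @export
detection_rate <- function(matched_count, total_count, conf = 0.95,
                           ci_method = c("wilson", "wald", "clopper-pearson"),
                           places = 1) {
  ci_method <- match.arg(ci_method)
  stopifnot(is_count(matched_count), is_count(total_count))
  if (total_count == 0) {
    return(structure(list(numerator = 0L, denominator = 0L,
                          rate_percent = NA_real_, percent_label = NA_character_,
                          ci_low = NA_real_, ci_high = NA_real_, conf = conf,
                          undefined = TRUE),
                     class = "detection_rate"))
  }
  if (matched_count > total_count) stop_config("numerator exceeds denominator")
  ci <- switch(ci_method,
               wilson = wilson_interval(matched_count, total_count, conf),
               wald = wald_interval(matched_count, total_count, conf),
               `clopper-pearson` = clopper_pearson_interval(matched_count,
                                                            total_count, conf))
  structure(list(numerator = as.integer(matched_count),
                 denominator = as.integer(total_count),
                 rate_percent = round_half_away(
                   100 * matched_count / total_count, places),
                 percent_label = report_percent(matched_count / total_count,
                                                places),
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 conf = conf, undefined = FALSE),
            class = "detection_rate")
}

#' @export
print.detection_rate <- function(x, ...) {
  if (x$undefined) {
    cat("detection rate: undefined (0 denominator)\n")
  } else {
    cat(sprintf("detection rate: %s (%d/%d; %g%% CI: %.4f to %.4f)\n",
                x$percent_label, x$numerator, x$denominator, 100 * x$conf,
                x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Patient-level positive-detection rate for one gene
#'
#' A patient counts once regardless of how many mutations they carry in the
#' gene. Modes:
#' \describe{
#'   \item{plasma_given_tissue}{denominator = patients with >= 1 tissue
#'     mutation in the gene; numerator = those for whom at least one of those
#'     tissue mutations is matched (same identity key) in their plasma.}
#'   \item{tissue_only}{patients with >= 1 tissue mutation, over `n_patients`.}
#'   \item{plasma_only}{patients with >= 1 plasma mutation, over `n_patients`.}
#'   \item{combined}{patients with >= 1 mutation in tissue or plasma, over
#'     `n_patients`.}
#' }
#'
#' @param calls data.frame of calls (tissue and plasma rows together) with
#'   `patient_id`, `gene`, `sample_type` and the key columns.
#' @param gene gene symbol.
#' @param mode counting mode, see Details.
#' @param n_patients cohort size for the tissue_only/plasma_only/combined
#'   denominators; defaults to the number of distinct patients in `calls`.
#' @param key_mode identity-key mode for matching, see [match_variants()].
#' @param conf,places passed to [detection_rate()].
#' @return a `detection_rate` object (zero-denominator results are flagged
#'   `undefined`, e.g. an unknown gene in plasma_given_tissue mode).
#' @export
gene_positive_rate <- function(calls, gene,
                               mode = c("plasma_given_tissue", "tissue_only",
                                        "plasma_only", "combined"),
                               n_patients = NULL, key_mode = "hgvs",
                               conf = 0.95, places = 1) {
  mode <- match.arg(mode)
  stopifnot(all(c("patient_id", "gene", "sample_type") %in% names(calls)))
  g <- calls[calls$gene == gene, , drop = FALSE]
  tis <- g[g$sample_type == "tissue", , drop = FALSE]
  pla <- g[g$sample_type == "plasma", , drop = FALSE]
  if (is.null(n_patients)) n_patients <- length(unique(calls$patient_id))
  if (mode == "plasma_given_tissue") {
    denom_pat <- unique(tis$patient_id)
    m <- match_variants(tis, pla, key_mode = key_mode)
    num_pat <- unique(m$matched$patient_id)
    return(detection_rate(length(num_pat), length(denom_pat), conf = conf,
                          places = places))
  }
  pat <- switch(mode,
                tissue_only = unique(tis$patient_id),
                plasma_only = unique(pla$patient_id),
                combined = unique(c(tis$patient_id, pla$patient_id)))
  detection_rate(length(pat), n_patients, conf = conf, places = places)
}

#' Reference-material panel detection rate
#'
#' @param panel data.frame with one row per panel variant and one observed-VAF
#'   column per extraction arm, named `observed_<arm>` (NA = not detected).
#' @param arm arm name, e.g. "liquid_liquid" or "solid_phase".
#' @param conf,places passed to [detection_rate()].
#' @return a `detection_rate` object: detected variants over panel size.
#' @export
refmat_detection_rate <- function(panel, arm, conf = 0.95, places = 1) {
  stopifnot(is.data.frame(panel))
  if (!nrow(panel)) stop_config("empty reference panel")
  col <- paste0("observed_", arm)
  if (!col %in% names(panel)) {
    stop_config("panel has no column '%s'; arms available: %s", col,
                paste(sub("^observed_", "",
                          grep("^observed_", names(panel), value = TRUE)),
                      collapse = ", "))
  }
  detection_rate(sum(!is.na(panel[[col]])), nrow(panel), conf = conf,
                 places = places)
}

#' Expected VAF of a volumetric mix of two materials
#'
#' Assumes equal DNA content per unit volume, so the expectation is the
#' ratio-weighted mean: mixing 1\% and 0\% VAF one-to-one gives 0.5\%.
#'
#' @param af_a,af_b allele frequencies of the two materials (any common unit).
#' @param ratio_a,ratio_b volumetric mixing ratios (not both zero).
#' @return expected VAF in the input unit.
#' @export
expected_mix_vaf <- function(af_a, af_b, ratio_a = 1, ratio_b = 1) {
  if (any(c(af_a, af_b, ratio_a, ratio_b) < 0)) {
    stop_config("inputs must be non-negative")
  }
  if (ratio_a + ratio_b == 0) stop_config("ratios must not both be zero")
  (ratio_a * af_a + ratio_b * af_b) / (ratio_a + ratio_b)
}

#' Format a proportion as a reporting-style percentage
#'
#' Rounds half away from zero: 13/16 prints "81.3\%" at one decimal and 2/16
#' prints "13\%" at zero decimals.
#'
#' @param x proportion (13/16, not 81.25).
#' @param places decimal places.
#' @return character percentage string.
#' @export
report_percent <- function(x, places = 1) {
  stopifnot(is.finite(x))
  paste0(formatC(round_half_away(100 * x, places), format = "f",
                 digits = places), "%")
}

#' Overall and per-patient detection rates from a matched cohort
#'
#' Convenience wrapper: matches per patient, sums numerators and denominators
#' (mutation-level counting), and returns per-patient rows plus the pooled
#' overall rate.
#'
#' @param tissue_calls,plasma_calls call data.frames with `patient_id`.
#' @param key_mode identity-key mode, see [match_variants()].
#' @param conf,places passed to [detection_rate()].
#' @return list with `per_patient` (data.frame: patient_id, tissue_n,
#'   matched_n, rate_percent) and `overall` (a `detection_rate`).
#' @export
cohort_detection_rates <- function(tissue_calls, plasma_calls,
                                   key_mode = "hgvs", conf = 0.95, places = 1) {
  m <- match_variants(tissue_calls, plasma_calls, key_mode = key_mode)
  pats <- unique(tissue_calls$patient_id)
  per <- do.call(rbind, lapply(pats, function(p) {
    tn <- sum(tissue_calls$patient_id == p)
    mn <- sum(m$matched$patient_id == p)
    data.frame(patient_id = p, tissue_n = tn, matched_n = mn,
               rate_percent = round_half_away(100 * mn / tn, places),
               stringsAsFactors = FALSE)
  }))
  overall <- detection_rate(sum(per$matched_n), sum(per$tissue_n),
                            conf = conf, places = places)
  list(per_patient = per, overall = overall)
}
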