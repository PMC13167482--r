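# Post-annotation somatic-variant filter cascade.
#
# Six criteria, applied in a fixed order with first-failing-criterion
# accounting:
#   1 vaf        - tumor VAF >= 0.05 (tissue) or >= 0.001 (plasma)
#   2 status     - caller hard-filter status equals "PASS"
#   3 pon        - not flagged by the panel of normals
#   4 popfreq    - every present gnomAD AF (exome, genome) < 0.001 (strict)
#   5 clinvar    - not excluded by the ClinVar significance/origin rule
#   6 noncoding  - coding class, or a retained noncoding class
#                  (splice region/site, promoter)

FILTER_CRITERIA <- c("vaf", "status", "pon", "popfreq", "clinvar", "noncoding")

#' Configure the somatic filter cascade
#'
#' Defaults reproduce the study criteria exactly: VAF thresholds are
#' inclusive (`>=`), the population-frequency cutoff is strict (`<`), and a
#' variant is excluded by the ClinVar rule when its significance is in
#' `excluded_clinvar` OR its origin is germline (`clinvar_combine = "and"`
#' selects the conjunctive reading).
#'
#' @param tissue_vaf_min minimum tumor VAF for tissue samples.
#' @param plasma_vaf_min minimum tumor VAF for plasma samples.
#' @param required_filter_status caller hard-filter status a call must carry.
#' @param popfreq_max population-frequency cutoff; present gnomAD AFs must be
#'   strictly below it.
#' @param excluded_clinvar ClinVar significance labels that trigger exclusion
#'   (matched case-insensitively).
#' @param germline_origin_labels origin labels counted as germline (substring
#'   match, case-insensitive, so "germline/somatic" annotations match).
#' @param clinvar_combine "or" (default) or "and": how significance and origin
#'   combine into an exclusion.
#' @param retained_noncoding noncoding classification labels that survive
#'   criterion 6.
#' @param coding_classes classification labels counted as coding.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(tissue_vaf_min = 0.05,
                          plasma_vaf_min = 0.001,
                          required_filter_status = "PASS",
                          popfreq_max = 0.001,
                          excluded_clinvar = c("benign", "not_provided",
                                               "uncertain_significance"),
                          germline_origin_labels = "germline",
                          clinvar_combine = c("or", "and"),
                          retained_noncoding = c("Splice_Site", "Splice_Region",
                                                 "Promoter", "5'Flank"),
                          coding_classes = c("Missense_Mutation",
                                             "Nonsense_Mutation",
                                             "Nonstop_Mutation", "Silent",
                                             "Frame_Shift_Del",
                                             "Frame_Shift_Ins",
                                             "In_Frame_Del", "In_Frame_Ins",
                                             "Translation_Start_Site")) {
  clinvar_combine <- match.arg(clinvar_combine)
  for (x in c(tissue_vaf_min, plasma_vaf_min, popfreq_max)) {
    if (!is_prob(x)) stop_config("thresholds must be fractions in [0, 1]")
  }
  structure(list(tissue_vaf_min = tissue_vaf_min,
                 plasma_vaf_min = plasma_vaf_min,
                 required_filter_status = required_filter_status,
                 popfreq_max = popfreq_max,
                 excluded_clinvar = excluded_clinvar,
                 germline_origin_labels = germline_origin_labels,
                 clinvar_combine = clinvar_combine,
                 retained_noncoding = retained_noncoding,
                 coding_classes = coding_classes),
            class = "filter_config")
}

REQUIRED_VARIANT_COLS <- c("chrom", "start", "end", "ref_allele", "alt_allele",
                           "gene", "variant_classification", "hgvs_c",
                           "tumor_vaf", "filter_status", "pon_flag",
                           "sample_type", "patient_id")
OPTIONAL_VARIANT_COLS <- c("gnomad_exome_af", "gnomad_genome_af",
                           "clinvar_significance", "clinvar_origin")

#' Read an annotated variant table (MAF-style TSV)
#'
#' Expects tab-separated text with a header row; lines beginning `#` are
#' comments. Column names may be remapped from a file-specific dialect via
#' `col_map`. Missing annotation cells (empty, ".", "NA") become `NA`, never
#' silently zero.
#'
#' @param path input file.
#' @param col_map optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(gene = "Hugo_Symbol", tumor_vaf = "t_AF")`.
#' @return data.frame of annotated variants with the canonical columns
#'   (`chrom`, `start`, `end`, `ref_allele`, `alt_allele`, `gene`,
#'   `variant_classification`, `hgvs_c`, `tumor_vaf`, `filter_status`,
#'   `pon_flag`, `sample_type`, `patient_id`, plus gnomAD/ClinVar columns when
#'   present).
#' @export
read_variant_table <- function(path, col_map = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop_config("mapped column '%s' (for '%s') not found in %s",
                    src, canon, path)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_VARIANT_COLS, names(raw))
  if (length(missing_cols)) {
    stop_config("variant table %s lacks required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  blank_na <- function(x) {
    x[x %in% c("", ".", "NA")] <- NA_character_
    x
  }
  out <- raw
  for (col in names(out)) out[[col]] <- blank_na(out[[col]])
  num_col <- function(col, required = FALSE) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(v))
    if (length(bad)) {
      stop_config("unparseable numeric value in column '%s', row %d ('%s')",
                  col, bad[1], out[[col]][bad[1]])
    }
    if (required && anyNA(v)) {
      stop_config("missing required value in column '%s', row %d",
                  col, which(is.na(v))[1])
    }
    v
  }
  out$start <- num_col("start", required = TRUE)
  out$end <- num_col("end", required = TRUE)
  out$tumor_vaf <- num_col("tumor_vaf", required = TRUE)
  if (any(out$tumor_vaf < 0 | out$tumor_vaf > 1)) {
    stop_config("tumor_vaf outside [0, 1] in row %d",
                which(out$tumor_vaf < 0 | out$tumor_vaf > 1)[1])
  }
  pf <- tolower(out$pon_flag)
  pon <- pf %in% c("true", "t", "1", "yes")
  bad <- which(!is.na(pf) & !pf %in% c("true", "t", "1", "yes",
                                       "false", "f", "0", "no"))
  if (length(bad)) {
    stop_config("unparseable pon_flag in row %d ('%s')", bad[1], pf[bad[1]])
  }
  out$pon_flag <- pon
  for (col in c("gnomad_exome_af", "gnomad_genome_af")) {
    if (col %in% names(out)) out[[col]] <- num_col(col)
    else out[[col]] <- rep(NA_real_, nrow(out))
  }
  for (col in c("clinvar_significance", "clinvar_origin")) {
    if (!col %in% names(out)) out[[col]] <- rep(NA_character_, nrow(out))
  }
  out
}

# Vectorised criterion evaluation: returns a character vector of
# first-failing criteria, NA_character_ where all criteria hold.
filter_eval <- function(variants, cfg) {
  stopifnot(is.data.frame(variants), inherits(cfg, "filter_config"))
  n <- nrow(variants)
  if (!n) return(character(0))
  st <- variants$sample_type
  if (any(!st %in% c("tissue", "plasma"))) {
    stop_config("unknown sample_type '%s'",
                st[which(!st %in% c("tissue", "plasma"))[1]])
  }
  vaf_min <- ifelse(st == "tissue", cfg$tissue_vaf_min, cfg$plasma_vaf_min)
  f1 <- variants$tumor_vaf < vaf_min
  f2 <- variants$filter_status != cfg$required_filter_status
  f3 <- variants$pon_flag
  ex_af <- variants$gnomad_exome_af %||% rep(NA_real_, n)
  ge_af <- variants$gnomad_genome_af %||% rep(NA_real_, n)
  f4 <- (!is.na(ex_af) & ex_af >= cfg$popfreq_max) |
    (!is.na(ge_af) & ge_af >= cfg$popfreq_max)
  sig <- tolower(variants$clinvar_significance %||% rep(NA_character_, n))
  org <- tolower(variants$clinvar_origin %||% rep(NA_character_, n))
  sig_bad <- !is.na(sig) & sig %in% tolower(cfg$excluded_clinvar)
  org_bad <- !is.na(org) &
    Reduce(`|`, lapply(tolower(cfg$germline_origin_labels),
                       function(g) grepl(g, org, fixed = TRUE)),
           rep(FALSE, n))
  f5 <- if (cfg$clinvar_combine == "or") sig_bad | org_bad else sig_bad & org_bad
  cls <- variants$variant_classification
  f6 <- !(cls %in% cfg$coding_classes | cls %in% cfg$retained_noncoding)
  fails <- cbind(f1, f2, f3, f4, f5, f6)
  first <- apply(fails, 1, function(r) {
    i <- which(r)
    if (length(i)) FILTER_CRITERIA[i[1]] else NA_character_
  })
  as.character(first)
}

#' Evaluate the filter criteria for variants
#'
#' @param variants data.frame of annotated variants (canonical columns, see
#'   [read_variant_table()]).
#' @param cfg a [filter_config()].
#' @return data.frame with logical `pass` and character `first_failed`
#'   (criterion label, `NA` for passing rows), one row per input variant.
#' @export
passes_filters <- function(variants, cfg = filter_config()) {
  first <- filter_eval(variants, cfg)
  data.frame(pass = is.na(first), first_failed = first,
             stringsAsFactors = FALSE)
}

#' Apply the full filter cascade with per-criterion accounting
#'
#' Removals are attributed to the first failing criterion in the fixed order
#' vaf, status, pon, popfreq, clinvar, noncoding; input row order is
#' preserved in the retained set.
#'
#' @param variants data.frame of annotated variants.
#' @param cfg a [filter_config()].
#' @return object of class `filter_report`: list with `input_count`,
#'   `retained_count`, `removed` (named integer vector over the six
#'   criteria), `retained` (data.frame) and `first_failed` (per input row).
#' @export
apply_filter_cascade <- function(variants, cfg = filter_config()) {
  first <- filter_eval(variants, cfg)
  removed <- stats::setNames(integer(length(FILTER_CRITERIA)), FILTER_CRITERIA)
  tab <- table(factor(first, levels = FILTER_CRITERIA))
  removed[names(tab)] <- as.integer(tab)
  retained <- variants[is.na(first), , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(input_count = nrow(variants),
                 retained_count = nrow(retained),
                 removed = removed,
                 retained = retained,
                 first_failed = first),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Somatic filter cascade: %d in, %d retained\n",
              x$input_count, x$retained_count))
  for (k in names(x$removed)) {
    if (x$removed[[k]] > 0) cat(sprintf("  removed by %-9s %d\n", k, x$removed[[k]]))
  }
  invisible(x)
}

#' Convert VCF-style variant coordinates to MAF-style
#'
#' VCF indels are anchored (POS points at the base before the event); MAF
#' uses 1-based inclusive coordinates with "-" for the empty allele.
#'
#' @param pos 1-based VCF POS.
#' @param ref,alt VCF REF and ALT alleles.
#' @return list with `start`, `end`, `ref_allele`, `alt_allele` in MAF style.
#' @export
vcf_to_maf_coords <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1 && na == 1) {
    list(start = pos, end = pos, ref_allele = ref, alt_allele = alt)
  } else if (nr == 1 && na > 1 && substr(alt, 1, 1) == ref) {
    list(start = pos, end = pos + 1L, ref_allele = "-",
         alt_allele = substr(alt, 2, na))
  } else if (na == 1 && nr > 1 && substr(ref, 1, 1) == alt) {
    list(start = pos + 1L, end = pos + nr - 1L,
         ref_allele = substr(ref, 2, nr), alt_allele = "-")
  } else {
    stop_config("unsupported VCF allele pair %s>%s", ref, alt)
  }
}
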