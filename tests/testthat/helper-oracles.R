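# Independent oracles and small builders shared across test files.

# Naive per-row re-implementation of the six filter criteria, written as a
# plain if-chain so it shares no code with the vectorised cascade.
brute_filter_pass <- function(row, cfg = filter_config()) {
  vaf_min <- if (row$sample_type == "tissue") cfg$tissue_vaf_min else cfg$plasma_vaf_min
  if (row$tumor_vaf < vaf_min) return(FALSE)
  if (row$filter_status != cfg$required_filter_status) return(FALSE)
  if (isTRUE(row$pon_flag)) return(FALSE)
  for (af in c(row$gnomad_exome_af, row$gnomad_genome_af)) {
    if (!is.na(af) && af >= cfg$popfreq_max) return(FALSE)
  }
  sig_bad <- !is.na(row$clinvar_significance) &&
    tolower(row$clinvar_significance) %in% tolower(cfg$excluded_clinvar)
  org_bad <- !is.na(row$clinvar_origin) &&
    any(sapply(tolower(cfg$germline_origin_labels), grepl,
               x = tolower(row$clinvar_origin), fixed = TRUE))
  clinvar_bad <- if (cfg$clinvar_combine == "or") sig_bad || org_bad
    else sig_bad && org_bad
  if (clinvar_bad) return(FALSE)
  cls <- row$variant_classification
  if (!(cls %in% cfg$coding_classes) && !(cls %in% cfg$retained_noncoding)) {
    return(FALSE)
  }
  TRUE
}

# One clean annotated variant row; override fields via ...
make_variant <- function(...) {
  row <- data.frame(
    patient_id = "P1", sample_type = "tissue", chrom = "chr1",
    start = 1000, end = 1000, gene = "KRAS", ref_allele = "G",
    alt_allele = "T", variant_classification = "Missense_Mutation",
    hgvs_c = "c.35G>T", tumor_vaf = 0.3, filter_status = "PASS",
    pon_flag = FALSE, gnomad_exome_af = NA_real_, gnomad_genome_af = NA_real_,
    clinvar_significance = NA_character_, clinvar_origin = NA_character_,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) row[[k]] <- over[[k]]
  row
}

# central 99.9% binomial interval, for stochastic recovery checks
binom_band <- function(n, p) stats::qbinom(c(0.0005, 0.9995), n, p)

# tiny alignment record builder for classify_read tests
make_record <- function(pos, cigar, seq, rname = "sim_ref", flag = 99L,
                        qname = "q1", mapq = 60L, tlen = 150L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "=", pnext = pos,
             tlen = tlen, seq = seq, qual = strrep("I", nchar(seq)),
             stringsAsFactors = FALSE)
}
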