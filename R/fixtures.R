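# Packaged fixtures: transcriptions of the published tables the package's
# concordance metrics are evaluated against.

FIXTURE_REGISTRY <- c(
  table2_refmat = "Reference-material VAF panel (38 variants, two extraction arms)",
  table3_tissue_plasma = "Matched tissue/plasma APC-KRAS-TP53 calls, 16 CRC patients",
  table4_counts = "Per-patient tumor-mutation counts and plasma-matched counts",
  table5_actionable = "Matched tissue/plasma calls in actionable genes (BRAF, PIK3CA, EGFR)"
)

#' Load a packaged fixture table
#'
#' @param name one of `names(fixture_registry())`.
#' @return data.frame with attributes `fixture_name` and, for the cohort
#'   fixtures, `n_patients` (16).
#' @export
#' @examples
#' nrow(load_fixture("table2_refmat"))  # 38
load_fixture <- function(name) {
  if (!name %in% names(FIXTURE_REGISTRY)) {
    stop_config("unknown fixture '%s'; available: %s", name,
                paste(names(FIXTURE_REGISTRY), collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "plasmaconcord", mustWork = TRUE)
  out <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if ("patient_id" %in% names(out)) {
    out$patient_id <- as.character(out$patient_id)
    attr(out, "n_patients") <- 16L
  }
  attr(out, "fixture_name") <- name
  out
}

#' @rdname load_fixture
#' @export
fixture_registry <- function() FIXTURE_REGISTRY
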