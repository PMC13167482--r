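# End-to-end orchestration: simulate -> filter -> concord / fragsize ->
# report, driven by a strict YAML configuration. Every stage's outputs and
# the config hash land in a single JSON manifest.

PIPELINE_KEYS <- c("seed", "out_dir", "stages", "simulate_reads",
                   "simulate_variants", "simulate_cohort", "filter",
                   "concord", "fragsize", "refeval", "reporting")

#' Combined allele-aware insert-size analysis over variant loci
#'
#' Classifies fragments at each locus, pools mutant and non-mutant insert
#' sizes across loci (mirroring the combine-across-genes design of the
#' analysis this package models), summarises each pool and tests whether
#' mutant fragments are stochastically shorter.
#'
#' @param records alignment records (see [read_sam()]).
#' @param variants data.frame with columns chrom, pos, ref, alt (one row per
#'   locus), or a single [variant_spec()].
#' @param min_mapq,min_anchor see [classify_fragments()].
#' @param threshold,mono,di see [size_summary()].
#' @param max_size see [fragment_sizes()].
#' @return list with `calls` (per-locus fragment-call data.frames), `sizes`
#'   (pooled mutant / non_mutant / other_allele vectors), `summary` (an
#'   `insert_size_summary` per pooled label), `test` (one-sided rank-sum
#'   result, NULL when either pool is empty) and `label_counts`.
#' @export
fragsize_analysis <- function(records, variants, min_mapq = 20L,
                              min_anchor = 1L, threshold = 150L,
                              mono = c(50L, 220L), di = c(221L, 400L),
                              max_size = 1000L) {
  if (inherits(variants, "variant_spec")) {
    vlist <- list(variants)
  } else {
    stopifnot(is.data.frame(variants),
              all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
    vlist <- lapply(seq_len(nrow(variants)), function(i) {
      variant_spec(variants$chrom[i], variants$pos[i],
                   variants$ref[i], variants$alt[i])
    })
  }
  pooled <- list(mutant = integer(0), non_mutant = integer(0),
                 other_allele = integer(0))
  calls <- vector("list", length(vlist))
  label_counts <- c(mutant = 0L, non_mutant = 0L, other_allele = 0L,
                    ambiguous = 0L, not_covered = 0L)
  for (i in seq_along(vlist)) {
    fc <- classify_fragments(records, vlist[[i]], min_mapq = min_mapq,
                             min_anchor = min_anchor)
    fs <- fragment_sizes(fc, records, max_size = max_size)
    for (lab in names(pooled)) {
      pooled[[lab]] <- c(pooled[[lab]], fs$sizes[[lab]])
    }
    tb <- table(factor(fc$label, levels = names(label_counts)))
    label_counts <- label_counts + as.integer(tb)
    calls[[i]] <- fc
  }
  test <- if (length(pooled$mutant) && length(pooled$non_mutant)) {
    rank_sum_less(pooled$mutant, pooled$non_mutant)
  }
  list(calls = calls, sizes = pooled,
       summary = list(
         mutant = size_summary(pooled$mutant, threshold, mono, di),
         non_mutant = size_summary(pooled$non_mutant, threshold, mono, di)),
       test = test, label_counts = label_counts)
}

size_summary_json <- function(s) {
  lapply(s[c("all", "mono", "di")], function(w) {
    w$histogram <- NULL
    w
  })
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop_config("unknown pipeline config key(s): %s",
                paste(unknown, collapse = ", "))
  }
  if (is.null(config$out_dir)) stop_config("pipeline config needs out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the pipeline described by a configuration
#'
#' Stages run in dependency order (simulate_reads, simulate_variants,
#' simulate_cohort, filter, concord, fragsize, refeval); by default every
#' stage with a config block runs. Unknown config keys are rejected before
#' any stage executes, and all randomness flows from the single `seed` key.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param seed optional seed override.
#' @return (invisibly) the manifest list, also written to
#'   `<out_dir>/manifest.json`: package version, seed, config hash and every
#'   stage's output paths.
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_order <- c("simulate_reads", "simulate_variants", "simulate_cohort",
                   "filter", "concord", "fragsize", "refeval")
  stages <- cfg$stages %||% intersect(stage_order, names(cfg))
  bad <- setdiff(stages, stage_order)
  if (length(bad)) stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- intersect(stage_order, stages)
  places <- (cfg$reporting$places %||% 1L)

  outputs <- list()
  state <- new.env(parent = emptyenv())

  cfg_json <- jsonlite::toJSON(cfg[sort(names(cfg))], auto_unbox = TRUE,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)

  for (stage in stages) {
    blk <- cfg[[stage]] %||% list()
    outputs[[stage]] <- switch(stage,
      simulate_reads = {
        vb <- blk$variant
        sc_args <- blk[setdiff(names(blk), "variant")]
        sc_args$seed <- cfg$seed
        if (!is.null(vb)) {
          sc_args$variant <- variant_spec(vb$chrom %||% "sim_ref", vb$pos,
                                          vb$ref, vb$alt)
        }
        sim <- simulate_read_pairs(do.call(sim_config, sc_args))
        state$sim_reads <- sim
        rl <- stats::setNames(sim$config$reference_length,
                              sim$config$variant$chrom)
        paths <- c(sam = file.path(out_dir, "reads.sam"),
                   fasta = file.path(out_dir, "reference.fa"),
                   truth = file.path(out_dir, "reads_truth.tsv"))
        write_sam(sim$records, paths["sam"], rl)
        write_fasta(sim$reference, sim$config$variant$chrom, paths["fasta"])
        utils::write.table(sim$truth, paths["truth"], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        as.list(paths)
      },
      simulate_variants = {
        sv <- simulate_variant_table(cfg$seed, blk$stratum_counts %||% list(),
                                     sample_type = blk$sample_type %||% "tissue")
        state$sim_variants <- sv
        p <- file.path(out_dir, "variants.tsv")
        write_variant_table(sv$table, p)
        list(table = p, expected_pass = sv$expected_pass)
      },
      simulate_cohort = {
        spec_args <- blk; spec_args$seed <- cfg$seed
        co <- simulate_cohort(do.call(cohort_sim_spec, spec_args))
        state$sim_cohort <- co
        paths <- c(tissue = file.path(out_dir, "cohort_tissue.tsv"),
                   plasma = file.path(out_dir, "cohort_plasma.tsv"),
                   truth = file.path(out_dir, "cohort_truth.tsv"))
        write_variant_table(co$tissue, paths["tissue"])
        write_variant_table(co$plasma, paths["plasma"])
        utils::write.table(co$truth, paths["truth"], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        as.list(paths)
      },
      filter = {
        variants <- if (!is.null(blk$input)) {
          read_variant_table(blk$input, col_map = blk$col_map)
        } else if (!is.null(state$sim_variants)) {
          state$sim_variants$table
        } else {
          stop_config("filter stage needs an input or a simulate_variants stage")
        }
        fc_args <- blk[intersect(names(blk), names(formals(filter_config)))]
        rep <- apply_filter_cascade(variants, do.call(filter_config, fc_args))
        state$filtered <- rep$retained
        p_out <- file.path(out_dir, "filtered.tsv")
        p_rep <- file.path(out_dir, "filter_report.json")
        write_variant_table(rep$retained, p_out)
        jsonlite::write_json(list(input_count = rep$input_count,
                                  retained_count = rep$retained_count,
                                  removed = as.list(rep$removed)),
                             p_rep, auto_unbox = TRUE)
        message(sprintf("[filter] %d in, %d retained", rep$input_count,
                        rep$retained_count))
        list(table = p_out, report = p_rep)
      },
      concord = {
        tis <- if (!is.null(blk$tissue)) read_calls_tsv(blk$tissue)
          else state$sim_cohort$tissue
        pla <- if (!is.null(blk$plasma)) read_calls_tsv(blk$plasma)
          else state$sim_cohort$plasma
        if (is.null(tis) || is.null(pla)) {
          stop_config("concord stage needs tissue/plasma inputs or simulate_cohort")
        }
        key_mode <- blk$key_mode %||% "coordinate"
        res <- cohort_detection_rates(tis, pla, key_mode = key_mode,
                                      places = places)
        p <- file.path(out_dir, "concordance.json")
        ov <- res$overall
        jsonlite::write_json(list(
          per_patient = res$per_patient,
          overall = list(numerator = ov$numerator,
                         denominator = ov$denominator,
                         rate_percent = ov$rate_percent,
                         ci_low = ov$ci_low, ci_high = ov$ci_high)),
          p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
        list(report = p)
      },
      fragsize = {
        recs <- if (!is.null(blk$alignments)) read_sam(blk$alignments)
          else state$sim_reads$records
        if (is.null(recs)) {
          stop_config("fragsize stage needs alignments or simulate_reads")
        }
        vars <- if (!is.null(blk$variants)) {
          utils::read.delim(blk$variants, comment.char = "#",
                            stringsAsFactors = FALSE)
        } else if (!is.null(state$sim_reads)) {
          v <- state$sim_reads$config$variant
          data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref_allele,
                     alt = v$alt_allele, stringsAsFactors = FALSE)
        } else {
          stop_config("fragsize stage needs a variants table")
        }
        fa <- fragsize_analysis(recs, vars,
                                min_mapq = blk$min_mapq %||% 20L,
                                threshold = blk$threshold %||% 150L,
                                max_size = blk$max_size %||% 1000L)
        p <- file.path(out_dir, "fragsize_summary.json")
        jsonlite::write_json(list(
          label_counts = as.list(fa$label_counts),
          mutant = size_summary_json(fa$summary$mutant),
          non_mutant = size_summary_json(fa$summary$non_mutant),
          rank_sum = fa$test),
          p, auto_unbox = TRUE, digits = NA)
        rl <- if (!is.null(attr(recs, "ref_lengths")) &&
                  length(attr(recs, "ref_lengths"))) {
          attr(recs, "ref_lengths")
        } else {
          stats::setNames(state$sim_reads$config$reference_length,
                          state$sim_reads$config$variant$chrom)
        }
        combined <- do.call(rbind, fa$calls)
        sams <- write_classified_sam(recs, combined, out_dir, rl)
        c(list(report = p), as.list(sams))
      },
      refeval = {
        panel <- if (!is.null(blk$panel) && file.exists(blk$panel %||% "")) {
          utils::read.delim(blk$panel, comment.char = "#",
                            stringsAsFactors = FALSE)
        } else {
          load_fixture(blk$panel %||% "table2_refmat")
        }
        arm <- blk$arm %||% "liquid_liquid"
        dr <- refmat_detection_rate(panel, arm, places = places)
        p <- file.path(out_dir, "refeval.json")
        jsonlite::write_json(list(arm = arm, numerator = dr$numerator,
                                  denominator = dr$denominator,
                                  rate_percent = dr$rate_percent,
                                  ci_low = dr$ci_low, ci_high = dr$ci_high),
                             p, auto_unbox = TRUE, digits = NA)
        list(report = p)
      })
  }

  manifest <- list(
    package = "plasmaconcord",
    version = as.character(utils::packageVersion("plasmaconcord")),
    seed = cfg$seed, config_hash = cfg_hash, stages = stages,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Calls TSV reader for the concord stage: tolerant about which identity
# columns are present (hgvs or coordinate mode decides what is required).
read_calls_tsv <- function(path) {
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("patient_id" %in% names(out)) out$patient_id <- as.character(out$patient_id)
  out
}
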