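# Seeded generator for paired-end alignments around a single variant locus.
#
# The generator emulates the structure the fragmentomics stage assumes:
# proper read pairs whose outer reference span (|TLEN|) is the cfDNA fragment
# size, a configurable mutant-allele fraction, and allele-specific fragment
# sizes drawn from a two-component (mono-/di-nucleosome) truncated normal
# mixture in which mutant fragments are shorter on average.

#' Describe a variant locus
#'
#' Alleles use the anchored VCF style: an insertion has a 1-base ref and a
#' longer alt beginning with that base; a deletion has a 1-base alt and a
#' longer ref beginning with that base. `kind` is inferred from the allele
#' lengths.
#'
#' @param chrom reference sequence name.
#' @param pos 1-based reference position of the variant anchor base.
#' @param ref_allele,alt_allele allele sequences (A/C/G/T).
#' @return object of class `variant_spec` with fields `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `kind` (one of "SNV", "insertion",
#'   "deletion").
#' @export
#' @examples
#' variant_spec("chr12", 25245350, "C", "A")          # SNV (KRAS-like)
#' variant_spec("chr5", 112839000, "A", "AT")         # 1-bp insertion
#' variant_spec("chr17", 7675000, "TGC", "T")         # 2-bp deletion
variant_spec <- function(chrom, pos, ref_allele, alt_allele) {
  stopifnot(is.character(chrom), length(chrom) == 1,
            is_count(pos), pos >= 1,
            is.character(ref_allele), is.character(alt_allele))
  ok <- function(a) grepl("^[ACGT]+$", a)
  if (!ok(ref_allele) || !ok(alt_allele)) {
    stop_config("alleles must be non-empty A/C/G/T strings")
  }
  nr <- nchar(ref_allele); na <- nchar(alt_allele)
  if (nr == 1 && na == 1) {
    if (ref_allele == alt_allele) stop_config("SNV with identical alleles")
    kind <- "SNV"
  } else if (nr == 1 && na > 1) {
    if (substr(alt_allele, 1, 1) != ref_allele) {
      stop_config("insertion alt must begin with the anchor (ref) base")
    }
    kind <- "insertion"
  } else if (na == 1 && nr > 1) {
    if (substr(ref_allele, 1, 1) != alt_allele) {
      stop_config("deletion ref must begin with the anchor (alt) base")
    }
    kind <- "deletion"
  } else {
    stop_config("unsupported allele pair (complex variants are out of scope)")
  }
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 kind = kind),
            class = "variant_spec")
}

# Inserted / deleted sequence relative to the anchor.
variant_indel_seq <- function(variant) {
  switch(variant$kind,
         insertion = substr(variant$alt_allele, 2, nchar(variant$alt_allele)),
         deletion  = substr(variant$ref_allele, 2, nchar(variant$ref_allele)),
         "")
}

# Reference interval a mate must fully align over (with one anchor base each
# side) to be informative for the variant.
variant_core <- function(variant) {
  pos <- variant$pos
  core <- switch(variant$kind,
    SNV       = c(pos, pos),
    insertion = c(pos, pos + 1L),
    deletion  = c(pos, pos + nchar(variant_indel_seq(variant)) + 1L)
  )
  c(core[1] - 1L, core[2] + 1L)
}

#' Configure the read-pair simulator
#'
#' Defaults state the world the package models: mutant fragments centred at
#' 153 bp and non-mutant at 162 bp (the mono-nucleosome means observed in
#' patient plasma), a di-nucleosome mixture component offset by +150 bp,
#' and sizes truncated to the 50-400 bp window used for nucleosome
#' segregation.
#'
#' @param seed integer seed; identical config + seed gives identical output.
#' @param reference_length reference length in bases (>= 2000).
#' @param variant a [variant_spec()]; default is a SNV at the reference
#'   midpoint.
#' @param n_fragments number of fragments (read pairs) to emit.
#' @param mutant_fraction probability a fragment carries the alt allele.
#' @param mutant_size_mean,mutant_size_sd mono-nucleosome size distribution of
#'   mutant fragments, bp.
#' @param nonmutant_size_mean,nonmutant_size_sd same for non-mutant fragments.
#' @param dinucleosome_weight mixture weight of the di-nucleosome component.
#' @param dinucleosome_offset mean shift of the di-nucleosome component, bp.
#' @param read_length aligned mate length, bp.
#' @param min_size,max_size truncation bounds for fragment sizes, bp.
#' @param background_fraction fraction of fragments placed away from the
#'   variant locus (exercise the not-covered path); default 0.
#' @param error_rate per-base substitution error probability; default 0 so
#'   truth labels are exact.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       reference_length = 3000L,
                       variant = NULL,
                       n_fragments = 1000L,
                       mutant_fraction = 0.1,
                       mutant_size_mean = 153, mutant_size_sd = 20,
                       nonmutant_size_mean = 162, nonmutant_size_sd = 20,
                       dinucleosome_weight = 0.15,
                       dinucleosome_offset = 150,
                       read_length = 75L,
                       min_size = 50L, max_size = 400L,
                       background_fraction = 0,
                       error_rate = 0) {
  if (is.null(variant)) {
    variant <- variant_spec("sim_ref", as.integer(reference_length / 2), "G", "T")
  }
  stopifnot(inherits(variant, "variant_spec"))
  if (!is_count(reference_length) || reference_length < 2000) {
    stop_config("reference_length must be an integer >= 2000")
  }
  if (!is_count(n_fragments)) stop_config("n_fragments must be a count")
  for (p in c(mutant_fraction, dinucleosome_weight, background_fraction,
              error_rate)) {
    if (!is_prob(p)) stop_config("probabilities must lie in [0, 1]")
  }
  if (min_size < 2 || max_size <= min_size) {
    stop_config("need 2 <= min_size < max_size")
  }
  if (max_size > reference_length - 2) {
    stop_config("max_size must leave placement margin inside the reference")
  }
  core <- variant_core(variant)
  if (core[1] < 1 || core[2] > reference_length) {
    stop_config("variant core extends outside the reference")
  }
  if (read_length < core[2] - core[1] + 1) {
    stop_config("read_length too short to span the variant core with anchors")
  }
  # truncated supports must hold usable mass for both allele classes
  for (m in c(mutant_size_mean, nonmutant_size_mean)) {
    mass <- (stats::pnorm(max_size, m, mutant_size_sd) -
               stats::pnorm(min_size, m, mutant_size_sd))
    if (mass < 1e-6) stop_config("empty truncated size support for mean %g", m)
  }
  structure(list(
    seed = as.integer(seed), reference_length = as.integer(reference_length),
    variant = variant, n_fragments = as.integer(n_fragments),
    mutant_fraction = mutant_fraction,
    mutant_size_mean = mutant_size_mean, mutant_size_sd = mutant_size_sd,
    nonmutant_size_mean = nonmutant_size_mean,
    nonmutant_size_sd = nonmutant_size_sd,
    dinucleosome_weight = dinucleosome_weight,
    dinucleosome_offset = dinucleosome_offset,
    read_length = as.integer(read_length),
    min_size = as.integer(min_size), max_size = as.integer(max_size),
    background_fraction = background_fraction, error_rate = error_rate
  ), class = "sim_config")
}

#' Generate a deterministic random reference sequence
#'
#' @param seed integer seed.
#' @param length sequence length in bases (>= 2000).
#' @return a single character string over A/C/G/T.
#' @export
generate_reference <- function(seed, length) {
  if (!is_count(length) || length < 2000) {
    stop_config("reference length must be an integer >= 2000")
  }
  local_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                         collapse = ""))
}

rtrunc_norm_int <- function(n, mean, sd, lo, hi, max_tries = 10000L) {
  out <- integer(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- as.integer(round(stats::rnorm(n - length(out), mean, sd)))
    draw <- draw[draw >= lo & draw <= hi]
    out <- c(out, draw)
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_config("truncated size support [%d, %d] is effectively empty", lo, hi)
    }
  }
  out
}

int_range <- function(lo, hi) if (lo > hi) integer(0) else seq.int(lo, hi)

# Legal fragment starts such that at least one mate fully spans `core`.
covering_starts <- function(size, rl, core, ref_len) {
  c1 <- core[1]; c2 <- core[2]
  # mate1 (left, [s, min(s+rl-1, s+size-1)]) covers core
  a1 <- int_range(max(1L, c2 - size + 1L, c2 - rl + 1L),
                  min(c1, ref_len - size + 1L))
  # mate2 (right, [max(s, e-rl+1), e]) covers core
  a2 <- int_range(max(1L, c2 - size + 1L),
                  min(c1, c1 - size + rl, ref_len - size + 1L))
  unique(c(a1, a2))
}

ref_sub <- function(ref, lo, hi) if (lo > hi) "" else substr(ref, lo, hi)

# Build one mate's (pos, cigar, seq) over reference interval [rs, re],
# honouring the fragment's allele. Mutant mates that only partially overlap
# an indel's core are trimmed back to the anchor so they never contradict
# the fragment label.
build_mate <- function(rs, re, mutant, variant, ref) {
  pos <- variant$pos
  ind <- variant_indel_seq(variant)
  il <- nchar(ind)
  if (mutant && variant$kind == "SNV" && rs <= pos && re >= pos) {
    s <- ref_sub(ref, rs, re)
    substr(s, pos - rs + 1L, pos - rs + 1L) <- variant$alt_allele
    return(list(pos = rs, cigar = sprintf("%dM", re - rs + 1L), seq = s))
  }
  if (mutant && variant$kind == "insertion" && rs <= pos && re >= pos + 1L) {
    cig <- sprintf("%dM%dI%dM", pos - rs + 1L, il, re - pos)
    s <- paste0(ref_sub(ref, rs, pos), ind, ref_sub(ref, pos + 1L, re))
    return(list(pos = rs, cigar = cig, seq = s))
  }
  if (mutant && variant$kind == "deletion") {
    ds <- pos + 1L; de <- pos + il
    if (rs <= pos && re >= de + 1L) {
      cig <- sprintf("%dM%dD%dM", pos - rs + 1L, il, re - de)
      s <- paste0(ref_sub(ref, rs, pos), ref_sub(ref, de + 1L, re))
      return(list(pos = rs, cigar = cig, seq = s))
    }
    # partial overlap with the deleted span: trim to the anchor base
    if (rs <= pos && re >= ds) re <- pos
    if (re >= de + 1L && rs <= de) rs <- de + 1L
  }
  list(pos = rs, cigar = sprintf("%dM", re - rs + 1L),
       seq = ref_sub(ref, rs, re))
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(bases, collapse = "")
}

#' Simulate aligned read pairs around a variant locus
#'
#' Draws an allele label per fragment (mutant with probability
#' `mutant_fraction`), a fragment size from the allele's truncated normal
#' mixture, and a placement that guarantees at least one mate aligns across
#' the variant with a one-base anchor on each side (background fragments, if
#' requested, are placed off the locus instead). Mutant fragments carry the
#' alt allele as a base substitution (SNV) or an I/D CIGAR operation (indel).
#' TLEN of the leftmost mate equals the fragment's reference span.
#'
#' @param config a [sim_config()].
#' @return list with `records` (SAM-writable data.frame, two rows per
#'   fragment), `truth` (data.frame: fragment, label, size, start, end,
#'   covers_locus), `reference` (the reference string) and `config`.
#' @export
simulate_read_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variant
  ref <- generate_reference(config$seed, config$reference_length)
  # force the reference to agree with the declared ref allele
  substr(ref, v$pos, v$pos + nchar(v$ref_allele) - 1L) <- v$ref_allele
  core <- variant_core(v)
  rl <- config$read_length
  n <- config$n_fragments

  local_seed(config$seed + 1L, {
    n_bg <- floor(config$background_fraction * n)
    is_bg <- rep(c(TRUE, FALSE), c(n_bg, n - n_bg))
    mutant <- !is_bg & stats::runif(n) < config$mutant_fraction
    mean0 <- ifelse(mutant, config$mutant_size_mean, config$nonmutant_size_mean)
    sd0 <- ifelse(mutant, config$mutant_size_sd, config$nonmutant_size_sd)
    di <- stats::runif(n) < config$dinucleosome_weight
    means <- mean0 + ifelse(di, config$dinucleosome_offset, 0)
    lo <- max(config$min_size, core[2] - core[1] + 1L)
    sizes <- vapply(seq_len(n), function(i) {
      rtrunc_norm_int(1L, means[i], sd0[i], lo, config$max_size)
    }, integer(1))

    starts <- integer(n)
    for (i in seq_len(n)) {
      if (is_bg[i]) {
        cand <- int_range(1L, config$reference_length - sizes[i] + 1L)
        cand <- cand[cand + sizes[i] - 1L < core[1] | cand > core[2]]
        if (!length(cand)) {
          stop_config("no off-locus placement possible for background fragment")
        }
        starts[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      } else {
        cand <- covering_starts(sizes[i], rl, core, config$reference_length)
        if (!length(cand)) {
          stop_config("no placement lets a mate span the variant core (size %d)",
                      sizes[i])
        }
        starts[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
    }
    ends <- starts + sizes - 1L
    read1_left <- stats::runif(n) < 0.5

    recs <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      s <- starts[i]; e <- ends[i]
      left <- build_mate(s, min(s + rl - 1L, e), mutant[i], v, ref)
      right <- build_mate(max(s, e - rl + 1L), e, mutant[i], v, ref)
      if (config$error_rate > 0) {
        left$seq <- apply_errors(left$seq, config$error_rate)
        right$seq <- apply_errors(right$seq, config$error_rate)
      }
      fl <- FLAG_PAIRED + FLAG_PROPER + FLAG_MATE_REVERSE +
        if (read1_left[i]) FLAG_READ1 else FLAG_READ2        # 99 or 163
      fr <- FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE +
        if (read1_left[i]) FLAG_READ2 else FLAG_READ1        # 147 or 83
      qn <- sprintf("frag_%05d", i)
      recs[[2L * i - 1L]] <- data.frame(
        qname = qn, flag = fl, rname = v$chrom, pos = left$pos, mapq = 60L,
        cigar = left$cigar, rnext = "=", pnext = right$pos,
        tlen = sizes[i], seq = left$seq, qual = strrep("I", nchar(left$seq)),
        stringsAsFactors = FALSE)
      recs[[2L * i]] <- data.frame(
        qname = qn, flag = fr, rname = v$chrom, pos = right$pos, mapq = 60L,
        cigar = right$cigar, rnext = "=", pnext = left$pos,
        tlen = -sizes[i], seq = right$seq, qual = strrep("I", nchar(right$seq)),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    truth <- data.frame(
      fragment = sprintf("frag_%05d", seq_len(n)),
      label = ifelse(is_bg, "background",
                     ifelse(mutant, "mutant", "non_mutant")),
      size = sizes, start = starts, end = ends,
      covers_locus = !is_bg, stringsAsFactors = FALSE)
    list(records = records, truth = truth, reference = ref, config = config)
  })
}
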