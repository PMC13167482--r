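# Allele-aware cfDNA fragment-size analysis.
#
# Read pairs overlapping a variant locus are classified as mutant /
# non-mutant by positional CIGAR pattern matching (exact base for SNVs,
# exact-length I/D operation at the exact junction/span for indels), then
# per-fragment insert sizes (|TLEN|) are summarised below a 150 bp threshold
# and inside mono- (50-220 bp) and di-nucleosome (221-400 bp) windows, with a
# one-sided rank-sum test for the mutant-shorter alternative.

CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")
CIGAR_ALIGNED_OPS <- c("M", "=", "X")

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string, e.g. "10M5D40M"; "*" yields zero operations.
#' @return data.frame with character `op` and integer `len`.
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1)
  if (cigar == "*" || cigar == "") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop_config("malformed CIGAR '%s'", cigar)
  }
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

cigar_query_length <- function(ops) sum(ops$len[ops$op %in% CIGAR_QUERY_OPS])
cigar_ref_length <- function(ops) sum(ops$len[ops$op %in% CIGAR_REF_OPS])

#' Project a reference position onto a read
#'
#' Walks the CIGAR maintaining a (reference, query) cursor pair: M/=/X advance
#' both, I/S advance the query, D/N advance the reference, H/P neither.
#'
#' @param pos 1-based leftmost aligned reference position of the read.
#' @param cigar the read's CIGAR string.
#' @param ref_pos reference position to project.
#' @return list with `covered` (TRUE iff `ref_pos` maps to an aligned query
#'   base), `offset` (0-based query offset, NA when not covered) and `op`
#'   (the CIGAR op containing `ref_pos`, NA when outside the alignment span;
#'   "D"/"N" with `covered = FALSE` when the position falls in a deletion or
#'   skip).
#' @export
project_locus <- function(pos, cigar, ref_pos) {
  ops <- parse_cigar(cigar)
  r <- as.integer(pos)  # next reference base to consume
  q <- 0L               # query bases consumed
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% CIGAR_ALIGNED_OPS) {
      if (ref_pos >= r && ref_pos <= r + len - 1L) {
        return(list(covered = TRUE, offset = q + (ref_pos - r), op = op))
      }
      r <- r + len; q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (ref_pos >= r && ref_pos <= r + len - 1L) {
        return(list(covered = FALSE, offset = NA_integer_, op = op))
      }
      r <- r + len
    } # H, P: no cursor movement
  }
  list(covered = FALSE, offset = NA_integer_, op = NA_character_)
}

# TRUE iff every reference position in [lo, hi] is consumed by an aligned op.
aligned_over <- function(pos, cigar, lo, hi) {
  if (lo > hi) return(TRUE)
  for (p in lo:hi) {
    pr <- project_locus(pos, cigar, p)
    if (!pr$covered) return(FALSE)
  }
  TRUE
}

#' Classify one read against a variant
#'
#' Positional CIGAR pattern matching. SNV: the projected base must equal the
#' alt (mutant) or ref (non-mutant) allele. Insertion: an I operation of
#' exactly the inserted length, carrying exactly the inserted sequence, at
#' the junction between the anchor base and the next reference base (mutant);
#' a junction spanned by aligned ops with no insertion (non-mutant).
#' Deletion: a D operation exactly covering the deleted span (mutant); the
#' span fully aligned (non-mutant). Any other pattern at the locus is
#' `other_allele`. In every case `min_anchor` aligned bases are required on
#' both sides of the locus/junction, otherwise `not_covered`.
#'
#' @param record one alignment record: list/one-row data.frame with `rname`,
#'   `pos`, `cigar`, `seq`.
#' @param variant a [variant_spec()].
#' @param min_anchor aligned bases required on each side of the locus.
#' @return label string: "mutant", "non_mutant", "other_allele" or
#'   "not_covered".
#' @export
classify_read <- function(record, variant, min_anchor = 1L) {
  stopifnot(inherits(variant, "variant_spec"))
  if (record$rname != variant$chrom) return("not_covered")
  pos <- variant$pos
  cig <- record$cigar
  rpos <- record$pos

  if (variant$kind == "SNV") {
    pr <- project_locus(rpos, cig, pos)
    if (!pr$covered) return("not_covered")
    if (!aligned_over(rpos, cig, pos - min_anchor, pos - 1L) ||
        !aligned_over(rpos, cig, pos + 1L, pos + min_anchor)) {
      return("not_covered")
    }
    base <- substr(record$seq, pr$offset + 1L, pr$offset + 1L)
    if (base == variant$alt_allele) return("mutant")
    if (base == variant$ref_allele) return("non_mutant")
    return("other_allele")
  }

  ind <- variant_indel_seq(variant)
  il <- nchar(ind)

  if (variant$kind == "insertion") {
    # anchors: `min_anchor` aligned bases ending at pos, starting at pos + 1
    if (!aligned_over(rpos, cig, pos - min_anchor + 1L, pos) ||
        !aligned_over(rpos, cig, pos + 1L, pos + min_anchor)) {
      return("not_covered")
    }
    ops <- parse_cigar(cig)
    r <- as.integer(rpos); q <- 0L
    for (i in seq_len(nrow(ops))) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op == "I" && r == pos + 1L) {
        inserted <- substr(record$seq, q + 1L, q + len)
        return(if (len == il && inserted == ind) "mutant" else "other_allele")
      }
      if (op %in% CIGAR_ALIGNED_OPS) { r <- r + len; q <- q + len }
      else if (op %in% c("I", "S")) q <- q + len
      else if (op %in% c("D", "N")) {
        if (r <= pos + 1L && r + len > pos + 1L) return("other_allele")
        r <- r + len
      }
    }
    return("non_mutant")  # junction spanned by aligned ops, no I there
  }

  # deletion: span ds..de must be either one exact D op or fully aligned
  ds <- pos + 1L; de <- pos + il
  ops <- parse_cigar(cig)
  span_hi <- rpos + cigar_ref_length(ops) - 1L
  lo_req <- pos - min_anchor + 1L; hi_req <- de + min_anchor
  if (rpos > lo_req || span_hi < hi_req) return("not_covered")
  anchors_ok <- aligned_over(rpos, cig, lo_req, pos) &&
    aligned_over(rpos, cig, de + 1L, hi_req)
  r <- as.integer(rpos)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("D", "N")) {
      if (r == ds && len == il && op == "D" && anchors_ok) return("mutant")
      # any other gap touching the span or its anchors is a different allele
      if (r <= hi_req && r + len - 1L >= lo_req) return("other_allele")
      r <- r + len
    } else if (op %in% CIGAR_ALIGNED_OPS) {
      r <- r + len
    }
  }
  if (anchors_ok && aligned_over(rpos, cig, ds, de)) return("non_mutant")
  "other_allele"
}

#' Classify fragments (read pairs) at a variant locus
#'
#' Secondary, supplementary and duplicate records are dropped; mates below
#' `min_mapq` are ignored. Per query name: agreeing informative mates (or a
#' single informative mate) give the fragment label; conflicting informative
#' mates are excluded as "ambiguous"; fragments with no informative mate are
#' "not_covered".
#'
#' @param records alignment-record data.frame (see [read_sam()]).
#' @param variant a [variant_spec()].
#' @param min_mapq minimum mapping quality per mate.
#' @param min_anchor passed to [classify_read()].
#' @return data.frame with `fragment`, `label` (mutant / non_mutant /
#'   other_allele / ambiguous / not_covered) and `n_informative` (mates that
#'   produced an informative call).
#' @export
classify_fragments <- function(records, variant, min_mapq = 20L,
                               min_anchor = 1L) {
  stopifnot(is.data.frame(records))
  keep <- !flag_has(records$flag, FLAG_SECONDARY) &
    !flag_has(records$flag, FLAG_SUPPLEMENTARY) &
    !flag_has(records$flag, FLAG_DUP)
  prim <- records[keep, , drop = FALSE]
  counts <- table(prim$qname)
  if (any(counts > 2)) {
    stop_config("query name '%s' has %d primary records (max 2)",
                names(counts)[which(counts > 2)[1]], max(counts))
  }
  qnames <- unique(prim$qname)
  labels <- character(length(qnames))
  n_inf <- integer(length(qnames))
  informative <- c("mutant", "non_mutant", "other_allele")
  idx <- split(seq_len(nrow(prim)), prim$qname)
  for (j in seq_along(qnames)) {
    rows <- idx[[qnames[j]]]
    calls <- character(0)
    for (i in rows) {
      if (prim$mapq[i] < min_mapq) next
      calls <- c(calls, classify_read(prim[i, ], variant, min_anchor))
    }
    calls <- calls[calls %in% informative]
    u <- unique(calls)
    labels[j] <- if (length(u) == 0) "not_covered"
      else if (length(u) == 1) u
      else "ambiguous"
    n_inf[j] <- length(calls)
  }
  data.frame(fragment = qnames, label = labels, n_informative = n_inf,
             stringsAsFactors = FALSE)
}

#' Extract per-fragment insert sizes by allele label
#'
#' One size per fragment, taken as the TLEN of the mate with positive TLEN.
#' Fragments with TLEN 0, |TLEN| above `max_size`, or mates whose TLENs are
#' not negations of each other are excluded and tallied.
#'
#' @param fragment_calls output of [classify_fragments()].
#' @param records the alignment records the calls came from.
#' @param max_size maximum plausible template length, bp.
#' @return list with `sizes` (named list of integer vectors for labels
#'   mutant, non_mutant, other_allele) and `excluded` (named counts:
#'   zero_tlen, oversize, inconsistent).
#' @export
fragment_sizes <- function(fragment_calls, records, max_size = 1000L) {
  excluded <- c(zero_tlen = 0L, oversize = 0L, inconsistent = 0L)
  sizes <- list(mutant = integer(0), non_mutant = integer(0),
                other_allele = integer(0))
  keep <- fragment_calls$label %in% names(sizes)
  tl_by_frag <- split(records$tlen, records$qname)
  for (i in which(keep)) {
    frag <- fragment_calls$fragment[i]
    tl <- tl_by_frag[[frag]]
    if (is.null(tl)) next
    if (all(tl == 0)) { excluded["zero_tlen"] <- excluded["zero_tlen"] + 1L; next }
    if (length(tl) == 2 && tl[1] != -tl[2]) {
      warning(sprintf("fragment %s: mate TLENs %d/%d are not negations; excluded",
                      frag, tl[1], tl[2]))
      excluded["inconsistent"] <- excluded["inconsistent"] + 1L
      next
    }
    sz <- abs(tl[tl > 0][1])
    if (is.na(sz)) { excluded["zero_tlen"] <- excluded["zero_tlen"] + 1L; next }
    if (sz > max_size) { excluded["oversize"] <- excluded["oversize"] + 1L; next }
    sizes[[fragment_calls$label[i]]] <- c(sizes[[fragment_calls$label[i]]], sz)
  }
  list(sizes = sizes, excluded = excluded)
}

window_stats <- function(sizes, threshold, window_name, lo = NULL, hi = NULL) {
  s <- if (is.null(lo)) sizes else sizes[sizes >= lo & sizes <= hi]
  n <- length(s)
  hist <- if (n) {
    tb <- table(s)
    data.frame(bin = as.integer(names(tb)), count = as.integer(tb))
  } else {
    data.frame(bin = integer(0), count = integer(0))
  }
  list(window = window_name, n = n,
       mean = if (n) mean(s) else NA_real_,
       median = if (n) stats::median(s) else NA_real_,
       n_below_threshold = sum(s < threshold),
       fraction_below_threshold = if (n) sum(s < threshold) / n else NA_real_,
       histogram = hist)
}

#' Summarise an insert-size distribution
#'
#' The sub-threshold fraction uses a strict `<` ("below 150 bp"); window
#' membership is inclusive of both endpoints, so 220 bp is mono-nucleosome
#' and 221 bp is di-nucleosome.
#'
#' @param sizes integer vector of fragment sizes, bp.
#' @param threshold short-fragment cutoff, bp.
#' @param mono,di inclusive \[lo, hi\] windows for the mono- and
#'   di-nucleosome populations, bp.
#' @return object of class `insert_size_summary`: list of per-window stats
#'   (`all`, `mono`, `di`), each with n, mean, median, n_below_threshold,
#'   fraction_below_threshold and a (bin, count) histogram. Empty windows
#'   have n = 0 and NA fractions.
#' @export
size_summary <- function(sizes, threshold = 150L, mono = c(50L, 220L),
                         di = c(221L, 400L)) {
  stopifnot(is.numeric(sizes), all(sizes >= 0))
  structure(list(
    all = window_stats(sizes, threshold, "all"),
    mono = window_stats(sizes, threshold, "mono", mono[1], mono[2]),
    di = window_stats(sizes, threshold, "di", di[1], di[2]),
    threshold = threshold
  ), class = "insert_size_summary")
}

#' @export
print.insert_size_summary <- function(x, ...) {
  for (w in c("all", "mono", "di")) {
    s <- x[[w]]
    cat(sprintf("%-5s n=%-6d mean=%-7.1f median=%-6.1f below %d bp: %s\n",
                w, s$n, s$mean, s$median, x$threshold,
                if (is.na(s$fraction_below_threshold)) "NA"
                else report_percent(s$fraction_below_threshold, 1)))
  }
  invisible(x)
}

#' One-sided rank-sum (Mann-Whitney) test: is sample a stochastically smaller?
#'
#' Exact null enumeration of rank assignments (with midranks for ties) when
#' `min(n_a, n_b) <= exact_max_single` and `n_a + n_b <= exact_max_total`;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The statistic is the Mann-Whitney U of sample `a`.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max_single,exact_max_total cutoffs for exact enumeration.
#' @return list with `p_value`, `statistic` (U of a), `method` ("exact" or
#'   "normal_approx").
#' @export
rank_sum_less <- function(a, b, exact_max_single = 8L, exact_max_total = 20L) {
  if (!length(a) || !length(b)) stop_config("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  ra <- sum(rk[seq_len(na)])
  u <- ra - na * (na + 1) / 2
  if (min(na, nb) <= exact_max_single && n <= exact_max_total) {
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(rk[combos], nrow = na))
    p <- mean(sums <= ra + 1e-9)
    return(list(p_value = p, statistic = u, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(p_value = 1, statistic = u, method = "normal_approx"))
  }
  z <- (u - mu + 0.5) / sqrt(sigma2)
  list(p_value = stats::pnorm(z), statistic = u, method = "normal_approx")
}

#' Write classified records into separate SAM files
#'
#' Mirrors sorting allele-supporting read pairs into separate alignment
#' files: every record whose fragment is labelled mutant goes to
#' `mutant.sam`, non-mutant to `non_mutant.sam`.
#'
#' @param records alignment records.
#' @param fragment_calls output of [classify_fragments()].
#' @param dir output directory (created if needed).
#' @param ref_lengths named reference lengths for the SAM header.
#' @return named character vector of the two paths, invisibly.
#' @export
write_classified_sam <- function(records, fragment_calls, dir, ref_lengths) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(mutant = file.path(dir, "mutant.sam"),
           non_mutant = file.path(dir, "non_mutant.sam"))
  for (lab in names(out)) {
    frags <- fragment_calls$fragment[fragment_calls$label == lab]
    write_sam(records[records$qname %in% frags, , drop = FALSE],
              out[[lab]], ref_lengths)
  }
  invisible(out)
}
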