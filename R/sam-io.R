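# Plain-text SAM and FASTA I/O.
#
# Alignment records live in an ordinary data.frame with the eleven mandatory
# SAM columns (qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
# qual). Only single-reference, tag-free SAM is written; the reader tolerates
# optional tags by ignoring them.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Write alignment records as SAM
#'
#' Emits a minimal, valid SAM file: an `@HD` line, one `@SQ` line per
#' reference sequence, then the eleven mandatory columns per record.
#'
#' @param records data.frame of alignment records (see [read_sam()] for the
#'   column contract).
#' @param path output file path.
#' @param ref_lengths named integer vector, reference name -> length, used for
#'   the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, ref_lengths) {
  stopifnot(is.data.frame(records), all(SAM_COLS %in% names(records)))
  stopifnot(!is.null(names(ref_lengths)), all(ref_lengths > 0))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  body <- do.call(paste, c(unname(records[SAM_COLS]), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment-record data.frame
#'
#' Header lines are skipped (reference lengths are returned as an attribute);
#' optional tag fields beyond column 11 are dropped. This is deliberately a
#' light reader for the tag-free SAM this package emits and consumes.
#'
#' @param path SAM file path.
#' @return data.frame with columns qname (character), flag (integer), rname
#'   (character), pos (integer), mapq (integer), cigar (character), rnext
#'   (character), pnext (integer), tlen (integer), seq (character), qual
#'   (character), and attribute `ref_lengths` (named integer vector from
#'   `@SQ`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- stats::setNames(ln, sn)
  }
  if (!length(body)) {
    out <- data.frame(matrix(nrow = 0, ncol = 11))
    names(out) <- SAM_COLS
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 11)) {
      stop_config("malformed SAM: line with %d < 11 fields", min(nf))
    }
    grab <- function(i) vapply(parts, `[[`, character(1), i)
    out <- data.frame(
      qname = grab(1), flag = as.integer(grab(2)), rname = grab(3),
      pos = as.integer(grab(4)), mapq = as.integer(grab(5)),
      cigar = grab(6), rnext = grab(7), pnext = as.integer(grab(8)),
      tlen = as.integer(grab(9)), seq = grab(10), qual = grab(11),
      stringsAsFactors = FALSE
    )
  }
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Write a reference sequence as FASTA
#'
#' @param seq character scalar of A/C/G/T.
#' @param name sequence name for the FASTA header.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, name, path, width = 70) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) > 0)
  starts <- seq.int(1, nchar(seq), by = width)
  chunks <- substring(seq, starts, pmin(starts + width - 1, nchar(seq)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}

# SAM flag bits used throughout.
FLAG_PAIRED <- 0x1
FLAG_PROPER <- 0x2
FLAG_REVERSE <- 0x10
FLAG_MATE_REVERSE <- 0x20
FLAG_READ1 <- 0x40
FLAG_READ2 <- 0x80
FLAG_SECONDARY <- 0x100
FLAG_DUP <- 0x400
FLAG_SUPPLEMENTARY <- 0x800

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L
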