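# SAM text I/O and the mapping-quality gate.
#
# Records are held as a plain data.frame with the 11 mandatory SAM columns
# (qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual);
# the header lines travel along as the "header" attribute. All user-facing
# coordinates are 1-based inclusive, as in SAM itself.

CIGAR_RE <- "^(\\*|([0-9]+[MIDNSHP=X])+)$"

cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op = sub("^[0-9]+", "", m))
}

# Query-consuming length implied by a CIGAR (M, I, S, =, X).
cigar_query_length <- function(cigar) {
  if (cigar == "*") return(NA_integer_)
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

# Reference span (number of reference bases consumed: M, D, N, =, X).
cigar_reference_length <- function(cigar) {
  if (cigar == "*") return(NA_integer_)
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' Read a SAM text file
#'
#' Parses the 11 mandatory columns of every record line, keeps the header
#' as an attribute, and validates each record: well-formed CIGAR, and the
#' query-consuming CIGAR length must equal the sequence length. Malformed
#' lines are reported with their line number. Unmapped records (FLAG 0x4)
#' are kept and can be identified with \code{\link{is_unmapped}}.
#'
#' @param path Path to a SAM text file.
#' @return data.frame of records (possibly zero rows) with the header lines
#'   in \code{attr(, "header")}.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body_idx <- which(!is_hdr & nzchar(lines))
  if (any(is_hdr & seq_along(lines) > suppressWarnings(min(body_idx))))
    stop("header line after first record", call. = FALSE)
  if (!length(body_idx)) {
    out <- empty_sam()
    attr(out, "header") <- header
    return(out)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed record at line %d: %d fields (need >= 11)",
                 body_idx[which(nf < 11L)[1L]], nf[which(nf < 11L)[1L]]),
         call. = FALSE)
  take <- function(i, mode = "character") {
    v <- vapply(fields, `[[`, character(1), i)
    if (mode == "integer") {
      iv <- suppressWarnings(as.integer(v))
      if (anyNA(iv))
        stop(sprintf("malformed record at line %d: non-integer field %d",
                     body_idx[which(is.na(iv))[1L]], i), call. = FALSE)
      iv
    } else v
  }
  out <- data.frame(
    qname = take(1), flag = take(2, "integer"), rname = take(3),
    pos = take(4, "integer"), mapq = take(5, "integer"),
    cigar = take(6), rnext = take(7), pnext = take(8, "integer"),
    tlen = take(9, "integer"), seq = take(10), qual = take(11),
    stringsAsFactors = FALSE)

  bad_cigar <- !grepl(CIGAR_RE, out$cigar)
  if (any(bad_cigar))
    stop(sprintf("malformed record at line %d: invalid CIGAR '%s'",
                 body_idx[which(bad_cigar)[1L]],
                 out$cigar[which(bad_cigar)[1L]]), call. = FALSE)
  has_seq <- out$seq != "*" & out$cigar != "*"
  if (any(has_seq)) {
    qlen <- vapply(out$cigar[has_seq], cigar_query_length, integer(1))
    mismatch <- qlen != nchar(out$seq[has_seq])
    if (any(mismatch)) {
      j <- which(has_seq)[which(mismatch)[1L]]
      stop(sprintf(
        "malformed record at line %d: CIGAR implies %d query bases but seq has %d",
        body_idx[j], vapply(out$cigar[j], cigar_query_length, integer(1)),
        nchar(out$seq[j])), call. = FALSE)
    }
  }
  if (any(out$pos < 0L))
    stop(sprintf("malformed record at line %d: negative POS",
                 body_idx[which(out$pos < 0L)[1L]]), call. = FALSE)
  attr(out, "header") <- header
  out
}

empty_sam <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), stringsAsFactors = FALSE)
}

#' @rdname read_sam
#' @param reads Record data.frame as returned by \code{read_sam} or the
#'   simulator.
#' @param sq Named integer vector of contig lengths for the \code{@SQ}
#'   header lines; inferred from the records when omitted.
#' @export
write_sam <- function(reads, path, sq = NULL) {
  if (is.null(sq)) {
    mapped <- reads[reads$rname != "*", , drop = FALSE]
    if (nrow(mapped)) {
      span <- vapply(mapped$cigar, cigar_reference_length, integer(1))
      ends <- mapped$pos + ifelse(is.na(span), 0L, span) - 1L
      sq <- tapply(ends, mapped$rname, max)
    } else sq <- integer()
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           if (length(sq))
             sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- do.call(paste, c(unname(reads[c("qname", "flag", "rname", "pos",
                                          "mapq", "cigar", "rnext", "pnext",
                                          "tlen", "seq", "qual")]),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Flag helpers
#' @param reads Record data.frame.
#' @return Logical vector.
#' @export
is_unmapped <- function(reads) bitwAnd(reads$flag, 0x4L) != 0L

#' @rdname is_unmapped
#' @export
is_secondary_or_supplementary <- function(reads)
  bitwAnd(reads$flag, bitwOr(0x100L, 0x800L)) != 0L

#' @rdname is_unmapped
#' @export
is_duplicate <- function(reads) bitwAnd(reads$flag, 0x400L) != 0L

#' Mapping-quality filter
#'
#' Retains exactly the records with MAPQ strictly greater than the
#' threshold (the published filter keeps MAPQ > 10). The number of removed
#' records is reported as a message and attached as the
#' \code{"n_removed"} attribute.
#'
#' @param reads Record data.frame.
#' @param threshold Nonnegative integer; records with \code{mapq >
#'   threshold} are kept.
#' @return Filtered data.frame.
#' @export
filter_mapq <- function(reads, threshold = 10L) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  keep <- reads$mapq > threshold
  out <- reads[keep, , drop = FALSE]
  attr(out, "header") <- attr(reads, "header")
  attr(out, "n_removed") <- sum(!keep)
  message(sprintf("filter_mapq: removed %d of %d records (MAPQ <= %d)",
                  sum(!keep), length(keep), as.integer(threshold)))
  out
}

#' Base aligned to a reference position
#'
#' Walks the read's CIGAR to find the query base aligned to a 1-based
#' reference position. Match ops (M, =, X) yield the base and its Phred
#' quality; a position inside a deletion yields \code{"DELETED"}; positions
#' outside the aligned span (including soft/hard clips) yield
#' \code{"NOT_COVERED"}. Inserted bases consume query only and never map to
#' a reference position.
#'
#' @param read One record (single-row data.frame or list with pos, cigar,
#'   seq, qual).
#' @param position 1-based reference coordinate.
#' @return List with \code{base} (a nucleotide, \code{"DELETED"} or
#'   \code{"NOT_COVERED"}) and \code{qual} (numeric Phred score, or NA).
#' @export
base_at <- function(read, position) {
  if (position <= 0) stop("position must be positive", call. = FALSE)
  b <- bases_at(read$pos, read$cigar, read$seq, read$qual, position)
  list(base = b$base[1L], qual = b$qual[1L])
}

# Vectorised core of base_at: one target position against many reads.
# Fast path for all-match CIGARs (the overwhelmingly common case); the
# general CIGAR walk handles the rest.
bases_at <- function(pos, cigar, seq, qual, position) {
  n <- length(pos)
  base <- rep("NOT_COVERED", n)
  q <- rep(NA_real_, n)
  simple <- grepl("^[0-9]+M$", cigar)
  if (any(simple)) {
    off <- position - pos[simple]
    len <- as.integer(sub("M$", "", cigar[simple]))
    inside <- off >= 0L & off < len
    idx <- which(simple)[inside]
    if (length(idx)) {
      at <- position - pos[idx] + 1L
      base[idx] <- substring(seq[idx], at, at)
      q[idx] <- utf8ToInt_at(qual[idx], at)
    }
  }
  for (i in which(!simple)) {
    r <- walk_cigar(pos[i], cigar[i], seq[i], qual[i], position)
    base[i] <- r$base
    q[i] <- r$qual
  }
  list(base = base, qual = q)
}

utf8ToInt_at <- function(strings, at) {
  vapply(seq_along(strings),
         function(i) utf8ToInt(substring(strings[i], at[i], at[i])) - 33,
         numeric(1))
}

walk_cigar <- function(pos, cigar, seq, qual, position) {
  if (cigar == "*") return(list(base = "NOT_COVERED", qual = NA_real_))
  ops <- cigar_ops(cigar)
  ref <- pos
  qcur <- 1L
  if (position < ref) return(list(base = "NOT_COVERED", qual = NA_real_))
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      if (position < ref + len) {
        at <- qcur + (position - ref)
        return(list(base = substring(seq, at, at),
                    qual = utf8ToInt(substring(qual, at, at)) - 33))
      }
      ref <- ref + len; qcur <- qcur + len
    } else if (op %in% c("D", "N")) {
      if (position < ref + len)
        return(list(base = "DELETED", qual = NA_real_))
      ref <- ref + len
    } else if (op %in% c("I", "S")) {
      qcur <- qcur + len
    }
    # H and P consume neither
  }
  list(base = "NOT_COVERED", qual = NA_real_)
}
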