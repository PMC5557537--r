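# SAM text I/O. Parsing is deliberately lossless: the eleven mandatory
# fields plus the raw tag string are kept verbatim so that
# write_sam(read_sam(x)) reproduces x byte-for-byte, and the MAPQ rewriter
# can guarantee it touches nothing but the MAPQ column.

FLAG_PAIRED <- 0x1L
FLAG_PROPER_PAIR <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L

#' Read a SAM file
#'
#' Parses a SAM file into a header (character vector of `@` lines) and a data
#' frame of alignment records. The eleven mandatory columns are kept verbatim
#' (as character/integer) alongside derived convenience columns: flag-bit
#' logicals (`is_paired`, `is_proper_pair`, `is_aligned`, `mate_aligned`,
#' `is_reverse`, `is_first_end`), the `MD:Z` tag value (`md`, `NA` when
#' absent) and the `ZT:Z` feature-tag payload (`feature_tag`, `NA` when
#' absent).
#'
#' @param path Path to a SAM file with header.
#' @return A list with components `header` (character vector) and `records`
#'   (data frame, one row per alignment line, input order preserved).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  if (any(is_hdr) && !all(which(is_hdr) == seq_len(sum(is_hdr)))) {
    stop("header lines must precede alignment lines in ", path, call. = FALSE)
  }
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(list(header = header, records = empty_sam_records()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("malformed SAM record (fewer than 11 fields) at alignment line ",
      bad, " of ", path,
      call. = FALSE
    )
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  flag <- suppressWarnings(as.integer(get(2)))
  pos <- suppressWarnings(as.integer(get(4)))
  mapq <- suppressWarnings(as.integer(get(5)))
  tlen <- suppressWarnings(as.integer(get(9)))
  for (nm in list(list(flag, "FLAG"), list(pos, "POS"), list(mapq, "MAPQ"), list(tlen, "TLEN"))) {
    if (anyNA(nm[[1]])) {
      bad <- which(is.na(nm[[1]]))[1]
      stop("malformed ", nm[[2]], " at alignment line ", bad, " of ", path, call. = FALSE)
    }
  }
  tags <- vapply(fields, function(f) {
    if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else ""
  }, "")
  recs <- data.frame(
    qname = get(1), flag = flag, rname = get(3), pos = pos, mapq = mapq,
    cigar = get(6), rnext = get(7), pnext = suppressWarnings(as.integer(get(8))),
    tlen = tlen, seq = get(10), qual = get(11), tags = tags,
    stringsAsFactors = FALSE
  )
  recs$is_paired <- bitwAnd(recs$flag, FLAG_PAIRED) != 0L
  recs$is_proper_pair <- bitwAnd(recs$flag, FLAG_PROPER_PAIR) != 0L
  recs$is_aligned <- bitwAnd(recs$flag, FLAG_UNMAPPED) == 0L
  recs$mate_aligned <- bitwAnd(recs$flag, FLAG_MATE_UNMAPPED) == 0L
  recs$is_reverse <- bitwAnd(recs$flag, FLAG_REVERSE) != 0L
  recs$is_first_end <- bitwAnd(recs$flag, FLAG_FIRST) != 0L
  recs$md <- extract_tag(tags, "MD:Z:")
  recs$feature_tag <- extract_tag(tags, "ZT:Z:")
  list(header = header, records = recs)
}

empty_sam_records <- function() {
  data.frame(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), qual = character(), tags = character(),
    is_paired = logical(), is_proper_pair = logical(), is_aligned = logical(),
    mate_aligned = logical(), is_reverse = logical(), is_first_end = logical(),
    md = character(), feature_tag = character(),
    stringsAsFactors = FALSE
  )
}

extract_tag <- function(tags, prefix) {
  out <- rep(NA_character_, length(tags))
  m <- regexpr(paste0("(^|\t)", prefix, "[^\t]*"), tags)
  found <- m != -1L
  hit <- regmatches(tags, m)
  out[found] <- sub(paste0("^\t?", prefix), "", hit)
  out
}

#' Write SAM records back to a file
#'
#' Emits the header lines followed by one line per record reassembled from
#' the verbatim mandatory fields and the raw tag string; reading and
#' rewriting a file is byte-identical.
#'
#' @param sam A list with `header` and `records` as returned by [read_sam()].
#' @param path Output path.
#' @export
write_sam <- function(sam, path) {
  r <- sam$records
  body <- paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
    r$rnext, r$pnext, r$tlen, r$seq, r$qual,
    sep = "\t"
  )
  has_tags <- nzchar(r$tags)
  body[has_tags] <- paste(body[has_tags], r$tags[has_tags], sep = "\t")
  writeLines(c(sam$header, body), path)
  invisible(path)
}

#' Parse CIGAR strings
#'
#' @param cigar Character vector of CIGAR strings (`"*"` allowed).
#' @return A list (one element per input) of lists with integer `len` and
#'   character `op` vectors; `"*"` or empty yields zero-length vectors.
#'   Hard clips (`H`) are rejected: templates and simulated reads always
#'   carry their full sequence.
#' @export
parse_cigar <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*" || !nzchar(cg)) {
      return(list(len = integer(), op = character()))
    }
    m <- gregexpr("\\d+[MIDNSHPX=]", cg)[[1]]
    toks <- regmatches(cg, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(cg)) {
      stop("invalid CIGAR string: ", cg, call. = FALSE)
    }
    op <- substring(toks, nchar(toks), nchar(toks))
    if (any(op %in% c("H", "P", "N"))) {
      stop("unsupported CIGAR op in: ", cg, call. = FALSE)
    }
    len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
    # "=" and "X" are match ops with the same span arithmetic as M; MD
    # remains authoritative for mismatch placement.
    op[op %in% c("=", "X")] <- "M"
    list(len = len, op = op)
  })
}

cigar_read_len <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "I", "S")])
}

#' Leading soft-clip length of a CIGAR
#' @param cigar A single CIGAR string.
#' @return Integer length of the leading `S` op (0 if none).
#' @export
leading_clip <- function(cigar) {
  ops <- parse_cigar(cigar)[[1]]
  if (length(ops$op) > 0L && ops$op[1] == "S") ops$len[1] else 0L
}

#' Convert a Phred quality string to integer qualities
#' @param qual Character vector of Phred+33 quality strings.
#' @return List of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), "")
}
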