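# Tandem-read simulation: replay reservoir templates at uniformly random
# genomic locations, encoding each read's true point of origin in its name
# so downstream steps can label alignments correct/incorrect.

#' Reference span of a CIGAR
#'
#' Sum of reference-consuming op lengths (`M`, `D`, with `=`/`X` normalised
#' to `M`).
#' @param cigar CIGAR string or parsed op list.
#' @return Integer span.
#' @export
ref_span <- function(cigar) {
  ops <- if (is.character(cigar)) parse_cigar(cigar)[[1]] else cigar
  sum(ops$len[ops$op %in% c("M", "D")])
}

#' Extraction span of a CIGAR
#'
#' Length of reference substring to extract when replaying a template:
#' the reference span plus soft-clipped lengths (clipped bases are drawn
#' from the flanking reference so the simulated read has sequence there).
#' @inheritParams ref_span
#' @return Integer span.
#' @export
extraction_span <- function(cigar) {
  ops <- if (is.character(cigar)) parse_cigar(cigar)[[1]] else cigar
  sum(ops$len[ops$op %in% c("M", "D", "S")])
}

# --- MD / mutation-pattern parsing ------------------------------------------

parse_md_tokens <- function(md) {
  # tokens: match lengths (integers), mismatch ref bases (letters),
  # deletions ("^" + letters)
  m <- gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md)[[1]]
  toks <- regmatches(md, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(md)) {
    stop("invalid MD string: ", md, call. = FALSE)
  }
  toks
}

#' Parse a template's CIGAR+MD into a replayable mutation pattern
#'
#' The pattern is the CIGAR op list with, for every `M` op, the 0-based
#' offsets (within that op) at which the alignment held a mismatch. With MD
#' absent, mismatch replay is disabled and only the CIGAR gaps are replayed.
#'
#' @param cigar CIGAR string (reference orientation, as in SAM).
#' @param md MD string or `NA`.
#' @return List with `op`, `len`, and `mism` (list of integer offset
#'   vectors, one per op).
#' @export
parse_template_pattern <- function(cigar, md = NA_character_) {
  ops <- parse_cigar(cigar)[[1]]
  mism <- rep(list(integer()), length(ops$op))
  if (is.na(md)) {
    return(list(op = ops$op, len = ops$len, mism = mism))
  }
  toks <- parse_md_tokens(md)
  ti <- 1L # token index
  carry <- 0L # unconsumed match run from current numeric token
  take_tok <- function() {
    if (ti > length(toks)) {
      stop("MD string inconsistent with CIGAR: ", md, " vs ", cigar,
        call. = FALSE
      )
    }
    t <- toks[ti]
    ti <<- ti + 1L
    t
  }
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]
    len <- ops$len[k]
    if (op == "M") {
      done <- 0L
      offs <- integer()
      while (done < len) {
        if (carry > 0L) {
          used <- min(carry, len - done)
          done <- done + used
          carry <- carry - used
        } else {
          t <- take_tok()
          if (grepl("^\\d+$", t)) {
            carry <- as.integer(t)
            if (carry == 0L) next # MD zeroes separate adjacent events
          } else if (grepl("^[A-Za-z]$", t)) {
            offs <- c(offs, done)
            done <- done + 1L
          } else {
            stop("MD deletion where CIGAR has M: ", md, " vs ", cigar,
              call. = FALSE
            )
          }
        }
      }
      mism[[k]] <- offs
    } else if (op == "D") {
      # consume a ^-token covering exactly this deletion
      while (carry == 0L && ti <= length(toks) && toks[ti] == "0") ti <- ti + 1L
      if (carry > 0L) {
        stop("MD/CIGAR mismatch at deletion: ", md, " vs ", cigar,
          call. = FALSE
        )
      }
      t <- take_tok()
      if (!startsWith(t, "^") || nchar(t) - 1L != len) {
        stop("MD deletion inconsistent with CIGAR: ", md, " vs ", cigar,
          call. = FALSE
        )
      }
    }
    # I and S consume no MD
  }
  leftover <- if (ti <= length(toks)) toks[ti:length(toks)] else character()
  if (carry > 0L || any(leftover != "0")) {
    stop("MD string inconsistent with CIGAR: ", md, " vs ", cigar,
      call. = FALSE
    )
  }
  list(op = ops$op, len = ops$len, mism = mism)
}

reverse_pattern <- function(pat) {
  n <- length(pat$op)
  idx <- rev(seq_len(n))
  list(
    op = pat$op[idx],
    len = pat$len[idx],
    mism = lapply(idx, function(k) {
      offs <- pat$mism[[k]]
      if (length(offs)) sort(pat$len[k] - 1L - offs) else offs
    })
  )
}

ALPHABET <- c("A", "C", "G", "T")

#' Mutate an extracted reference substring according to a template
#'
#' Walks the template's CIGAR+MD left to right: matching `M` positions copy
#' the substring base; MD-mismatch positions emit a base drawn uniformly
#' from the three alternatives; `D` ops skip substring bases; `I` ops emit
#' uniform random bases; `S` ops copy substring bases unmutated. For a
#' reverse-strand template the caller passes the already
#' reverse-complemented substring and the pattern is replayed in read
#' orientation.
#'
#' @param substring Reference substring of length
#'   `extraction_span(template$cigar)` (reverse-complemented already for
#'   `-`-strand templates).
#' @param template An `unpaired_template` (or a list with `cigar`, `md`,
#'   `strand`).
#' @return Simulated read sequence (length = template read length).
#' @export
apply_template_mutations <- function(substring, template) {
  pat <- parse_template_pattern(template$cigar, template$md)
  if (identical(template$strand, "-")) pat <- reverse_pattern(pat)
  stopifnot(nchar(substring) == sum(pat$len[pat$op %in% c("M", "D", "S")]))
  replay_pattern(substring, pat)
}

replay_pattern <- function(substring, pat) {
  spos <- 1L
  pieces <- character(0)
  for (k in seq_along(pat$op)) {
    op <- pat$op[k]
    len <- pat$len[k]
    if (op == "M" || op == "S") {
      piece <- substr(substring, spos, spos + len - 1L)
      if (op == "M" && length(pat$mism[[k]])) {
        chars <- strsplit(piece, "", fixed = TRUE)[[1]]
        for (o in pat$mism[[k]]) {
          alt <- ALPHABET[ALPHABET != chars[o + 1L]]
          chars[o + 1L] <- alt[sample.int(length(alt), 1L)]
        }
        piece <- paste(chars, collapse = "")
      }
      pieces <- c(pieces, piece)
      spos <- spos + len
    } else if (op == "D") {
      spos <- spos + len
    } else if (op == "I") {
      pieces <- c(pieces, paste(ALPHABET[sample.int(4L, len, replace = TRUE)],
        collapse = ""
      ))
    }
  }
  paste(pieces, collapse = "")
}

# --- origin encoding --------------------------------------------------------

ORIGIN_SENTINEL <- "qt"

#' Encode a read's true point of origin in its name
#'
#' Single-end form: `qt!<refname>!<start>!<strand>!<category>!s`. Pair form
#' (both ends share one SAM QNAME, so one name carries both origins):
#' `qt!<refname>!<start1>!<strand1>!<start2>!<strand2>!<category>!p`.
#' `start` is the 1-based leftmost reference coordinate of the simulated
#' substring.
#'
#' @param refname Contig name (must not contain `"!"` or whitespace).
#' @param start 1-based leftmost coordinate (single) — or end1's coordinate.
#' @param strand `"+"` or `"-"` (single/end1).
#' @param category Category label (one of [CATEGORIES] or `"input"`).
#' @param start2,strand2 For pairs, end2's coordinate and strand.
#' @return Encoded read name(s); vectorised over the coordinate arguments.
#' @export
encode_origin <- function(refname, start, strand, category,
                          start2 = NULL, strand2 = NULL) {
  if (any(grepl("[![:space:]]", refname))) {
    stop("refname must not contain '!' or whitespace", call. = FALSE)
  }
  if (is.null(start2)) {
    paste(ORIGIN_SENTINEL, refname, start, strand, category, "s", sep = "!")
  } else {
    paste(ORIGIN_SENTINEL, refname, start, strand, start2, strand2,
      category, "p",
      sep = "!"
    )
  }
}

#' Decode a read name into its origin
#'
#' @param name Read name (single).
#' @param end For pair-encoded names, which end's origin to return
#'   (`"1"` or `"2"`); ignored for single-end names.
#' @return A list with `refname`, `start`, `strand`, `category`,
#'   `mate_role`; or `NULL` when `name` does not carry the tandem-read
#'   sentinel (a stray read, to be ignored).
#' @export
decode_origin <- function(name, end = "1") {
  f <- strsplit(name, "!", fixed = TRUE)[[1]]
  if (length(f) < 2L || f[1] != ORIGIN_SENTINEL) {
    return(NULL)
  }
  # an optional trailing serial number keeps QNAMEs unique within a batch
  if (length(f) %in% c(7L, 9L) && grepl("^\\d+$", f[length(f)])) {
    f <- f[-length(f)]
  }
  kind <- f[length(f)]
  if (kind == "s" && length(f) == 6L) {
    list(
      refname = f[2], start = as.integer(f[3]), strand = f[4],
      category = f[5], mate_role = "single"
    )
  } else if (kind == "p" && length(f) == 8L) {
    if (identical(end, "2")) {
      list(
        refname = f[2], start = as.integer(f[5]), strand = f[6],
        category = f[7], mate_role = "end2"
      )
    } else {
      list(
        refname = f[2], start = as.integer(f[3]), strand = f[4],
        category = f[7], mate_role = "end1"
      )
    }
  } else {
    stop("corrupt origin-encoded name: ", name, call. = FALSE)
  }
}

#' Decode many origin-encoded names at once
#'
#' @param names Character vector of read names.
#' @param end Character vector (recycled) saying which end's origin to take
#'   for pair-encoded names (`"1"`/`"2"`).
#' @return Data frame with `refname`, `start`, `strand`, `category`,
#'   `mate_role`, and a logical `is_tandem`; rows for names without the
#'   sentinel have `is_tandem = FALSE` and `NA` fields.
#' @export
decode_origins <- function(names, end = "1") {
  end <- rep_len(as.character(end), length(names))
  parts <- strsplit(names, "!", fixed = TRUE)
  len <- lengths(parts)
  first <- vapply(parts, `[[`, "", 1L)
  # drop a trailing serial field
  ser <- len %in% c(7L, 9L) &
    grepl("^\\d+$", vapply(parts, function(f) f[[length(f)]], ""))
  len[ser] <- len[ser] - 1L
  n <- length(names)
  is_tandem <- first == ORIGIN_SENTINEL & len %in% c(6L, 8L)
  refname <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  category <- rep(NA_character_, n)
  mate_role <- rep(NA_character_, n)
  fld <- function(idx, k) vapply(parts[idx], `[[`, "", k)
  sgl <- which(is_tandem & len == 6L)
  if (length(sgl)) {
    refname[sgl] <- fld(sgl, 2L)
    start[sgl] <- as.integer(fld(sgl, 3L))
    strand[sgl] <- fld(sgl, 4L)
    category[sgl] <- fld(sgl, 5L)
    mate_role[sgl] <- "single"
  }
  pr <- which(is_tandem & len == 8L)
  if (length(pr)) {
    refname[pr] <- fld(pr, 2L)
    category[pr] <- fld(pr, 7L)
    e2 <- pr[end[pr] == "2"]
    e1 <- setdiff(pr, e2)
    if (length(e1)) {
      start[e1] <- as.integer(fld(e1, 3L))
      strand[e1] <- fld(e1, 4L)
      mate_role[e1] <- "end1"
    }
    if (length(e2)) {
      start[e2] <- as.integer(fld(e2, 5L))
      strand[e2] <- fld(e2, 6L)
      mate_role[e2] <- "end2"
    }
  }
  data.frame(
    refname = refname, start = start, strand = strand, category = category,
    mate_role = mate_role, is_tandem = is_tandem, stringsAsFactors = FALSE
  )
}

# --- simulation -------------------------------------------------------------

draw_positions <- function(genome, span, n) {
  # contigs chosen weighted by number of valid start positions so genomic
  # positions are uniform overall
  valid <- nchar(genome) - span + 1L
  ok <- valid > 0L
  if (!any(ok)) {
    stop("no contig long enough for extraction span ", span, call. = FALSE)
  }
  ci <- sample.int(length(genome), n, replace = TRUE, prob = pmax(valid, 0))
  start <- 1L + floor(stats::runif(n) * valid[ci])
  list(contig = ci, start = as.integer(start))
}

redraw_ambiguous <- function(genome, span, pos, seqs, policy, max_redraws) {
  if (policy == "keep") {
    return(list(pos = pos, seqs = seqs))
  }
  attempt <- 0L
  repeat {
    bad <- grep("[^ACGT]", seqs)
    if (length(bad) == 0L) {
      return(list(pos = pos, seqs = seqs))
    }
    attempt <- attempt + 1L
    if (attempt > max_redraws) {
      stop(
        "could not draw an unambiguous substring after ", max_redraws,
        " redraws (contig ", names(genome)[pos$contig[bad[1]]], ")",
        call. = FALSE
      )
    }
    np <- draw_positions(genome, span, length(bad))
    pos$contig[bad] <- np$contig
    pos$start[bad] <- np$start
    seqs[bad] <- substring(
      genome[np$contig], np$start,
      np$start + span - 1L
    )
  }
}

#' Simulate a batch of unpaired tandem reads from one category
#'
#' Templates are drawn uniformly with replacement from the category's
#' reservoir; each is replayed at a uniformly random genomic position
#' (reverse-complemented first for `-`-strand templates), its quality string
#' copied verbatim, and its origin encoded in the read name.
#'
#' @param model An `input_model`.
#' @param genome Named character vector ([read_fasta()]).
#' @param cat Category (`"unp"` or `"bad_end"`).
#' @param n Number of reads.
#' @param n_policy `"redraw"` (default) or `"keep"` for ambiguous bases.
#' @param max_redraws Redraw attempts before giving up.
#' @return Data frame `name`, `seq`, `qual`.
#' @export
simulate_unpaired_batch <- function(model, genome, cat, n,
                                    n_policy = "redraw", max_redraws = 1000L) {
  templates <- reservoir_items(model$reservoirs[[cat]])
  if (length(templates) == 0L) stop("empty reservoir for category ", cat)
  tinfo <- prepare_templates(templates)
  ti <- sample.int(length(templates), n, replace = TRUE)
  out <- replay_batch(tinfo, ti, genome, n_policy, max_redraws)
  names <- encode_origin(
    names(genome)[out$contig], out$start,
    tinfo$strand[ti], cat
  )
  data.frame(
    name = names, seq = out$seq, qual = tinfo$quals[ti],
    stringsAsFactors = FALSE
  )
}

# Precompute spans and parsed patterns once per distinct (cigar, md, strand).
prepare_templates <- function(templates) {
  cigar <- vapply(templates, `[[`, "", "cigar")
  md <- vapply(templates, function(t) {
    if (is.na(t$md)) NA_character_ else t$md
  }, "")
  strand <- vapply(templates, `[[`, "", "strand")
  quals <- vapply(templates, `[[`, "", "quals")
  key <- paste(cigar, md, strand, sep = "\r")
  uk <- !duplicated(key)
  pat_by_key <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    p <- parse_template_pattern(cigar[i], md[i])
    if (strand[i] == "-") p <- reverse_pattern(p)
    p$identity <- all(p$op %in% c("M", "S")) &&
      all(lengths(p$mism) == 0L)
    assign(key[i], p, envir = pat_by_key)
  }
  span <- vapply(
    which(uk), function(i) extraction_span(cigar[i]),
    integer(1)
  )
  span_by_key <- span[match(key, key[uk])]
  list(
    cigar = cigar, md = md, strand = strand, quals = quals,
    key = key, patterns = pat_by_key, span = span_by_key
  )
}

replay_batch <- function(tinfo, ti, genome, n_policy, max_redraws) {
  n <- length(ti)
  span <- tinfo$span[ti]
  contig <- integer(n)
  start <- integer(n)
  seqs <- character(n)
  for (sp in unique(span)) {
    idx <- which(span == sp)
    pos <- draw_positions(genome, sp, length(idx))
    ss <- substring(genome[pos$contig], pos$start, pos$start + sp - 1L)
    fixed <- redraw_ambiguous(genome, sp, pos, ss, n_policy, max_redraws)
    contig[idx] <- fixed$pos$contig
    start[idx] <- fixed$pos$start
    seqs[idx] <- fixed$seqs
  }
  neg <- tinfo$strand[ti] == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  # replay mutations (identity patterns pass through untouched)
  out <- seqs
  for (i in seq_len(n)) {
    pat <- get(tinfo$key[ti[i]], envir = tinfo$patterns)
    if (!pat$identity) out[i] <- replay_pattern(seqs[i], pat)
  }
  list(contig = contig, start = start, seq = out)
}

#' Simulate one unpaired tandem read
#' @inheritParams simulate_unpaired_batch
#' @return One-row data frame `name`, `seq`, `qual`.
#' @export
simulate_unpaired <- function(model, genome, cat = "unp",
                              n_policy = "redraw", max_redraws = 1000L) {
  simulate_unpaired_batch(model, genome, cat, 1L, n_policy, max_redraws)
}

#' Simulate a batch of paired tandem reads
#'
#' A paired template's fragment is placed uniformly at random; the two end
#' substrings are taken at the fragment's extremes according to the
#' template's fragment length and upstream flag, and each end is replayed
#' from its own end template. Both ends share one origin-encoded name.
#'
#' @inheritParams simulate_unpaired_batch
#' @param cat `"conc"` or `"disc"`.
#' @return List of two data frames (`end1`, `end2`) with `name`, `seq`,
#'   `qual`.
#' @export
simulate_pair_batch <- function(model, genome, cat, n,
                                n_policy = "redraw", max_redraws = 1000L) {
  templates <- reservoir_items(model$reservoirs[[cat]])
  if (length(templates) == 0L) stop("empty reservoir for category ", cat)
  t1 <- prepare_templates(lapply(templates, `[[`, "end1"))
  t2 <- prepare_templates(lapply(templates, `[[`, "end2"))
  frag <- vapply(templates, `[[`, numeric(1), "frag_len")
  upstream <- vapply(templates, `[[`, logical(1), "first_end_upstream")
  frag <- pmax(frag, t1$span, t2$span) # clip degenerate overlapping TLENs
  ti <- sample.int(length(templates), n, replace = TRUE)

  # place fragments uniformly; redraw whole fragment on ambiguous bases
  fspan <- as.integer(frag[ti])
  contig <- integer(n)
  fstart <- integer(n)
  for (sp in unique(fspan)) {
    idx <- which(fspan == sp)
    pos <- draw_positions(genome, sp, length(idx))
    ss <- substring(genome[pos$contig], pos$start, pos$start + sp - 1L)
    fixed <- redraw_ambiguous(genome, sp, pos, ss, n_policy, max_redraws)
    contig[idx] <- fixed$pos$contig
    fstart[idx] <- fixed$pos$start
  }

  span1 <- t1$span[ti]
  span2 <- t2$span[ti]
  up <- upstream[ti]
  start1 <- ifelse(up, fstart, fstart + fspan - span1)
  start2 <- ifelse(up, fstart + fspan - span2, fstart)

  build_end <- function(tinfo, starts, spans) {
    seqs <- substring(genome[contig], starts, starts + spans - 1L)
    neg <- tinfo$strand[ti] == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    out <- seqs
    for (i in seq_len(n)) {
      pat <- get(tinfo$key[ti[i]], envir = tinfo$patterns)
      if (!pat$identity) out[i] <- replay_pattern(seqs[i], pat)
    }
    out
  }
  seq1 <- build_end(t1, as.integer(start1), span1)
  seq2 <- build_end(t2, as.integer(start2), span2)
  names <- encode_origin(
    names(genome)[contig], as.integer(start1), t1$strand[ti],
    cat,
    start2 = as.integer(start2), strand2 = t2$strand[ti]
  )
  list(
    end1 = data.frame(
      name = names, seq = seq1, qual = t1$quals[ti],
      stringsAsFactors = FALSE
    ),
    end2 = data.frame(
      name = names, seq = seq2, qual = t2$quals[ti],
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate one paired tandem read
#' @inheritParams simulate_pair_batch
#' @return List of two one-row data frames.
#' @export
simulate_pair <- function(model, genome, cat = "conc",
                          n_policy = "redraw", max_redraws = 1000L) {
  simulate_pair_batch(model, genome, cat, 1L, n_policy, max_redraws)
}

#' Simulate tandem reads for every category present in an input model
#'
#' The per-category counts default to [target_tandem_count()] applied to the
#' model's input-alignment counts.
#'
#' @param model An `input_model`.
#' @param genome Named character vector.
#' @param counts Named vector of per-category read/pair counts; `NULL` for
#'   the defaults.
#' @param seed Integer seed for the simulation RNG.
#' @param ... Passed to the batch simulators (`n_policy`, `max_redraws`).
#' @return List with `unpaired` (data frame; `unp` + `bad_end` reads) and
#'   `pairs` (list of `end1`/`end2` data frames; `conc` + `disc`).
#' @export
simulate_tandem_reads <- function(model, genome, counts = NULL, seed = 1L,
                                  ...) {
  if (is.null(counts)) {
    counts <- vapply(
      CATEGORIES,
      function(cc) target_tandem_count(model$counts[[cc]], cc),
      numeric(1)
    )
  }
  set.seed(seed)
  unpaired <- list()
  pairs1 <- list()
  pairs2 <- list()
  for (cc in c("unp", "bad_end")) {
    n <- counts[[cc]]
    if (is.na(n) || n < 1 || length(model$reservoirs[[cc]]) == 0L) next
    b <- simulate_unpaired_batch(model, genome, cc, as.integer(n), ...)
    b$name <- paste0(b$name, "!", seq_len(nrow(b))) # unique QNAMEs
    unpaired[[cc]] <- b
  }
  for (cc in c("conc", "disc")) {
    n <- counts[[cc]]
    if (is.na(n) || n < 1 || length(model$reservoirs[[cc]]) == 0L) next
    b <- simulate_pair_batch(model, genome, cc, as.integer(n), ...)
    sfx <- paste0("!", seq_len(nrow(b$end1)))
    b$end1$name <- paste0(b$end1$name, sfx)
    b$end2$name <- paste0(b$end2$name, sfx)
    pairs1[[cc]] <- b$end1
    pairs2[[cc]] <- b$end2
  }
  list(
    unpaired = if (length(unpaired)) do.call(rbind, unpaired) else NULL,
    pairs = if (length(pairs1)) {
      list(end1 = do.call(rbind, pairs1), end2 = do.call(rbind, pairs2))
    } else {
      NULL
    }
  )
}
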