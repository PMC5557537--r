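# Self-contained fixture layer: a synthetic repetitive genome generator,
# an independent truth-labeled read simulator, and an R wrapper around the
# built-in seed-and-extend aligner. Together these let the whole tandem
# pipeline run end-to-end with no external tools.

#' Generate a synthetic genome with controlled repetitiveness
#'
#' The sequence is built in blocks of `unit_len` bases. A block is one of:
#' fresh i.i.d. sequence with the requested GC content; a dispersed-repeat
#' copy of a random earlier window mutated at a per-base `divergence` rate
#' (transposon-like); or fresh sequence containing a short-period tandem
#' array (satellite/VNTR-like — the classic source of alignments that are
#' shift-ambiguous by less than a read length). The repeat budget
#' `repeat_fraction` is split between dispersed copies and tandem arrays by
#' `tandem_share`; the realised repeat base fraction matches the request up
#' to block granularity, and every repeat is annotated.
#'
#' @param length Total genome length in bp.
#' @param repeat_fraction Fraction of the genome consisting of repeat
#'   sequence (dispersed copies + tandem arrays), in `[0, 1)`.
#' @param unit_len Dispersed-repeat unit length in bp (also the block
#'   size).
#' @param divergence Per-base substitution rate between a dispersed copy
#'   and its source. Tandem arrays are emitted without internal divergence
#'   (young arrays).
#' @param gc GC content of fresh sequence.
#' @param tandem_share Fraction of the repeat budget emitted as tandem
#'   arrays.
#' @param tandem_unit Range of tandem-array period lengths in bp.
#' @param tandem_len Range of total tandem-array lengths in bp.
#' @param n_contigs Number of contigs to split the genome into.
#' @param seed Integer seed; output is deterministic per seed.
#' @return A `synthetic_genome` list: `contigs` (named character vector)
#'   and `repeat_annotation` (data frame: `type` "copy"/"tandem",
#'   source/copy intervals in global coordinates, `divergence`, and the
#'   array `period` for tandem rows).
#' @export
generate_genome <- function(length, repeat_fraction = 0.3, unit_len = 500L,
                            divergence = 0.02, gc = 0.5,
                            tandem_share = 0.15,
                            tandem_unit = c(8L, 24L),
                            tandem_len = c(130L, 190L),
                            n_contigs = 1L, seed = 1L) {
  stopifnot(repeat_fraction >= 0, repeat_fraction < 1)
  stopifnot(tandem_share >= 0, tandem_share <= 1)
  if (unit_len > length) stop("unit_len must not exceed genome length")
  if (max(tandem_len) > unit_len) stop("tandem arrays must fit in a block")
  set.seed(seed)
  n_blocks <- ceiling(length / unit_len)
  n_copies <- round(repeat_fraction * (1 - tandem_share) * n_blocks)
  if (n_copies > n_blocks - 1L) n_copies <- n_blocks - 1L
  mean_arr <- mean(tandem_len)
  n_arrays <- round(repeat_fraction * tandem_share * n_blocks *
    unit_len / mean_arr)
  avail <- if (n_blocks >= 2L) sample(2:n_blocks) else integer()
  n_arrays <- min(n_arrays, max(0L, base::length(avail) - n_copies))
  copy_blocks <- if (n_copies > 0L) avail[seq_len(n_copies)] else integer()
  array_blocks <- if (n_arrays > 0L) {
    avail[n_copies + seq_len(n_arrays)]
  } else {
    integer()
  }
  kind <- rep("fresh", n_blocks)
  kind[copy_blocks] <- "copy"
  kind[array_blocks] <- "tandem"
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  fresh <- function(n) {
    paste(sample(ALPHABET, n, replace = TRUE, prob = base_probs),
      collapse = ""
    )
  }
  blocks <- character(n_blocks)
  built <- 0L # bases emitted so far
  ann <- list()
  seq_so_far <- "" # lazily re-pasted prefix for copy sources
  paste_upto <- 0L
  for (b in seq_len(n_blocks)) {
    if (kind[b] == "fresh") {
      blocks[b] <- fresh(unit_len)
    } else if (kind[b] == "tandem") {
      p <- sample(tandem_unit[1]:tandem_unit[2], 1L)
      alen <- sample(tandem_len[1]:tandem_len[2], 1L)
      unit <- fresh(p)
      array <- substr(strrep(unit, ceiling(alen / p)), 1L, alen)
      pre <- sample.int(unit_len - alen, 1L)
      blocks[b] <- paste0(fresh(pre), array, fresh(unit_len - alen - pre))
      ann[[base::length(ann) + 1L]] <- data.frame(
        type = "tandem", src_start = NA_integer_, src_end = NA_integer_,
        copy_start = built + pre + 1L, copy_end = built + pre + alen,
        divergence = 0, period = p
      )
    } else {
      if (paste_upto < built) {
        seq_so_far <- paste(blocks[seq_len(b - 1L)], collapse = "")
        paste_upto <- built
      }
      src <- sample.int(built - unit_len + 1L, 1L)
      copy <- substr(seq_so_far, src, src + unit_len - 1L)
      if (divergence > 0) {
        chars <- strsplit(copy, "", fixed = TRUE)[[1]]
        mut <- which(stats::runif(unit_len) < divergence)
        for (m in mut) {
          alt <- ALPHABET[ALPHABET != chars[m]]
          chars[m] <- alt[sample.int(3L, 1L)]
        }
        copy <- paste(chars, collapse = "")
      }
      blocks[b] <- copy
      ann[[base::length(ann) + 1L]] <- data.frame(
        type = "copy", src_start = src, src_end = src + unit_len - 1L,
        copy_start = built + 1L, copy_end = built + unit_len,
        divergence = divergence, period = NA_integer_
      )
    }
    built <- built + unit_len
  }
  full <- substr(paste(blocks, collapse = ""), 1L, length)
  # split into contigs
  cl <- rep(floor(length / n_contigs), n_contigs)
  cl[n_contigs] <- length - sum(cl[-n_contigs])
  starts <- cumsum(c(1L, cl[-n_contigs]))
  contigs <- substring(full, starts, starts + cl - 1L)
  names(contigs) <- paste0("chrS", seq_len(n_contigs))
  structure(
    list(
      contigs = contigs,
      repeat_annotation = if (base::length(ann)) do.call(rbind, ann) else
        data.frame(
          type = character(), src_start = integer(), src_end = integer(),
          copy_start = integer(), copy_end = integer(),
          divergence = numeric(), period = integer()
        )
    ),
    class = "synthetic_genome"
  )
}

#' Default per-base quality profile of the read simulator
#'
#' Phred values and their frequencies, loosely shaped like an Illumina
#' run: mostly high-quality bases with a small low-quality tail (overall
#' expected error rate about 0.4%).
#' @export
DEFAULT_QUALITY_PROFILE <- list(
  q = c(37L, 33L, 28L, 22L, 12L),
  p = c(0.50, 0.20, 0.15, 0.10, 0.05)
)

#' Simulate truth-labeled input reads from a genome
#'
#' Positions are uniform over the genome; per-base qualities are drawn from
#' `quality_profile` and each base is substituted with probability
#' `sub_rate * 10^(-q/10)` (so emitted qualities are honest; `sub_rate = 0`
#' gives error-free reads). Truth is encoded in the read names with
#' category marker `"input"`. Paired mode draws the fragment length
#' uniformly from `frag_range` and simulates FR-oriented ends.
#'
#' @param genome Named character vector, or a `synthetic_genome`.
#' @param n Number of reads (or pairs).
#' @param read_len Read length in nt.
#' @param sub_rate Error-rate multiplier (default 1 = follow qualities).
#' @param quality_profile List with `q` (Phred values) and `p` (weights).
#' @param paired Simulate pairs?
#' @param frag_range Fragment length range (default `c(2, 4) * read_len`).
#' @param seed Integer seed.
#' @return For unpaired, a data frame `name`/`seq`/`qual`; for paired, a
#'   list of two such frames (`end1`, `end2`).
#' @export
simulate_input_reads <- function(genome, n, read_len, sub_rate = 1,
                                 quality_profile = DEFAULT_QUALITY_PROFILE,
                                 paired = FALSE, frag_range = NULL,
                                 seed = 1L) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$contigs
  set.seed(seed)
  if (is.null(frag_range)) frag_range <- c(2L, 4L) * read_len

  draw_quals <- function(nbase) {
    sample(quality_profile$q, nbase,
      replace = TRUE,
      prob = quality_profile$p
    )
  }
  apply_errors <- function(seqs, qmat_rows) {
    # qmat_rows: list of integer vectors (per-read qualities)
    qv <- unlist(qmat_rows, use.names = FALSE)
    perr <- sub_rate * 10^(-qv / 10)
    hit <- stats::runif(length(qv)) < perr
    if (any(hit)) {
      lens <- lengths(qmat_rows)
      read_of <- rep(seq_along(lens), lens)
      off_in <- sequence(lens)
      for (i in which(hit)) {
        rd <- read_of[i]
        o <- off_in[i]
        base <- substr(seqs[rd], o, o)
        alt <- ALPHABET[ALPHABET != base]
        substr(seqs[rd], o, o) <- alt[sample.int(length(alt), 1L)]
      }
    }
    seqs
  }
  make_end <- function(starts, contig, rc) {
    seqs <- substring(
      genome[contig], starts,
      starts + read_len - 1L
    )
    if (any(rc)) seqs[rc] <- revcomp(seqs[rc])
    quals <- replicate(length(starts), draw_quals(read_len), simplify = FALSE)
    seqs <- apply_errors(seqs, quals)
    list(seq = seqs, qual = vapply(quals, function(q) intToUtf8(q + 33L), ""))
  }

  if (!paired) {
    pos <- draw_positions(genome, read_len, n)
    rc <- stats::runif(n) < 0.5
    e <- make_end(pos$start, pos$contig, rc)
    name <- paste0(
      encode_origin(
        names(genome)[pos$contig], pos$start,
        ifelse(rc, "-", "+"), "input"
      ),
      "!", seq_len(n)
    )
    return(data.frame(
      name = name, seq = e$seq, qual = e$qual,
      stringsAsFactors = FALSE
    ))
  }
  frag <- frag_range[1] + floor(stats::runif(n) * (frag_range[2] - frag_range[1] + 1L))
  # place fragments; all fragments of same length batched
  contig <- integer(n)
  fstart <- integer(n)
  for (fl in unique(frag)) {
    idx <- which(frag == fl)
    pos <- draw_positions(genome, fl, length(idx))
    contig[idx] <- pos$contig
    fstart[idx] <- pos$start
  }
  # FR orientation; which end is upstream is random
  e1_up <- stats::runif(n) < 0.5
  start1 <- ifelse(e1_up, fstart, fstart + frag - read_len)
  start2 <- ifelse(e1_up, fstart + frag - read_len, fstart)
  rc1 <- !e1_up
  rc2 <- e1_up
  e1 <- make_end(as.integer(start1), contig, rc1)
  e2 <- make_end(as.integer(start2), contig, rc2)
  name <- paste0(
    encode_origin(names(genome)[contig], as.integer(start1),
      ifelse(rc1, "-", "+"), "input",
      start2 = as.integer(start2), strand2 = ifelse(rc2, "-", "+")
    ),
    "!", seq_len(n)
  )
  list(
    end1 = data.frame(
      name = name, seq = e1$seq, qual = e1$qual,
      stringsAsFactors = FALSE
    ),
    end2 = data.frame(
      name = name, seq = e2$seq, qual = e2$qual,
      stringsAsFactors = FALSE
    )
  )
}

#' Default scoring parameters of the built-in aligner
#' @export
TOY_SCORING <- list(
  match = 1L, mismatch = -2L, gap_open = -4L,
  gap_extend = -1L
)

reverse_qual <- function(q) {
  vapply(q, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Align reads with the built-in seed-and-extend aligner
#'
#' Exact k-mer seeds vote for candidate loci on both strands; candidates
#' are rescored with a banded affine-gap alignment that must cover the
#' whole read (end-to-end, so no soft clipping). One best alignment is
#' reported (ties broken by smallest position); the best score observed at
#' a locus more than one read length away is recorded as the second-best
#' score. Each aligned record carries the feature tag
#' `ZT:Z:best,second_or_NA,qsum_aligned,qsum_clipped` and a deliberately
#' coarse native MAPQ, `min(40, 2 * (best - second))`, or 40 when no
#' second-best locus was seen. Alignments scoring below
#' `min_score_frac * read_len * match` are suppressed.
#'
#' @param reads Data frame `name`/`seq`/`qual` (unpaired), or a list of two
#'   such frames (`end1`, `end2`) for paired alignment.
#' @param genome Named character vector or `synthetic_genome`.
#' @param k_seed Seed k-mer length.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param min_score_frac Minimum fraction of the maximum possible score.
#' @param seed_stride Offset between successive seeds along the read.
#' @param max_candidates Maximum candidate loci scored per read.
#' @param band Half-width of the alignment band.
#' @param conc_range Paired mode: fragment-length window (in nt) treated as
#'   concordant, default `c(2, 4) * read_len`.
#' @return A `sam` list (`header`, `records`).
#' @export
toy_align <- function(reads, genome, k_seed = 21L, scoring = TOY_SCORING,
                      min_score_frac = 0.6, seed_stride = 40L,
                      max_candidates = 24L, band = 3L, conc_range = NULL) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$contigs
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)),
    "@PG\tID:toy_align\tPN:tandemsim-toy-aligner"
  )
  paired <- is.list(reads) && !is.data.frame(reads)
  align_batch <- function(df) {
    res <- toy_align_cpp(
      names(genome), unname(genome), df$seq,
      as.integer(k_seed), scoring$match, scoring$mismatch,
      scoring$gap_open, scoring$gap_extend, min_score_frac,
      as.integer(seed_stride), as.integer(max_candidates), as.integer(band)
    )
    res
  }
  qsums <- function(df) {
    # end-to-end alignment: no soft clips, all bases aligned
    vapply(df$qual, function(s) sum(utf8ToInt(s) - 33L), numeric(1),
      USE.NAMES = FALSE
    )
  }
  rec_frame <- function(df, res, flag_extra = 0L) {
    n <- nrow(df)
    qa <- qsums(df)
    # extensible tag fields 5-6: nearby-alternative evidence (best score at
    # any other evaluated position, e.g. a tandem-array shift), reported as
    # an indicator plus a score gap with the same absent-value ceiling
    # convention as score_diff
    rl <- nchar(df$seq)
    alt_diff <- ifelse(res$has_alt, res$score - res$alt,
      res$score - scoring$mismatch * rl
    )
    zt <- paste(
      format_feature_tag(
        res$score,
        ifelse(res$has_second, res$second, NA), qa, 0L
      ),
      as.integer(res$has_alt), alt_diff,
      sep = ","
    )
    flag <- ifelse(res$aligned, ifelse(res$rc, 16L, 0L), 4L) + flag_extra
    seq_out <- df$seq
    qual_out <- df$qual
    if (any(res$aligned & res$rc)) {
      i <- which(res$aligned & res$rc)
      seq_out[i] <- revcomp(seq_out[i])
      qual_out[i] <- reverse_qual(qual_out[i])
    }
    tags <- ifelse(res$aligned, paste0("MD:Z:", res$md, "\tZT:Z:", zt), "")
    data.frame(
      qname = df$name, flag = flag,
      rname = ifelse(res$aligned, names(genome)[res$contig], "*"),
      pos = ifelse(res$aligned, res$pos, 0L),
      mapq = ifelse(res$aligned, res$mapq, 0L),
      cigar = ifelse(res$aligned, res$cigar, "*"),
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = seq_out, qual = qual_out, tags = tags,
      stringsAsFactors = FALSE
    )
  }
  if (!paired) {
    body <- rec_frame(reads, align_batch(reads))
  } else {
    L <- nchar(reads$end1$seq[1])
    if (is.null(conc_range)) conc_range <- c(2L, 4L) * L
    r1 <- align_batch(reads$end1)
    r2 <- align_batch(reads$end2)
    b1 <- rec_frame(reads$end1, r1, flag_extra = 1L + 64L)
    b2 <- rec_frame(reads$end2, r2, flag_extra = 1L + 128L)
    both <- r1$aligned & r2$aligned
    same <- both & b1$rname == b2$rname
    # FR orientation: leftmost end forward, rightmost end reverse
    left1 <- b1$pos <= b2$pos
    fr <- same & ifelse(left1, !r1$rc & r2$rc, !r2$rc & r1$rc)
    span_lo <- pmin(b1$pos, b2$pos)
    span_hi <- pmax(
      b1$pos + ref_span_vec(b1$cigar) - 1L,
      b2$pos + ref_span_vec(b2$cigar) - 1L
    )
    frag <- span_hi - span_lo + 1L
    proper <- fr & frag >= conc_range[1] & frag <= conc_range[2]
    # mate flags
    b1$flag <- b1$flag + ifelse(r2$aligned, 0L, 8L) +
      ifelse(r2$aligned & r2$rc, 32L, 0L) + ifelse(proper, 2L, 0L)
    b2$flag <- b2$flag + ifelse(r1$aligned, 0L, 8L) +
      ifelse(r1$aligned & r1$rc, 32L, 0L) + ifelse(proper, 2L, 0L)
    b1$rnext <- ifelse(r2$aligned, ifelse(same, "=", b2$rname), "*")
    b2$rnext <- ifelse(r1$aligned, ifelse(same, "=", b1$rname), "*")
    b1$pnext <- ifelse(r2$aligned, b2$pos, 0L)
    b2$pnext <- ifelse(r1$aligned, b1$pos, 0L)
    b1$tlen <- ifelse(same, ifelse(left1, frag, -frag), 0L)
    b2$tlen <- ifelse(same, ifelse(left1, -frag, frag), 0L)
    # interleave ends: end1, end2, end1, end2, ...
    body <- rbind(b1, b2)
    o <- order(rep(seq_len(nrow(b1)), 2L), rep(c(1L, 2L), each = nrow(b1)))
    body <- body[o, , drop = FALSE]
    rownames(body) <- NULL
  }
  recs <- body
  recs$is_paired <- bitwAnd(recs$flag, FLAG_PAIRED) != 0L
  recs$is_proper_pair <- bitwAnd(recs$flag, FLAG_PROPER_PAIR) != 0L
  recs$is_aligned <- bitwAnd(recs$flag, FLAG_UNMAPPED) == 0L
  recs$mate_aligned <- bitwAnd(recs$flag, FLAG_MATE_UNMAPPED) == 0L
  recs$is_reverse <- bitwAnd(recs$flag, FLAG_REVERSE) != 0L
  recs$is_first_end <- bitwAnd(recs$flag, FLAG_FIRST) != 0L
  recs$md <- extract_tag(recs$tags, "MD:Z:")
  recs$feature_tag <- extract_tag(recs$tags, "ZT:Z:")
  list(header = header, records = recs)
}

ref_span_vec <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") 0L else as.integer(ref_span(cg))
  }, integer(1), USE.NAMES = FALSE)
}
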