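# Comparison statistics for two sets of mapping-quality predictions over
# the same alignments: cumulative incorrect (C) and cumulative squared
# error (E) vectors with tie-group averaging, their difference curves
# (CID = C' - C, CSED = E' - E), and the relative-change summaries RCA and
# RCE. Negative values favour the challenger's predictions.

#' Is an alignment correct?
#'
#' An alignment is correct when its implied leftmost base — SAM POS minus
#' the leading soft-clip length, so clipped and unclipped alignments of the
#' same read are comparable — is within `threshold` nucleotides of the
#' leftmost base of the simulated substring, on the same contig. Strand is
#' not compared.
#'
#' @param rec One alignment record (list/one-row data frame with `rname`,
#'   `pos`, `cigar`).
#' @param truth Origin as returned by [decode_origin()].
#' @param threshold Maximum distance in nt (default 30).
#' @return `1` or `0`.
#' @export
alignment_correct <- function(rec, truth, threshold = 30L) {
  implied <- rec$pos - leading_clip(rec$cigar)
  as.integer(rec$rname == truth$refname &&
    abs(implied - truth$start) <= threshold)
}

# vectorised form used by the pipeline
correct_vec <- function(rname, pos, cigar, truth_ref, truth_start,
                        threshold = 30L) {
  clip <- integer(length(cigar))
  has_clip <- grepl("^\\d+S", cigar)
  if (any(has_clip)) {
    clip[has_clip] <- as.integer(sub("S.*$", "", cigar[has_clip]))
  }
  as.integer(!is.na(truth_ref) & rname == truth_ref &
    abs((pos - clip) - truth_start) <= threshold)
}

sort_desc_stable <- function(x) order(-x)

tie_group_increments <- function(sorted_key, values) {
  # per-element increment: group total / group size over maximal runs of
  # equal sorted keys
  r <- rle(sorted_key)
  gid <- rep(seq_along(r$lengths), r$lengths)
  gmean <- tapply(values, gid, mean)
  as.numeric(gmean[gid])
}

#' Cumulative incorrect vector
#'
#' Alignments are sorted in descending order of quality; element i of C is
#' the number of incorrect alignments among the i+1 best. Within a maximal
#' group of equal qualities the group's incorrect count is spread evenly
#' over its elements, so the curve does not depend on how ties are broken.
#'
#' @param correctness 0/1 vector.
#' @param Q Numeric vector of mapping qualities (same length).
#' @return Numeric non-decreasing vector; last element equals the total
#'   incorrect count.
#' @export
cumulative_incorrect <- function(correctness, Q) {
  stopifnot(length(correctness) == length(Q))
  ord <- sort_desc_stable(Q)
  inc <- (1 - correctness)[ord]
  cumsum(tie_group_increments(Q[ord], inc))
}

#' Cumulative squared error vector
#'
#' Alignments are sorted in descending order of predicted probability;
#' element i of E accumulates the squared error (correct - p)^2. Within a
#' tie group each element adds the group's mean squared error.
#'
#' @param correctness 0/1 vector.
#' @param P Numeric vector of correctness probabilities in `[0,1]`.
#' @return Numeric non-decreasing vector; last element equals `SSE(P)`.
#' @export
cumulative_squared_error <- function(correctness, P) {
  stopifnot(length(correctness) == length(P))
  ord <- sort_desc_stable(P)
  se <- (correctness[ord] - P[ord])^2
  cumsum(tie_group_increments(P[ord], se))
}

#' Cumulative incorrect difference (CID) curve
#' @param correctness 0/1 vector.
#' @param Q Baseline (aligner) qualities.
#' @param Qp Challenger qualities.
#' @return `D = C' - C`; negative values favour the challenger.
#' @export
cid <- function(correctness, Q, Qp) {
  stopifnot(length(Q) == length(Qp))
  cumulative_incorrect(correctness, Qp) -
    cumulative_incorrect(correctness, Q)
}

#' Cumulative squared-error difference (CSED) curve
#' @param correctness 0/1 vector.
#' @param P Baseline probabilities.
#' @param Pp Challenger probabilities.
#' @return `S = E' - E`; negative values favour the challenger.
#' @export
csed <- function(correctness, P, Pp) {
  stopifnot(length(P) == length(Pp))
  cumulative_squared_error(correctness, Pp) -
    cumulative_squared_error(correctness, P)
}

#' Relative change in area under CID
#'
#' `RCA = (sum(C') - sum(C)) / sum(C)`. Invariant under strictly monotone
#' transformations of the quality vectors — it measures ranking only.
#'
#' @param C,Cp Cumulative incorrect vectors ([cumulative_incorrect()]).
#' @return RCA as a fraction (negative: challenger ranks better); `NA` when
#'   there are no incorrect alignments.
#' @export
rca <- function(C, Cp) {
  denom <- sum(C)
  if (denom <= 0) {
    return(NA_real_)
  }
  (sum(Cp) - sum(C)) / denom
}

#' Relative change in sum of squared errors
#'
#' `RCE = (SSE(P') - SSE(P)) / SSE(P)`; negative values mean the
#' challenger's probabilities fit the actual correctness better.
#'
#' @param correctness 0/1 vector.
#' @param P,Pp Probability vectors.
#' @return RCE as a fraction; `NA` when `SSE(P)` is zero.
#' @export
rce <- function(correctness, P, Pp) {
  sse <- sum((correctness - P)^2)
  if (sse <= 0) {
    return(NA_real_)
  }
  (sum((correctness - Pp)^2) - sse) / sse
}

#' y-axis scaling used for CSED plots
#'
#' `sign(y) * log10(|y| + 1)`: odd, monotone, and compresses large
#' magnitudes so curves of different sample sizes are comparable.
#' @param y Numeric vector.
#' @return Scaled values.
#' @export
csed_plot_scale <- function(y) sign(y) * log10(abs(y) + 1)

#' Evaluate challenger vs. baseline mapping qualities
#'
#' Computes the full set of comparison statistics for one correctness
#' vector and two quality assignments. Probabilities are derived from the
#' qualities via [p_from_q()] (so CID sorts by Q and CSED by P; the
#' orderings coincide because the transform is monotone). Records with
#' MAPQ 255 ("unavailable") in either assignment should be excluded by the
#' caller.
#'
#' @param correctness 0/1 vector.
#' @param Q Baseline qualities.
#' @param Qp Challenger qualities.
#' @return An `eval_result` list: `n`, `C`, `Cp`, `D`, `E`, `Ep`, `S`,
#'   `rca`, `rce` (fractions) and `rca_pct`, `rce_pct` (percentages).
#' @export
evaluate_predictions <- function(correctness, Q, Qp) {
  stopifnot(
    length(correctness) == length(Q),
    length(Q) == length(Qp),
    all(correctness %in% c(0, 1))
  )
  P <- p_from_q(Q)
  Pp <- p_from_q(Qp)
  C <- cumulative_incorrect(correctness, Q)
  Cp <- cumulative_incorrect(correctness, Qp)
  E <- cumulative_squared_error(correctness, P)
  Ep <- cumulative_squared_error(correctness, Pp)
  r_a <- rca(C, Cp)
  r_e <- rce(correctness, P, Pp)
  structure(
    list(
      n = length(correctness),
      C = C, Cp = Cp, D = Cp - C,
      E = E, Ep = Ep, S = Ep - E,
      rca = r_a, rce = r_e,
      rca_pct = 100 * r_a, rce_pct = 100 * r_e
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "mapping-quality comparison over %d alignments\n  RCA: %+.2f%%   RCE: %+.2f%%\n  (negative values favour the challenger)\n",
    x$n, x$rca_pct, x$rce_pct
  ))
  invisible(x)
}

#' Compare two MAPQ assignments over the same alignments in SAM files
#'
#' Both files must contain the same aligned records (e.g. the step-1 SAM
#' and the rewritten SAM); truth is decoded from the origin-encoded read
#' names. Unaligned records, records whose names carry no origin, and
#' records with MAPQ 255 in either file are excluded.
#'
#' @param baseline_sam,challenger_sam Paths or [read_sam()] lists.
#' @param threshold Correctness distance threshold in nt.
#' @return An `eval_result` (see [evaluate_predictions()]).
#' @export
compare_sams <- function(baseline_sam, challenger_sam, threshold = 30L) {
  if (is.character(baseline_sam)) baseline_sam <- read_sam(baseline_sam)
  if (is.character(challenger_sam)) challenger_sam <- read_sam(challenger_sam)
  b <- baseline_sam$records
  ch <- challenger_sam$records
  b <- b[b$is_aligned, , drop = FALSE]
  ch <- ch[ch$is_aligned, , drop = FALSE]
  key <- function(r) paste(r$qname, bitwAnd(r$flag, FLAG_FIRST + FLAG_SECOND))
  m <- match(key(b), key(ch))
  if (anyNA(m)) stop("SAM files do not cover the same aligned records")
  ch <- ch[m, , drop = FALSE]
  ends <- ifelse(b$is_paired & !b$is_first_end, "2", "1")
  truth <- decode_origins(b$qname, ends)
  keep <- truth$is_tandem & b$mapq != 255L & ch$mapq != 255L
  b <- b[keep, , drop = FALSE]
  ch <- ch[keep, , drop = FALSE]
  truth <- truth[keep, , drop = FALSE]
  correctness <- correct_vec(
    b$rname, b$pos, b$cigar, truth$refname,
    truth$start, threshold
  )
  evaluate_predictions(correctness, b$mapq, ch$mapq)
}
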