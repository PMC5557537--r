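#' Convert a correctness probability to a mapping quality
#'
#' Mapping quality is defined on the Phred-like decibel scale
#' \eqn{q = -10 \log_{10}(1 - p)}, where \eqn{p} is the probability that the
#' reported alignment is correct. A read aligning equally well to two loci has
#' \eqn{p = 0.5} and therefore \eqn{q \le 3}.
#'
#' @param p Numeric vector of probabilities, each in `[0, 1)`.
#' @return Numeric vector of non-negative mapping qualities (real-valued;
#'   rounding to integer happens only when writing SAM).
#' @seealso [p_from_q()] for the inverse.
#' @export
#' @examples
#' q_from_p(0.5)   # ~3.01
#' q_from_p(0.9)   # 10
q_from_p <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 1)) {
    stop("'p' must lie in [0, 1); clamp before converting", call. = FALSE)
  }
  -10 * log10(1 - p)
}

#' Convert a mapping quality to a correctness probability
#'
#' Exact inverse of [q_from_p()]: \eqn{p = 1 - 10^{-q/10}}.
#'
#' @param q Numeric vector of non-negative mapping qualities.
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @export
#' @examples
#' p_from_q(10)  # 0.9
#' p_from_q(0)   # 0
p_from_q <- function(q) {
  if (any(is.na(q)) || any(q < 0)) {
    stop("'q' must be non-negative", call. = FALSE)
  }
  1 - 10^(-q / 10)
}

#' Alignment categories
#'
#' Aligned reads fall into exactly one of four categories, each of which gets
#' its own template reservoir and its own mapping-quality model:
#' `unp` (unpaired), `conc` (paired, concordantly aligned), `disc` (paired,
#' both ends aligned but not concordantly), and `bad_end` (paired, with the
#' opposite end unaligned).
#'
#' @return Character vector of the four category names.
#' @export
CATEGORIES <- c("unp", "conc", "disc", "bad_end")

#' Classify an aligned record into its category
#'
#' Concordance is read from the SAM proper-pair flag (0x2) as set by the
#' aligner; it is not recomputed here.
#'
#' @param rec An alignment record (a row of the data frame returned by
#'   [read_sam()], or any list with fields `is_aligned`, `is_paired`,
#'   `mate_aligned`, `is_proper_pair`).
#' @return One of `"unp"`, `"conc"`, `"disc"`, `"bad_end"`.
#' @export
classify_category <- function(rec) {
  if (!isTRUE(all(rec$is_aligned))) {
    stop("categories apply to aligned records only", call. = FALSE)
  }
  ifelse(!rec$is_paired, "unp",
    ifelse(!rec$mate_aligned, "bad_end",
      ifelse(rec$is_proper_pair, "conc", "disc")
    )
  )
}
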