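# The input model: per-alignment templates and bounded per-category
# reservoir samples. A template records everything needed to replay a
# read-like sequence at a new genomic location: the strand aligned to, the
# quality string (in read orientation), and the mutation pattern given by
# the CIGAR and MD fields. Paired templates additionally carry the inferred
# fragment length and which end aligned upstream.

#' Default minimum tandem-read counts per category
#' @export
TANDEM_MINIMUMS <- c(unp = 30000, conc = 30000, disc = 10000, bad_end = 10000)

#' Number of tandem reads to simulate for a category
#'
#' The default is `ceiling(45 * sqrt(x))` where `x` is the number of input
#' alignments (pairs, for the paired categories) observed in that category,
#' subject to a per-category floor: 30,000 for `unp` and `conc`, 10,000 for
#' `disc` and `bad_end`. A category with no input alignments gets no tandem
#' reads (and no model).
#'
#' @param x Number of input alignments of the category.
#' @param cat Category name (one of [CATEGORIES]).
#' @param factor Scaling factor applied to `fn(x)`.
#' @param fn Count function: `"sqrt"` (default), `"linear"`, `"const"`, or a
#'   function of `x`.
#' @param minimums Named numeric vector of per-category floors.
#' @return Integer number of tandem reads (pairs, for paired categories).
#' @export
target_tandem_count <- function(x, cat, factor = 45, fn = "sqrt",
                                minimums = TANDEM_MINIMUMS) {
  stopifnot(length(x) == 1L, x >= 0)
  if (!is.numeric(factor) || factor <= 0) {
    stop("'factor' must be positive", call. = FALSE)
  }
  cat <- match.arg(cat, CATEGORIES)
  if (x == 0) {
    return(0L)
  }
  f <- if (is.function(fn)) {
    fn
  } else {
    switch(match.arg(fn, c("sqrt", "linear", "const")),
      sqrt = sqrt,
      linear = identity,
      const = function(x) 1
    )
  }
  as.integer(ceiling(max(factor * f(x), minimums[[cat]])))
}

#' Create an empty reservoir sample
#'
#' A reservoir keeps a uniform subsample of a stream of templates using
#' Algorithm R: the first `capacity` items are kept; afterwards the i-th
#' item replaces a uniformly chosen slot with probability `capacity / i`.
#' The reservoir draws from the session RNG; seed it (e.g. with
#' [set.seed()]) before offering for reproducible subsamples.
#'
#' @param capacity Maximum number of retained items (default 10,000).
#' @return A reservoir object (an environment).
#' @export
reservoir_new <- function(capacity = 10000L) {
  stopifnot(capacity >= 1L)
  res <- new.env(parent = emptyenv())
  res$capacity <- as.integer(capacity)
  res$items <- vector("list", 0L)
  res$seen <- 0L
  class(res) <- "reservoir"
  res
}

#' Offer one item to a reservoir
#' @param res A reservoir from [reservoir_new()].
#' @param item Any R object.
#' @return The reservoir, invisibly (modified in place).
#' @export
reservoir_offer <- function(res, item) {
  res$seen <- res$seen + 1L
  if (res$seen <= res$capacity) {
    res$items[[res$seen]] <- item
  } else {
    j <- sample.int(res$seen, 1L)
    if (j <= res$capacity) res$items[[j]] <- item
  }
  invisible(res)
}

#' Retained items of a reservoir
#' @param res A reservoir.
#' @return List of retained items (length `min(seen, capacity)`).
#' @export
reservoir_items <- function(res) res$items

#' @export
length.reservoir <- function(x) length(x$items)

#' Extract a template from an aligned record (or pair)
#'
#' For a single record the template stores the strand, the quality string
#' converted to read orientation (SAM stores reverse-strand reads
#' reference-oriented), and the CIGAR/MD mutation pattern verbatim. For a
#' pair, both end templates plus the inferred fragment length (`|TLEN|`) and
#' a flag saying whether the first-in-pair end aligned upstream.
#'
#' @param rec A single-row record (list or one-row data frame) as produced
#'   by [read_sam()].
#' @param mate Optional mate record (both ends aligned) for a pair template.
#' @return An object of class `unpaired_template` or `paired_template`.
#' @export
extract_template <- function(rec, mate = NULL) {
  one <- function(r) {
    quals <- r$qual
    if (r$is_reverse) {
      quals <- int_to_phred(list(rev(phred_to_int(quals)[[1]])))
    }
    structure(
      list(
        strand = if (r$is_reverse) "-" else "+",
        quals = quals,
        cigar = r$cigar,
        md = if (is.null(r$md) || is.na(r$md)) NA_character_ else r$md
      ),
      class = "unpaired_template"
    )
  }
  if (is.null(mate)) {
    return(one(rec))
  }
  if (!isTRUE(rec$is_first_end)) {
    # normalise so end1 is the first-in-pair end
    tmp <- rec
    rec <- mate
    mate <- tmp
  }
  if (rec$tlen == 0L) {
    stop("paired template requires a non-zero TLEN", call. = FALSE)
  }
  structure(
    list(
      end1 = one(rec),
      end2 = one(mate),
      frag_len = abs(rec$tlen),
      first_end_upstream = rec$tlen > 0L
    ),
    class = "paired_template"
  )
}

#' Build the input model from step-1 alignments
#'
#' Walks the SAM records, classifies every aligned record into its category,
#' extracts templates, and maintains one bounded reservoir per category.
#' Paired templates are extracted only when both ends aligned (`conc`,
#' `disc`); for `bad_end` the aligned end is stored as an unpaired template.
#' Records carrying no usable template (e.g. `*` CIGAR on an aligned flag)
#' are skipped.
#'
#' @param sam A list with `header`/`records` from [read_sam()], or a path.
#' @param capacity Reservoir capacity per category.
#' @param seed Integer seed; each category reservoir is seeded with
#'   `seed + <category index>` so subsamples are reproducible.
#' @return An `input_model`: list with `reservoirs` (per category), `counts`
#'   (input alignments or pairs per category), and `capacity`.
#' @export
build_input_model <- function(sam, capacity = 10000L, seed = 1L) {
  if (is.character(sam)) sam <- read_sam(sam)
  recs <- sam$records
  aligned <- recs[recs$is_aligned, , drop = FALSE]
  reservoirs <- list()
  counts <- c(unp = 0L, conc = 0L, disc = 0L, bad_end = 0L)
  for (i in seq_along(CATEGORIES)) {
    reservoirs[[CATEGORIES[i]]] <- reservoir_new(capacity)
  }
  if (nrow(aligned) == 0L) {
    return(structure(
      list(reservoirs = reservoirs, counts = counts, capacity = capacity),
      class = "input_model"
    ))
  }
  cat <- classify_category(aligned)

  offer_all <- function(res, templates) {
    for (t in templates) reservoir_offer(res, t)
  }
  # vectorised template construction (row-wise data.frame access is slow)
  unp_templates <- function(sub) {
    quals <- sub$qual
    rev_i <- which(sub$is_reverse)
    if (length(rev_i)) {
      quals[rev_i] <- vapply(
        quals[rev_i],
        function(s) intToUtf8(rev(utf8ToInt(s))), "",
        USE.NAMES = FALSE
      )
    }
    strand <- ifelse(sub$is_reverse, "-", "+")
    md <- sub$md
    Map(function(s, q, cg, m) {
      structure(
        list(strand = s, quals = q, cigar = cg, md = m),
        class = "unpaired_template"
      )
    }, strand, quals, sub$cigar, md, USE.NAMES = FALSE)
  }

  # unpaired and bad_end: one unpaired template per record
  for (cc in c("unp", "bad_end")) {
    idx <- which(cat == cc)
    counts[[cc]] <- length(idx)
    if (length(idx) == 0L) next
    set.seed(seed + match(cc, CATEGORIES))
    offer_all(reservoirs[[cc]], unp_templates(aligned[idx, , drop = FALSE]))
  }

  # conc and disc: one paired template per mate pair
  for (cc in c("conc", "disc")) {
    idx <- which(cat == cc)
    if (length(idx) == 0L) next
    sub <- aligned[idx, , drop = FALSE]
    first <- sub[sub$is_first_end, , drop = FALSE]
    second <- sub[!sub$is_first_end, , drop = FALSE]
    m <- match(first$qname, second$qname)
    ok <- which(!is.na(m) & first$tlen != 0L)
    counts[[cc]] <- length(ok)
    if (length(ok) == 0L) next
    e1 <- unp_templates(first[ok, , drop = FALSE])
    e2 <- unp_templates(second[m[ok], , drop = FALSE])
    frag <- abs(first$tlen[ok])
    upstream <- first$tlen[ok] > 0L
    set.seed(seed + match(cc, CATEGORIES))
    offer_all(reservoirs[[cc]], Map(function(a, b, fl, up) {
      structure(
        list(end1 = a, end2 = b, frag_len = fl, first_end_upstream = up),
        class = "paired_template"
      )
    }, e1, e2, frag, upstream, USE.NAMES = FALSE))
  }

  structure(
    list(reservoirs = reservoirs, counts = counts, capacity = capacity),
    class = "input_model"
  )
}

#' @export
print.input_model <- function(x, ...) {
  cat("input model (reservoir capacity", x$capacity, ")\n")
  for (cc in CATEGORIES) {
    cat(
      sprintf(
        "  %-8s input: %8d  retained templates: %d\n",
        cc, x$counts[[cc]], length(x$reservoirs[[cc]])
      )
    )
  }
  invisible(x)
}

template_to_list <- function(t) {
  if (inherits(t, "paired_template")) {
    list(
      kind = "paired",
      end1 = unclass(t$end1), end2 = unclass(t$end2),
      frag_len = t$frag_len, first_end_upstream = t$first_end_upstream
    )
  } else {
    c(list(kind = "unpaired"), unclass(t))
  }
}

#' Serialise an input model to JSON lines
#'
#' One line per retained template, preceded by one metadata line holding the
#' per-category counts and capacity; [read_input_model()] restores it.
#'
#' @param model An `input_model`.
#' @param path Output path.
#' @export
write_input_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(
    kind = "meta", capacity = model$capacity,
    counts = as.list(model$counts)
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), con)
  for (cc in CATEGORIES) {
    for (t in reservoir_items(model$reservoirs[[cc]])) {
      rec <- c(list(category = cc), template_to_list(t))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Restore an input model written by [write_input_model()]
#' @param path Path to the JSON-lines sidecar file.
#' @return An `input_model`.
#' @export
read_input_model <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  stopifnot(identical(meta$kind, "meta"))
  reservoirs <- list()
  for (cc in CATEGORIES) reservoirs[[cc]] <- reservoir_new(meta$capacity)
  from_list <- function(l) {
    unp <- function(e) {
      structure(
        list(
          strand = e$strand, quals = e$quals, cigar = e$cigar,
          md = if (is.null(e$md)) NA_character_ else e$md
        ),
        class = "unpaired_template"
      )
    }
    if (identical(l$kind, "paired")) {
      structure(
        list(
          end1 = unp(l$end1), end2 = unp(l$end2),
          frag_len = l$frag_len,
          first_end_upstream = l$first_end_upstream
        ),
        class = "paired_template"
      )
    } else {
      unp(l)
    }
  }
  for (line in lines[-1]) {
    l <- jsonlite::fromJSON(line)
    res <- reservoirs[[l$category]]
    res$seen <- res$seen + 1L
    res$items[[res$seen]] <- from_list(l)
  }
  counts <- stats::setNames(
    as.integer(unlist(meta$counts)[CATEGORIES]),
    CATEGORIES
  )
  structure(
    list(
      reservoirs = reservoirs, counts = counts,
      capacity = meta$capacity
    ),
    class = "input_model"
  )
}
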