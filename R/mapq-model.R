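# Per-category mapping-quality models. The aligner reports per-alignment
# feature data in a ZT:Z tag ("best,second_or_NA,qsum_aligned,qsum_clipped",
# extensible with further numeric fields); together with the read length
# and |TLEN| (concordant pairs only) these form the model's input vector.
# Tandem alignments provide truth labels; a random forest per category maps
# the features to a probability-correct, which is written back as MAPQ.

#' Format a feature-tag payload
#' @param best Best alignment score.
#' @param second Second-best score or `NA`.
#' @param qsum_aligned Sum of base qualities of aligned bases.
#' @param qsum_clipped Sum of base qualities of soft-clipped bases.
#' @return `ZT:Z` payload string(s), e.g. `"87,62,3210,0"`.
#' @export
format_feature_tag <- function(best, second, qsum_aligned, qsum_clipped) {
  paste(best, ifelse(is.na(second), "NA", second), qsum_aligned,
    qsum_clipped,
    sep = ","
  )
}

#' Parse feature tags from alignment records into a feature frame
#'
#' @param recs Data frame of aligned records ([read_sam()]`$records`).
#' @param min_score Minimum possible alignment score for a read, used to
#'   encode an absent second-best score: when the aligner found no second
#'   alignment, `score_diff` is set to the ceiling `best - min_score`
#'   (with `has_second = 0`). Either a single number or a function of the
#'   read length; the default `-2 * read_len` matches the built-in
#'   aligner's mismatch penalty.
#' @return Data frame with columns `best_score`, `has_second`, `score_diff`,
#'   `read_len`, `qsum_aligned`, `qsum_clipped`, `tlen_abs`, plus one
#'   numeric column per extra comma-separated tag field, and a logical
#'   `has_tag` flagging records that carried a parseable tag.
#' @export
parse_feature_frame <- function(recs, min_score = NULL) {
  n <- nrow(recs)
  read_len <- nchar(recs$seq)
  if (is.null(min_score)) min_score <- function(len) -2 * len
  floor_score <- if (is.function(min_score)) min_score(read_len) else min_score
  out <- data.frame(
    best_score = NA_real_, has_second = NA_real_, score_diff = NA_real_,
    read_len = as.numeric(read_len), qsum_aligned = NA_real_,
    qsum_clipped = NA_real_, tlen_abs = abs(as.numeric(recs$tlen)),
    has_tag = FALSE
  )
  ok <- which(!is.na(recs$feature_tag))
  if (length(ok)) {
    parts <- strsplit(recs$feature_tag[ok], ",", fixed = TRUE)
    np <- lengths(parts)
    good <- np >= 4L
    okg <- ok[good]
    pg <- parts[good]
    fld <- function(k) {
      suppressWarnings(as.numeric(vapply(pg, `[[`, "", k)))
    }
    best <- fld(1)
    second <- fld(2) # "NA" parses to NA
    out$best_score[okg] <- best
    out$has_second[okg] <- as.numeric(!is.na(second))
    out$score_diff[okg] <- ifelse(is.na(second), best - floor_score[okg],
      best - second
    )
    out$qsum_aligned[okg] <- fld(3)
    out$qsum_clipped[okg] <- fld(4)
    extra <- max(np) - 4L
    if (extra > 0L) {
      for (k in seq_len(extra)) {
        col <- paste0("x", k)
        out[[col]] <- NA_real_
        long <- np[good] >= 4L + k
        out[[col]][okg[long]] <- suppressWarnings(as.numeric(
          vapply(pg[long], `[[`, "", 4L + k)
        ))
      }
    }
    out$has_tag[okg] <- !is.na(best)
  }
  out
}

feature_columns <- function(category, frame) {
  base <- c(
    "best_score", "has_second", "score_diff", "read_len",
    "qsum_aligned", "qsum_clipped"
  )
  extra <- grep("^x\\d+$", names(frame), value = TRUE)
  if (category == "conc") c(base, "tlen_abs", extra) else c(base, extra)
}

#' Build labeled training records from aligned tandem reads
#'
#' Every aligned tandem read with a parseable feature tag yields one
#' training record labeled by whether the alignment matches the origin
#' encoded in its name. Unaligned tandem reads yield no record (failures to
#' align are not modeled); reads whose names carry no origin are skipped
#' with a warning.
#'
#' @param tandem_sam Path or [read_sam()] list of step-4 alignments.
#' @param threshold Correctness distance threshold in nt.
#' @param min_score See [parse_feature_frame()].
#' @return A list of per-category data frames (feature columns + `label`
#'   factor with levels `incorrect`, `correct`).
#' @export
build_training_records <- function(tandem_sam, threshold = 30L,
                                   min_score = NULL) {
  if (is.character(tandem_sam)) tandem_sam <- read_sam(tandem_sam)
  recs <- tandem_sam$records
  recs <- recs[recs$is_aligned, , drop = FALSE]
  if (nrow(recs) == 0L) {
    return(list())
  }
  ends <- ifelse(recs$is_paired & !recs$is_first_end, "2", "1")
  truth <- decode_origins(recs$qname, ends)
  if (any(!truth$is_tandem)) {
    warning(
      sum(!truth$is_tandem),
      " aligned reads without origin-encoded names were skipped"
    )
  }
  frame <- parse_feature_frame(recs, min_score)
  if (any(truth$is_tandem & !frame$has_tag)) {
    warning(
      sum(truth$is_tandem & !frame$has_tag),
      " aligned tandem reads lacked a feature tag and were excluded"
    )
  }
  keep <- truth$is_tandem & frame$has_tag
  recs <- recs[keep, , drop = FALSE]
  truth <- truth[keep, , drop = FALSE]
  frame <- frame[keep, , drop = FALSE]
  cat <- classify_category(recs)
  # bad_end tandem reads are simulated single-end (only the aligned mate's
  # properties can be learned), so their alignments classify as unpaired;
  # route them to the bad_end model via the origin-encoded category
  cat[cat == "unp" & truth$category == "bad_end"] <- "bad_end"
  label <- correct_vec(
    recs$rname, recs$pos, recs$cigar, truth$refname,
    truth$start, threshold
  )
  out <- list()
  for (cc in unique(cat)) {
    idx <- which(cat == cc)
    df <- frame[idx, feature_columns(cc, frame), drop = FALSE]
    df$label <- factor(ifelse(label[idx] == 1L, "correct", "incorrect"),
      levels = c("incorrect", "correct")
    )
    out[[cc]] <- df
  }
  out
}

#' Train the mapping-quality model for one category
#'
#' A random forest of `trees` decision trees, each fit on a bootstrap
#' resample of the training records; the prediction is the average of the
#' per-tree votes for the "correct" class. A single-label training set
#' (e.g. every tandem alignment correct) degenerates to a constant
#' predictor.
#'
#' @param records Data frame from [build_training_records()] (one
#'   category).
#' @param trees Number of trees (default 100).
#' @param max_depth Maximum tree depth; `NULL` = unlimited.
#' @param min_leaf Minimum records per leaf (default 1).
#' @param seed Integer seed; predictions are deterministic given records,
#'   hyperparameters, and seed.
#' @return A `category_model`.
#' @export
train_category_model <- function(records, trees = 100L, max_depth = NULL,
                                 min_leaf = 1L, seed = 1L) {
  if (is.null(records) || nrow(records) == 0L) {
    return(NULL)
  }
  features <- setdiff(names(records), "label")
  if (length(unique(records$label)) < 2L) {
    return(structure(
      list(
        constant = as.numeric(records$label[1] == "correct"),
        features = features, n_train = nrow(records)
      ),
      class = "category_model"
    ))
  }
  fit <- ranger::ranger(
    dependent.variable.name = "label",
    data = records,
    num.trees = trees,
    probability = TRUE,
    min.node.size = min_leaf,
    max.depth = if (is.null(max_depth)) 0L else max_depth,
    importance = "impurity",
    replace = TRUE,
    seed = seed,
    num.threads = 1L,
    verbose = FALSE
  )
  structure(
    list(fit = fit, features = features, n_train = nrow(records)),
    class = "category_model"
  )
}

#' Predict probability-correct for a feature frame
#'
#' Average of the per-tree votes, clamped so the implied mapping quality
#' does not exceed `q_cap` (a vote average of exactly 1 would otherwise
#' imply infinite q).
#'
#' @param model A `category_model`.
#' @param frame Data frame containing the model's feature columns.
#' @param q_cap Maximum mapping quality (default 60).
#' @return Numeric vector of probabilities in `[0, 1 - 10^(-q_cap/10)]`.
#' @export
predict_p <- function(model, frame, q_cap = 60) {
  if (!all(model$features %in% names(frame))) {
    stop(
      "feature frame is missing columns: ",
      paste(setdiff(model$features, names(frame)), collapse = ", "),
      call. = FALSE
    )
  }
  p_max <- 1 - 10^(-q_cap / 10)
  if (!is.null(model$constant)) {
    return(rep(min(model$constant, p_max), nrow(frame)))
  }
  pred <- stats::predict(model$fit, data = frame[, model$features, drop = FALSE],
    num.threads = 1L, verbose = FALSE
  )
  p <- pred$predictions[, "correct"]
  pmin(pmax(p, 0), p_max)
}

#' Per-feature importances of a trained category model
#' @param model A `category_model`.
#' @return Data frame with `feature` and `importance` (non-negative,
#'   summing to 1), sorted descending.
#' @export
feature_importances <- function(model) {
  if (!is.null(model$constant)) {
    imp <- rep(0, length(model$features))
    names(imp) <- model$features
  } else {
    imp <- ranger::importance(model$fit)
  }
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  out <- data.frame(
    feature = names(imp), importance = as.numeric(imp),
    stringsAsFactors = FALSE
  )
  out[order(-out$importance), , drop = FALSE]
}

#' Train one model per category
#'
#' @param training List of per-category record frames
#'   ([build_training_records()]).
#' @param trees,max_depth,min_leaf,seed Passed to
#'   [train_category_model()]; each category's forest is seeded with
#'   `seed + <category index>`.
#' @return Named list of `category_model`s.
#' @export
train_mapq_models <- function(training, trees = 100L, max_depth = NULL,
                              min_leaf = 1L, seed = 1L) {
  models <- list()
  for (cc in names(training)) {
    models[[cc]] <- train_category_model(
      training[[cc]],
      trees = trees, max_depth = max_depth, min_leaf = min_leaf,
      seed = seed + match(cc, CATEGORIES)
    )
  }
  models
}

#' Rewrite the MAPQ field of input alignments with model predictions
#'
#' Every aligned record whose category has a trained model gets
#' `MAPQ = floor(q + 0.5)` (round half up) where `q = q_from_p(p)` for the
#' model's clamped prediction. Unaligned records, records without feature
#' tags, and categories without a model pass through with their original
#' MAPQ (with a warning); every byte outside the MAPQ column is preserved,
#' and one `@PG` header line is appended.
#'
#' @param input_sam Path or [read_sam()] list of step-1 alignments.
#' @param models Named list from [train_mapq_models()].
#' @param q_cap Maximum mapping quality.
#' @param min_score See [parse_feature_frame()].
#' @return A `sam` list (header + records) with rewritten MAPQs.
#' @export
rewrite_mapq <- function(input_sam, models, q_cap = 60, min_score = NULL) {
  if (is.character(input_sam)) input_sam <- read_sam(input_sam)
  recs <- input_sam$records
  aligned <- which(recs$is_aligned)
  if (length(aligned)) {
    cat <- classify_category(recs[aligned, , drop = FALSE])
    frame <- parse_feature_frame(recs[aligned, , drop = FALSE], min_score)
    newq <- recs$mapq[aligned]
    for (cc in unique(cat)) {
      idx <- which(cat == cc)
      model <- models[[cc]]
      if (is.null(model)) {
        warning(
          "no model for category '", cc,
          "'; original MAPQ passed through for ", length(idx), " records"
        )
        next
      }
      usable <- idx[frame$has_tag[idx]]
      if (length(usable) < length(idx)) {
        warning(
          length(idx) - length(usable), " aligned '", cc,
          "' records lacked a feature tag; original MAPQ kept"
        )
      }
      if (length(usable)) {
        p <- predict_p(model, frame[usable, , drop = FALSE], q_cap)
        newq[usable] <- floor(q_from_p(p) + 0.5)
      }
    }
    recs$mapq[aligned] <- as.integer(newq)
  }
  header <- c(
    input_sam$header,
    paste0(
      "@PG\tID:tandemsim\tPN:tandemsim\tVN:",
      as.character(utils::packageVersion("tandemsim")),
      "\tDS:MAPQ rewritten from tandem-simulation model"
    )
  )
  list(header = header, records = recs)
}
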