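fake_records <- function(tags, seq_len = 100L, tlen = 0L) {
  n <- length(tags)
  data.frame(
    qname = paste0("r", seq_len(n)), flag = 0L, rname = "c", pos = 1L,
    mapq = 0L, cigar = paste0(seq_len, "M"), rnext = "*", pnext = 0L,
    tlen = tlen, seq = strrep("A", seq_len), qual = strrep("I", seq_len),
    tags = ifelse(is.na(tags), "", paste0("ZT:Z:", tags)),
    is_paired = FALSE, is_proper_pair = FALSE, is_aligned = TRUE,
    mate_aligned = FALSE, is_reverse = FALSE, is_first_end = FALSE,
    md = NA_character_, feature_tag = tags,
    stringsAsFactors = FALSE
  )
}

test_that("feature tags parse into model inputs", {
  f <- parse_feature_frame(fake_records("87,62,3210,0"))
  expect_equal(f$best_score, 87)
  expect_equal(f$score_diff, 87 - 62)
  expect_equal(f$has_second, 1)
  expect_equal(f$read_len, 100)
  expect_equal(f$qsum_aligned, 3210)
  expect_equal(f$qsum_clipped, 0)
  # absent second-best: indicator 0, score_diff at the configured ceiling
  f2 <- parse_feature_frame(fake_records("100,NA,3500,40"))
  expect_equal(f2$has_second, 0)
  expect_equal(f2$score_diff, 100 - (-2 * 100))
  f3 <- parse_feature_frame(fake_records("100,NA,3500,40"),
    min_score = -150
  )
  expect_equal(f3$score_diff, 250)
  # extra comma-separated fields become anonymous numeric features
  f4 <- parse_feature_frame(fake_records("90,80,3000,0,1,7"))
  expect_equal(f4$x1, 1)
  expect_equal(f4$x2, 7)
  # missing tag flagged
  f5 <- parse_feature_frame(fake_records(NA_character_))
  expect_false(f5$has_tag)
})

test_that("format/parse feature tags roundtrip on random records", {
  set.seed(13)
  n <- 500
  best <- sample.int(100, n, replace = TRUE)
  second <- ifelse(stats::runif(n) < 0.3, NA, best - sample.int(40, n, TRUE))
  qa <- sample.int(4000, n, TRUE)
  qc <- sample.int(200, n, TRUE) - 1L
  tags <- format_feature_tag(best, second, qa, qc)
  f <- parse_feature_frame(fake_records(tags))
  expect_equal(f$best_score, best)
  expect_equal(f$has_second, as.numeric(!is.na(second)))
  expect_equal(f$qsum_aligned, as.numeric(qa))
  expect_equal(f$qsum_clipped, as.numeric(qc))
  expect_equal(f$score_diff[!is.na(second)], (best - second)[!is.na(second)])
})

test_that("training records are labeled from origin-encoded names", {
  recs <- fake_records(rep("90,NA,3000,0", 3))
  recs$rname <- "chrT"
  recs$qname <- c(
    paste0(encode_origin("chrT", 500L, "+", "unp"), "!1"),
    paste0(encode_origin("chrT", 1000L, "+", "unp"), "!2"),
    "not_a_tandem_read"
  )
  recs$pos <- c(500L, 1500L, 7L) # exact, 500 nt away, stray
  sam <- list(header = character(), records = recs)
  expect_warning(
    training <- build_training_records(sam),
    "origin-encoded"
  )
  expect_named(training, "unp")
  expect_equal(nrow(training$unp), 2L)
  expect_equal(as.character(training$unp$label), c("correct", "incorrect"))
})

test_that("forests separate score_diff-driven correctness and are deterministic", {
  set.seed(17)
  n <- 600
  df <- data.frame(
    best_score = stats::rnorm(n, 90, 5),
    has_second = 1,
    score_diff = stats::runif(n, 0, 40),
    read_len = 100,
    qsum_aligned = stats::rnorm(n, 3000, 100),
    qsum_clipped = 0
  )
  df$label <- factor(ifelse(df$score_diff > 20, "correct", "incorrect"),
    levels = c("incorrect", "correct")
  )
  m1 <- train_category_model(df, trees = 50L, seed = 5L)
  m2 <- train_category_model(df, trees = 50L, seed = 5L)
  hold <- df[sample.int(n, 200), ]
  p1 <- predict_p(m1, hold)
  p2 <- predict_p(m2, hold)
  expect_identical(p1, p2)
  # held-out ranking: all correct above all incorrect
  expect_gt(
    min(p1[hold$label == "correct"]),
    max(p1[hold$label == "incorrect"])
  )
  imp <- feature_importances(m1)
  expect_equal(imp$feature[1], "score_diff")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_true(all(diff(imp$importance) <= 0))
})

test_that("degenerate single-label training sets give clamped constants", {
  df <- data.frame(
    best_score = 100, has_second = 0, score_diff = 300,
    read_len = 100, qsum_aligned = 3000, qsum_clipped = 0
  )[rep(1, 10), ]
  df$label <- factor("correct", levels = c("incorrect", "correct"))
  m <- train_category_model(df, seed = 1L)
  p <- predict_p(m, df, q_cap = 60)
  expect_equal(p, rep(1 - 1e-6, 10))
  expect_equal(q_from_p(p[1]), 60)
  df$label <- factor("incorrect", levels = c("incorrect", "correct"))
  m0 <- train_category_model(df, seed = 1L)
  expect_equal(predict_p(m0, df), rep(0, 10))
  expect_null(train_category_model(df[0, ]))
  expect_error(predict_p(m, df[, 1:2]), "missing columns")
})

test_that("MAPQ rewriting touches only aligned records' MAPQ", {
  set.seed(19)
  # train a simple model
  n <- 400
  df <- data.frame(
    best_score = stats::rnorm(n, 90, 5), has_second = 1,
    score_diff = stats::runif(n, 0, 40), read_len = 10,
    qsum_aligned = stats::rnorm(n, 300, 10), qsum_clipped = 0
  )
  df$label <- factor(ifelse(df$score_diff > 20, "correct", "incorrect"),
    levels = c("incorrect", "correct")
  )
  models <- list(
    unp = train_category_model(df, seed = 2L),
    conc = train_category_model(df, seed = 3L),
    disc = train_category_model(df, seed = 4L),
    bad_end = train_category_model(df, seed = 5L)
  )
  sam <- read_sam(write_category_sam(tempfile(fileext = ".sam")))
  out <- rewrite_mapq(sam, models)
  expect_equal(nrow(out$records), nrow(sam$records))
  # unaligned records unchanged entirely
  expect_identical(
    out$records[!out$records$is_aligned, 1:12],
    sam$records[!sam$records$is_aligned, 1:12]
  )
  # aligned records: every column except mapq identical
  keep <- setdiff(names(sam$records), "mapq")
  expect_identical(out$records[, keep], sam$records[, keep])
  expect_true(all(out$records$mapq[out$records$is_aligned] >= 0))
  # one @PG line appended, header otherwise untouched
  expect_equal(length(out$header), length(sam$header) + 1L)
  expect_identical(out$header[seq_along(sam$header)], sam$header)
  expect_match(out$header[length(out$header)], "^@PG")
})

test_that("round-half-up integerisation maps p=0.5 to MAPQ 3", {
  expect_equal(floor(q_from_p(0.5) + 0.5), 3)
  expect_equal(floor(q_from_p(0.68) + 0.5), 5) # 4.948 -> 5
})
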