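test_that("genome generator honours the repeat budget and annotations", {
  g0 <- generate_genome(20000, repeat_fraction = 0, seed = 1)
  expect_equal(nrow(g0$repeat_annotation), 0L)
  expect_equal(nchar(g0$contigs), c(chrS1 = 20000L))

  g <- generate_genome(1e6,
    repeat_fraction = 0.3, unit_len = 500,
    divergence = 0.02, seed = 2
  )
  ann <- g$repeat_annotation
  expect_true(all(ann$type %in% c("copy", "tandem")))
  rep_bases <- sum(ann$copy_end - ann$copy_start + 1)
  expect_equal(rep_bases / 1e6, 0.3, tolerance = 0.02)
  # a zero-divergence copy is identical to its source
  g3 <- generate_genome(20000,
    repeat_fraction = 0.1, unit_len = 500,
    divergence = 0, tandem_share = 0, seed = 3
  )
  full <- paste(g3$contigs, collapse = "")
  a <- g3$repeat_annotation[1, ]
  expect_equal(
    substr(full, a$copy_start, a$copy_end),
    substr(full, a$src_start, a$src_end)
  )
  # divergence shows up at roughly the requested rate
  g4 <- generate_genome(200000,
    repeat_fraction = 0.3, unit_len = 500,
    divergence = 0.05, tandem_share = 0, seed = 4
  )
  full4 <- paste(g4$contigs, collapse = "")
  ann4 <- g4$repeat_annotation
  mm <- mapply(function(s1, e1, s2, e2) {
    a <- utf8ToInt(substr(full4, s1, e1))
    b <- utf8ToInt(substr(full4, s2, e2))
    mean(a != b)
  }, ann4$src_start, ann4$src_end, ann4$copy_start, ann4$copy_end)
  expect_equal(mean(mm), 0.05, tolerance = 0.01)
  # tandem annotation carries a period and the array really is periodic
  gt <- generate_genome(100000, repeat_fraction = 0.3, seed = 5)
  ta <- gt$repeat_annotation[gt$repeat_annotation$type == "tandem", ][1, ]
  fullt <- paste(gt$contigs, collapse = "")
  arr <- substr(fullt, ta$copy_start, ta$copy_end)
  shifted <- substr(arr, ta$period + 1, nchar(arr))
  expect_equal(substr(arr, 1, nchar(shifted)), shifted)
  expect_error(generate_genome(100, unit_len = 500), "unit_len")
})

test_that("read simulator emits honest qualities and exact truth", {
  set.seed(1)
  g <- generate_genome(100000, repeat_fraction = 0.2, seed = 6)
  reads0 <- simulate_input_reads(g, 300, 80, sub_rate = 0, seed = 7)
  genome <- g$contigs
  truth <- decode_origins(reads0$name)
  for (i in seq_len(50)) {
    slice <- substr(
      genome[truth$refname[i]], truth$start[i],
      truth$start[i] + 79L
    )
    expected <- if (truth$strand[i] == "-") revcomp(slice) else slice
    expect_equal(reads0$seq[i], unname(expected))
  }
  # empirical mismatch rate tracks the emitted qualities
  reads <- simulate_input_reads(g, 3000, 100, seed = 8)
  truth <- decode_origins(reads$name)
  slices <- substring(
    genome[truth$refname], truth$start,
    truth$start + 99L
  )
  neg <- truth$strand == "-"
  slices[neg] <- revcomp(slices[neg])
  obs <- mapply(function(r, s) {
    sum(utf8ToInt(r) != utf8ToInt(s))
  }, reads$seq, slices)
  qv <- unlist(phred_to_int(reads$qual))
  expected_rate <- mean(10^(-qv / 10))
  expect_equal(sum(obs) / (3000 * 100), expected_rate, tolerance = 0.1)
})

test_that("paired input reads respect the 2L-4L fragment window", {
  g <- generate_genome(100000, repeat_fraction = 0.1, seed = 9)
  pr <- simulate_input_reads(g, 500, 100, paired = TRUE, seed = 10)
  t1 <- decode_origins(pr$end1$name, end = "1")
  t2 <- decode_origins(pr$end2$name, end = "2")
  lo <- pmin(t1$start, t2$start)
  hi <- pmax(t1$start, t2$start) + 99L
  frag <- hi - lo + 1L
  expect_true(all(frag >= 200 & frag <= 400))
  # FR orientation: the upstream end is forward
  up1 <- t1$start <= t2$start
  expect_true(all(t1$strand[up1] == "+" & t2$strand[up1] == "-"))
  expect_true(all(t1$strand[!up1] == "-" & t2$strand[!up1] == "+"))
})

test_that("toy aligner recovers unique reads and reports tie structure", {
  set.seed(31)
  left <- random_dna(3000)
  unit <- random_dna(400)
  mid <- random_dna(2000)
  right <- random_dna(3000)
  # exact duplicate repeat placed twice, far apart
  genome <- c(chrA = paste0(left, unit, mid, unit, right))
  # unique read
  r_unique <- substr(genome, 1001, 1100)
  # read from inside the duplicated unit (present at exactly 2 loci)
  r_dup <- substr(genome, 3101, 3200)
  # random read absent from the genome
  r_none <- random_dna(100)
  reads <- data.frame(
    name = c("u", "d", "n"),
    seq = c(r_unique, r_dup, r_none),
    qual = strrep("I", 100),
    stringsAsFactors = FALSE
  )
  sam <- toy_align(reads, genome)
  r <- sam$records
  expect_true(r$is_aligned[1])
  expect_equal(r$pos[1], 1001L)
  expect_equal(r$cigar[1], "100M")
  expect_equal(r$mapq[1], 40L) # no second-best locus anywhere
  # duplicated read: second score equals best, native MAPQ 0
  expect_true(r$is_aligned[2])
  zt <- strsplit(r$feature_tag[2], ",")[[1]]
  expect_equal(zt[1], zt[2])
  expect_equal(r$mapq[2], 0L)
  expect_in(r$pos[2], c(3101L, 3101L + 2400L))
  # unalignable read
  expect_false(r$is_aligned[3])
  expect_equal(r$cigar[3], "*")
})

test_that("toy aligner is deterministic and truthful on clean unique reads", {
  g <- generate_genome(200000,
    repeat_fraction = 0.3, divergence = 0.02,
    seed = 11
  )
  reads <- simulate_input_reads(g, 2000, 100, sub_rate = 0, seed = 12)
  sam1 <- toy_align(reads, g)
  sam2 <- toy_align(reads, g)
  p1 <- tempfile()
  p2 <- tempfile()
  write_sam(sam1, p1)
  write_sam(sam2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # reads from unique (never-annotated) regions align correctly
  ann <- g$repeat_annotation
  in_repeat <- function(start) {
    any(start + 99L >= ann$copy_start & start <= ann$copy_end) ||
      any(!is.na(ann$src_start) &
        start + 99L >= ann$src_start & start <= ann$src_end)
  }
  r <- sam1$records
  truth <- decode_origins(r$qname)
  unique_reads <- !vapply(truth$start, in_repeat, logical(1))
  sub <- r$is_aligned & unique_reads
  corr <- correct_vec <- tandemsim:::correct_vec(
    r$rname[sub], r$pos[sub], r$cigar[sub],
    truth$refname[sub], truth$start[sub]
  )
  expect_gte(mean(corr), 0.999)
})

test_that("toy aligner emits MD strings consistent with its alignments", {
  g <- generate_genome(100000,
    repeat_fraction = 0.2, divergence = 0.02,
    seed = 13
  )
  reads <- simulate_input_reads(g, 300, 100, seed = 14)
  sam <- toy_align(reads, g)
  r <- sam$records[sam$records$is_aligned & sam$records$cigar == "100M", ]
  # replaying each alignment's template against the reference at the
  # aligned position must reproduce the aligned read exactly when the
  # mismatch bases are taken from the read
  genome <- g$contigs
  for (i in seq_len(40)) {
    pat <- parse_template_pattern(r$cigar[i], r$md[i])
    nm <- sum(lengths(pat$mism))
    slice <- substr(
      genome[r$rname[i]], r$pos[i],
      r$pos[i] + ref_span(r$cigar[i]) - 1L
    )
    mism <- sum(utf8ToInt(slice) != utf8ToInt(r$seq[i]))
    expect_equal(nm, mism) # MD mismatch count agrees with the sequences
  }
})

test_that("paired toy alignment sets pairing flags and concordance window", {
  g <- generate_genome(150000, repeat_fraction = 0.2, seed = 15)
  pr <- simulate_input_reads(g, 400, 100, paired = TRUE, seed = 16)
  sam <- toy_align(pr, g)
  r <- sam$records
  expect_equal(nrow(r), 800L)
  expect_true(all(r$is_paired))
  both <- r$is_aligned & r$mate_aligned
  # most clean pairs align concordantly within the 2L-4L window
  expect_gt(mean(r$is_proper_pair[both]), 0.9)
  conc <- r[r$is_proper_pair & r$is_aligned, ]
  expect_true(all(abs(conc$tlen) >= 200 & abs(conc$tlen) <= 400))
  # TLEN signs: leftmost end positive, rightmost negative
  first <- conc[conc$is_first_end, ]
  mate <- conc[!conc$is_first_end, ]
  m <- match(first$qname, mate$qname)
  expect_true(all(sign(first$tlen) == -sign(mate$tlen[m])))
})
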