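test_that("CIGAR spans follow reference/extraction accounting", {
  expect_equal(ref_span("10M"), 10)
  expect_equal(extraction_span("10M"), 10)
  expect_equal(ref_span("2M1D2M"), 5)
  expect_equal(ref_span("2M1I2M"), 4)
  expect_equal(ref_span("3S5M"), 5)
  expect_equal(extraction_span("3S5M"), 8)
  expect_error(extraction_span("5H5M"), "unsupported")
})

test_that("template mutation replay follows CIGAR+MD semantics", {
  tmpl <- function(cigar, md) {
    structure(list(strand = "+", quals = "", cigar = cigar, md = md),
      class = "unpaired_template"
    )
  }
  set.seed(5)
  # identity
  expect_equal(apply_template_mutations("ACGT", tmpl("4M", "4")), "ACGT")
  # mismatch at offset 1: Hamming distance exactly 1, never the original
  for (i in 1:25) {
    out <- apply_template_mutations("ACGT", tmpl("4M", "1A2"))
    expect_equal(nchar(out), 4L)
    expect_equal(substr(out, 1, 1), "A")
    expect_equal(substr(out, 3, 4), "GT")
    expect_true(substr(out, 2, 2) != "C")
  }
  # deletion removes the offset-2 base
  expect_equal(
    apply_template_mutations("ACGTA", tmpl("2M1D2M", "2^G2")),
    "ACTA"
  )
  # insertion adds bases without consuming substring
  out <- apply_template_mutations("ACGT", tmpl("2M2I2M", "4"))
  expect_equal(nchar(out), 6L)
  expect_equal(substr(out, 1, 2), "AC")
  expect_equal(substr(out, 5, 6), "GT")
  # soft clips copy unmutated
  expect_equal(apply_template_mutations("ACGT", tmpl("2S2M", "2")), "ACGT")
  # inconsistent MD
  expect_error(
    apply_template_mutations("ACGTA", tmpl("5M", "2^G2")),
    "MD"
  )
  expect_error(
    apply_template_mutations("ACG", tmpl("3M", "5")),
    "inconsistent"
  )
})

test_that("origin names roundtrip and strays are recognised", {
  o <- encode_origin("chrT", 1234L, "+", "unp")
  expect_equal(o, "qt!chrT!1234!+!unp!s")
  d <- decode_origin(o)
  expect_equal(d$refname, "chrT")
  expect_equal(d$start, 1234L)
  expect_equal(d$strand, "+")
  expect_equal(d$category, "unp")
  expect_equal(d$mate_role, "single")
  expect_null(decode_origin("random_read_7"))
  expect_error(encode_origin("chr!T", 1, "+", "unp"), "refname")
  # pair form carries both ends
  p <- encode_origin("c1", 100L, "+", "conc", start2 = 350L, strand2 = "-")
  expect_equal(decode_origin(p, end = "1")$start, 100L)
  expect_equal(decode_origin(p, end = "2")$start, 350L)
  expect_equal(decode_origin(p, end = "2")$strand, "-")
  # property: roundtrip over random origins (with serial suffixes)
  set.seed(9)
  for (i in 1:200) {
    ref <- paste0("ctg", sample.int(99, 1))
    st <- sample.int(1e8, 1)
    sd <- sample(c("+", "-"), 1)
    cat <- sample(c(CATEGORIES, "input"), 1)
    nm <- paste0(encode_origin(ref, st, sd, cat), "!", i)
    d <- decode_origin(nm)
    expect_equal(
      list(d$refname, d$start, d$strand, d$category),
      list(ref, st, sd, cat)
    )
  }
})

test_that("vectorised origin decoding matches the scalar decoder", {
  names <- c(
    "qt!chrT!10!+!unp!s", "stray", "qt!c2!5!-!bad_end!s!44",
    encode_origin("c3", 7L, "+", "conc", start2 = 90L, strand2 = "-")
  )
  d <- decode_origins(names, end = c("1", "1", "1", "2"))
  expect_equal(d$is_tandem, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(d$start, c(10L, NA, 5L, 90L))
  expect_equal(d$strand, c("+", NA, "-", "-"))
  expect_equal(d$mate_role, c("single", NA, "single", "end2"))
})

make_identity_model <- function(genome, strand = "+", len = 40L,
                                cat = "unp") {
  res <- reservoir_new(10L)
  res$items <- list(structure(
    list(
      strand = strand, quals = strrep("I", len),
      cigar = paste0(len, "M"), md = as.character(len)
    ),
    class = "unpaired_template"
  ))
  res$seen <- 1L
  model <- structure(
    list(
      reservoirs = stats::setNames(
        lapply(CATEGORIES, function(x) res), CATEGORIES
      ),
      counts = c(unp = 1L, conc = 0L, disc = 0L, bad_end = 0L),
      capacity = 10L
    ),
    class = "input_model"
  )
  model
}

test_that("identity templates reproduce reference slices exactly", {
  set.seed(21)
  genome <- c(chrA = random_dna(5000))
  model <- make_identity_model(genome)
  set.seed(1)
  rd <- simulate_unpaired(model, genome)
  truth <- decode_origin(rd$name)
  expect_equal(rd$seq, unname(substr(genome, truth$start, truth$start + 39L)))
  expect_equal(nchar(rd$seq), nchar(rd$qual))
  # reverse-strand template: read is the reverse complement of the slice
  model_rev <- make_identity_model(genome, strand = "-")
  set.seed(2)
  rd2 <- simulate_unpaired(model_rev, genome)
  truth2 <- decode_origin(rd2$name)
  slice <- substr(genome, truth2$start, truth2$start + 39L)
  expect_equal(rd2$seq, unname(revcomp(slice)))
  expect_equal(revcomp(revcomp(rd2$seq)), rd2$seq)
})

test_that("positions are uniform across contigs weighted by length", {
  set.seed(31)
  genome <- c(big = random_dna(9000), small = random_dna(1000))
  model <- make_identity_model(genome)
  set.seed(3)
  b <- simulate_unpaired_batch(model, genome, "unp", 20000L)
  truth <- decode_origins(b$name)
  frac_big <- mean(truth$refname == "big")
  # valid-start weighting: (9000-39)/(9000-39+1000-39)
  expect_equal(frac_big, 0.903, tolerance = 0.015)
})

test_that("simulated read quality strings mirror the reservoir multiset", {
  set.seed(41)
  genome <- c(chrA = random_dna(20000))
  quals <- replicate(20, paste(
    sample(c("I", "H", "5", "#"), 30, replace = TRUE),
    collapse = ""
  ))
  res <- reservoir_new(100L)
  for (q in quals) {
    reservoir_offer(res, structure(
      list(strand = "+", quals = q, cigar = "30M", md = "30"),
      class = "unpaired_template"
    ))
  }
  model <- structure(
    list(
      reservoirs = list(
        unp = res, conc = reservoir_new(1L),
        disc = reservoir_new(1L), bad_end = reservoir_new(1L)
      ),
      counts = c(unp = 20L, conc = 0L, disc = 0L, bad_end = 0L),
      capacity = 100L
    ),
    class = "input_model"
  )
  set.seed(4)
  b <- simulate_unpaired_batch(model, genome, "unp", 4000L)
  obs <- table(factor(b$qual, levels = unique(quals)))
  pval <- stats::chisq.test(obs, p = rep(1 / 20, 20))$p.value
  expect_gt(pval, 0.001)
})

test_that("ambiguous-base policy redraws or keeps N runs", {
  genome_n <- c(chrN = strrep("N", 500))
  model <- make_identity_model(genome_n)
  set.seed(5)
  expect_error(
    simulate_unpaired_batch(model, genome_n, "unp", 1L, max_redraws = 10L),
    "redraws"
  )
  b <- simulate_unpaired_batch(model, genome_n, "unp", 1L,
    n_policy = "keep"
  )
  expect_equal(b$seq, strrep("N", 40))
  # mixed genome: redraw lands on the clean contig
  set.seed(6)
  genome_mix <- c(chrN = strrep("N", 500), chrA = random_dna(500))
  b2 <- simulate_unpaired_batch(model, genome_mix, "unp", 50L)
  expect_false(any(grepl("N", b2$seq)))
})

test_that("paired simulation honours fragment geometry", {
  set.seed(51)
  genome <- c(chrA = random_dna(20000))
  tmpl <- function(strand, len) {
    structure(
      list(
        strand = strand, quals = strrep("I", len),
        cigar = paste0(len, "M"), md = as.character(len)
      ),
      class = "unpaired_template"
    )
  }
  res <- reservoir_new(10L)
  res$items <- list(structure(
    list(
      end1 = tmpl("+", 100L), end2 = tmpl("-", 100L),
      frag_len = 300L, first_end_upstream = TRUE
    ),
    class = "paired_template"
  ))
  res$seen <- 1L
  model <- structure(
    list(
      reservoirs = list(
        unp = reservoir_new(1L), conc = res,
        disc = reservoir_new(1L), bad_end = reservoir_new(1L)
      ),
      counts = c(unp = 0L, conc = 1L, disc = 0L, bad_end = 0L),
      capacity = 10L
    ),
    class = "input_model"
  )
  set.seed(7)
  pr <- simulate_pair(model, genome, "conc")
  t1 <- decode_origin(pr$end1$name[1], end = "1")
  t2 <- decode_origin(pr$end2$name[1], end = "2")
  # frag 300, read lengths 100/100: starts differ by 200; end1 upstream
  expect_equal(t2$start - t1$start, 200L)
  # identity templates: ends match the fragment's extreme slices
  expect_equal(
    pr$end1$seq,
    unname(substr(genome, t1$start, t1$start + 99L))
  )
  expect_equal(
    pr$end2$seq,
    unname(revcomp(substr(genome, t2$start, t2$start + 99L)))
  )
  # first_end_upstream = FALSE puts end2 at the smaller coordinate
  res$items[[1]]$first_end_upstream <- FALSE
  res$items[[1]]$end1 <- tmpl("-", 100L)
  res$items[[1]]$end2 <- tmpl("+", 100L)
  set.seed(8)
  pr2 <- simulate_pair(model, genome, "conc")
  s1 <- decode_origin(pr2$end1$name[1], end = "1")$start
  s2 <- decode_origin(pr2$end2$name[1], end = "2")$start
  expect_lt(s2, s1)
})
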