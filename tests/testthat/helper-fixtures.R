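# Shared fixtures, built in code.

# A tiny hand-written SAM covering all four alignment categories plus an
# unaligned record, with MD and ZT tags.
write_category_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrT\tLN:10000",
    # unpaired, forward
    "u1\t0\tchrT\t101\t40\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10\tZT:Z:10,NA,350,0",
    # unpaired, reverse
    "u2\t16\tchrT\t201\t7\t4S6M\t*\t0\t0\tACGTACGTAC\tIIIIIHHHHH\tMD:Z:6\tZT:Z:6,3,210,140",
    # concordant pair (proper-pair flag set)
    "p1\t99\tchrT\t301\t40\t10M\t=\t391\t100\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10\tZT:Z:10,NA,350,0",
    "p1\t147\tchrT\t391\t40\t10M\t=\t301\t-100\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10\tZT:Z:10,NA,350,0",
    # discordant pair (both aligned, no proper-pair flag)
    "p2\t97\tchrT\t501\t30\t10M\t=\t901\t410\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10\tZT:Z:10,5,350,0",
    "p2\t145\tchrT\t901\t30\t10M\t=\t501\t-410\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10\tZT:Z:10,5,350,0",
    # bad-end pair (mate unaligned)
    "p3\t73\tchrT\t701\t20\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tMD:Z:10\tZT:Z:10,2,350,0",
    "p3\t133\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    # unaligned single
    "u3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"
  )
  writeLines(lines, path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Literal implementation of the tie-group recurrences for the cumulative
# incorrect and cumulative squared-error vectors: sort descending, find
# maximal equal-quality stretches, and apply
#   c_i = c_{i-1} + sum_j incorrect_j / group_size        (within the group)
#   e_i = e_{i-1} + sum_j (correct_j - p_j)^2 / group_size
# This is the independent oracle for the vectorised implementation.
oracle_cumulative <- function(correctness, key, values) {
  ord <- order(-key)
  k <- key[ord]
  v <- values[ord]
  n <- length(v)
  out <- numeric(n)
  prev <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && k[j + 1L] == k[i]) j <- j + 1L
    inc <- sum(v[i:j]) / (j - i + 1L)
    for (t in i:j) {
      out[t] <- prev + inc
      prev <- out[t]
    }
    i <- j + 1L
  }
  out
}

oracle_C <- function(correctness, Q) {
  oracle_cumulative(correctness, Q, 1 - correctness)
}

oracle_E <- function(correctness, P) {
  oracle_cumulative(correctness, P, (correctness - P)^2)
}

# The study-condition world for the end-to-end checks: a 1 Mbp genome with
# 30% repeats at 2% divergence, 50k unpaired 100 nt reads, and their
# built-in-aligner alignments. Built once per test run and cached.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (is.null(.acceptance_cache$world)) {
    genome <- generate_genome(1000000, 0.3,
      unit_len = 500L,
      divergence = 0.02, seed = 301L
    )
    reads <- simulate_input_reads(genome,
      n = 50000, read_len = 100,
      seed = 302L
    )
    input_sam <- toy_align(reads, genome)
    .acceptance_cache$world <- list(
      genome = genome, reads = reads,
      input_sam = input_sam
    )
  }
  .acceptance_cache$world
}
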