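---
title: "Tandem simulation: learning mapping qualities alongside an aligner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem simulation: learning mapping qualities alongside an aligner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A read aligner reports, for each read, the highest-scoring alignment it
found, together with a MAPQ value: an integer encoding of
$q = -10\log_{10}(1-p)$, where $p$ is the probability that the reported
location is the read's true origin. Downstream tools either threshold on
MAPQ (variant callers discarding alignments below a cutoff) or use $p$
directly as a weight, so both the *ranking* induced by $q$ and its
*calibration* as a probability matter. Aligners' built-in MAPQ formulas
are ad hoc — typically a coarse function of the best and second-best
alignment scores — and are often confidently wrong, most notably when the
search heuristics never surfaced the competing locus that would have
revealed the ambiguity.

`tandemsim` implements an aligner-agnostic alternative: learn the mapping
between per-alignment features and correctness *for the dataset at hand*,
using simulated reads whose truth is known and whose statistics mimic the
input reads. Because the simulated ("tandem") reads are aligned with the
same aligner and parameters as the input, the learned model inherits
exactly the error modes of that alignment scenario.

## The pipeline

1. Align the input reads (built-in aligner or any SAM-producing tool that
   emits the feature tag described below).
2. Build the **input model**: for each aligned read, a *template* records
   the strand, the quality string (in read orientation), and the mutation
   pattern of the alignment (CIGAR + MD). Pair templates add the inferred
   fragment length and which end aligned upstream. One bounded reservoir
   sample of templates is kept per alignment category — `unp`, `conc`,
   `disc`, `bad_end` — using Algorithm R with a default capacity of
   10,000, so memory is constant regardless of input size.
3. Simulate **tandem reads**: draw a template uniformly with replacement,
   draw a genome position uniformly (contigs weighted by valid
   placements), reverse-complement for minus-strand templates, replay the
   template's mismatches (a mismatch position receives one of the three
   non-reference bases uniformly; insertions receive uniform bases;
   deletions skip reference bases), and copy the quality string verbatim.
   The true origin is encoded in the read name. The per-category count
   defaults to $\lceil 45\sqrt{x}\rceil$ for $x$ input alignments, with
   floors of 30,000 (`unp`, `conc`) and 10,000 (`disc`, `bad_end`).
4. Align the tandem reads with the identical aligner invocation.
5. Label each aligned tandem read correct/incorrect: correct means the
   implied leftmost base (POS minus leading soft clip) is within 30 nt of
   the encoded origin on the same contig.
6. Train one random forest per category (100 trees, unlimited depth,
   minimum leaf size 1, bootstrap resampling; `ranger` backend with a
   fixed seed and one thread so runs are reproducible). Features are the
   aligner-reported best score, an indicator and magnitude of the
   best-minus-second score difference, read length, quality sums over
   aligned and soft-clipped bases, |TLEN| for concordant pairs, and any
   extra numeric fields the aligner appends to its tag.
7. Predict $p$ for every input alignment and rewrite its MAPQ as
   `floor(q + 0.5)`; everything outside the MAPQ column is preserved
   byte-for-byte, and one `@PG` header line is appended.

## The feature-tag contract

The aligner communicates per-alignment feature data in a `ZT:Z:` tag of
comma-separated values: `best,second_or_NA,qsum_aligned,qsum_clipped`,
optionally followed by further numeric fields that are passed to the
model as anonymous features. When no second-best alignment was found the
model receives an indicator of 0 and a score difference set to the
ceiling `best - min_score` (by default `min_score = -2 * read_len`,
matching the built-in scoring); this keeps "no competitor seen" ordered
above every observed competitor without inventing a sentinel the trees
would have to special-case.

## Evaluation statistics

For a truth-labeled dataset and two quality assignments over the same
alignments (aligner = baseline, model = challenger), the package computes:

- the **cumulative incorrect vector** $C$: sort by descending quality;
  $c_i$ counts incorrect alignments among the $i+1$ best, with the
  penalty of an equal-quality group spread evenly over the group so tie
  breaking is irrelevant;
- the **cumulative squared-error vector** $E$: the same construction for
  $(\mathrm{correct}-p)^2$, sorted by each assignment's own $p$;
- difference curves CID $= C'-C$ and CSED $= E'-E$ (negative favours the
  challenger), with CSED plotted through the odd compression
  $\mathrm{sign}(y)\log_{10}(|y|+1)$;
- summary measures $\mathrm{RCA} = (\sum C' - \sum C)/\sum C$ (ranking
  only: invariant under strictly monotone transforms of either quality
  scale) and $\mathrm{RCE} = (\mathrm{SSE}(P')-\mathrm{SSE}(P))/
  \mathrm{SSE}(P)$ (calibration), reported as percentages.

MAPQ 255 means "unavailable" in SAM and is excluded from comparisons.

## The synthetic fixture

The package carries its own test surface so the whole pipeline runs
without external tools.

**Genome.** `generate_genome()` emits blocks of fresh i.i.d. sequence
interleaved with two kinds of repeats: *dispersed copies* of earlier
windows mutated at a per-base divergence rate (transposon-like), and
*short-period tandem arrays* (satellite/VNTR-like; by default 15% of the
repeat budget, periods 8–24 bp, array lengths 130–190 bp, no internal
divergence). The arrays matter: alignments inside them are
shift-ambiguous by multiples of the period — often more than the 30 nt
correctness window but less than one read length — which is precisely the
situation in which a score-based MAPQ heuristic that only looks for
competitors at *distant* loci is confidently wrong. Without such a
population, a full-sensitivity toy aligner on substitution-only dispersed
repeats detects a near-tie for essentially every error it makes, its
native MAPQ already ranks errors optimally, and no feature-based model
could improve the ranking; the arrays restore the failure mode the
framework exists to fix.

**Reads.** `simulate_input_reads()` draws positions uniformly, assigns
per-base Phred qualities from a profile (default: mostly 33–37 with a
small low-quality tail, overall error rate ≈ 0.4%), and substitutes each
base with probability $10^{-q/10}$, so emitted qualities are honest.
Paired mode draws fragment lengths uniformly from $[2L, 4L]$ with FR
orientation, the window the aligner also treats as concordant.

**Aligner.** `toy_align()` is a deterministic seed-and-extend aligner:
exact 21-mer seeds (sampled every 40 nt of the read) vote for candidate
diagonals on both strands; candidates are scored gaplessly on their
diagonal and re-scored with a banded (half-width 3) affine-gap
alignment whenever an indel could in principle improve the score
(match 1, mismatch −2, gap open −4, gap extend −1; the read must align
end-to-end, so there is no soft clipping). It reports one best alignment
(ties broken toward the smallest coordinate), suppresses alignments
below `0.6 × read_len` score, and emits
`ZT:Z:best,second_or_NA,qsum_aligned,qsum_clipped,has_alt,alt_diff`,
where the second-best score is the best score seen at a locus more than
one read length away and `alt_diff` is the gap to the best score at *any*
other evaluated position — the analogue of the suboptimal-score fields
real aligners expose. Its native MAPQ is the deliberately coarse
`min(40, 2*(best - second))`, or 40 when no distant second was seen; it
ignores the nearby-alternative evidence, which is what leaves the trained
model room to beat it on both RCA and RCE.

## A small run

```{r, eval = FALSE}
library(tandemsim)
genome <- generate_genome(400000, repeat_fraction = 0.3, seed = 1)
reads <- simulate_input_reads(genome, 20000, read_len = 100, seed = 2)
run <- run_tandem_pipeline(reads, genome, seed = 3)
ev <- evaluate_run(run)
ev
plot_difference_curve(ev, "csed")
```

Negative RCA and RCE mean the rewritten MAPQs rank and calibrate better
than the aligner's own; the package's acceptance script
(`scripts/acceptance.R`) performs exactly this computation.

## Numerical and design choices

- **Reservoir RNG**: each category's reservoir is seeded with
  `seed + category index`, and the simulation, forest training, and
  pipeline share the one user seed, so identical seeds give
  byte-identical rewritten SAMs.
- **Orientation**: templates are converted to read orientation at
  extraction (SAM stores reverse-strand reads reference-oriented);
  replay is extract → reverse-complement → apply pattern.
- **Origin encoding**: `qt!ref!start!strand!category!s` for single-end
  reads. Both ends of a pair must share one SAM QNAME, so pair names
  carry both origins (`qt!ref!s1!st1!s2!st2!cat!p`) and decoding takes
  the end as an argument. `!` is safe in QNAMEs; contig names containing
  `!` are rejected at load.
- **Ambiguous bases**: substrings containing non-ACGT characters are
  redrawn (up to 1,000 attempts) by default; a `keep` policy passes them
  through for callers that want N-aware behaviour.
- **Probability clamp**: a vote average of 1 would imply infinite $q$;
  predictions are clamped so $q \le 60$ (`q_cap`, configurable).
- **Rounding**: MAPQ integerisation is round-half-up, the fixed tie rule
  for "rounded to the nearest integer".
- **bad_end simulation**: only the aligned end of a bad-end pair is
  simulated (the unaligned mate's properties cannot be learned from an
  alignment); those single-end tandem reads are routed back to the
  `bad_end` model via their origin-encoded category.
- **Degenerate training sets**: a category whose tandem alignments are
  all one label yields a constant (clamped) predictor; a category with
  no tandem alignments yields no model and the original MAPQs pass
  through with a warning.
- **Problem sizes**: the test suite exercises the full study conditions —
  a 1 Mbp genome with 30% repeats at 2% divergence and 50,000 unpaired
  100 nt reads, with ten independently seeded model builds — and smaller
  200 kb worlds for conservation/determinism checks; these sizes give
  stable statistics while keeping a complete run of the suite to a few
  minutes on one CPU.

## What the fixture does and does not emulate

The generator reproduces the features that drive category-3 alignment
errors: dispersed near-identical repeats, young tandem arrays, and
quality-dependent substitution errors. It does not emulate indel
sequencing errors, homopolymer artifacts, positional coverage bias,
sample-versus-reference genetic variation, or contamination (reads from
sequence absent from the reference). Consequently, passing tests show
the framework's machinery is correct and that its directional advantage
holds in a realistic repeat landscape; they do not certify performance
margins on real sequencing data or with production aligners, whose
feature sets, score scales, and heuristics differ. Category-2 events
(reads that fail to align) yield no training records and are not
modeled, and category-1 contamination is ignored by design.

## Limitations

- The built-in aligner fixes one score scale; cross-scale behaviour
  (local vs end-to-end scoring) is untested by design.
- Models are rebuilt per run and are deliberately not persistable: a
  model is only meaningful for the aligner, parameters, genome, and read
  set it was trained alongside.
- Tandem-read counts follow $45\sqrt{x}$ with fixed floors; very small
  categories (a handful of discordant pairs) train on mostly-duplicated
  templates and produce correspondingly rough models.
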