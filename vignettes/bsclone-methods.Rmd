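---
title: "Clone-level bisulfite methylation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-level bisulfite methylation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsclone)
```

## Scope and data model

`bsclone` analyses primary bisulfite sequencing data from subcloned PCR
products. The input is a reference (or repeat-family consensus) sequence and
a set of reads, one per sequenced clone. Bisulfite chemistry converts
unmethylated cytosine to uracil — read as thymine after PCR — while
5-methylcytosine stays cytosine. In the mammalian setting the package
targets, methylation is assayed at CpG dinucleotides only; a cytosine read
at any *non*-CpG position is treated as a conversion artifact and used for
quality control, never as non-CpG methylation. Users interested in plant
style CHG/CHH methylation need different tooling; lowering the conversion
threshold here merely stops such reads from being discarded.

The central objects are:

* `bs_reference` — original and in-silico converted sequence with indexed
  CpG and non-CpG cytosine positions. Conversion replaces every C *not*
  followed by G with T; CpG cytosines stay C because they legitimately read
  C or T. All coordinates in the package are 1-based.
* `bs_alignment` — all reads placed in one gapped coordinate frame over the
  converted reference.
* `bs_calls` — a clones × CpG-sites matrix over {M, U, X}.

## Alignment

Reads are aligned individually to the converted reference with an
end-gap-free global (overlap) alignment: match +1, mismatch −1, gap open 4,
gap extend 1. Two bisulfite-specific choices matter:

* **Scoring is methylation-blind.** A read T opposite a reference C scores
  as a match. After conversion the only cytosines left in the reference are
  CpG cytosines, so this one rule makes both methylated (C) and
  unmethylated (T) readings score identically and keeps the alignment from
  biasing downstream calls.
* **Free end gaps implement vector trimming.** Subcloned inserts carry
  plasmid sequence at their ends; with read end gaps free, these overhangs
  simply extend past the reference and are cut away. Orientation is decided
  by aligning both the read and its reverse complement and keeping the
  higher score; a read whose best score falls below `min_score_frac` (0.3)
  times the shorter sequence length is flagged unalignable and excluded
  with a logged reason rather than failing the run.

The per-read pairwise alignments are merged into one frame. The default
*stitched* merge reserves, at each reference position, the longest
insertion observed in any read (insertions left-aligned). The *msa* mode
runs a progressive center-star multiple alignment around the converted
reference with the same scoring, adding reads under a
once-a-gap-always-a-gap rule; the reference is the center because reference
and reads are not of equal weight — every read is meaningfully compared
only to the reference. In `auto` mode, msa is selected only when a CpG lies
within `end_window` (30 bp) of a reference end *and* is immediately
preceded by a T-homopolymer of at least `tstretch_min` (4) bases — the
configuration where slippage-induced T indels make stitched frames fail at
a terminal CpG. The window and run-length values are the package's own
calibration of "close to the end" and "T-stretch" (undefined terms in the
workflow this implements); both are configurable, and the rule checks both
ends because terminal CpGs are equally fragile on either side. Alignment
tie-breaking is delegated to the aligner (Biostrings), which is
deterministic; identical inputs always produce identical frames, which the
tests assert at the byte level on written outputs.

## Quality control

Per read, within its aligned span (columns where the read is present,
ignoring columns gapped in both rows):

* **identity** — matching columns over columns where both rows carry a
  base, with C *or* T opposite a reference CpG cytosine counted as a match
  and N columns excluded. Conversion artifacts therefore depress identity
  slightly, which is intended: they are genuine disagreements with the
  converted reference.
* **conversion rate** — among non-CpG reference cytosines, the fraction
  read T of those read C or T. If no position is assessable the rate is
  undefined (`NA`) and the conversion criterion is treated as not failed:
  an unassessable read should be caught by identity or gaps, not by a
  criterion it provides no evidence about.
* **gap fraction** — columns gapped in exactly one row over span columns;
  insertions and deletions are counted jointly.
* **N at cytosines** — unresolved basecalls at reference cytosine
  positions, a direct indicator of poor trace quality.

Unique-mode defaults are identity ≥ 90%, conversion ≥ 95%, gaps ≤ 20%.
Repeat-mode defaults are identity ≥ 70% and gaps ≤ 20%, with the conversion
criterion replaced by a rate rule: reads with 3 or more unconverted
cytosines per 100 bp of aligned span are excluded. All boundaries are
inclusive for passing except that repeat rule, whose "3 and more" phrasing
is explicit about excluding at the boundary; the per-100bp rate is
evaluated globally over the aligned span rather than in fixed windows,
because window phase would be an arbitrary degree of freedom. The
N-at-cytosine cap defaults to 3 — a package-chosen default, since the
source workflow filters on N-sites without stating a count — and is
configurable like every other threshold. Filtering is a pure function of
the metrics and the configuration, and improving any single metric can
never flip a passing read to failing (a property the tests exercise).

## CpG calling

For a site at reference position *i*, the caller first requires a read G in
the column aligned to position *i*+1 (the CpG guanine). Only then does it
read the read's previous non-gap base — in read coordinates, not the
reference C column — and maps C → methylated, T → unmethylated, everything
else (A, G, N, absent) → unknown. This guanine-anchored rule has two
consequences worth spelling out:

* mutated or unreadable dinucleotides (TA, TT, TN, CN, gaps) are always
  *unknown*, never silently counted as methylation states;
* a thymine inserted or deleted within a T-stretch 5' of the CpG shifts the
  informative C/T into or out of the reference C column, but the read-space
  "previous base before the G" is unaffected.

The truth table is exhaustively enumerated in the test suite: over all 36
aligned base pairs, only C·G yields M and only T·G yields U.

Per-site statistics are reported only where at least `min_site_n` (default
5) reads were informative; thinner sites print `NA`. The threshold counts
only M/U calls — unknowns carry no methylation information, and counting
them would defeat the rule's purpose of suppressing weak data points.
Per-clone means have no such threshold (clones with zero informative sites
report `NA`), and the optional sort orders clones by descending methylation
with stable ties; descending is a fixed, configurable choice made for
determinism.

## Clonal duplicate filtering

PCR can over-amplify one converted template molecule, producing several
identical subclones that would inflate the apparent homogeneity of the
region. Each read is reduced to a cytosine pattern over every reference
cytosine position: M/U/X at CpGs, and converted (`t`) / artifact (`C`) /
other (`.`) at non-CpG cytosines. Positions where the read shows an N are
masked and ignored in comparisons — an N reflects sequencing quality, not a
different template — so two reads differing only by an N still match.
Matching is symmetric but, because of N-wildcarding, not transitive;
grouping therefore takes the transitive closure, and the group
representative is the earliest read in input order (which member is kept
does not change the kept-set size, and the choice is exposed as an option).

* `strict`: keep only the representative of each group.
* `suggested` (default): remove a member only if it shares at least one
  conversion artifact with the representative at the same unmasked
  position. Identical CpG-only patterns are kept — in a region that is
  mostly methylated or mostly unmethylated, independent molecules *will*
  produce identical patterns, and removing them fabricates heterogeneity.
  A shared failure of conversion at the same non-CpG cytosine, by
  contrast, is individually rare and jointly diagnostic of clonal origin.
* `off`: keep everything (decisions can also be overridden by the caller,
  since the full decision table is returned).

An unknown (X) CpG call is compared as an ordinary symbol unless the
underlying base was N: X states arising from mutations are reproducible
molecule properties, while N-induced ones are not. Removals are monotone
across modes (strict ⊇ suggested ⊇ off) and classification is idempotent
on the kept set; both are property-tested.

## Repeat (consensus) mode

Repetitive elements have no unique genomic reference; reads originate from
thousands of diverged copies and are compared to a family consensus.
Clonal filtering is therefore not applied. Two complementary analyses run
on the quality-passed reads (the frame is always stitched — the consensus
is the natural center, and the terminal-CpG fallback was designed for
unique PCR products):

1. **Per-read methylated-CpG extraction.** A methylated CpG is any read C
   whose next non-gap read base is G — detected in read space, so CpGs
   absent from the consensus (including ones inside read insertions) are
   counted, flagged by whether their column is a consensus CpG cytosine.
   Reads are summarised by count, by count histogram, and by methylated
   CpGs per 100 bp of aligned span (consensus-length normalisation is
   available as an alternative denominator via the stored spans).
2. **Mutation-corrected overall methylation.** At consensus CpG sites the
   dinucleotide read through the calling convention above is tallied as
   CG, TG, CA, TA, or other. CG→TG mutations in the sequenced strand are
   indistinguishable from unmethylated CpGs; mutations on the opposite
   strand, however, surface as CA (methylated) or TA. Assuming equal
   per-strand mutation rates, the unmethylated count is corrected to
   `TG − CA` (clamped at zero with a warning) and the methylation
   percentage computed as `100·CG/(CG + max(0, TG − CA))`. TA pairs are
   tallied but not subtracted by default, following the estimator's
   published description; `use_ta = TRUE` enables the stricter correction
   for users who prefer to treat TA as unmethylated-and-mutated. With a
   true methylation *p* and per-strand mutation rate *m*, the naive
   estimate converges to *p*(1−*m*) while the corrected one converges to
   *p*(1−*m*)/(*p*(1−*m*)+1−*p*) — still marginally conservative but far
   closer to *p*; at *p* = 0.9, *m* = 0.05 the residual bias (≈0.5
   percentage points) is well inside the sampling noise of a 50-clone
   experiment, which the simulation tests confirm.

## The simulator

`sim_config()` / `simulate_reference()` / `simulate_reads()` generate
datasets with a full truth manifest (per-clone methylation states,
duplicate-of map, planted artifact positions, planted mutations,
orientations). The defaults describe a typical subcloned bisulfite
experiment: a 400 bp amplicon, 20 CpGs, 50 clones — the upper end of common
practice, chosen so binomial checks have power — per-site methylation 0.3,
and 2% conversion failure (98% conversion, typical of a successful
treatment). Noise channels that are off by default are enabled per
scenario: substitution errors, N basecalls, one-T indels at T-homopolymers
of length ≥ 4, clonal duplication (copying the template's converted
molecule *before* per-read noise, as real re-amplification does), random
vector flanks, random orientation, and per-strand CG→TG mutation for
repeat-mode data (opposite-strand mutations surface as CA/TA in the
sequenced strand).

What the simulator does *not* emulate: realistic per-base quality profiles
and their position dependence, chromatogram-level artifacts, primer-biased
amplification, chimeric PCR products, and sequence-dependent conversion
resistance. Passing tests therefore demonstrate correctness of the
pipeline's logic under a clean generative model of the assay, not
robustness to every failure mode of real traces; the quality filters exist
precisely because real data violate the clean model.

## Numerical and degenerate-input choices

* All randomness flows from one integer seed; reference and read
  generation use distinct deterministic streams derived from it.
* Identical inputs give byte-identical output files (fixed column formats,
  fixed JSON digit count, no timestamps).
* Degenerate cases are defined rather than fatal: an empty surviving read
  set produces a header-only call matrix and `NA` summaries; a read with
  no assessable non-CpG cytosine has an undefined conversion rate that
  does not fail it; an all-other tally is an error for the estimator
  (division by zero has no scientific reading).
* Test and acceptance simulations use 50 clones × 20 CpGs (≤1000
  informative cells), sized so that every stochastic assertion can use a
  3-standard-error band around the planted parameter.

## Known limitations

* The center-star multiple alignment shares its pairwise scoring with the
  stitched merge; it is a fallback for terminal T-stretch CpGs, not a
  general-purpose MSA, and will not reproduce ClustalW gap placement.
* Identity, conversion and gap metrics are computed against the aligned
  span only; a read covering a small fraction of the reference can pass
  all filters while informing few sites (the ≥5-informative-reads rule is
  the guard on the reporting side).
* The mutation correction assumes strand-symmetric mutation rates and
  ignores TA by default; families with strongly asymmetric deamination
  histories will retain bias.
* AB1 support reads basecalls (edited, falling back to primary) only;
  no chromatogram inspection or re-calling is attempted.
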