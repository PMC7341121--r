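---
title: "Detecting rare cell-specific genome edits by amplicon sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare cell-specific genome edits by amplicon sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprseq)
```

## The problem

When Cas9 is expressed from a tissue-specific promoter in a multicellular
animal, only a small fraction of cells — for example the ~10% of *C. elegans*
L1/L3 cells that are body-wall muscle — can acquire an edit at the sgRNA
target site. Enzymatic heteroduplex assays (T7E1) routinely fail at this
mosaicism level. Deep amplicon sequencing can succeed: amplify a short region
around the predicted cut site with a two-step PCR that attaches Illumina
clustering/sequencing adapters and sample indices, sequence to ≥100,000
reads, align, and ask whether reads missing bases near the PAM-proximal cut
site are significantly enriched over a matched unedited control.

`crisprseq` implements that computational pipeline end to end — library
design with in-silico PCR, a mosaic-population read simulator with truth
labels, a semi-global affine-gap aligner, per-position deletion ("absence
rate") profiling, and a read-level editing call — plus the Q-neuroblast
migration genetics statistics used to phenotype the same strains
(five-position AQR/PQR tallies, Fisher exact tests, and additive-expectation
synergy tests).

## Library design model

A design is a reference region, a pair of PCR1 primers (gene-specific 3'
part, Illumina adapter tail on the 5' end: the "smRNA" tail on the forward
primer, the "Read2" tail on the reverse), and a PCR2 index primer set
(P5 + i5 index; P7 + i7 index). In-silico PCR requires exactly one exact
occurrence of the forward gene-specific sequence and, downstream of it, of
the reverse complement of the reverse gene-specific sequence; zero matches or
multiple valid pairings are hard errors — no silent first-hit choice.
Primer matching is exact (no mismatch tolerance): no tolerance is on record
for the assay, and exact matching keeps failure modes explicit.

The final sequenced molecule is

    P5 + i5 + fwd_tail + insert + revcomp(rev_tail) + revcomp(i7) + revcomp(P7)

For the etr-1 exon 8 design — 170-bp insert, 32- and 34-nt tails, 29-nt P5,
24-nt P7, two 6-nt indices — this predicts a 301-bp library molecule, which
the packaged defaults reproduce exactly:

```{r design}
primers <- read_primer_table(system.file("extdata", "table1_primers.tsv",
                                         package = "crisprseq"))
design <- library_design(synthetic_target(), primers[["etr-1PCR1F"]],
                         primers[["etr-1PCR1R"]])
predict_library_molecule(design)$length
```

Design choices where the protocol is silent:

* **Coordinates** are 0-based, half-open throughout.
* **Cut site** is fixed 3 bp 5' of the PAM — the standard SpCas9 blunt cut.
* **Illumina constants**: P5/P7 are the standard 29- and 24-nt clustering
  sequences; indices default to 6-mers (the documented i7 index `CAGATC` and
  an arbitrary i5 6-mer, since the i5 primer is described only by an opaque
  label). All four are overridable via `index_primer_set()`.
* **The bundled locus is synthetic.** The published gene-specific primer
  sequences are embedded in a fixed synthetic 1-kb reference, with a
  synthetic 20-nt sgRNA placed so that the PAM lies 24 bp downstream of the
  forward primer's 3' end. The real protospacer is not available in
  machine-readable form and is deliberately not guessed.

## Mosaic simulation model

`simulate_population()` draws `n_alleles` alleles; each carries a deletion
with probability `edited_cell_fraction * per_allele_edit_prob`. Deletion
lengths follow a geometric distribution truncated at `max_del_len`
(inverse-CDF sampling, so a fixed seed gives lengths monotone in
`max_del_len`); `floor(len * left_extent_frac)` deleted bases go 5' of the
cut, the rest 3', so every deletion contains or abuts the cut site. An
allele is **amplifiable** unless its deletion intersects a primer binding
site — deletions that remove a primer site are simply never amplified, and
this dropout is the central mechanism making the observed deleted-read
fraction an underestimate of the edited-cell fraction.

Defaults state the emulated world once:

| parameter | default | rationale |
|---|---|---|
| `edited_cell_fraction` | 0.10 | body-wall-muscle share of larval cells |
| `per_allele_edit_prob` | 1 | continuous transgenic Cas9 exposure; keeps the cell-fraction vs read-fraction comparison about dropout |
| `del_len_mean` | 25 bp | decaying length spectrum reaching tens of bp, consistent with a PAM-proximal peak that grades off over the amplicon |
| `max_del_len` | 160 bp | large deletions possible but bounded inside the amplicon |
| `left_extent_frac` | 0.3 | deletion mass extends mostly 3' of the cut, matching the graded 3' decline of the observed absence profile |
| `insertion_prob` | 0 | the readout counts missing bases only |
| `n_reads` | 100,000 | stated per-sample minimum |
| `read_len` | 250 nt single-end | platform mode not on record; MiSeq-plausible stand-in |
| `subst_error_rate` | 10^-3 | typical Illumina substitution rate |

`simulate_reads()` uses read-1 geometry: a read starts immediately 3' of the
forward adapter tail and reads through into the reverse adapter (and i7/P7)
when the molecule is shorter than the read — which it always is for this
amplicon (234 nt < 250 nt), so adapter trimming is a real, exercised stage.
Qualities are constant Q40; the analysis never uses them. PhiX spike-in and
PCR duplicates/chimeras are not simulated — the former never reaches
alignment, the latter is out of scope.

**What a green simulation-based test does not establish**: real NHEJ
spectra are not geometric, real error profiles are position-dependent, and
real samples contain primer dimers and library artifacts. The simulator
establishes that the *pipeline machinery* (dropout accounting, alignment,
profiling, calling) behaves correctly in a controlled world, not that the
biological deletion spectrum is as modelled.

## Alignment

Reads are aligned to the amplicon only (not genome-wide): for per-position
profiling of a single amplicon the two are equivalent, but this is an
amplicon-local aligner, not a general read mapper. The aligner is
semi-global with affine gaps: the read must be fully consumed; gaps at the
reference ends are free. A gap of length L scores
`gap_open + (L - 1) * gap_extend`; defaults (+1 / −4 / −6 / −1) follow
BWA-MEM-like ratios. A read is reported unaligned when its optimal score is
below `min_score_frac * match * read_length` (default 0.6) — large
deletions can therefore fail alignment, another documented reason the method
undercounts edits. Reads are never silently clipped, and reverse-complement
search is off by default (read-1 orientation is known).

Determinism: traceback ties break diagonal > deletion > insertion, and all
indels are then left-normalized — shifted maximally 5' among equal-scoring
placements (the common variant-normalization convention) — so per-position
deletion profiles are stable. Left-normalization is idempotent and never
changes the score; both properties are tested, and scores are checked
exactly against an independent quadratic-space DP oracle.

## Profiling and the editing call

For each reference position, coverage counts aligned reads whose reference
span contains the position and deletions counts those with a D operation
covering it; the absence rate is their ratio (0, flagged, at uncovered
positions). Only D operations count: substitution errors and insertions
never inflate the deletion signal. Insertions are retained in CIGARs but do
not contribute to any position.

The headline call is read-level, not position-level: a two-sided Fisher
exact test on (deleted, non-deleted) × (treated, control), detected when
p < alpha (default 0.01) and the treated fraction exceeds the control's.
The claim being tested is about read fractions, so the read is the sampling
unit; per-position binomial tests are exposed
(`position_binomial_tests()`) for exploration but make no call. The package
deliberately does **not** correct the edited-read fraction for dropout —
the method is a detector, not a quantifier, and the estimate is documented
as a lower bound.

## Migration genetics statistics

AQR and PQR positions are scored at five positions along the
anterior-posterior axis (1 = normal AQR, 5 = normal PQR). Every test
collapses the four non-scored positions into "elsewhere", exactly as the
published footnotes specify single-position comparisons.

The Fisher test is two-sided by the **minimum-likelihood convention** (sum
of hypergeometric probabilities ≤ the observed table's, with the usual
1+1e-7 relative tolerance). Three of the four printed exact p-values
(0.051, 0.010, 0.065) and the printed synergy p (0.003) reproduce under
this convention at printed precision; the doubling convention is computed as
a documented fallback in `reproduce_tables()` and reported alongside, never
silently switched. One printed value (0.023) reproduces under neither
convention from its printed tallies (both give 0.0092, which is *more*
significant); `reproduce_tables()` reports that discrepancy as a failing row
by design.

For synergy, the additive expectation `pA = p1 + p2 − p1·p2` (equivalently
`1 − (1−p1)(1−p2)`: independent single-mutant effects) is converted to
expected counts by rounding `pA·n` to the nearest integer — Fisher needs
integer counts and nearest-integer rounding is the minimal-assumption
discretization — and the observed double-mutant counts are Fisher-tested
against them.

```{r synergy}
lq61 <- position_tally("etr-1(lq61)", "AQR", c(85, 12, 2, 0, 1))
cwn2 <- position_tally("cwn-2(ok895)", "AQR", c(91, 9, 0, 0, 0))
dbl  <- position_tally("etr-1(lq61); cwn-2(ok895)", "AQR",
                       c(56, 35, 7, 0, 2))
res <- synergy_test(lq61, cwn2, dbl)
c(pA = res$pA, p = signif(res$p_value, 1))
```

Fixture note: four published table rows have position counts that do not sum
to the printed n = 100 (they sum to 99, 99, 108 and 110). The fixtures
transcribe the counts verbatim and set n to the actual sum so the tally
invariant holds; none of these rows feeds a printed exact p-value, and the
affected printed bounds still hold by wide margins.

## Numerical and degenerate-input choices

* Fisher with a zero row or column margin returns p = 1 with a `degenerate`
  flag rather than erroring.
* An empty aligned set makes `edited_read_fraction()` an explicit
  undefined-fraction error; total amplification dropout is an explicit
  empty-library error — both signal real biological situations, not bugs.
* A flat treated-minus-control difference profile flags its peak as
  degenerate instead of reporting an arbitrary argmax; ties break to the
  smallest coordinate.
* `N` bases never match (scored as mismatch), and invalid alphabets error
  with the offending position.
* Identical seeds produce byte-identical FASTQ; the design stage consumes no
  randomness, so changing the seed changes reads but never the design.

## Known limitations

* The deletion spectrum is a modelling choice, not an inferred NHEJ profile.
* The aligner is amplicon-local; reads from elsewhere in a real genome would
  be forced onto the amplicon or dropped by the score threshold.
* The editing call's null uses a matched unedited control; without one, the
  method makes no claim.
* SAM text only (no BAM); qualities are carried, not used.
* The ≤4% deleted-read fraction observed on the real SRA data (project
  SRP257957) is not reproduced offline; `sra_fraction_check()` runs the
  identical machinery on user-downloaded FASTQ, and the packaged simulations
  cover the property (read fraction strictly below cell fraction under
  dropout) that the observation exemplifies.
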