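# crisprseq

Amplicon deep-sequencing analysis for detecting **rare, cell-specific
CRISPR/Cas9 genome edits in mosaic animals**, plus the Q-neuroblast
migration genetics statistics used to phenotype the same strains.

When Cas9 is expressed from a tissue-specific promoter, only a fraction *f*
of cells (e.g. ~10% body-wall muscle in a *C. elegans* larva) can carry an
edit — below the resolution of the T7E1 heteroduplex assay. The approach
implemented here instead sequences a short amplicon around the sgRNA site to
≥100,000 reads, aligns the reads, and tests whether reads with deleted bases
near the PAM-proximal cut site are enriched over a matched unedited control.
Crucially, the observed deleted-read fraction *underestimates* *f*: alleles
whose deletions remove a primer binding site are never amplified
(amplification dropout), and very large deletions may fail to align — the
method is a detector, not a quantifier.

The package provides:

* **Library design** — two-step PCR model (gene-specific tailed PCR1
  primers, indexed Illumina PCR2 primers) with strict in-silico PCR. The
  bundled published primer table plus default Illumina constants reproduce
  the expected **301-bp** library molecule for the etr-1 exon 8 design.
* **Mosaic simulation** — truth-labelled FASTQ read sets from a population
  in which a fraction of cells carry cut-site-anchored deletions
  (truncated-geometric lengths), with primer-site dropout, adapter
  read-through, and substitution errors. Byte-identical output for a fixed
  seed.
* **Alignment** — a semi-global affine-gap aligner (read fully consumed,
  free reference end gaps), deterministic tie-breaking, left-normalized
  indels, `=`/`X`/`I`/`D` CIGARs, SAM text output.
* **Edit profiling and calling** — per-position coverage / deletion counts
  ("absence rate"), treated-vs-control comparison, and a read-level
  two-sided Fisher exact detection call.
* **Migration statistics** — five-position AQR/PQR tallies (position 1 =
  normal AQR, position 5 = normal PQR), a minimum-likelihood two-sided
  Fisher exact test, the additive expectation `p(A) = p1 + p2 − p1·p2` for
  double-mutant synergy, and `reproduce_tables()`, which recomputes every
  footnoted published comparison beside its printed value or bound.

Coordinates are **0-based, half-open** throughout.

## Worked example

```r
library(crisprseq)

primers <- read_primer_table(system.file("extdata", "table1_primers.tsv",
                                         package = "crisprseq"))
design <- library_design(synthetic_target(),
                         primers[["etr-1PCR1F"]], primers[["etr-1PCR1R"]])
design
#> Amplicon library design: etr-1_exon8_synthetic
#>   amplicon: 415 - 585 (170 bp)
#>   PCR1 molecule: 236 bp; PCR2 molecule: 301 bp
#>   cut site at reference position 459
```

The 170-bp amplicon sits in a synthetic 1-kb reference (the real intervening
sequence and protospacer are not available in machine-readable form; the
published primer sequences are). The PCR2 molecule length matches the
expected 301 bp.

Simulate a 10%-edited mosaic sample and a matched unedited control, align,
and call:

```r
pop <- simulate_population(design, edit_model(edited_cell_fraction = 0.10),
                           n_alleles = 2000, seed = 7)
treated <- simulate_reads(pop, read_sim_params(n_reads = 20000, seed = 8))
control <- simulate_reads(
  simulate_population(design, edit_model(0), 2000, seed = 9),
  read_sim_params(n_reads = 20000, seed = 10))

call_editing(align_set(treated, design), align_set(control, design))
#> Edit call: EDITING DETECTED (p = 2.23e-308, alpha = 0.01)
#>   treated deleted-read fraction: 0.0828 (1537 / 18564)
#>   control deleted-read fraction: 0.0000 (0 / 18761)
#>   peak difference at position 44
```

Although 10% of cells are edited, only 8.3% of aligned reads show a
deletion — dropout and alignment losses at work — yet detection against the
control is unambiguous. The peak difference falls at amplicon position 44,
the cut site (reference 459 − amplicon start 415).

Reproduce the published genetics comparisons:

```r
rep <- reproduce_tables()
rep[rep$genotype == "etr-1(lq61); cwn-2(ok895)",
    c("neuron", "computed_p", "printed_p", "pass")]
#>    neuron  computed_p printed_p pass
#> 30    AQR 0.002599549     0.003 TRUE
```

The etr-1;cwn-2 double mutant shows significantly more AQR migration failure
than the additive expectation of the single mutants — genetic synergy,
p = 0.003 at printed precision. Across all three tables, 31 of 32
comparisons reproduce; the one failure is the 0.023 discrepancy above,
reported with both two-sided conventions rather than hidden.

## Command line

```sh
crisprseq design   --target etr-1 --out design.json
crisprseq simulate --edit-fraction 0.10 --n-reads 100000 --seed 7 \
                   --out sample.fastq --truth truth.tsv
crisprseq align    --reads sample.fastq --ref amplicon.fa --out sample.sam
crisprseq profile  --sam sample.sam --out profile.tsv
crisprseq call     --sam-treated t.sam --sam-control c.sam
crisprseq interact --out report.tsv
crisprseq run      --out-dir out --seed 1     # full pipeline + plot
```

`run` executes design → simulate (treated + control) → align → profile →
call and writes `design.json`, FASTQs, truth table, SAMs, profile TSVs,
`edit_call.json`, and a two-sample deletion plot (`profiles.pdf`).

## Real data

FASTQ for the original etr-1 and mab-5 experiments is in SRA project
**SRP257957**. The package does not download data;
`sra_fraction_check(fastq, design)` runs trimming, alignment, and
deleted-read-fraction measurement on a locally downloaded run and checks it
against the ≤4% ceiling observed for mosaic muscle samples.

## Notes

* SAM text only (no BAM); single-end read-1 geometry; qualities carried but
  unused.
* See `vignettes/crisprseq-methods.Rmd` for the models, defaults and their
  rationale, numerical conventions, and known limitations.
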