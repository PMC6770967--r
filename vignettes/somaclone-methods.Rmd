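---
title: "Analysing genome alterations in long-term plant cell cultures"
author: "somaclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing genome alterations in long-term plant cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaclone)
```

## The problem

A plant suspension culture that has divided asexually for decades is no
longer the diploid genome it started from.  Without meiosis there is no
recombination and no purifying segregation: spontaneous mutations accumulate
along a single somatic lineage (Muller's Ratchet), whole chromosomal blocks
are duplicated or lost, and the genome becomes a patchwork of regions
present in zero, one, two, three or more copies.  Short-read sequencing of
such a culture against the progenitor reference shows this directly:

* sequencing depth is quantised at multiples of a **per-copy depth unit**
  `c` (≈50× in the motivating data set); a region at `1·c` is *hemizygous*
  (one copy left), at `3·c` triploid, and so on;
* long runs of **zero coverage** are complete deletions;
* at a variant site, the **allele depth** (AD) fraction of the alternative
  allele sits near `m/k` when the mutation arose on `m` of the local `k`
  haplophase copies — almost always `m = 1`, because a mutation occurs once
  in one allele and is inherited by all daughter cells.  Sites where only
  one allele remains visible ("homozygous") are mostly an artefact of
  hemizygosity; sites with several supported alleles have **deviating
  frequencies**, the culture analogue of heterozygosity;
* transcript abundance at a variant follows allele copy number, so a
  disrupted allele present on 1 of 3 copies contributes roughly a third of
  the RNA reads — distinguishing a copy-number explanation from
  transcript-degradation pathways such as nonsense-mediated decay.

`somaclone` implements this analysis as a reusable, fully tested pipeline,
plus a truth-labelled synthetic genome generator so every stage can be
verified without the original sequencing data.

## The model behind the synthetic generator

The generator states a world with exactly the structure the analysis
assumes:

* **Genome** — random nucleotide sequence (≈36% GC, the nuclear composition
  of *Arabidopsis*-like genomes) carrying non-overlapping single-exon genes;
  every CDS is a multiple of 3 long, starts with ATG and ends with a stop
  codon, strand-aware.  Two small replicons labelled `plastome` and
  `chondrome` stand in for the organelles.
* **Copy map** — each chromosome is partitioned into segments with integer
  copy number `k ∈ {0, 1, 2, 3, 5}` (weights 0.02/0.15/0.13/0.50/0.20:
  predominantly triploid with hemizygous and pentaploid blocks and rare
  complete deletions, the karyotype the analysis was built for).
* **Depth** — each base in a `k`-copy segment draws `Poisson(k·c)` depth
  (negative binomial optional), `c = 50` by default.  Organelle depth uses
  multipliers of `c` (defaults 4× plastome, 40× chondrome, i.e. the
  ~10-fold elevated chondrome:plastome ratio of cultured cells).
* **Variants** — SNVs and 1–30 bp InDels (geometric length law, mean 3) at
  5×10⁻⁴ per base each, matching the observed ≈1 variant/kb split roughly
  evenly between SNVs and InDels.  The default carrier rule plants each
  variant on exactly **one** copy; the true alternative-allele fraction in a
  `k`-copy segment is therefore `1/k`.  No variant is planted in `k = 0`
  segments.  The carrier distribution of the real culture is unknown; the
  single-carrier default is an assumption, configurable via `carrier_rule`.
* **Observed calls** — at each truth site the VCF depth DP is read from the
  simulated track and the alternative AD drawn `Binomial(DP, carriers/k)`,
  so AD always sums to DP.
* **RNA** — per expressed variant site, a `Poisson(300)` read total split
  binomially at the copy share `carriers/k`: copy-proportional expression
  with **no** decay term.

What the generator does *not* emulate: read-level artefacts (mapping
ambiguity, duplicates, sequencing error), repeat-driven collapsed regions,
InDel effects on the depth track (large deletions are modelled as `k = 0`
segments instead), or any transcript-degradation mechanism.  A green test on
synthetic data therefore establishes that the *statistical logic* of each
stage is correct under the stated model — not that the thresholds are
optimal for any particular real library.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `c` | 50 reads/base | per-copy depth unit; all copy calls are relative to it |
| `r_min` | 5 reads | minimum reads supporting a non-dominant allele (inclusive) |
| `f_min` | 0.05 | minimum supporting fraction of DP (inclusive) |
| `flank` | 2000 bp | half-width of the coverage-deviation window |
| `max_dev` | 0.20 | maximum relative depth deviation (strict: exactly 20% passes) |
| `L_min` | 100 bp | zero-coverage regions must be strictly longer than this |
| `block_size` | 100 kb | variant-density block |
| `tau` | 0.20 | flanking-gene similarity tolerance |
| `k_max` | 8 | copy-number clamp (extreme depths pooled) |

The inclusive/strict conventions follow the wording of the thresholds
("at least 5 reads and at least 5%" → `≥`; "deviates … by more than 20%" and
"regions larger than 100 bp" → `>`).  `tau` has no stated value in the
source analysis; 0.20 reuses the only stated relative-coverage tolerance.

## Numerical and design choices

**Coordinates.** Internally everything is 1-based closed — the
IRanges/GenomicRanges convention that backs the interval arithmetic.
Emitted files follow each format's own standard: GFF3 and VCF 1-based,
BED and bedGraph 0-based half-open.

**Ploidy baseline.** The per-copy unit is estimated from the per-gene mean
depth distribution (arithmetic mean over the full gene span), smoothed with
a kernel density (default bandwidth `median(depth)/20`, about a tenth of a
first-pass unit guess for a 2–3 copy genome).  The unit is the location of
the first non-zero peak, refined to the median of the depths below the first
valley; valleys between peaks act as copy-class boundaries.  A histogram
with a single detectable peak returns the unit with a `low_confidence` flag
— note that when *no* hemizygous class exists the first peak sits at a
multiple of the true unit and copy calls are relatively, not absolutely,
correct.  Gene copy number is `round(depth / c)` clamped to `[0, k_max]`.

**Flanking similarity.** A gene is "similar to flanking" when its mean depth
is within `tau` of *at least one* neighbouring gene's depth.  Requiring
closeness to the neighbour mean would also flag both neighbours of every
isolated CNV gene (three flags per event); the one-sided rule flags exactly
the deviating gene, which matches the intent of measuring how much of the
genome changes in blocks rather than gene-by-gene.

**Zygosity.** The dominant allele is the AD maximum; a dominance tie is
classified deviating if the tied depth passes the thresholds (two equally
supported co-existing alleles is the clearest deviating case) and ties are
counted.  Multi-allelic records are deviating if *any* non-dominant allele
passes.  The coverage-deviation filter uses the depth track (not VCF DP) for
the flank mean, excludes the variant base, clips windows at chromosome ends,
and runs *before* classification; both deviating-frequency denominators
(pre- and post-filter) appear in the run report because the source analysis
does not state which it used.

**Effect annotation.** One transcript per gene, CDS-only: SNVs are
translated in codon context under the standard genetic code (stop
introduced → `stop_gain`; amino-acid change → `missense`; else
`synonymous`); CDS-overlapping InDels are `frameshift` when the length is
not a multiple of 3, else `inframe_indel`; `high` impact is exactly
{stop_gain, frameshift}.  Start-loss and stop-loss map to `missense` — a
documented simplification relative to full annotators, whose exact rule set
the analysis this emulates did not specify.  Insertions belong to the CDS
compartment when their anchor base does (an insertion has no reference
footprint, so a convention is required); deletions when any deleted base
does.  CDS compartment length is the union of CDS intervals.

**Frame enrichment.** A pooled two-proportion z-test without continuity
correction compares the divisible-by-3 fraction of InDels inside vs outside
CDS, falling back to Fisher's exact test when any expected cell is below 5.
The uncorrected z keeps the type-I error at the nominal level (the
continuity-corrected version is conservative), which the acceptance suite
verifies against the [0.03, 0.07] band at α = 0.05.

**Mann–Whitney U.** Self-contained: midrank ties, exact enumeration of all
`choose(n1+n2, n1)` labelings up to `max(n1, n2) ≤ 10`, otherwise normal
approximation with tie correction and 0.5 continuity correction.  Two-sided
p doubles the smaller tail, capped at 1.  A p-value that underflows is
floored at 1e-300 and never reported as a literal 0 — an "exact zero" from
the approximate tail is a representation limit, not a probability.

**Determinism.** Every stochastic function takes an explicit seed and
restores the caller's RNG state; the pipeline derives per-stage sub-seeds
(all < 2³¹) from the master seed, so a rerun with the same configuration
reproduces every output file byte-identically (no timestamps are written).

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(outdir = tempfile(), seed = 1,
                  chrom_lengths = c(chr1 = 6e5, chr2 = 4e5), n_genes = 80)
report <- run_pipeline(cfg)
report$stats$baseline_c          # estimated per-copy unit
report$counts$gene_copy_classes  # genes per copy class
report$stats$ase_rna_p           # RNA ref-vs-alt contrast
```

## Known limitations

* Copy calls are only absolutely calibrated when a hemizygous (or otherwise
  lowest-copy) class is present; a pure-triploid genome yields a unit of
  `3c` and relative calls.
* The effect model ignores splicing, UTRs, start-loss and multi-transcript
  genes; high-impact counts are comparable to full annotators only at the
  stop-gain/frameshift core.
* The zygosity thresholds are taken as given; no attempt is made to model
  caller-specific AD biases, and absolute depths are used without
  duplicate-read correction.
* The ASE contrast treats sites as independent; linked variants in one gene
  are counted once each.
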