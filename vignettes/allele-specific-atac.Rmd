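---
title: "Quantifying allele-specific chromatin accessibility at a CRISPR-edited regulatory variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific chromatin accessibility at a CRISPR-edited regulatory variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacAllele)
```

## The problem

A single-nucleotide variant (rs182722517, G>A at chr19:50739310, GRCh38)
sits inside an ENCODE candidate cis-regulatory element
(chr19:50739241-50739456) downstream of the Osteolectin gene and is
associated with reduced height and plasma Osteolectin. A direct way to ask
whether the variant itself changes regulatory activity is to engineer it
into human bone marrow stromal cells by CRISPR/Cas9 homology-directed
repair and measure chromatin accessibility of each allele by ATAC-seq.

The engineering introduces a second, silent edit: a C>G substitution at
chr19:50739290 that destroys the protospacer-adjacent motif (PAM) so Cas9
cannot re-cut a repaired allele. This PAM-blocking mutation doubles as a
sequence tag: in a heterozygous clone, reads from the edited allele carry
the PAM edit while reads from the unedited allele do not. Because both
alleles live in the same nucleus, the edited-to-total read ratio within a
clone is an internally controlled measure of allele-specific
accessibility: het **control** clones (PAM edit only) should sit near 0.5,
and a het **variant** clone (PAM edit + variant) falls below its control
counterpart if the variant closes chromatin.

This package implements that analysis end to end — dual-locus read
classification, per-clone allelic ratios, and the group comparison —
together with a seeded read simulator that provides ground truth, and an
auditable implementation of the test-selection procedure used for the
phenotype comparisons.

## Read classification

Only reads spanning *both* tagged positions are informative. With the
default `edit_scheme()` the rules are, for the base pair observed at
(PAM site, variant site):

| PAM (50739290) | variant (50739310) | call |
|---|---|---|
| C | G | wild-type allele read |
| G | G | control-edited allele read |
| G | A | variant allele read |
| C | A | uninformative (`variant_without_pam`) |
| anything else | | uninformative (`unexpected_base`) |

The (C, A) combination cannot descend from either donor template — it can
only arise from sequencing error or an aberrant repair — and the published
totals are defined as wild-type plus edited reads, so it is tracked
separately rather than counted. Reads that do not span both sites, have a
deletion over a site, fall at or below the MAPQ threshold (strictly
greater than 10 is kept, matching the published filter), or carry a
low-quality base at an interrogated position are tallied per reason.

Two choices deserve comment because the original description leaves them
open:

* **Counting unit.** The published wording counts *reads*; with 75 bp
  reads and the two sites 20 bp apart, a single mate frequently spans
  both. The default therefore counts each mate independently
  (`unit = "read"`). Because the protocol is paired-end, a fragment-level
  mode is provided (`unit = "fragment"`): concordant mate calls count
  once, discordant informative mates are demoted to
  `unexpected_base`, and a fragment with one informative mate takes that
  mate's call.
* **Base quality.** No base-quality rule is stated in the source
  procedure. `min_base_quality = 20` at the two interrogated positions is
  the default — standard practice for single-base genotyping from reads —
  and setting it to 0 reproduces the literal rule.

## Allelic ratio and group comparison

For a heterozygous clone with `n_wt` wild-type and `n_mut` edited-allele
reads, the ratio is `n_mut / (n_wt + n_mut)` with a Clopper–Pearson 95%
interval (exact binomial inversion; chosen over Wald intervals for its
coverage at boundary counts). The count in the *other* edited category is
reported as a contamination diagnostic. Homozygous clones have no
informative within-clone ratio and are excluded from the imbalance
comparison by default.

The clone — not the read — is the unit of replication: with three
independently targeted clones per genotype, `compare_allelic_ratios()`
runs a two-sided Student's t test on the per-clone ratios, mirroring the
published comparison. The full decision engine can be substituted with
`use_stats_policy = TRUE`.

Under the simulator's sampling model, an edited haplotype with
accessibility weight $w$ relative to the wild-type haplotype yields an
expected edited-read fraction of $w/(1+w)$; this closed form is the oracle
used throughout the tests.

## The read simulator

`simulate_clone_reads()` emits already-aligned SAM records rather than raw
FASTQ: trimming and alignment are off-the-shelf stages, and bypassing them
isolates the bespoke counting logic while keeping every downstream stage
testable without any external data. The generator models:

* **Reference window.** The printed 121-nt control donor oligo, with its
  PAM base reverted to the reference C, embedded between seeded-random
  flanks (default 200 bp each side). This anchors C at chr19:50739290 and
  the major allele G at chr19:50739310.
* **Haplotype sampling.** Each fragment is drawn from one of the clone's
  two haplotypes with probability proportional to its accessibility
  weight; the per-fragment haplotype labels are returned as ground truth.
* **Positions.** Fragment midpoints are Gaussian around the element's
  midpoint (default centre 50739348, SD 60 bp), truncated to the window;
  no positional model is given in the source, and a uniform alternative is
  available. Fragment lengths are Normal(180, 35) bp, resampled when a
  fragment would be shorter than the 75 bp read length or overflow the
  window (the resample count is reported).
* **Errors and qualities.** Substitution-only errors, i.i.d. per base at
  `error_rate`; indels are not simulated by default, but the classifier
  handles deletions defensively. Base qualities are constant Phred 37
  except at injected errors (Phred 11), so base-quality filtering is
  exercisable. A configurable fraction of reads receives MAPQ ≤ 10 to
  exercise the mapping-quality gate.
* **Determinism.** All randomness flows from one seeded generator;
  pipeline runs derive per-clone seeds from the master seed by fixed
  offsets, and identical configurations give byte-identical output.

What the simulator does *not* emulate — Tn5 insertion bias, PCR
duplicates, GC bias, multi-peak genomes, alignment artefacts — bounds what
passing tests show about real data: they validate the counting, estimation
and decision logic under the stated sampling model, not robustness to
library-preparation pathologies.

## The statistical decision engine

The phenotype comparisons in the source follow a fixed procedure, which
`select_and_run()` reproduces as a pure function of the data and declared
design, returning a complete audit trace:

1. **Normality gate**, per group: Shapiro–Wilk for 3 ≤ n < 20,
   D'Agostino omnibus for n ≥ 20. The omnibus K² statistic (transformed
   skewness plus transformed kurtosis, χ² with 2 df) is implemented in the
   package and verified against an independent reference implementation.
   Normality passes only if *every* group passes.
2. **Variance gate**: variance-ratio F test for two groups, Levene's test
   with median centring for more.
3. **log2 fallback**: if either gate fails and all values are positive,
   the data are transformed and re-gated; parametric tests run on the
   transformed scale only when both gates then pass. Nonpositive data skip
   the transform, with the reason recorded.
4. **Test selection**: Student's/paired t (two groups), nested t
   (replicates within subjects), one-way or two-way ANOVA when both gates
   pass; Welch's t when data (raw or transformed) are normal but unequally
   variable; Mann–Whitney when normality fails on both scales. For more
   than two non-normal groups the source names no test; Kruskal–Wallis is
   used as the standard analogue. There is likewise no standard
   nonparametric two-factor ANOVA; the engine falls back to the parametric
   fit and says so in the trace.
5. **Multiplicity**: Šidák (`1-(1-p)^m`), Holm–Šidák (step-down with
   monotonicity enforcement), and Dunnett many-to-one adjustment. Dunnett
   quantiles come from seeded Monte-Carlo of the equicorrelated
   multivariate t (10⁵ draws by default; Monte-Carlo SE ≈ 0.0007 at
   p ≈ 0.05) rather than numerical integration, keeping the adjustment
   dependency-free and reproducible.

The gate α is fixed at 0.05 — the source says "significantly deviated"
without a number — and is configurable. The nested t is computed as
sign(Δ)·√F from the nested ANOVA, F = MS(group)/MS(subject within group)
on (subjects − 2) df; with zero within-subject variance it collapses
exactly to Student's t on subject means, which the tests assert.

## A worked run

```{r, eval = FALSE}
cfg <- demo_config(seed = 1)        # 3 het-control + 3 het-variant clones,
                                    # variant accessibility weight 0.6
res <- run_pipeline(cfg, "demo_out")
res$comparison
```

With the default 20,000 fragments per clone this reports het-control mean
ratio ≈ 0.50, het-variant mean ratio ≈ 0.375 (the closed form
0.6/1.6 = 0.375), and a Student's t p-value far below 0.05 with direction
`het_variant < het_control` — the qualitative finding the analysis is
designed to detect.

## Problem sizes and numerical choices

The calibration checks use sizes chosen to give tight Monte-Carlo error
while remaining comfortable on a laptop: 2,000 replicates at reduced read
depth (300 fragments/clone) for null calibration of the clone-level test,
200 replicates at full depth (22,000 fragments/clone, ≈10⁴ informative
reads) for power, 50 replicates per weight for estimator recovery, and
2,000 replicates for the engine's type-I rate. Binomial/empirical standard
errors set the test tolerances; no tolerance is tuned to an observed
outcome.

Degenerate inputs are handled explicitly: zero informative reads is an
error (the ratio is undefined), zero-variance groups abort the variance
gate, identical comparison groups return t = 0 and p = 1 rather than a
division error, and amplicons not covering both edit positions are
rejected.

## Known limitations

* The simulator's fragment model is single-peak and bias-free; estimates
  of power on real libraries will be optimistic.
* Fragment-mode counting resolves mate discordance conservatively rather
  than by base quality.
* Sanger het calls use IUPAC ambiguity codes as a proxy for double peaks;
  chromatogram parsing is out of scope.
* No beta-binomial overdispersion across clones is modelled; with three
  clones per group the t test on ratios is the intended analysis.
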