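---
title: "Cross-platform consensus filtering of strain-distinguishing variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform consensus filtering of strain-distinguishing variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofilter)
```

## Motivation and model

Two nearly isogenic inbred lines differ at a small number of genomic
positions, but a joint call set from whole-genome sequencing contains
millions of candidate records, almost all of which are either shared
differences to the reference genome or platform artifacts. Sequencing
each strain on three platforms (Illumina short-read, IonTorrent, 10X
Chromium linked-read) makes the artifact structure *identifiable*:
a real strain difference should be called consistently by independent
chemistries in one strain and be homozygous-reference in the other,
while artifacts tend to be platform-specific.

The unit of analysis is one VCF site with six per-sample calls — strain
$s \in \{\mathrm{WLI}, \mathrm{WMI}\}$ by platform $p$ — each a genotype
$g(s,p)$ with Phred-scaled genotype quality ($GQ$), read depth ($DP$)
and per-allele read counts ($AD$). We define per strain:

* the **best call** $\hat g(s)$: the genotype of the maximum-$GQ$
  non-missing call, ties broken by the fixed platform priority
  Illumina > linked-read > IonTorrent (the priority only matters on
  exact $GQ$ ties and makes the pipeline deterministic);
* **concordance**: all three platform calls non-missing and identical;
* **dispute at Q30**: another platform of the same strain makes a
  different non-missing call with $GQ \ge 30$.

"Phred quality of a call" is the per-sample `FORMAT/GQ`, not the
site-level `QUAL`: the cascade compares qualities *between samples of
one strain* (for example "un-opposed by any other sample"), which only a
per-sample quantity supports. Genotypes are compared allele-resolved, so
at a multiallelic site `1/1` and `2/2` are different calls. Any genotype
containing a missing allele (`./.`, `./1`) is treated as missing. Depth
falls back to `sum(AD)` when `DP` is absent, and to 0 when both are.

## The cascade

`run_pipeline()` applies ten steps in a fixed order; each is also
exported as a `step_*()` function returning `list(kept, removed)`:

| # | step | removes when | default thresholds |
|---|------|--------------|--------------------|
| 1 | `depth` | $\sum_{s,p} DP < 10$ or any single $DP > 300$ | 10 / 300 |
| 2 | `equal_best` | $\hat g(\mathrm{WLI}) = \hat g(\mathrm{WMI})$, both non-missing | — |
| 3 | *(flag)* concordance | never removes; marks the "stored" side channel | — |
| 4 | `uncertain` | $\ge 5$ of 6 genotypes missing | 5 |
| 5 | `equal_best` (re-applied) | as step 2 | — |
| 6 | `low_quality_discordant` | 5 identical calls + 1 different with $GQ < 10$ | 10 |
| 7 | `allele_balance` | one allele > 90% of pooled $AD$ and each strain ≥ 25% of reads | 0.90 / 0.25 |
| 8 | `cross_platform_dispute` | carrying strain disputed at $GQ \ge 30$ | 30 |
| 9 | `require_difference` + `quality_tier` | no reference-anchored difference, or carrier lacks a $GQ \ge 30$ call, or any conflicting call at $GQ \ge 10$ | 30 / 10 |
| 10 | `homopolymer_deletions` | carried deletion inside a homopolymer run with < 2 supporting platforms | run ≥ 2, platforms ≥ 2 |

All thresholds live in `filter_config()` and can be overridden
individually.

Several design points were genuinely open and are resolved as follows:

* **The duplicated equal-best step.** The cascade description lists the
  equal-best-call removal twice (positions 2 and 5). We apply it at
  both positions as listed and note that the second application is
  idempotent in practice: it can only remove records whose best call
  changed between the two applications, and no intermediate step
  rewrites calls, so its count is 0 on all generated data. Keeping it
  makes the flowchart shape stable against future steps that *do*
  rewrite calls.
* **The allele-balance denominator.** "All reads" is read as the pooled
  allele-supporting reads ($AD$) over the six samples, not raw `DP`:
  the filter asks whether one allele dominates the *evidence* and both
  strains contribute to it, which is an $AD$ property. Sites with no
  $AD$ at all are never removed here — insufficient evidence is the
  depth step's job.
* **Dispute before carrier assignment.** Step 8 runs before the
  carrier strain is formally assigned (step 9). The disputed strain is
  therefore any strain whose best call is non-missing and
  non-reference — the strain carrying the putative difference — which
  coincides with the carrier whenever one is later assigned.
* **Opposition vs evidence.** In the final quality tier, the opposite
  strain's homozygous-reference calls are *required* evidence for a
  strain difference; treating them as opposition would remove every
  true difference. Hom-ref calls within the carrier strain, however,
  do count as opposition.
* **The cross-technology side set.** Records whose carrier strain is
  supported by all three platforms at $GQ \ge 10$ but by none at
  $GQ \ge 30$ are verified across technologies, yet qualities cannot
  simply be summed; they are reported separately (`$cross_tech`) and
  excluded from the finals.
* **Chromosome Y** passes through the cascade normally; excluding it is
  a plotting/reporting choice (the `exclude` argument of
  `bin_density()`), not a filter.

Homopolymer context is evaluated on the *reference* sequence: a VCF
deletion (ALT a prefix of REF, anchored one base left of the deleted
interval) is homopolymeric when every deleted base lies in a run of at
least two identical bases within the deleted interval plus one flanking
base on each side. Runs of length two already count — the
platform-specific error mode appears as soon as a base is duplicated.

## Downstream summaries

`classify_variant()` partitions REF/ALT pairs into transition SNPs
(A↔G, C↔T), transversion SNPs, insertions, deletions, and `other`
(equal-length multi-base substitutions, which are reported rather than
silently dropped). Multiallelic finalists are classified by the allele
the carrier strain actually called, so each final variant has exactly
one class. Fractions are rounded half-up to one decimal so that
reported percentages sum to 100 ± 0.1.

`bin_density()` uses half-open bins (a variant on a bin boundary
belongs to the right-hand bin) and an optional centred moving average;
the default smoothing window of 5 bins is a presentation choice, not a
statistical one, and is configurable. `find_clusters()` slides a
1 kb window (configurable) and merges overlapping hits, reporting the
maximum single-window count per region — it agrees with a quadratic
brute-force scan by construction and by test.

`parse_ann()` expands SnpEff `ANN` entries. Compound '&'-joined effects
keep their full string for impact reports (`extract_high_moderate()`,
which keeps one highest-impact annotation per variant) while the
first-listed term is the primary category for `tabulate_effects()`.
Tabulation counts unique (variant, primary category) assignments per
strain, which is why column totals legitimately exceed the number of
unique finalists. Upstream/downstream proximity is taken from the
annotator's own classification (5 kb upstream in the reference
workflow) and never recomputed from coordinates.

`confirm_targets()` scores targeted re-sequencing of 4 + 4 individual
rats: a target is confirmed when at least three target-strain rats are
homozygous-alternative and no opposite-strain rat is. Missing genotypes
count toward neither criterion — a missing opposite-strain call is not
evidence of presence — and heterozygous target-strain calls count
against criterion 1 only. The positive rate is confirmed / amplified;
targets without PCR product never enter the denominator.

## The synthetic-data generator

No deposited raw call set accompanies the study design this package
targets, so `generate_reference()` / `plant_variants()` produce the
full input contract from a seed. The generator emulates, per planted
class, the observed failure modes of a real joint call set:

* `TRUE_DIFF_HOM` / `TRUE_DIFF_HET` — clean strain differences:
  carrier concordant across platforms with at least one $GQ \ge 31$
  call, opposite strain hom-ref at $GQ \ge 12$;
* `SHARED_VARIANT` — both strains hom-alt (reference-discordant
  background);
* `COLLAPSED_PSEUDO_HET` — heterozygous calls in both strains at
  roughly two-fold depth, the signature of collapsed duplications in
  the reference;
* `HOMOPOLYMER_ARTIFACT` — a deletion inside a homopolymer run called
  by a single platform (IonTorrent by default);
* `LOW_DEPTH` / `HIGH_DEPTH` / `UNCERTAIN_CALLS` /
  `LOW_Q_DISCORDANT` — the corresponding single-step failure modes.

Depths are Poisson draws around the per-platform coverage means 43 / 27
/ 41 (Illumina / linked-read / IonTorrent), truncated to [5, 250] so a
draw can never accidentally cross the depth bounds; class-defining
constraints (a lone call clearing the total-depth gate, a single-sample
depth above 300) are enforced after the draw rather than merely
expected. Genotype-quality distributions per platform are not published
for this design, so they are stylized uniform draws on the ranges the
classes require; this is documented as a modelling choice. Plants keep
at least 10 bp spacing so one plant's homopolymer context cannot
perturb another's, which is what makes every record's expected fate
derivable by construction. Each generator call uses a single seeded RNG
stream and restores the caller's RNG state.

What the generator does *not* emulate: mapping artifacts beyond the
collapsed-region depth signature, correlated errors between platforms,
indel length distributions of real chemistry, or linkage between
neighbouring variants. Passing the planted-fate suite therefore shows
the cascade implements its specification exactly; it does not by itself
certify performance on real data, whose artifact mix is messier.

## Numerical choices and problem sizes

* Quality-tier boundaries are inclusive ($GQ \ge 30$, opposition at
  $GQ \ge 10$); depth bounds are exclusive on both sides (total < 10
  removed, single > 300 removed) — both match the boundary examples in
  the test suite.
* A non-missing call with absent $GQ$ ranks at quality 0: it can still
  be a best call when nothing else calls the site, but can never pass a
  quality gate.
* Fraction rounding is half-up (`round_half_up()`), not banker's.
* The test and acceptance suites run the full cascade on 1,000 planted
  variants over a 300 kb reference (about 15 s), and each brute-force
  oracle comparison uses at least 500 random instances; these sizes
  exercise every class and keep the suite quick on one CPU.

## Limitations

* The cascade is a hard-filter design: no genotype refinement,
  recalibration or phasing, and structural variants are out of scope.
* Interpretation choices (per-sample $GQ$ rather than site `QUAL`; the
  pooled-$AD$ denominator; assignment-counting in the effect table) are
  documented above and in the function help; alternative readings would
  change counts at the margins.
* The validation scorer starts from called genotypes of the 8-rat
  panel; amplicon alignment and genotype calling are upstream of this
  package.
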