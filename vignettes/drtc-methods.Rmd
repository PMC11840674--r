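---
title: "Methods: defining and tracking donor-reactive T-cell clones"
author: "alloTCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defining and tracking donor-reactive T-cell clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloTCR)
```

## Scope and data model

`alloTCR` starts from collapsed clonotype tables: one row per unique
TCRβ rearrangement with a template count, where a template is a sequenced
genomic-DNA molecule and therefore a cell-level quantity. Everything
upstream — sequencing chemistry, read-level error correction, V/J
annotation — is assumed done by the platform that produced the table.

Three conventions run through the whole package:

* **Clone identity is the nucleotide rearrangement string**, not the CDR3
  amino-acid sequence. DNA-level identity is the unit the sequencing
  platform tracks across samples of one subject, and it avoids collisions
  between convergent CDR3s encoded by different rearrangements. Amino
  acid and V/J annotations are carried as metadata only.
* **Non-productive rearrangements are parsed and retained but excluded**
  from totals, frequencies, tests and overlap indices. Productive
  template totals are the repertoire-size denominators everywhere.
  Whether out-of-frame rearrangements should contribute anywhere is
  genuinely open; the productive-only convention is the conservative
  choice and is applied uniformly so no metric mixes denominators.
* **Detection means at least one template.** Template counts are already
  molecule counts, so presence is not thresholded further. The same rule
  drives tracking tables, graft categorization, urine overlap and the
  breadth/depth metrics, keeping "detected" a single concept.

## The differential-abundance test

For a clone with counts $a$ (MLR-sorted sample, productive total $N_a$)
and $b$ (unstimulated sample, total $N_b$), the null hypothesis is that
the $n = a + b$ templates are distributed between the samples in
proportion to repertoire size: $a \sim \mathrm{Bin}(n, p_0)$ with
$p_0 = N_a / (N_a + N_b)$.

The two-sided p-value uses the **minimum-likelihood rule**: the sum of
$P(k \mid n, p_0)$ over all outcomes no more probable than the observed
one. This is the common exact-test convention, is symmetric under
swapping the two samples (swapping maps the DRTC class onto the
`enriched_unstim` class with identical p-values, a property the test
suite asserts), and reduces to doubling a single tail under a symmetric
null. Tail-doubling is available as `method = "doubling"` for users who
prefer the conservative convention; which convention the upstream
platform's own implementation uses is not documented, so exact agreement
with any particular external run is not claimed.

Numerical choices:

* Probability ties in the minimum-likelihood comparison use a relative
  tolerance of $1 + 10^{-7}$, the convention of R's own exact tests;
  it is configurable (`tieTolerance`).
* A clone with $n = 0$ is an error by contract — the caller must gate on
  the count floor first, and `callDRTC` does.
* p-values are floored at the smallest positive double so the result is
  always in $(0, 1]$.

Gates, in order:

1. **Count floor** (default 5): clones with $a + b < 5$ get the call
   `below_count_floor` and no p-value. The floor is applied *before*
   testing, so the Benjamini–Hochberg multiplicity $m$ counts only the
   tested clones.
2. **FDR** (default $\alpha = 0.01$ on the BH-adjusted p-value). BH is
   applied per pairwise comparison, never pooled across subjects or
   subsets: each subject's MLR-vs-unstimulated comparison is its own
   family, mirroring a per-subject analysis design.
3. **Fold change** (default 2): the MLR frequency must be at least
   2-fold the unstimulated frequency. A clone absent from the
   unstimulated sample satisfies the criterion by convention — no
   pseudocount. A pseudocount would silently move the 2-fold frontier
   for exactly the clones the assay is designed to find (those newly
   detectable after stimulation), so absence is treated as evidence of
   enrichment once the significance gate has been passed.

Clones significant in the opposite direction (unstimulated frequency at
least 2-fold the MLR frequency) are classed `enriched_unstim`; they can
never be DRTC, whatever their p-value.

## Overlap and DRTC metrics

The "Morisita index" is implemented as **Morisita–Horn** on template
frequencies,
$MH = 2\sum_i p_i q_i \,/\, (\sum_i p_i^2 + \sum_i q_i^2)$,
clamped to $[0,1]$. The classical Morisita index requires integer
dispersion terms and can exceed 1; the Morisita–Horn form is the
0–1-bounded variant that matches the "0 divergent, 1 identical" scoring
used in repertoire work. Jaccard is plain set overlap of productive
clone keys. The two indices degrade differently under subsampling —
abundance weighting keeps Morisita–Horn high between deep and shallow
draws of one repertoire while Jaccard collapses — which is why both are
carried; a regression test exercises exactly this contrast.

DRTC **breadth** is the fraction of a sample's unique productive
clonotypes that belong to the DRTC set; **depth** is the summed
frequency of the detected DRTC. Depth of a set and of its complement sum
to one, which the suite asserts.

The pairwise QC flags possible sample swaps or material transfer: any
pair of samples from *different* subjects with Morisita–Horn above a
threshold (default 0.2) is flagged. Unrelated repertoires share
essentially no high-frequency mass, so the threshold is generous;
same-subject pairs are never flagged however similar.

T-cell fraction is productive templates over input genome equivalents.
The platform's own reference-gene normalization is proprietary, so this
ratio is the package's stated stand-in and requires the
`genome_equivalents` field; when absent the metric is reported as `NA`,
never fabricated.

## Tracking and categorization

Tracking tables are complete clone-by-sample grids over a subject's
longitudinal samples, ordered pre-transplant, 2 weeks, 3/6/12 months,
rejection; absence is an explicit (FALSE, 0, 0) cell.

Graft-detected DRTC are categorized by circulating detectability into
the exclusive four-way partition *pre-only / pre-and-post / post-only /
graft-only*. The cumulative pre-transplant detection share
(pre-only + pre-and-post) is derived from the partition, so both the
exclusive and the cumulative presentations are available. When the
paired post-transplant blood sample is missing the partition degrades
explicitly to *pre-only / undetermined* with a `partial` flag — a clone
undetected pre-transplant cannot then be split into post-only versus
graft-only — and nothing is imputed. Per-subject proportions are
summarized by medians at the cohort level, consistent with the
median-with-range reporting convention used throughout.

The urine analysis counts DRTC detected in the early (2-week) urine
sample and intersects them with later biopsies, clone by clone; the
chronological precondition is enforced, with rejection-episode samples
ranked after scheduled visits.

## Cohort statistics

Group comparisons are nonparametric: Mann–Whitney U for independent
groups, Wilcoxon signed rank for paired series, Fisher's exact test for
2×2 tables, Kruskal–Wallis across several groups. The engines are R's
vetted `stats` routines behind a uniform record interface; independent
enumeration oracles (full U-distribution recursion, $2^n$ sign-pattern
enumeration, hypergeometric summation) verify the exact paths in the
test suite. Exact distributions are used up to combined $n = 20$
(Mann–Whitney) and $n = 15$ non-zero differences (signed rank) without
ties, thresholds chosen for desk-scale exactness and configurable. Zero
differences in the signed-rank test are dropped (Wilcoxon's original
rule) and noted in the record; all-zero differences, zero margins and
complete ties are degenerate results reported as $p = 1$ with a flag,
never errors.

## What the synthetic cohort emulates

The generator exists so every stage is testable end to end. Per subject
it draws a Zipf-law baseline repertoire (exponent 1.5, the standard
power-law model for clone sizes; no distribution is canonical, so it is
configurable), assigns a small alloreactive subset (2% of clones, split
CD4:CD8 2:1 to reproduce the larger alloreactive CD4 compartment), and
produces the full specimen set by multinomial template sampling at
realistic depths (blood 100,000; MLR sort 20,000; biopsy 3,000; urine
500 templates).

**Alloreactive clones are drawn from Zipf ranks beyond the top 500** by
default. Alloreactive precursors circulate at low frequency; placing
them in the hyperexpanded head of the repertoire would make every
compartment detect them trivially and erase the contrast between
rejecting and stable subjects that the tracking analysis is about.

**The MLR sort is modelled as a sort**, not as a perturbation: in the
default `"sorted"` model the sorted sample is a mixture in which the
proliferated alloreactive population — weighted baseline frequency times
a lognormal per-clone expansion factor (median 8) — occupies 90% of the
sorted template mass (`sortPurity`), the remainder being
non-proliferating baseline carry-over. This reflects what flow-sorting
proliferation-diluted cells actually yields: composition proportional to
proliferated cell numbers, with rare precursors strongly enriched. A
pure `"multiplicative"` model (baseline frequencies times expansion,
renormalized) is kept for benchmarking, because it makes "expanded
exactly $k$-fold" a well-defined spike-in; with a median 8-fold
multiplicative expansion at these depths, only clones already in the top
few hundred ranks would ever reach the count floor, which is why it is
not the default for cohort emulation.

Post-transplant dynamics: lymphodepletional induction removes 90% of
clone identities (10% otherwise); rejecting subjects get a 5-fold
pre-transplant baseline boost of their CD8 alloreactive clones
(pre-existing donor-reactive memory), 20-fold alloreactive
over-representation in the biopsy (infiltration seeded from the
pre-transplant circulating pool), and 30% of infiltrating clones shed
into the 2-week urine at half the urine template mass. Group assignment
is a deterministic function of the configuration, not of the random
stream. All of these are fixed, documented defaults chosen once to
represent the study conditions; they are not tuned.

Each subject's child seed is derived arithmetically from the global seed
and the subject index (`(seed*1009 + index*9973 + 104729) mod 2^31-1`),
so any subject is reproducible in isolation and cohorts are bit-stable.

What the generator does **not** emulate: VDJ recombination statistics or
biological V/J usage (clone identities are random in-frame 87-mers with
an embedded CDR3 — identity, not sequence content, drives every
computation), HLA-mismatch-dependent effect sizes, batch effects,
cross-reactive memory phenotypes, and the absolute DRTC counts of any
particular real cohort (those are data-dependent). Passing tests
therefore demonstrate the correctness and calibration of the procedure
under a realistic statistical structure, not agreement with any
particular patient dataset.

Analyses of rejection-associated signals are evaluated within the
non-lymphodepleted stratum, because depleting 90% of clone identities
and renormalizing concentrates the surviving repertoire and dominates
every downstream signal — the same reason such analyses are restricted
to non-lymphodepleted subjects in practice.

## Validation design and problem sizes

The suite validates at three levels, with problem sizes chosen to make
the exact regimes exhaustive and the stochastic checks stable:

* **Oracle equivalence**: the binomial test against brute-force pmf
  enumeration for all counts with $n \le 50$ at four null proportions;
  BH against exhaustive step-up search for 1,000 random p-vectors;
  the nonparametric tests against full enumeration in their exact
  regimes (Mann–Whitney to 10+10, signed rank to $n=15$, Fisher totals
  to 40).
* **Calibration against ground truth**: 200 null replicates (5,000
  clones, 50,000 templates per side, no enrichment) with the median
  number of DRTC calls required to be zero and the mean false-discovery
  proportion within twice the nominal level; 50 spike-in replicates
  (50 clones expanded 8-fold with expected sorted-sample counts of at
  least 20) with sensitivity at least 0.9 and realized FDR at most 0.05.
* **Structural reproduction**: the default 12-subject cohort must show
  lower pre/post Morisita under lymphodepletion, higher pre-transplant
  CD8 DRTC depth and biopsy DRTC counts in rejecting subjects, urinary
  DRTC reappearing in later biopsies only with rejection, and a
  cumulative pre-transplant share of graft CD8 DRTC exceeding the
  post-only share — the qualitative signatures the method is meant to
  surface — plus byte-identical outputs across repeated runs.

## Known limitations

* The count-floor/BH interaction means a clone's testability depends on
  sequencing depth; very shallow samples test few clones, and the
  package reports that rather than rescaling.
* The T-cell fraction is a stand-in ratio, comparable within a study
  that records genome equivalents consistently but not calibrated to
  any proprietary normalization.
* Exact agreement with p-values produced by other software depends on
  their two-sided and tie conventions, which are often undocumented;
  the package documents its own and exposes the alternatives.
* The generator's clone-size law, depths and effect sizes are stylized;
  conclusions about power on real data require real pilot data.
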