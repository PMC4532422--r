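---
title: "Calling and analysing low-level mtDNA heteroplasmy with mitohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analysing low-level mtDNA heteroplasmy with mitohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The problem

Human mitochondrial DNA is present in hundreds to thousands of copies per
cell, and a mutation typically affects only a fraction of them -- a state
called *heteroplasmy*. In tumours, an initially rare variant can rise to high
fractions through clonal expansion, so detecting heteroplasmies down to the
1% level, and following their levels across tissues of the same patient, is
informative about tumour origin and progression. At the same time,
high-coverage sequencing of a small circular genome produces its own class of
systematic artifacts that masquerade as low-level heteroplasmies. `mitohet`
implements the full chain: strand-resolved base counting, a dual-strand
confirmed caller, artifact exclusion, method-agreement statistics against an
orthogonal quantification (Sanger electropherogram peak ratios), and cohort
level germline/somatic classification -- plus simulators that generate every
input the pipeline needs.

## The calling model

The caller's sole input is a table of per-position, per-strand counts of the
four bases (`pos ref strand A C G T depth`), built from read observations
that pass two quality filters: base quality (PHRED) $\ge$ 30 and mapping
quality $\ge$ 30. N calls, insertions and deletion evidence are not counted
toward depth; the coordinate system is the 16,569-bp circular rCRS, and
positions outside `1..16569` wrap modulo the genome length.

At a site with forward depth $d_f$ and reverse depth $d_r$, let the pooled
major allele be the most frequent base overall. A point heteroplasmy is
reported if and only if one and the same minor allele $m$ satisfies

$$\frac{c_f(m)}{d_f} \ge t \quad\text{and}\quad \frac{c_r(m)}{d_r} \ge t,$$

with $t$ the detection threshold (default $t = 0.01$; the bound is closed,
"at least"). Requiring the *same* allele at the threshold on *each* strand
separately is what suppresses strand-specific chemistry errors at ~35,000x
coverage. Sites with zero depth on either strand are reported as
insufficient-coverage no-calls, not silently dropped.

Two level conventions are carried on every call, because both are needed and
they disagree above 50%:

* `level_pct` -- the pooled percentage of the most frequent *non-reference*
  allele ("percentage of the mutated nucleotide relative to the rCRS", the
  convention of per-patient results tables; may exceed 50).
* `minor_pct` -- the pooled percentage of the minor component,
  $\min(f, 100{-}f) \le 50$, used for the low/high classification at the 10%
  boundary (low iff $< 10$).

If two non-reference alleles are present, the minor allele is the most
frequent allele other than the pooled major; ties break toward the allele
with the higher minimum per-strand fraction, then alphabetically. Triallelic
sites are not expected in practice; the rule just makes the caller total.
Reported percentages are kept at full precision internally and rounded only
for display.

## Artifact filters

Four heuristics target the artifact classes seen in high-coverage mtDNA data,
run in a fixed order (context, strand drop, correlated neighbours, zones):

1. **Recurrent low-level positions** (`flag_recurrent_context`): a position
   called at minor level $\le$ 5% in $\ge$ 8 distinct samples is a phantom
   mutation candidate; flagged positions with an identical flanking 9-mer are
   grouped, since context-driven errors recur at sequence-similar loci.
2. **Strand coverage drop** (`strand_coverage_drop`): the site's depth on one
   strand at $\le$ 0.8 of the flanking median (5 positions per side) while
   the other strand stays $\ge$ 0.9 of its own.
3. **Correlated neighbours** (`correlated_neighbors`): positions within 3 bp
   of a phantom anchor whose levels correlate with the anchor's across
   samples at $r \ge 0.9$ and occur only in anchor-positive samples.
4. **Zones** (`zone_exclusion`): the long-range PCR primer annealing region
   (default 2523--2667) and a 5-bp circular-edge margin around the origin,
   where mapping against a linearised circular genome is unreliable.

The defaults are the envelope of observed artifact instances, not estimated
thresholds, and all are configurable via `filter_config()`. Exclusion is
deliberately asymmetric in level: recurrence evidence (stages 1--2) only
indicts the *low-level* calls at a flagged position -- a 60% heteroplasmy at a
phantom hotspot is genuine signal and is retained -- whereas correlated
neighbours and zone calls are excluded at any level. Filtering is
non-destructive (`pass` and `excluded` partition the input, flags are
recorded per call, and an audit log counts per flag kind) and idempotent.
Phantom flagging needs recurrence and is therefore cohort-level; a
single-sample run can only apply the strand-drop and zone stages.

## Method agreement

Sanger sequencing cannot resolve secondary peaks below roughly 10%, so paired
Sanger/NGS comparisons substitute below-detection-limit Sanger values with
$\mathrm{LOD}/\sqrt{2} = 10/1.414 = 7.07$ before computing summary statistics
(the `half` rule, LOD/2, is available as an alternative). Agreement is then
assessed the standard way: plot pair means against differences, report the
mean difference (fixed bias), SD of differences, limits of agreement
$\bar d \pm 1.96\,\mathrm{SD}$ (the literal 1.96, not a $t$ quantile), the
percentage of pairs within the limits, a two-sided one-sample $t$-test of the
mean difference against zero (flagged degenerate at zero variance rather
than given a fake p-value), and Pearson's $r$.

## Cohort analysis

A patient's variant is summarised as its level per tissue class, with two
distinct absence marks: `n.d.` (tissue sequenced, heteroplasmy below the 1%
threshold -- treated as absence for classification, never imputed as a zero
level) and `n.a.` (tissue not collected -- excluded from all denominators).
Classification is total and exclusive: homoplasmic in all sampled tissues
$\to$ germline homoplasmic; heteroplasmic in a benign-class tissue *and* a
cancerous tissue $\to$ germline heteroplasmy; absent from benign but present
in $\ge$ 2 cancerous tissues $\to$ shared somatic; otherwise private somatic.
A benign-only heteroplasmy therefore falls into the private class -- with no
cancerous observation there is no evidence to call it either germline-carried
or tumour-related.

Level comparisons between tissue groups use the 2x2 Pearson chi-square
**without** continuity correction: on the published benign/tumour counts
(65/82 vs 62/97 below 10%) the uncorrected statistic is 5.08 with p = 0.024,
matching the printed value, while the Yates-corrected one is not. Regional
mutation spectra group each protein gene and rRNA separately, pool the tRNAs
and pool the control region; this grouping (one of several defensible ones,
and the one used for the published spectrum correlation) is configurable via
`grouping = "class"`. Length correlations are computed among protein-coding
genes only. Non-synonymous enrichment switches from chi-square to Fisher's
exact test when any expected cell is below 5.

Coding effects are evaluated under the vertebrate mitochondrial genetic code
against the reference codon, with light-strand genes (MT-ND6 and eight
tRNAs) complemented before translation and incomplete terminal codons
completed with A (the polyadenylation convention). The shipped annotation
tiles the genome exactly once: intergenic spacers belong to the upstream
feature and gene overlaps to the upstream gene, while true CDS spans are kept
separately so reading frames are exact; a substitution in a dual-coding
overlap is evaluated in the owning region's frame only. The control-region
boundary convention (16024--576, with HVS-I/II/III sub-labels and the small
non-coding features OL and the spacers counted as control class) is the
fixture's documented choice.

## What the simulators emulate -- and what they do not

`make_haplotype_pair()`/`simulate_mixture_counts()` reproduce the structure
of a two-donor dilution series: two haplotypes differing at 27 transition
sites, mixed at a minor fraction (1+1, 1+9, 1+49, 1+99 correspond to 0.5,
0.1, 0.02, 0.01), sequenced to a Poisson per-strand depth (default 17,500
per strand, i.e. ~35,000x total). Base counts at differing sites are
binomial in the mixing fraction; uniform miscalls at `error_rate` (default
0.001, the Q30 operating point) are scattered over the three alternative
bases. A known consequence: the expected estimated minor fraction is not
$f$ but $f(1-e) + (1-f)e/3$, an offset of about +0.03 percentage points at
$f = 1\%$ -- visible in the validation output (typically 1.02--1.03%) and
small against the binomial standard error of a single site's estimate at
35,000x (0.053 points), which is the acceptance band used. Mixture fractions
are defined on total DNA; a per-haplotype copy-number skew factor is not
modelled (equal mtDNA per unit DNA assumed).

`simulate_cohort()` generates 28 patients with benign margin and primary
tumour samples, plus a recurrence (p = 6/28), lymph-node metastasis (5/28)
and blood (4/28); germline heteroplasmies at log-normal low levels (~80%
below 10%), clonal expansion multipliers log-normal with median 2.8, shared
somatic mutations expanding from tumour into recurrence/metastasis, private
somatic mutations, and injected phantom artifacts: two anchor positions
recurring at ~1.5% in ~45% of samples with a forward-strand coverage drop,
plus two satellite neighbours tracking the first anchor. Ground-truth labels
are emitted for every variant, and calls are generated directly at the call
level (per-strand counts binomial at the true level) rather than via reads.

The simulators deliberately do not model: read-level artefacts (adapters,
quality ramps, alignment), NUMT contamination, overlapping read pairs,
length heteroplasmy in homopolymer tracts, or context-dependent error
hotspots beyond the injected artifact positions. Passing the end-to-end
recovery tests therefore demonstrates that the pipeline's logic is correct
under its stated error model -- not that real tissue data are free of failure
modes outside that model.

## Numerical and scale choices

* Depth is Poisson around the target per-strand coverage; strand split 50/50.
* Every generator is deterministic under an explicit seed, and seeded
  sub-streams never disturb the caller's RNG state.
* The reference model validates the annotation partition on load and rejects
  malformed variant labels naming the offending token.
* Problem sizes in the test suite are chosen to keep the full run around half
  a minute: binomial-moment checks use 1,000 replicates of a 50-bp
  mini-haplotype; mixture validation runs one full-genome simulation at
  35,000x for quantification and twenty for detection sensitivity; the
  end-to-end cohort run uses the full default design (28 patients) once.

## Known limitations

* Indels and length heteroplasmy are not called from counts; they enter only
  as parsed labels on externally supplied records (frameshift classification
  works on such labels).
* Contamination handling is limited to major/minor profile splitting
  (`split_profiles()`); no haplogroup-based checks.
* The phantom filter needs a cohort; single samples get only strand-drop and
  zone protection.
* "Confirmed each other" across strands is implemented as same-minor-allele
  on both strands at the threshold; no additional statistical concordance
  test is applied.
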