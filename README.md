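# mitohet

Strand-confirmed calling and cohort analysis of mitochondrial DNA
heteroplasmy.

Human mtDNA is polyploid: a mutation usually affects only a fraction of a
cell's genome copies (*heteroplasmy*), and in tumours that fraction can grow
by clonal expansion from below 1% in normal tissue to dominant levels in a
recurrence or metastasis. `mitohet` is for researchers analysing
high-coverage (~35,000x) mitochondrial genome sequencing of tissue cohorts
who need to (i) detect point heteroplasmies down to the 1% level without
being swamped by systematic sequencing artifacts, (ii) check their
quantification against an orthogonal method such as Sanger electropherogram
peak ratios, and (iii) classify variants as germline or somatic across
benign, tumour, recurrence, metastasis and blood samples of the same
patient.

## The core rule

All calling happens on per-position, per-strand base counts after quality
filtering (base PHRED >= 30, mapping quality >= 30) against the 16,569-bp
circular rCRS coordinate system. With forward/reverse depths *d_f*, *d_r*
and counts *c_f(m)*, *c_r(m)* of a candidate minor allele *m*, a point
heteroplasmy is called iff

    c_f(m)/d_f >= t   AND   c_r(m)/d_r >= t        (default t = 1%)

for the **same** allele on both strands — dual-strand confirmation. Each call
carries two levels: the percentage of the non-rCRS allele (`level_pct`, may
exceed 50) and the minor-component percentage (`minor_pct` <= 50), which
drives the low/high split at 10%. Downstream filters flag recurrent
low-level "phantom" positions sharing a sequence context, one-strand
coverage drops, neighbour positions whose levels ride on a phantom anchor,
primer-annealing zones and the circular edge. Method agreement uses
Bland-Altman limits of agreement (mean difference ± 1.96 SD) with
below-detection-limit Sanger values substituted by LOD/√2 = 7.07.

## Worked example

Validate the 1% detection limit on a simulated 1+99 two-haplotype mixture at
~35,000x, then reproduce the cohort-table arithmetic shipped with the
package:

```r
library(mitohet)

g   <- synthetic_genome(seed = 1)                     # 16,569-bp stand-in reference
des <- make_haplotype_pair(g, n_diff = 27, fraction_b = 0.01, seed = 7)
pu  <- simulate_mixture_counts(des, seed = 8)         # strand-resolved counts
calls <- call_heteroplasmies(pu, threshold = 0.008, sample = "mix_1_99")
est <- estimate_mixture_fraction(calls, des)
#> detected 27/27 sites, mean minor fraction 1.044%

head(calls[, c("pos","ref","major","minor","level_pct","minor_pct")], 3)
#>    pos ref major minor level_pct minor_pct
#> 1  288   T     T     C    0.9589    0.9589
#> 2  571   A     A     G    1.0613    1.0613
#> 3 2888   C     C     T    1.0277    1.0277
```

All 27 sites where the two haplotypes differ are recovered, and the mean
estimated minor fraction sits at the injected 1% (plus the ~0.03-point
offset contributed by the uniform 0.1% error model; see the vignette). The
published per-patient tables ship as a fixture, and their summary statistics
come straight out of the cohort functions:

```r
som <- study_shared_mutations()
som <- som[som$table == "somatic", ]
shared_somatic_summary(som)$means
#>            tissue_class  n mean_level_pct
#> 1 lymph_node_metastasis  7           49.8
#> 2         primary_tumor 12           17.9
#> 3            recurrence  5           39.6

res <- level_distribution_test(c(rep(5, 65), rep(20, 17)),   # benign: 65/82 low
                               c(rep(5, 62), rep(20, 35)))   # tumour: 62/97 low
sprintf("chi-square %.2f, p = %.3f", res$statistic, res$p_value)
#> "chi-square 5.08, p = 0.024"
```

Shared somatic mutations average 17.9% heteroplasmy in primary tumours and
rise to 39.6% in recurrences and 49.8% in lymph-node metastases — the
clonal-expansion signature — and low-level heteroplasmies are significantly
more frequent in benign than in tumour tissue (uncorrected 2x2 chi-square).

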