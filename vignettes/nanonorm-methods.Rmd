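---
title: "Methods and design of nanonorm"
author: "nanonorm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of nanonorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanonorm)
```

# The problem

The nCounter platform counts RNA molecules directly via optical barcodes:
each lane of a cartridge yields a Reporter Code Count (RCC) file with raw
counts for endogenous target probes, a housekeeping panel, synthetic
positive controls spiked in at a known concentration ladder (128, 32, 8,
2, 0.5, 0.125 fM), and negative-control probes that measure nonspecific
binding. Because there is no amplification, raw counts carry several
technical layers that must be removed before any biology can be read off:

* a **lane-level technical effect** (hybridization efficiency, imaging),
  visible in the positive spike-ins;
* a **sample-input effect** (amount and quality of RNA), which affects
  mRNA probes but *not* the spike-ins — this is what content
  normalization targets, and why positive-control scaling alone is
  insufficient;
* an **additive background** from nonspecific binding, estimated from the
  negative controls;
* counting noise, empirically overdispersed relative to Poisson.

`nanonorm` implements the full preprocessing path — parsing, lane QC,
background handling, technical and content normalization with data-driven
reference-gene selection, factor-based removal of unwanted variation, and
diagnostics — as a scriptable R library with a thin command-line front
end.

# Lane quality control

Five metrics are computed per lane and compared against configurable
acceptance ranges (`qc_thresholds()`): imaged field-of-view percentage
(default minimum 75%), binding density (0.1–2.25 spots/µm², read from the
lane attributes since image data are unavailable downstream), linearity
of the positive ladder (squared Pearson correlation between
`log2(count + 0.5)` and log2 concentration, minimum 0.95), the positive
scaling factor (acceptance 0.3–3), and the percentage of endogenous genes
below background (maximum 80%). A lane with any flag is *suggested* for
removal; nothing is dropped automatically, and re-running QC with edited
thresholds is cheap by design. The 0.125 fM ladder point sits near
background in standard panels and is excluded from the linearity fit by
default (configurable). Throughout the package, logs of possibly-zero
counts use a single convention: `log2(count + 0.5)`; geometric means
replace zeros by 0.5.

# Background

Per-lane background is summarized from the negative controls by one of
`mean`, `mean + 2 SD` (default, sample SD with denominator n−1), `max`,
`geomean`, or a manual constant. When the panel's negatives behave poorly
the estimate can instead come from low-expressed, stable endogenous genes
(`select_alternative_negatives()`: lowest mean count subject to a
coefficient-of-variation cap, defaults n = 10 and CV ≤ 0.5; the rule is
this package's own concrete definition of that idea).

Correction offers `subtract` (`max(count − b, 0)`), `floor`
(`max(count, b)`) and `skip`. The pipeline default is **floor**: on data
whose low-count probes are dominated by background, subtraction sends
counts toward zero and the `log2(· + 0.5)` transform then explodes their
variance, which measurably *widens* the RLE distributions the user is
trying to narrow. Flooring pins below-background probes at the background
level instead, suppressing their spurious variability while leaving
well-expressed probes untouched. Subtraction remains available for users
who need background-free count magnitudes.

# Normalization

**Technical normalization** multiplies lane *i* by
$f_i = \bar g / g_i$, where $g_i$ is the lane's geometric mean of
positive-control counts and $\bar g$ the arithmetic mean of the $g_i$
(geometric-mean target available). After scaling, the positive geometric
means agree across lanes to within 1e−9 relative. As an alternative, a
per-lane ordinary least-squares regression of `log2(count + 0.5)` on log2
ladder concentration maps every gene onto the concentration axis
(`regression_calibrate()`); unlike a single factor it also corrects
compression or expansion of the dynamic range. It replaces, rather than
composes with, positive scaling, since both consume the same ladder.

**Content normalization** applies the same scaling contract with a
biological reference statistic: the geometric mean of chosen reference
genes (default), total counts, the top-n most expressed endogenous genes,
or all endogenous genes. The default stage order runs technical
normalization *before* background correction, then content normalization;
the executed order is recorded in the provenance log and configurable.

**Standardization** (per-gene z-scores on the log2 scale) is available as
a final step for tools that expect it; constant genes become all-zero
rows and are flagged.

# Reference-gene selection

Candidates are the housekeeping panel plus the `endo_n = 10` endogenous
genes with the lowest coefficient of variation among those with mean
count ≥ 200 — reference genes must sit well above background, where
relative counting noise is small.

Stability is ranked by iterative elimination: the pairwise variation
$V_{jk}$ is the sample SD across lanes of $\log_2(x_j/x_k)$, the
stability value $M_j$ is the mean of $V_{jk}$ over partners, and the gene
with the highest weighted score $M_j / w_j$ is removed each round until
two remain. Unit weights reduce exactly to the unweighted algorithm;
division is the simplest order-preserving weighting and is this package's
own definition. Ties eliminate the alphabetically later gene, making
results platform-independent. The series $V(n, n+1)$ — the SD across
lanes of the log-ratio of normalization factors built from the top $n$
versus $n+1$ genes — indicates how many references are enough. The
default selection size is 6.

Because log-ratios cancel per-lane factors, the ranking is invariant to
lane scaling. Two caveats are worth knowing. First, a set of co-regulated
genes (for example, genes sharing a condition effect) is mutually stable
and can dominate the ranking — this is why the group-driven refinement
below exists. Second, "an exact copy of a candidate always ends up in the
final pair" is a good heuristic but not a theorem: once the tie between
the two copies is broken, a chance cluster of mutually tight candidates
can outlast the remaining copy. The test suite checks the guaranteed
final-three behavior and the statistical form of the property.

## Group-driven refinement

A reference gene must not differ between condition groups. Each candidate
is tested three ways at level `alpha` (default 0.05): Kruskal–Wallis
across all groups; Wilcoxon rank-sum for every group pair (minimum p
retained; exact p-values when both groups have ≤ 10 lanes, normal
approximation with continuity correction otherwise); and a reverse
sequential feature selection that captures *combined* effects —
starting from all candidates, the candidate whose removal most reduces
the Kruskal–Wallis statistic of the per-lane geometric mean of the
remaining set is removed until that statistic stops being significant or
two candidates remain. The SFS criterion is this package's concrete
definition of a combined-effect screen. Flagged candidates are removed
(`filter`) or annotated (`flag`); if filtering leaves fewer than three
genes, the least-offending ones are restored so the ranking stays
defined.

## Two-pass selection

`choose_reference_genes()` runs the screen, the refinement and the
ranking on a *provisionally normalized* copy of the data (total-count
scaling) and returns a selection to be applied to the original counts.
The reason is subtle but important: group tests on absolute expression
see the shared sample-input effect, and with an unlucky draw that effect
correlates with the condition groups — genuinely stable genes then look
differential while co-regulated differential genes look stable, and the
selection inverts. Screening on provisionally normalized data removes the
shared component before any candidate is judged. In simulations this
eliminated reference sets composed entirely of differential genes.

# Removing unwanted variation

`ruvg_fit()` estimates unwanted factors from control genes: on the
lanes × genes matrix of `log2(count + 0.5)`, the column-centered control
block is decomposed by SVD; the first *k* left singular vectors scaled by
their singular values form the factor matrix **W**, loadings **α** are
the least-squares regression of all centered genes on **W**, and the
corrected expression is **Y − Wα** with gene means restored. Because
**W** has orthogonal columns, the regression is solved in diagonal form,
and factors beyond the control rank receive zero loadings rather than
destabilizing the solve. Signs are fixed so each factor's
largest-magnitude entry is positive, making output identical across
linear-algebra backends. Controls default to the selected reference
genes; the negative controls are an alternative. Zero-variance controls
are dropped with a warning; if none remain the data are returned
uncorrected.

`median_of_ratios()` provides the classical size-factor
pre-normalization: each lane's factor is the median ratio of its counts
to the per-gene geometric means, computed over genes with strictly
positive counts everywhere. `k_scan()` tabulates, for k = 1..k_max, the
corrected mean RLE IQR and the variance explained by each factor; the
choice of k is left to the user.

# Evaluation

Relative log expression subtracts each gene's median across lanes from
`log2(count + 0.5)`, restricted to endogenous genes by default (controls
would dilute the diagnostic). Narrow, zero-centered per-lane
distributions indicate successful normalization; the scalar summary is
the per-lane interquartile range (type-7, linear-interpolation quantiles
— stated because IQR values depend on the convention) and its mean over
lanes. `compare_normalization()` computes both summaries and a verdict —
improved / unchanged / worsened by strict comparison of the mean IQR —
plus RLE boxplots and PCA scatter plots (gene-centered log2 endogenous
matrix, SVD, same sign convention) colored by group and batch. Plots are
artifacts only; every assertion in the test suite runs on the underlying
tables. No plot is consulted for the verdict.

A limitation worth stating: a *purely* multiplicative lane effect shifts
a lane's whole RLE column without widening it, so the IQR criterion
detects lane effects mainly through their interaction with additive
background and noise. This matches its behavior on real data, where
below-background probes and additive offsets dominate RLE width.

# The synthetic generator

`simulate_dataset()` / `simulate_rcc()` emulate an nCounter run with
known ground truth; defaults describe a realistic full-size experiment
and were fixed as the package's standard study conditions:

| parameter | default | rationale |
|---|---|---|
| lanes | 12 | one cartridge |
| endogenous genes | 730 | full-size panel |
| housekeeping / negatives / ladder | 10 / 8 / 6 points | standard panel composition |
| technical lane effect | log-normal, SD 0.3 (log2) | moderate run-to-run variation, seen by all probes |
| RNA-input effect | log-normal, SD 0.4 (log2) | sample-to-sample input variation, mRNA probes only |
| additive background | 12 counts on every probe | nonspecific binding affects all probes, not only negatives |
| positive scale | 250 counts/fM | puts POS_A in the tens of thousands, as instruments report |
| differential genes | 20% at 1 log2 FC | typical case/control contrast |
| noise | negative binomial, dispersion 0.05 | mild overdispersion resembling real counts |

Two aspects matter for interpreting test results. The input effect is
invisible to the positive controls by construction, so passing the
content-normalization properties genuinely demonstrates removal of a
signal the spike-ins cannot see. And the background term applies to every
probe, which is what gives background correction a measurable job; a
generator that adds background only to the negative controls would make
that stage a no-op by construction. What the generator does *not*
emulate: probe-specific affinities, image-level artifacts (binding
density is written directly as a lane attribute), batch effects beyond a
uniform log2 shift, and count truncation other than final rounding when
RCC files are written. Conclusions from these simulations therefore
speak to lane-level and sample-level variation, not probe chemistry.

With `noise = "none"` counts equal their expected values exactly; the
recovery tests (lane effects (1, 2, 4) inverted to 1e−9 relative;
median-of-ratios multipliers to 1e−9) run under that setting with zero
background and zero input effect, which is the generating condition those
contracts describe.

`make_stability_fixture()` constructs datasets in which designated
endogenous genes are more stable than every housekeeping gene by
construction (extra independent per-lane noise on the housekeeping
panel); it refuses configurations in which the noise ordering would not
force the ranking.

# Pipeline and provenance

`run_pipeline()` executes ingest → QC → normalize → evaluate as
file-based stages in an output directory, writing the raw matrix, QC
report (JSON + HTML), normalized matrix, reference-gene report,
evaluation JSON and plots, and a `provenance.json` recording every
executed stage with parameters and MD5 digests of its outputs.
`rerun_stage()` re-executes any stage with overrides, reusing cached
upstream artifacts after verifying their digests — a tampered upstream
file aborts the rerun. Given the same inputs, configuration and seed,
numeric outputs are byte-identical; matrices are written with 15
significant digits so values round-trip.

Problem sizes in the test suite are chosen to exercise each property at
the smallest scale that makes it meaningful: oracle comparisons use
panels up to 8 candidates × 12 lanes, recovery tests run noise-free, and
the end-to-end properties use 50 replicate runs of the standard
simulation.
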