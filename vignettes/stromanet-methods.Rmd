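---
title: "Methods: network enrichment analysis of fibroblast confrontation transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network enrichment analysis of fibroblast confrontation transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stromanet` analyses transcriptomes of fibroblasts confronted with cancer
cells in co-culture. The design it targets is self-controlled and paired:
each fibroblast line is profiled before and after confrontation, and the
lines additionally differ in their measured capacity to inhibit tumor-cell
growth, giving two contrasts — *confrontation* (post vs pre, paired by line)
and *inhibitory capacity* (high- vs low-inhibitory lines, independent).
Because gene-level differences in such designs are noisy, the central tool
is network enrichment analysis (NEA): significance is carried by functional
*links* between gene sets in a global functional-coupling network rather
than by member overlap.

## The network enrichment statistic

Let the altered gene set (AGS) be an experiment-derived list (here, top-N
differentially expressed genes) and the functional gene set (FGS) a pathway,
term, or a single gene. With $n$ the observed number of network edges
joining any AGS member to any FGS member, the expectation under the
configuration-model null (random graph preserving node degrees) is

$$\hat n = \frac{N_{AGS} \, N_{FGS}}{2\,N_{total}},$$

where $N_{AGS}$ and $N_{FGS}$ are the sums of network degrees over the set
members (genes absent from the network contribute 0) and $N_{total}$ is the
total edge count. The test statistic is a 1-df chi-square over the two-cell
classification of all edges (cross vs non-cross):

$$\chi^2 = \frac{(n - \hat n)^2}{\hat n} +
           \frac{\big((N_{total}-n) - (N_{total}-\hat n)\big)^2}{N_{total}-\hat n}.$$

The p-value is the upper chi-squared tail; enrichment vs depletion is
carried separately by the signed $z = \mathrm{sign}(n-\hat n)\sqrt{\chi^2}$.
A batch run over all AGS × FGS pairs applies Benjamini–Hochberg within the
batch (one analysis, one FDR family) and calls a pair significant only when
FDR < 0.1 **and** it is supported by at least 5 observed links — the
links floor keeps calls from resting on one or two edges of a hub.

Conventions that the formula itself does not fix, resolved here once:

* **Overlapping members.** A gene in both sets contributes its degree to
  both $N_{AGS}$ and $N_{FGS}$; an edge between two such genes is counted
  once as a cross-link. Edges internal to only one set are not counted.
* **Internal connectivity** (coherence of a single list) sets FGS = AGS and
  halves the expectation to $N_{AGS}^2 / (4 N_{total})$, because unordered
  within-set pairs would otherwise be double-counted. The observed count is
  the number of edges with both endpoints in the set.
* **Degenerate pairs.** $\hat n = 0$ with observed links yields a flagged
  infinite-enrichment record (p clipped to the smallest representable
  value), never an exception, so batch runs cannot abort mid-way.
* **No continuity correction** is applied; the raw statistic is used.
* **Single-gene mode** is the identical computation with a singleton FGS;
  it ranks individual regulators (e.g. transcription factors) against a DEG
  list. For TF maps the significance rule tightens to FDR < 0.01 with at
  least 3 links per TF.

### Validation against the edge-swap null

The chi-squared approximation is validated, not assumed. The package
carries a degree-preserving edge-swap (Maslov–Sneppen) randomization
oracle (`ms_null_counts()`, built on `igraph::rewire(keeping_degseq())`,
10 swap attempts per edge per replicate): the mean cross-link count over
rewired replicates must agree with $\hat n$, and empirical enrichment
p-values must track the chi-squared ones. On a 500-node / 2000-edge
synthetic scale-free network with disjoint random 20-gene sets, the test
suite requires agreement within 3 Monte-Carlo standard errors, Spearman
correlation of at least 0.9 between the two p-value sets over 200 pairs,
and null calibration (fraction of p < 0.05 within [0.03, 0.07] over 1000
random pairs). Set size 20 was chosen analytically before testing: the
closed-form formula slightly overstates the expectation for hub-heavy sets
(the simple-graph constraint caps edge multiplicities), and the bias grows
with $\sum_{u \in A} d_u^2 \cdot \sum_{v \in B} d_v^2$; at size 20 on this
network it is an order of magnitude below the Monte-Carlo error band.
Because the one-sided randomization p measures enrichment only, the
comparison converts the two-sided chi-squared p into its enrichment-side
version via the sign of $z$.

## Differential expression

Log2 microarray intensities contain a low-mean / low-variance cluster of
unexpressed ("absent") genes. The filter removes a gene iff its variance
across all samples is strictly below 0.1 **and** its mean strictly below 4
(both thresholds on the log2 scale; strict inequalities, so a gene sitting
exactly on a threshold is kept). Filter statistics always pool all samples.

Per-gene tests are ordinary t-tests: paired by line for the confrontation
contrast (df = pairs − 1), independent with the Welch correction for the
inhibition contrast (the variance-equality assumption is not imposed
because the lines come from different donors and tissues). P-values are
two-sided throughout — downstream NEA consumes unsigned lists — and
adjusted by Benjamini–Hochberg over all tested genes. A gene with zero
within-pair variance and a nonzero difference is flagged, given an
infinite t and the smallest representable p: the statistic is undefined
but the gene unambiguously ranks first. Top-N lists are ranked by p with
ties broken by larger |t| and then lexicographic gene id, so a run is
byte-reproducible.

Companion views: per-line fold-change matrices (post − pre), PCA of the
fold-change vectors (variables = genes, centered; fractions of variance
reported non-increasing), Pearson/Spearman correlation of two gene
profiles, and the cross-model check that correlates per-gene differences
(low − high inhibitory) between an in vitro line pair and an ex vivo line
pair.

## TF–target co-expression validation

Binding-site maps (TF → target edge lists) are converted to undirected
networks and each TF is scored by single-gene NEA against the DEG list. To
cross-validate a map on the expression data itself,
`correlated_pair_excess()` computes the Pearson correlation of every
TF–target pair across all samples (p from the t distribution with
$n_{samples} - 2$ df — the "profile length" enters only through the exact
sample count), applies BH at FDR < 0.05, and compares the passing count
with an **empirical** baseline: the mean count among many same-sized draws
of random gene pairs (map pairs excluded, at least 100 draws). The
baseline is empirical rather than the nominal FDR rate because real
expression data — and the synthetic data here, by construction — contain
genuinely co-expressed random pairs; fold-excess over that baseline is the
reported quantity. Null pairs are matched in count only, not degree: no
matching detail is imposed beyond what the procedure defines.

## Survival meta-analysis

Per cohort, each gene's standardized expression is tested by the Cox
proportional-hazards **score test** (closed form at $\beta = 0$, Breslow
convention for ties), vectorized over all genes at once; on tie-free data
it is identical to the score test of a fitted Cox model, and the test
suite verifies that against `survival::coxph`. Per-gene p-values from all
cohorts are combined by Fisher's method ($-2\sum\ln p_i$ against
$\chi^2_{2k}$; a single cohort is the identity; zeros are clipped with a
warning), then BH-adjusted. Candidate lists are judged by fold-enrichment
among genes with combined p below a cutoff, with a hypergeometric tail
p-value; a network hands the same machinery the list's direct neighbors
(candidates excluded) to ask whether the *neighborhood* is prognostic.
An empty survival set or an expansion without network presence yields a
flagged report, not an error.

## What the synthetic data emulate — and what they do not

`synth_spec()` fixes the study conditions: 8 lines × pre/post = 16 paired
samples; 45% of ~20,000 genes in an absent cluster at mean 3, variance
0.05 (straddling the filter thresholds with a clear margin); expressed
baselines Normal(8, 1) per gene and line; per-sample noise sd 0.5; 300
confrontation DEGs shifted by 1 log2 unit in post samples (random sign);
300 inhibition DEGs shifted in the 4 high-inhibition lines. The
inhibition effect defaults to 1.5 log2 units — larger than the
confrontation effect because it is a line-level contrast that must stand
against the between-line baseline sd of 1 without the benefit of pairing.
A latent sample factor with ±2 loadings on 10% of expressed genes gives
the co-expression background the TF baseline needs. The TF generator's
`correlated_fraction` defaults to 0.10, calibrated once so that the
planted map shows a ~9-fold correlated-pair excess under the default
conditions. Survival cohorts draw a latent per-patient risk; prognostic
genes correlate with it at ρ = 0.7 so each carries the stated marginal
hazard ratio per expression sd; censoring is independent exponential.

Deliberate simplifications, hence limits on what green tests show about
real data: no probe-level structure or normalization artifacts; no
mean–variance trend among expressed genes; no tumor-cell contamination of
sorted fibroblasts; DEG lists are not planted as network modules, so
internal-connectivity z-scores on synthetic lists hover near zero (on real
data coherent lists are the interesting finding, not a given); cohorts
share no batch structure, so Fisher's independence assumption holds by
construction.

## Problem sizes and numerical choices in the checks

The recall check for planted DEGs runs at 2,000 genes. The choice is
analytic, made before any test was executed: with effect 1.0, per-sample
noise sd 0.5 and 8 pairs, the paired t has noncentrality 4 at 7 df, and
the expected top-300 recall is ~0.90 against ~800 kept null genes but
only ~0.67 against the full-scale ~10,700 — recall is a function of the
competing-null count, and the desk-scale suite pins the regime where the
expected value sits clearly above the 0.8 bar. The full-scale default is
still exercised (absent-filter completeness at 9,000 planted absent genes)
and keeps a weaker recall property. A related caveat: at these conditions
the count of q < 0.05 calls sits at the detection margin and varies
strongly between seeds; the top-N list, not the q-threshold count, is the
stable object.

Link planting (`plant_cross_links()`) adds cross edges and removes an
equal number of edges untouched by either set, so the total edge count is
conserved exactly while degrees drift (reported in a message). Because
added edges inflate the degree sums and with them the expectation, the
target is re-evaluated iteratively; for large sets the expectation can
inflate as fast as edges are planted (no fixed point), in which case the
function stops at the achieved ratio with a warning instead of looping.

Randomness is never ambient: every generator and every randomized
procedure takes an explicit seed, and reruns are byte-identical — the
pipeline tests assert this on the written result tables.
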