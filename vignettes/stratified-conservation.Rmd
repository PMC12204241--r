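---
title: "Stratified composition analysis and cross-population conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified composition analysis and cross-population conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratocyte)
```

## The problem

Single-nucleus studies of Alzheimer's disease (AD) ask whether the relative
abundance of a transcriptomic cell subpopulation — say, a particular
microglial subcluster — tracks pathology (plaques, tangles, Braak stage,
CERAD score) or cognition (clinical diagnosis, slope of cognitive decline).
When donors come from several self-identified population groups that are
not demographically matched, a pooled regression confounds group membership
with everything that differs between groups. The approach implemented here
is stratified: fit the association separately in each population group,
pool the per-group coefficients with a random-effects meta-analysis, and
call an association *conserved* only when it is significant after
multiple-testing correction, has the same sign in every group, and shows
acceptable between-group heterogeneity.

`stratocyte` implements that pipeline end to end, together with the
surrounding decision rules such a study needs (nucleus QC, subcluster
merging, expression-program selection, risk-locus accessibility
normalization, pooled-library demultiplexing, donor subgrouping), and a
synthetic-data module that generates every input with known ground truth so
each stage is testable at desk scale.

## The proportion model

Within a broad cell class, the per-sample counts over subclusters are
compositional: the response for subcluster $s$ in sample $i$ is the
proportion $y_{is} = c_{is} / N_i$ with $N_i$ the within-class total.
Proportions live in $[0,1]$, are zero-enriched and left-skewed, so the
model is a logistic regression with a quasibinomial variance,

$$\operatorname{logit} E[y_i] = \beta_0 + \beta_1 x_i + \gamma^\top z_i,
\qquad \operatorname{Var}(y_i) = \phi\, \mu_i (1-\mu_i) / w_i,$$

where $x$ is the phenotype of interest, $z$ the covariates (age at death,
sex, post-mortem interval, plus education for cognition-related
phenotypes), $w_i$ prior weights, and $\phi$ a free dispersion absorbing
overdispersion. Coefficients are fitted by iteratively reweighted least
squares (deviance tolerance `1e-8`, at most 100 iterations, step-halving
on divergence); $\hat\phi$ is Pearson $X^2/(n-p)$. Two weighting modes are
provided: `weighted = TRUE` (default) uses the within-class denominators
as prior weights, on the grounds that a sample contributing 20,000 nuclei
measures its composition better than one contributing 500;
`weighted = FALSE` treats all samples equally, a pure proportion
regression.

### Robust standard errors

Under a Dirichlet-multinomial-like generative process the binomial weight
model is misspecified — the sample-to-sample variance of a proportion is
dominated by biological overdispersion and nearly independent of $N_i$ —
so inference uses a heteroskedasticity-consistent sandwich covariance and
a $t$ reference distribution on $n-p$ degrees of freedom. The estimator
flavor matters at this design's scale: per-(group, region) fits have a few
dozen samples against five or six model terms, where the uncorrected HC0
estimator is known to be anticonservative. In the package's own
calibration simulations (a null Dirichlet-multinomial cohort of 30 donors
per group, fully crossed with regions) HC0 roughly doubles the nominal
false-positive rate while HC3, which rescales each score by its leverage
(Long & Ervin's small-sample recommendation), holds it at the nominal
level — the permutation facility (`permutation_calibration()`) and the
acceptance script both verify this at run time. The package therefore
defaults to `hc_type = "HC3"`; `"HC0"` (White's original estimator) and
`"HC1"` remain available.

### Eligibility and calibration

A subcluster is modeled only when the number of complete samples is at
least one more than the number of model terms (intercept + phenotype +
covariates, sex counting as one term). `permutation_calibration()`
shuffles the (proportion, denominator) pairs across samples and refits,
reporting the empirical rejection rate at $\alpha \in \{0.01, 0.05,
0.10\}$ — a direct check of the model's false-positive behavior on the
data at hand.

## Cross-group pooling and the conservation rule

Per-group estimates $\hat\beta_g$ with robust standard errors $s_g$
($k = 3$ groups) are pooled with a random-effects model. The between-group
variance $\tau^2$ is estimated by REML (Fisher scoring on the profiled
restricted likelihood, analytic gradient, floored at zero, at most 50
iterations); the pooled coefficient is the inverse-variance-weighted mean
with weights $w_g = 1/(s_g^2 + \hat\tau^2)$. Inference uses the
Hartung-Knapp-Sidik-Jonkman adjustment: the pooled variance is rescaled by
$q = \sum_g w_g(\hat\beta_g - \hat\beta)^2/(k-1)$ and tested on $k-1$
degrees of freedom. The untruncated $q$ is the default, matching the
cited method's standard behavior; `truncate_hksj = TRUE` applies
$\max(q, 1)$. On non-convergence a restart cascade doubles the iteration
cap and halves the scoring step twice, then falls back to ML, then to a
fixed-effect pool with a $t$-test, recording which method succeeded.

Heterogeneity is summarized by Cochran's $Q$ (fixed-effect weights) and
$I^2 = \max(0, (Q - (k-1))/Q) \times 100$. After Benjamini-Hochberg
correction across the full family of pooled results (all regions,
subclusters and traits together — the family definition is a choice;
per-class families are a `filter()` away since results are plain tibbles),
an association is flagged conserved when

1. adjusted $p < 0.05$,
2. all per-group coefficient signs agree, and
3. $I^2 < 50$ (strict: exactly 50 fails).

$k = 3$ is small for REML; this is inherent to a three-group design and is
why HKSJ inference (rather than a normal approximation) is used
throughout. Leave-one-out pooled estimates are attached for influence
inspection.

## Expression programs

The continuous counterpart to discrete subclusters is a nonnegative
factorization of the cells-by-genes count matrix. The engine is pluggable
— any function returning nonnegative `gene_weights` and `cell_scores`
matrices can be slotted in, so externally trained probabilistic
factorization output is accepted directly — and the default is
multiplicative-update NMF under the generalized Kullback-Leibler
divergence (the objective matched to Poisson counts), 500 iterations,
relative tolerance `1e-6`, seeded initialization. Gene-weight columns are
renormalized to sum to one (scale moved into the cell scores), which makes
the downstream correlation and top-gene rules reproducible.

The number of programs is chosen by the correlation rule: fit every $K$ in
a grid and keep the largest $K$ at which no two factors have a Pearson
correlation above 0.75 between gene-weight columns or between cell-score
columns, compared within each $K$'s own model (the only self-consistent
reading — columns from different $K$ fits are not aligned). "Largest"
is read literally as an argmax over the grid; note that with a noisy
engine an over-parameterized fit can occasionally slip under the ceiling,
so `first_crossing = TRUE` offers the stricter stop-at-first-violation
reading. If no $K$ qualifies, the smallest grid value is returned with a
warning flag. Per-factor reporting takes the five largest-weight genes
among genes with mean pseudobulk CPM strictly above 10 (ties broken
lexicographically). Phenotype associations use the median factor score per
(donor, region) sample in an ordinary least-squares model with the same
covariate rule as the proportion analysis; the per-group output feeds the
same meta-analysis unchanged.

## Taxonomy rules

* **QC**: nuclei are kept when UMIs > 500 and mitochondrial percentage
  < 5, both strict.
* **Merging**: two subclusters are separable when their pseudobulk
  profiles show at least 4 genes with $\log_2$ fold change $> 2$ *and* at
  least 4 with $< -2$ (CPM + pseudocount 1; both directions required,
  which makes the rule symmetric in the pair). While any pair fails, the
  least-separable failing pair (fewest qualifying genes; lexicographic
  tie-break) is merged and everything recomputed — the deterministic order
  makes the procedure idempotent and input-order invariant.
* **Clustering quality**: Calinski-Harabasz and Davies-Bouldin scores in
  their standard Euclidean forms, for selecting among externally produced
  clusterings (the graph clustering itself is out of scope).
* **Marker filter**: FDR < 0.05, mean CPM ≥ 10 (inclusive, unlike the
  factor rule's strict bound — both thresholds are kept exactly as
  specified for their respective uses), $\log_2$FC > 1.
* **Consensus transfer**: the reference is split into 5 seeded folds, one
  classifier per fold (default: nearest centroid on log1p-CPM with Pearson
  similarity; any `function(train_x, train_labels, query_x)` can be
  substituted), and a query keeps its modal label only with ≥ 4 of 5
  votes, otherwise it is `"ambiguous"`.

## Locus accessibility

Pseudobulked ATAC peak counts per (donor, region, cell class) sample are
(1) CPM-normalized within sample, (2) summed over peaks overlapping a risk
locus by at least one base pair (BED half-open convention; prose 1-based
coordinates are shifted on ingest) and divided by the total length of
those peaks, (3) averaged over the samples of each (region, class,
population group) combination with equal sample weights, and (4) divided
by the per-locus maximum so the most accessible combination sits at 1.
"Total length" uses full peak lengths by default; `clip = TRUE` uses
intersection lengths instead — the choice matters only for peaks
straddling locus edges and both are provided because either reading is
defensible.

## Pooled-library demultiplexing

Libraries pool three samples from three distinct donors, designed so no
donor pair recurs across libraries (`validate_design()` checks both).
Identity assignment without reference genotypes works by linking anonymous
per-library genotype clusters across libraries when their variant-allele
fraction vectors agree at ≥ 0.9 concordance over ≥ 100 shared SNPs
(defaults far above the Hardy-Weinberg chance-agreement level for common
variants), taking connected components as putative donors, and matching
each component's library set against the plan; only an exact, unique
fingerprint match assigns a donor. The synthetic generator draws diploid
genotypes at uniform(0.05, 0.5) allele frequencies and corrupts each SNP
independently with probability $e$ through a fixed deterministic miscall
map on $\{0, 0.5, 1\}$, chosen so that two independently corrupted copies
of one genotype agree at a SNP with probability exactly $(1-e)^2 + e^2$ —
a closed form the tests verify.

## Donor subgrouping

Donor feature vectors concatenate within-class subcluster proportions
(left on the simplex) with per-donor median factor scores (z-scaled by
default so high-variance factors do not dominate; configurable off).
Pairwise dissimilarity is $1 - r$ (Pearson), clustered with Ward linkage
via the Lance-Williams recursion applied directly to these correlation
distances — common practice for correlation metrics, documented here as an
approximation since Ward's variance interpretation is Euclidean. The tree
is cut at each candidate $k$; the cut maximizing the median silhouette
width (same distance) is chosen, smallest $k$ on ties. Subgroup
composition is summarized with hypergeometric enrichment tests
($P(X \ge x)$, BH-corrected across subgroup-level pairs). By default the
pipeline subgroups on STG-region features, the region named for this
analysis in the source design; other regions are a config switch.

## What the synthetic data does and does not emulate

The generator reproduces the *statistical* structure the pipeline assumes:
three population groups with configurable demographic imbalance (default:
AA-NL mean age at death 4 years younger), phenotypes driven by one latent
severity variable (so staging measures are mutually correlated),
incomplete region coverage, Dirichlet-multinomial composition noise
(concentration 50 — dispersion $\phi$ in the hundreds at typical sample
depths, matching the strongly overdispersed regime the quasibinomial model
targets), planted log-odds effects that enter the target subcluster's
logit linearly (so recovery against ground truth is exact in expectation
up to the Dirichlet bias term), Poisson factor-structured counts, and
pooled genotype mixtures. Totals per sample are log-normal with median
5,000 nuclei — a stand-in, since no per-sample denominator distribution is
part of the design. It deliberately does **not** emulate transcriptome
biology: no marker-gene structure, ambient RNA, doublets, or
batch effects. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under its assumed data-generating
process, not that those assumptions hold for any particular real data set.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen to keep Monte-Carlo error small relative to each assertion:
null calibration on 3,000 simulated fits (per-fit rejections are
correlated within a cohort, so more than the minimal 1,000 fits are used
to tighten the rate estimate); effect recovery on 200 replicates at 40
donors per group; conservation-flag behavior on 100 replicates;
demultiplexing and subgrouping on 50 seeds; factorization checks at a few
hundred cells and genes. All randomness flows from one seed through
stage-name-hashed substreams, so toggling a stage never perturbs another
stage's draws and pipeline reruns are byte-identical.

Other numerical choices: proportions exactly 0 or 1 are retained (no
continuity correction); REML's $\tau^2$ is floored at zero; the HKSJ
variance ratio is untruncated by default; silhouette ties resolve to the
smallest $k$; merge-rule ties resolve lexicographically; degenerate inputs
(constant features, zero-total samples, folds missing a label) drop with
warnings rather than errors wherever the surrounding analysis can
proceed.

## Known limitations

* The quasibinomial model fits each subcluster separately; it does not
  model the full compositional covariance (a planted increase in one
  subcluster necessarily depresses the logits of the others — visible in
  the generator's ground truth and accepted by the modeling approach).
* REML with $k = 3$ groups estimates $\tau^2$ very noisily; HKSJ inference
  compensates for, but cannot remove, this.
* The default KL-NMF engine is a stand-in for probabilistic count
  factorization: adequate for exercising the selection and reporting
  rules, not a substitute for a fitted hierarchical model on real data.
* The centroid-correlation classifier in the consensus transfer is
  intentionally simple; the consensus protocol, not the classifier, is the
  contribution, and the classifier is pluggable.
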