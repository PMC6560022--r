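---
title: "Network interference models and longitudinal biomarker validation with netmoa"
author: "netmoa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network interference models and longitudinal biomarker validation with netmoa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmoa)
```

## The problem netmoa addresses

A recurring question in systems medicine is whether a drug touches the
molecular processes that drive a disease, and which measurable proteins
could serve as biomarkers of that effect. netmoa implements one complete
route to an answer:

1. Represent the **disease** as a molecular model: the disease-associated
   genes mapped onto a protein–protein interactome, keeping their induced
   interactions.
2. Represent the **drug** the same way: a mechanism-of-action (MoA) core
   built from literature-associated genes, extended by genes found
   deregulated in a treated-vs-control expression experiment.
3. Intersect the two models. The shared nodes and shared interactions —
   the **interference signature** — are the disease processes the drug
   plausibly reaches.
4. Prioritise **candidate biomarkers**: prognostic proteins inside the
   signature, or in close network proximity to it.
5. Validate candidates in a longitudinal trial with a **mixed-model
   repeated-measures (MMRM)** analysis of percentage changes between arms.

Every stage is exercised end to end on synthetic data with known planted
truth, so the statistical behaviour of the pipeline can be verified without
access to any proprietary trial or expression dataset.

## Molecular models on an interactome

An interactome here is an undirected simple graph whose nodes are genes
(identifiers are treated as opaque strings; no namespace mapping is
attempted) and whose edges are protein–protein interactions.

`extractConnectedSubmodel()` maps a gene set onto the interactome and keeps
a gene only if it *shares at least one interaction with another member of
the set*. "Connected" is deliberately interpreted as *non-isolated*
(induced degree ≥ 1), not as membership of a single connected component: a
disease model routinely consists of several mechanistically coherent
clusters, and requiring global connectivity would discard whole clusters
for lack of a bridging edge. A model is therefore an induced subgraph minus
its isolated vertices, possibly with several components.

`extendMoaModel()` grows a literature MoA core by expression evidence. A
non-core gene is added when it

* passes the fold-change threshold (magnitude ≥ 1.2 by default), **and**
* interacts directly with a *deregulated core* gene (a literature gene
  itself past the threshold).

The rule is one-pass: adjacency to another extension gene does not qualify,
so the extension cannot snowball transitively away from the literature
anchor. Edges of the extended model are recomputed as the
interactome-induced edge set on the final nodes, which keeps the
induced-closure invariant (`extractConnectedSubmodel(net, nodes(m)) == m`)
true for every model the package produces.

```{r models}
bench <- syntheticBenchmark()
core <- extractConnectedSubmodel(bench$network, bench$drugLiteratureGenes)
core
moa <- extendMoaModel(core, bench$network, bench$foldChanges)
moa
```

`syntheticBenchmark()` is a deliberately engineered synthetic dataset: of
its 78 drug literature genes exactly 74 are mutually linked, 11 core genes
pass the deregulation threshold, 31 qualifying extension genes exist next
to decoys that each fail exactly one rule, and the disease model shares
exactly 44 genes with the extended MoA model. Because every count is forced
by construction, it pins down the behaviour of each rule, including the
boundary cases (a gene with the right fold change but the wrong neighbour,
and vice versa).

## Fold-change filtering of expression data

Expression data enter as a probe-level `SummarizedExperiment` with positive
intensities, a probe→gene annotation and treated/control group labels.
Three choices deserve justification:

* **Probe summarisation** (`summarizeProbes()`) takes the arithmetic mean
  of a gene's probes per sample. Any location estimate works here because
  the downstream quantity is a ratio of group means; the arithmetic mean is
  the simplest order-invariant choice.
* **Fold change** (`computeFoldChanges()`) is the ratio of arithmetic group
  means on the linear intensity scale, encoded as a *signed* fold change
  (ratio $r$ reported as $r$ when $r \ge 1$, as $-1/r$ otherwise) so that
  up- and down-regulation are symmetric and magnitude is directly
  comparable to the threshold.
* **Selection** (`selectDeregulated()`) is inclusive at the threshold:
  a gene at exactly 1.2-fold is deregulated. A strict-comparison switch
  exists because the two readings ("greater than 1.2" vs "at least
  1.2-fold") differ only on the boundary; inclusive is the default.
  Statistical significance is *not* part of the deregulation rule — the
  filter exists precisely because isolated significance testing in vitro
  yields many features with negligible effect sizes. A Welch test on log
  intensities is attached as an optional column and cutoff for users who
  want both.

On noise-free synthetic data the selected set equals the planted set
exactly; with 5% multiplicative noise, four replicates per arm, and planted
magnitudes ≥ 1.5, sensitivity and specificity both exceed 0.95 — the
log-scale noise of a gene's mean ratio is about
$\sigma\sqrt{2/n_\mathrm{rep}} = 0.035$, far below the
$\log 1.5 - \log 1.2 \approx 0.22$ margin.

## Interference and candidate ranking

`computeInterference()` intersects node sets and edge sets; because both
models are induced on the same interactome, the shared edges equal the
induced edge set on the shared nodes. The operation is symmetric and an
empty signature is a legitimate result, not an error.

`filterPrognosticEvidence()` reduces literature curation to a transparent
table rule. A publication counts for a gene iff it (i) carries the required
disease term as a *major* topic, (ii) carries all required marker/prognosis
terms, (iii) is flagged with at least one allowed study context (human,
animal model, or clinical trial), and (iv) carries no excluded flag —
high-throughput omics profiling studies are excluded by default, since a
gene's appearance in an omics list is weak evidence of prognostic
relevance. Matching is exact string equality after case folding and
whitespace normalisation; no term-hierarchy expansion is attempted, so the
caller's table must already use consistent vocabulary.

`rankCandidates()` tiers prognostic genes by shortest-path distance to the
signature, measured **on the full interactome** rather than within either
model — proximity is meant to recruit mechanistically linked genes that the
models themselves missed. "Close proximity" defaults to distance 1 (a
direct interaction partner); the radius is a parameter, and growing it can
only add candidates. The output ordering (tier, distance, descending
evidence count, gene identifier) is total, making results reproducible
across runs and platforms.

```{r interference}
dkd <- extractConnectedSubmodel(bench$network, bench$diseaseGenes)
sig <- computeInterference(dkd, moa)
sig
head(rankCandidates(sig, bench$network,
                    filterPrognosticEvidence(bench$annotation)))
```

## The MMRM stage

`fitMMRM()` fits, by REML, a marginal linear model to the post-baseline
visits of one biomarker: fixed effects for treatment arm, visit, their
interaction and the baseline level, with an **unstructured**
variance–covariance matrix across each subject's visits (implemented as a
general correlation structure plus per-visit variances). Unstructured
covariance spends a few extra parameters to avoid assuming anything about
how correlation decays between annual visits. All available records
contribute, so subjects with missing visits are retained — the
likelihood-based analysis is valid when missingness is at random (MAR), and
the synthetic dropout mechanism is MAR by construction.

Skewed biomarkers are log-transformed (the default); an untransformed
biomarker is modelled on the percentage-change-from-baseline scale instead,
so that its treatment contrast is already a percentage and the two response
scales report comparable quantities.

`estimateContrast()` reports the arm difference per visit and averaged over
visits. On the log scale a contrast $\delta$ becomes the percentage
difference $100(e^{\delta}-1)$, with confidence bounds transformed the same
way; this back-transform is exact, and on data where one arm is an exact
scaled clone of the other the averaged estimate reproduces
$100(c-1)\%$ to optimizer tolerance. Inference uses two-sided Wald tests
with a normal reference — with hundreds of subjects and a handful of fixed
effects the small-sample degrees-of-freedom correction is immaterial, and
the simulation-based calibration checks (type-I error within [0.03, 0.07]
at nominal 0.05, CI coverage within [0.92, 0.98], at 100 subjects per arm)
are the safeguard that this choice is adequate at the design sizes the
package targets.

One subtlety is worth writing down. The trial generator plants a
within-subject correlation $\rho$ through a subject random intercept on the
log scale. The MMRM conditions on the baseline value, which carries that
same intercept, so the *residual* correlation the unstructured covariance
estimates is not $\rho$ but $\rho/(1+\rho)$ (e.g. 1/3 when $\rho = 0.5$) —
the closed form follows from conditioning a compound-symmetric trivariate
normal on its first coordinate. The parameter-recovery test asserts
agreement with this conditional value.

`correlateChanges()` computes pairwise Pearson correlations of percentage
changes (or achieved levels) at a chosen week over complete pairs, flagging
significance at p < 0.001; a constant vector yields an undefined
correlation and is reported as `NA`, never silently as a number.

`stratifyTertiles()` splits subjects by ranked change into three groups
whose sizes differ by at most one, allocating remainders to the lower
tertiles first and breaking ties by subject identifier — an arbitrary but
fixed convention that makes the labelling order-invariant.
`associateEgfrDecline()` then relates a biomarker's change to subsequent
kidney-function decline: an MMRM on the change in eGFR with treatment and
visit as factors, the biomarker change (continuous, tertile, or named
bands: ≥30% reduction, 0–30% reduction, any increase) and its
visit interaction as covariates, adjusted for baseline age, sex, blood
pressures, BMI, HbA1c, eGFR, log UACR and, when supplied, UACR change.
Least-squares means weight factor levels equally and hold numeric
covariates at their means.

## What the synthetic data do and do not emulate

`simulationConfig()` fixes the study conditions; the generators are pure
functions of (config, seed), with independent derived streams per module.

* **Interactome**: preferential attachment (`attachment` edges per new
  node), giving the heavy-tailed degree distribution characteristic of
  curated interactomes, with a forced edge count of
  $m(n-m)$ and guaranteed connectivity. Defaults: 1000 genes, $m = 2$. The
  real interactome's exact degree distribution is not matched — no
  published constraint pins it down.
* **Expression**: log-normal baseline intensities (meanlog 5, sdlog 1),
  probe affinities (sdlog 0.3), multiplicative treatment effects on planted
  genes and log-normal noise (default sd 0.05 on the log scale, about a 5%
  coefficient of variation, typical of technical replicates on two-colour
  arrays); four replicates per arm by default. No probe-sequence effects,
  spatial artefacts or background correction are modelled — the pipeline
  consumes normalised intensities by contract.
* **Trial**: three visits (weeks 0, 52, 104), 100 subjects per arm,
  multiplicative arm×visit effects (default: treated arm at 0.75 of
  control), log-scale total standard deviation `trialSd = 0.4` (≈ 40%
  between-measurement CV, realistic for plasma inflammation markers) split
  between a subject intercept and visit residuals so that any two visits of
  a subject correlate at `withinSubjectCorr` (default 0.5). Covariates are
  drawn from fixed plausible distributions for a type 2 diabetes
  population. Longitudinal eGFR is generated with a mild background decline
  and an optional planted linear dependence on a biomarker's log change.
  Dropout is optional, monotone and missing-at-random.

Passing tests on these data demonstrate the *statistical machinery* —
recovery of planted truth, calibration of tests and intervals — not the
biology of any particular disease or drug: real literature curation, real
interactome coverage and real assay behaviour are all outside what the
generators emulate.

## Numerical and design choices

* Problem sizes in the test-suite simulations: 500-gene interactomes and 20
  seeds for expression recovery; 100 subjects per arm and 500 replicates
  for contrast calibration (300 in the acceptance script); 1000 replicates
  of 50 subjects for the correlation flag. These sizes put Monte-Carlo
  error well inside the asserted bands.
* Edges are stored with lexicographically ordered endpoints and sorted
  rows, so edge sets compare as plain character vectors and serialised
  output is canonical.
* Degenerate inputs fail loudly: empty gene sets, non-positive intensities,
  thresholds below 1, a single post-baseline visit, arms or visits with
  fewer than two subjects, and correlations outside $[0,1)$ are errors, not
  warnings. Unknown genes in input sets are the one tolerated
  irregularity — dropped with a warning — because literature-derived
  identifiers routinely miss an interactome.
* Seeds are 32-bit integers; derived stream seeds are reduced modulo
  $2^{31}-1$.
* No multiplicity adjustment is applied across biomarkers in the contrast
  stage, matching the unadjusted two-sided p < 0.05 convention of the
  analyses the package supports; users who need it can apply `p.adjust` to
  the returned p values.

## Known limitations

* Interference treats all edges equally; no centrality, edge-confidence or
  co-expression weighting (deliberately out of scope).
* The annotation filter does no ontology expansion — synonyms must be
  normalised upstream.
* Wald/normal inference can be liberal in very small trials (tens of
  subjects); the calibration evidence covers the hundred-per-arm regime.
* The eGFR association model reuses the unstructured-covariance MMRM; no
  alternative covariance structures are exposed.
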