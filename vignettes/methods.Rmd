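---
title: "Methods: qPCR co-expression networks and the M-value activity score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR co-expression networks and the M-value activity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(takcoex)
```

## Scope and model

`takcoex` analyses targeted RT-qPCR panels measured in small clinical
cohorts, built around the design of a Takayasu's arteritis (TAK) study: a
29-gene panel spanning Toll-like receptor (TLR) signalling and T-cell
activation/differentiation, profiled in five condition groups (healthy
controls and untreated/treated patients split by disease activity).  The
chain is:

1. reference-gene stability assessment and selection;
2. relative quantification by $2^{-\Delta\Delta C_q}$;
3. per-condition gene–gene correlation and hard-thresholded co-expression
   networks with topology statistics;
4. complete-linkage clustering with fixed-height module extraction;
5. a regression-residual ("M-value") disease-activity score;
6. a three-metric score of each gene's functional closeness to the TLR set;
7. a miRNA-target network builder with family pooling.

Every stage is driven either by user data (Cq TSV + sample CSV) or by the
synthetic cohort generator, so the full pipeline is testable without
patient data.

## Quantification

With amplification efficiency fixed at 2 (no efficiency correction — the
panel protocol this package mirrors used plain $2^{-\Delta\Delta C_q}$),
log2 expression equals $-C_q$ up to per-gene constants.  Consequently:

* **geNorm** $M_j$ is the mean over partners $k$ of
  $\mathrm{SD}_\text{samples}(C_{q,k} - C_{q,j})$; it is invariant to
  per-gene constant shifts, i.e. to primer-efficiency offsets.
* **NormFinder** is implemented as a variance decomposition on
  sample-centred $C_q$: per gene, the mean over groups of
  (|intergroup bias| + intragroup standard error).  We omit the original
  publication's shrinkage of the bias estimate; with the panel sizes in
  scope (6–20 samples/group) the ranking is driven by the raw components.
  With a single group the intergroup term is undefined and the function
  falls back to the intragroup SD, flagged `intragroup_only`.
* **BestKeeper** reports per-gene SD/CV of $C_q$ and Pearson correlation
  with the per-sample candidate mean (the log-scale equivalent of the
  geometric-mean index), with the conventional 1-cycle SD advisory flag.

The two references are the pair with the best mean rank across the three
methods (the study this mirrors reports chosen pairs but no aggregation
rule; a plain mean of ranks is the least-structured choice).  Ties resolve
by geNorm M, then gene name.  The calibrator defaults to the mean
$\Delta C_q$ of the healthy-control group — the study does not name its
calibrator, and a group-mean calibrator keeps single-sample outliers out
of the denominator; it is configurable to any sample set.

Downstream correlation and clustering consume $2^{-\Delta\Delta C_q}$
values.  Spearman results are identical on $-\Delta C_q$; Pearson results
are not, and the exponential scale is what the mirrored analysis used.

## Group statistics

`mann_whitney()` defaults to the *exact two-tailed* rule of legacy
clinical software (SPSS): twice the lower tail of the tie-free exact U
distribution at $\lfloor\min(U, n_1 n_2 - U)\rfloor$, clamped at 1.  This
choice is pinned by reproduction: it matches all seven printed
demographic p-values of the packaged 27-patient table (0.82, 0.1, 0.33,
0.02, 0.1, 0.66, 0.37) at printed precision, whereas the tie-corrected
continuity-corrected normal approximation — also available as
`mode = "normal"` — gives 0.34 for ESR and 0.35 for prednisone.  With
ties present the tie-free null is an approximation and the result carries
a note.  `chi_square()` is the uncorrected Pearson statistic on a 2×2
table: with Yates correction the cohort's 9F/0M vs 10F/1M sex comparison
gives p = 1.0 rather than the printed 0.35.  `ks_normality()` tests
against a normal with fitted mean/SD and records the Lilliefors caveat
(anti-conservative p).  No multiplicity adjustment is applied by default
anywhere (raw p-values are what the mirrored analysis reports);
`differential_expression(adjust = "BH")` opts in.

## Networks

Correlation p-values use the t approximation on $n-2$ df for both Pearson
and Spearman (average ranks for ties); $|r| = 1$ is reported as p = 0
rather than an error.  Networks take every pair passing the threshold —
the loose rule is p < 0.05, the strict rule $|r| > 0.73$ *and* p < 0.01 —
as undirected edges; isolated genes remain nodes, so all topology metrics
are computed over the full 29-gene panel.  Edge identity ignores the
correlation sign (a "relation" is a relation whether positive or
negative); the sign is carried as an attribute.

Topology follows the Cytoscape network-analyzer conventions, which is
what makes printed values from that tool comparable: shortest paths by
BFS; characteristic path length and diameter over *connected pairs only*
(a disconnected sparse network therefore has a finite, and possibly
short, path length — see the generator discussion below); mean local
clustering coefficient with degree < 2 nodes contributing 0.  Whether
isolated nodes should enter the clustering-coefficient average is not
stated in the mirrored tables; we follow the Cytoscape default (they do,
as zeros), and note that excluding them raises every reported coefficient
roughly proportionally without affecting between-condition direction.

## Clustering

Gene and sample clustering uses the sign-sensitive correlation distance
$d = 1 - r \in [0, 2]$, *not* $1 - |r|$: the inactive-stage trees must
place the anti-correlated TLR and T-cell blocks in separate top-level
clusters, which only a sign-sensitive distance can do.  Agglomeration is
complete linkage; leaves are sorted alphabetically before merging so
distance ties resolve identically on every platform.  Modules are read
off at cut height 1.0 (sub-structure at 2.0) — heights on the $1-r$ scale
mean "clusters whose members correlate positively" (within-cluster
cophenetic distance below 1).  The printed five-cluster partitions of the
mirrored study cannot be reproduced without its raw data; cluster counts
at a fixed height on synthetic data are structure-dependent, so counts
are descriptive, not acceptance targets.

`sample_separation()` reports the fraction of a focal class contained in
maximal pure subtrees of at least two leaves.  The 2-leaf floor is what
makes the statistic informative: every singleton leaf is trivially
"pure", so without the floor the fraction would always be 1.

## The M-value activity score

Pairs with $|r| > 0.73$, p < 0.01 in the *fit group* (inactive-treated
patients) define ordinary least-squares lines $y = \beta x + \alpha$,
with $y$ the second-named gene (the mirrored description "relating the
TLR6 level to the TLR4 level" fixes $y$ = TLR6, $x$ = TLR4; the
orientation is configurable).  A patient's M-value for a pair is the
relative prediction error $M = |(\hat y - y)/y|$; it is invariant to
common rescaling of both genes.  Per-pair thresholds maximize the Youden
index over midpoints between consecutive sorted unique M-values (ties:
higher sensitivity, then lower threshold; the mirrored study's "adjusted
when appropriate" is irreproducible, so thresholds here are strict
maximizers with a manual override).  A score of 1 (inactive-like) is
given when M is below the pair threshold; the total is the sum over
available pairs, and the final call is inactive when the total reaches
the Youden-chosen total threshold.  The standalone TLR4–TLR6 model in the
mirrored study scores in the opposite direction (1 = active, M above
0.173); both conventions exist in the API via the threshold direction
argument.  ROC metrics are in-sample (no cross-validation), matching the
mirrored analysis; AUC is the rank-concordance probability and equals
$U/(n_1 n_2)$ exactly, which the suite asserts.  The ROC can be computed
on either the total score or the binary call; the printed
sensitivity/specificity pairs are consistent with thresholding the total
score, which is the default reported.

## TLR closeness

Three counts per gene, one point per gene per metric: (i) TLR neighbours
in the network — the *loose* p < 0.05 network, because the mirrored counts
include co-expressions with p ≈ 0.04 that the strict rule would drop;
(ii) neighbours shared with the TLR set pooled into a single node,
excluding the probe gene and the TLRs themselves (this exclusion is
pinned by reproducing the printed BCL6 count of 4 shared genes, none of
which is a TLR); (iii) TLRs in the gene's height-1.0 cluster.  Whether
metric (ii) should read the loose or strict network is unstated; the
loose network is the default for consistency with (i), and the choice is
exposed.

## miRNA-target networks

Target maps are file inputs (two-column TSV or GMT-like), never live
database queries — prediction databases drift between versions, so any
printed degree ranking is version-bound.  The pipeline keeps miRNAs
targeting ≥ 2 panel genes (applied after restriction to the analysed
panel, matching the mirrored network's gene universe; configurable),
pools families with ≥ 2 members into one node with the union of targets,
ranks by target count (ties alphabetical), and emits the bipartite
network of nodes with degree ≥ 3 or a differential-expression flag.
`mirna_fold_change()` is an explicitly labelled stand-in (normalized-mean
ratio + Mann–Whitney) for a proper count-model DE method, which is out of
scope.

## The synthetic cohort generator

`generate_cohort()` draws per-condition $\Delta C_q$ vectors from a
multivariate normal whose correlation matrix is a two-block
equicorrelation structure: `within_block_r` inside the 13-gene TLR block
and the 16-gene T-cell block, `between_block_r` across them, marginal SD
`delta_sd` (1 cycle), plus technical noise (`noise_sd` 0.25 cycles) and a
baseline of 22 cycles.  Correlations are induced on the $\Delta C_q$
(log2-expression) scale, so Pearson correlations of the derived
$2^{-\Delta\Delta C_q}$ values are monotone-related and Spearman is
invariant.  Reference candidates are drawn independently with per-gene
stability SDs (B2M and YWHAZ planted best).  Observed-Cq correlations are
attenuated relative to the configured values by
$1/(1 + \sigma_\text{noise}^2/\sigma_\Delta^2) \approx 0.94$; the
generator returns the latent draw so moment checks can target the
configured matrix directly.

Defaults state the cohort world: group sizes 10/3/4/9/11; inactive-treated
within-block r 0.90 with between-block r −0.85 (the inverse TLR-vs-T-cell
signature, at the strength of the printed pair correlations, |r| ≈
0.85–0.90); healthy controls and untreated groups weakly structured
(within 0.35, between 0.10); active-treated within 0.80 with between
+0.55.  Two of these are constrained choices worth recording:

* The 13×16 two-block equicorrelation matrix with between −0.85 is only
  positive semi-definite when within ≥ ~0.83, so the inactive within
  default is 0.90; requesting infeasible combinations triggers eigenvalue
  clipping, which is logged, and is rejected outright if the repair moves
  any correlation by more than 0.1.
* The active-treated defaults were calibrated once against the printed
  topology profile of the mirrored study's active network (72 edges,
  clustering 0.549, path length 2.333 — denser and more clustered than
  the control network, with the TLR and T-cell programs co-varying
  positively, as that study's merged active cluster shows).  A weakly
  bridged active network (between ≈ 0.3) has *longer* finite-pair path
  lengths than a fragmented control network, inverting the expected
  direction — an artefact of the connected-pairs convention on
  equicorrelated draws, not of the analysis code.

What the generator does **not** emulate: heterogeneous per-pair
correlation strength (real panels have hubs and chains; equicorrelated
blocks make island-or-clique networks, which is why control-network path
lengths here are shorter than the mirrored study's 3.27), plate/batch
effects, amplification-efficiency variation, and count-based miRNA
sequencing noise.  A green synthetic test therefore establishes that the
*algorithms* recover planted structure, not that real cohorts have that
structure.

Clinical covariates are drawn per condition from log-normal/normal
distributions with locations matching the magnitudes of the packaged
patient table (hs-CRP and ESR elevated in active groups, prednisone zero
off treatment); missingness is configurable and never applied to
condition labels.

## Numerical and testing choices

* Fixed seeds everywhere; identical config + seed is byte-identical
  output, including the pipeline manifest (no timestamps).
* The regression-recovery property (fitted line within 3 SE of the
  planted one in ≥ 99% of simulations) is assessed at fit size 30: at the
  cohort's n = 9 (7 df) a ±3 SE band jointly covers only ~96% by
  Student-t tail mathematics, so the 99% bar cannot be met at that n by
  any correct implementation.
* Simulation-based power examples use a per-gene biological scatter of
  0.5 $C_q$ cycles (sdlog = 0.5 ln 2 on the expression scale), a typical
  qPCR panel scatter; a 2-fold shift is then a ~2 SD effect.
* The Mann–Whitney exact rule has attainable size ≈ 0.046 at n = 9 vs 11,
  inside the 0.05 ± 0.02 calibration band asserted by the suite.
* Degenerate inputs fail loudly and early: zero-variance regressors,
  single-class ROC labels, zero margins in 2×2 tables, all-missing
  groups, non-symmetric distance matrices, mixed-method correlation sets.

## Known limitations

The mirrored study's raw 29-gene expression matrix is not deposited, so
its headline results (AUC 0.939/0.919, the exact topology table, the
five-cluster memberships, the 35/39 differential-edge counts, printed
correlation coefficients, miRNA fold changes) are reference points, not
reproduction targets; the package reproduces everything recomputable from
printed tables (demographics, closeness arithmetic, cluster sizes) and
validates the rest by property-based testing against independent oracles.
Reference-gene choice materially affects correlation structure (the
mirrored study itself used different pairs for different comparisons
without stating a rule); the pipeline supports per-comparison reference
sets but does not guess one.
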