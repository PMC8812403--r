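# takcoex

Gene co-expression network analysis of targeted RT-qPCR panels for
disease-activity assessment in Takayasu's arteritis (TAK).

## The problem

TAK is a large-vessel vasculitis whose activity is hard to stage
biochemically.  One line of evidence comes from small targeted qPCR
panels measured in PBMCs: in treated patients at remission, the
Toll-like-receptor gene program (TLR1/2/4/6/8, BCL6, NR4A1, ...) and the
T-cell activation/differentiation program (TCR, CD28, T-bet, FOXP3,
CCL5, ...) are strongly *inversely* co-expressed, a signature that
vanishes in active disease.  That makes co-expression itself — not
expression level — the biomarker.  `takcoex` implements the full analysis
chain such a study needs, for anyone running targeted panels in small
clinical cohorts:

* **Reference-gene stability**: geNorm ($M_j = \overline{\mathrm{SD}(C_{q,k}-C_{q,j})}$
  with stepwise exclusion), NormFinder (intergroup-bias + intragroup-variance
  decomposition), and BestKeeper (SD/CV and index correlation), plus a
  mean-rank aggregate and pair selection.
* **Relative quantification**: $2^{-\Delta\Delta C_q}$ against the chosen
  pair and a calibrator group.
* **Co-expression networks**: per-condition Pearson/Spearman correlations
  with t-based p-values; hard thresholds (p < 0.05 and |r| > 0.73 ∧
  p < 0.01); topology statistics (mean degree, diameter, clustering
  coefficient, characteristic path length) under Cytoscape conventions;
  gained/lost edges and multi-condition edge overlap.
* **Module extraction**: complete-linkage clustering on the
  sign-sensitive distance $d = 1 - r$, cut at heights 1.0 / 2.0;
  sample-separation scoring.
* **M-value activity score**: least-squares lines fitted to highly
  co-expressed pairs of the inactive-treated group; per-patient relative
  error $M = |(\hat{y}-y)/y|$; Youden-index thresholds; summed
  multi-pair score with ROC/AUC (AUC ≡ U/(n₁n₂)).
* **TLR closeness**: the three-metric count (co-expressed TLRs, shared
  neighbours with the pooled TLR node, TLRs in the same cluster), one
  point per gene per metric.
* **miRNA-target networks**: multi-target filtering, family pooling
  (union of member target sets), degree ranking, degree-or-DE filtered
  bipartite network.
* **Synthetic cohorts**: a generator that emulates the study design
  (group sizes 10/3/4/9/11, two correlated gene blocks, between-block
  r = −0.85 only in inactive-treated, reference genes of controlled
  stability, clinical covariates), so everything above is testable
  without patient data.

A packaged fixture ships the study's printed 27-patient clinical table;
the demographic statistics computed from it reproduce the printed
p-values exactly (hs-CRP 0.02, ESR 0.33, age 0.82, duration 0.1, sex
0.35 between the treated subgroups).

## Worked example

```r
library(takcoex)
man <- run_pipeline(pipeline_config(outdir = "takcoex_run", seed = 42))
pipeline_report(man)
```

```
takcoex pipeline report (seed 42)
stages run: simulate, quantify, stats, network, cluster, score, closeness
reference genes: B2M + YWHAZ

network topology (p < 0.05 networks):
  condition            nodes edges avg.neigh diameter clust.coef  char.path
  HC                      29    34     2.345        7      0.211      3.194
  untreated-inactive      29    20     1.379        2      0.379      1.200
  untreated-active        29    29     2.000        7      0.290      2.663
  treated-inactive        29   245    16.897        3      0.799      1.401
  treated-active          29   203    14.000        5      0.753      1.754

TLR-closeness (top genes):
  gene       coexpr.    common   cluster  total
  TIM3             5        19         5     29
  IkBa             4        19         5     28
  ...

combined M-value score: AUC 1.000, sens 100.0%, spec 100.0%
```

Reading the output: the generator planted weak correlation in healthy
controls and strong block structure in treated groups, so the treated
networks are denser (245/203 vs 34 edges), more clustered (0.80/0.75 vs
0.21) and shorter-pathed (1.40/1.75 vs 3.19) — the qualitative direction
the real cohort shows.  The stability stage recovered the two reference
genes planted as most stable (B2M, YWHAZ).  The scoring stage selected
the four strongest inactive-group pairs, fitted their regression lines,
and the summed M-value score separates the synthetic active from
inactive patients perfectly here (in the real study: AUC 0.939 for the
4-pair score).  The closeness table ranks genes by proximity to the TLR
set; on synthetic data the block structure makes whole blocks score
high, whereas the real cohort singles out BCL6 (12), CCL5 (11), ...

Individual stages are plain functions — e.g.

```r
tab <- load_clinical_table()
treated <- tab[tab$condition == "treated", ]
mann_whitney(treated$hscrp_mg_l[1:9], treated$hscrp_mg_l[10:20])
#> mann-whitney-exact: statistic = 16, p = 0.01721 (n = 9/10)
```

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and oracle
  tests plus `test-acceptance.R`; `scripts/acceptance.R` — the report;
  `inst/extdata/` — printed-table fixtures (clinical table, cluster
  memberships, closeness components); `vignettes/methods.Rmd` — the
  methods notes (model, conventions, generator design, limitations).
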