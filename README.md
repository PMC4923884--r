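# modnet

Gene networks from expression data, with adaptive functional module
partition and a survival/classification evaluation harness.

## What it does, and for whom

Cancer transcriptome studies often need gene networks that reflect *that
cancer's* expression program, not the interactions shared across diseases
in curated databases.  modnet is for analysts who have a genes × samples
expression matrix (microarray or processed RNA-seq) plus per-sample
survival annotation, and who want to:

1. estimate a gene–gene network from the expression data alone,
2. partition it into functional modules, and
3. ask whether those modules' expression profiles stratify patient risk
   and predict outcome.

## The model in brief

With `S` the empirical covariance of `P` genes over `N` samples and
`θ = Σ⁻¹` the precision matrix of an assumed Gaussian model, the network is
estimated by maximising the penalised log-likelihood

```
log det θ − tr(Sθ) − ρ‖θ‖₁
```

(the graphical lasso).  Zero entries of `θ` encode conditional
independence, so edges are the nonzero off-diagonal entries — well-defined
even when `P > N`, where `S` itself is singular.  The penalty `ρ` is chosen
on the fixed grid 0, 0.1, …, 1.0 as the smallest value whose network still
admits a *seed module set* (two or more disjoint hub neighbourhoods),
i.e. the densest network the partition algorithm can work with.

The partition is hub-seeded: the top-20-degree genes seed one module each
(hub + direct neighbours); every maximal collection of pairwise-disjoint
seed modules grows a candidate partition by repeatedly merging each
remaining module into the candidate with the largest current overlap; the
partition with the smallest average pairwise overlap
`E = Σ_{a<b} |c_a ∩ c_b| / C(α,2)` wins.

Modules are then evaluated by two-group hierarchical clustering plus a
log-rank survival comparison (with a random-gene-set Monte-Carlo null) and
by 100× re-sampled SVM classification on 30 SVM-RFE-selected genes
(1:1 class balance, 4:1 train/validation split, 5-fold-CV grid search),
reported as SEN/SPC/ACC/MCC.

## Worked example

Everything below runs on synthetic data with known ground truth; no
downloads are needed.

```r
library(modnet)

# a 30-gene model with two planted hub modules (9 genes each),
# sampled at 1000 patients per risk class
model <- make_model(p = 30, n_hubs = 2, hub_degree = 8, seed = 42)
dat   <- sample_expression(model, n_per_class = 1000, seed = 7)

scan <- penalty_scan(dat$expression, k = 2)
scan
#> Penalty scan: selected rho = 0.1
#>  rho n_edges n_nodes_degree_ge1 has_seed_set converged
#>  0.0     435                 30        FALSE      TRUE
#>  0.1      26                 29         TRUE      TRUE
#>  0.2       8                 11         TRUE      TRUE
#>  0.3       0                  0        FALSE      TRUE
#>  ...

part <- partition_network(scan$network, k = 2)
part$best[[1]]
#> Module partition from seeds {g01, g10}: 2 modules, E = 0
#>   g01: 9 genes
#>   g10: 9 genes
```

Reading: at `ρ = 0` the singular-free inverse keeps all 435 possible edges
(no structure, no seed set); `ρ = 0.1` is the smallest penalty whose
network admits disjoint hub modules, so it is selected; the partition
recovers the two planted 9-gene stars exactly, with average overlap 0
(perfectly separated modules).

Classification of the risk classes from one module's expression:

```r
m <- classification_metrics(confusion_matrix(TP = 13, TN = 192,
                                             FP = 19, FN = 13))
round(unlist(m), 3)
#>   SEN   SPC   ACC   MCC
#> 0.500 0.910 0.865 0.375
```

A command-line interface wrapping the same functions ships in
`inst/cli/modnet.R` (subcommands `simulate`, `degs`, `network`,
`partition`, `evaluate`, `pipeline`).

## Package layout

* `R/` — expression/annotation I/O and risk labelling; t-test DEG filter;
  graphical-lasso solver and penalty scan; network construction and
  degree diagnostics; the partition algorithm; clustering/log-rank,
  SVM-RFE and re-sampling evaluation; the synthetic generator; the
  pipeline driver.
* `vignettes/modnet-methods.Rmd` — the model, its assumptions, defaults
  and their rationale, and known limitations.
* `tests/testthat/` — unit, property and acceptance tests, including
  independent oracles (a proximal-gradient reference solver, exhaustive
  seed-set enumeration, hand-computed log-rank tables).
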