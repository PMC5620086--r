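---
title: "Methods: mixed-model association mapping and network assembly in startlenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model association mapping and network assembly in startlenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlenet)
```

## The model

startlenet maps the genetic architecture of a quantitative trait — the
motivating application is startle-induced locomotion, measured as seconds of
activity in the 45 s after a mechanical disturbance — in panels of fully
inbred lines such as the Drosophila Genetic Reference Panel (DGRP). Every
line is homozygous at every SNP, each line is phenotyped in both sexes, and
transcript abundance is available per line and sex. The observation for line
$k$ in sex $h$ is modelled as

$$
y_{kh} = \mu + \sum_i q_i u_{ik} + \sum_{i<j} qq_{ij}\, u_{ik}u_{jk}
       + e_h + \sum_i qe_{ih}\, u_{ik} s_h + \sum_{i<j} qqe_{ijh}\, u_{ik}u_{jk} s_h
       + \varepsilon_{kh},
$$

where $u_{ik} \in \{+1, -1\}$ codes the major/minor homozygote at locus $i$,
$s_h$ is the sex contrast ($+1$ female, $-1$ male), $q_i$ are additive locus
effects, $qq_{ij}$ epistatic pair effects, $e_h$ the sex main effect and
$qe$, $qqe$ the locus-by-sex and pair-by-sex interactions. The same model is
reused with transcript abundance as the response (eQTL-style layers) or with
standardized transcript abundances as predictors.

Conventions this package fixes (the field often leaves them implicit):

* **Genotype coding** $+1$/$-1$ for major/minor homozygote, epistasis as the
  elementwise product. Balanced designs are then orthogonal, and a pair
  coefficient for codes $(+1, -1)$ is $-1$.
* **Sum-to-zero sex coding**: $e_{\text{male}} = -e_{\text{female}}$, so
  $\mu$ is the grand mean. A single number per locus (the female-side
  effect) parameterizes each $qe$ term; the male-side effect is its
  negative.
* **Observation unit**: line-by-sex means (two observations per line). The
  model has no replicate term, so replicates are averaged by default;
  replicate-level fitting is available via
  `design_spec(observation_unit = "replicates")`.
* **Transcript predictors** are standardized to mean 0, SD 1 within each
  sex, so effects are comparable across transcripts; reported records also
  carry the raw-scale conversion.

## Variance components and heritability

Phenotypic variance is partitioned as
$V_P = V_Q + V_{QQ} + V_{QE} + V_{QQE} + V_\varepsilon$.
Each genetic component is the *population* (divide-by-$n$) variance of the
summed fitted contributions of its term group across observations, and
$V_\varepsilon$ is the mean squared residual; $V_P$ is defined as their sum,
so the decomposition identity is exact and a noise-free fit gives total
heritability exactly 1. Heritabilities are the component shares,
$h^2_Q = V_Q / V_P$ and so on, with
$h^2_T = h^2_Q + h^2_{QQ} + h^2_{QE} + h^2_{QQE}$.

The per-locus heritability scaling deliberately uses the empirical variance
of each term's own fitted contribution over $V_P$. Under balanced $\pm 1$
coding this reduces to $q_i^2 / V_P$; the degrees-of-freedom scaling that
sometimes appears in this decomposition is never defined numerically in the
literature the package follows, so the empirical convention — which keeps
per-term and group components consistent — was chosen.

The determination coefficient $R^2_{\hat G \to Y}$ is the squared Pearson
correlation between the total predicted genotypic values (all genetic terms;
intercept, sex main effect and residual excluded) and the observed response.

## Two-step detection and experiment-wise error

Detection follows a two-step strategy:

1. **Pre-screen.** Every predictor is tested alone in the single-locus model
   (main + sex + locus-by-sex), and candidates are retained at nominal
   $P < 0.001$ on the joint 2-df locus test. This plays the candidate-
   reduction role of the original study's screening step; the screening
   algorithm used there (GMDR) is configuration-unreported and out of scope,
   so an equivalent single-locus F-test screen at the same threshold stands
   in its place.
2. **Permutation-calibrated thresholds.** Line labels of the response are
   permuted (both sex observations of a line move together, preserving the
   sex main effect under the null), all per-term F statistics are recomputed
   over the *full* predictor set, and the maximum is recorded per
   permutation. The critical F at $\alpha_{EW}$ is the
   $\lceil (1-\alpha_{EW}) B \rceil$-th order statistic of the $B$ null
   maxima, and experiment-wise P values use add-one smoothing,
   $P_{EW}(F) = (1 + \#\{\text{null maxima} \ge F\}) / (B + 1)$, so no
   reported P is ever zero.

Calibrating the null on the full predictor set (rather than on the
pre-screened candidates) is essential: candidates are selected *because*
they look significant, so a null built only over them would be far too
small and the family-wise error would balloon. With the full-set null the
declared set is, up to the pre-screen's mild extra conservatism, the set of
predictors whose statistic exceeds a genuine genome-wide threshold, and the
family-wise type-I error is controlled at $\alpha_{EW}$. The package's
acceptance suite verifies this empirically: on 200 null panels (100 lines,
200 SNPs, pure-noise phenotypes, 200 permutations each) the fraction of
panels declaring any locus is required to stay within two binomial standard
errors of 0.05.

The 1D scan therefore reports, per candidate, the same marginal per-term
statistic the permutation recomputes. The 2D scan tests every candidate
pair (up to a configurable budget) in the two-locus model — both mains,
both sex interactions, the product term and its sex interaction — with a
dedicated permutation null of the max pair statistic. Final model selection
is forward inclusion of all terms passing their critical F (mains before
pairs), with perfectly collinear survivors resolved by keeping the smaller
genomic position, followed by backward elimination that refits the joint
model and drops the weakest term until every survivor stays experiment-wise
significant. An empty selection (intercept + sex) is a valid outcome.

**Significance tiers.** Records are labelled `ew_high` when
$-\log_{10} P_{EW} \ge 5$ and `ew_significant` otherwise; a secondary
reporting tier at $-\log_{10} P_{EW} \ge 3$ is used when collecting edges.
Note that the permutation estimator floors $P_{EW}$ at $1/(B+1)$: with the
default $B = 2000$ the floor is $-\log_{10} P_{EW} \approx 3.30$, so the
`ew_high` tier is only reachable with $B \ge 10^5$ permutations. This is an
honest property of the permutation estimator, not a defect: at desk scale
the reporting tier is the operative one.

## Effect estimation

Detection is frequentist; reported effect sizes come from a Gibbs sampler on
the selected model — mirroring the split in the original analysis between
permutation-calibrated F tests and MCMC effect estimates. The sampler places
zero-mean normal priors with a common variance per term group (main, pair,
qe, qqe) and inverse-gamma hyperpriors (shape = rate = 0.001) on those group
variances and on the residual variance; the intercept and sex terms get an
essentially flat prior (variance $10^8$). Defaults are 20,000 iterations,
10% burn-in, thinning 10. Under these vague priors the posterior means agree
with least squares to within Monte-Carlo error (a standing test), and a
split-chain potential-scale-reduction diagnostic above 1.1 raises a warning.

## The four layers and the network

`run_full_study()` chains the layers: QTS (SNP to phenotype), QTT
(transcript to phenotype), then for each significant QTT transcript, tQTS
(SNP to transcript) and tQTT (other transcripts to that transcript, the
target always excluded from its own predictor set). SNP hygiene filters run
first: minor allele in at least 4 lines, called in at least 60 lines (a
per-SNP `called_lines` metadata column is honoured; inbred panels here have
no missing calls), and chromosome 4 excluded; X-linked SNPs are retained by
default with an autosomes-only switch. The original study's read-coverage
filter (between 2X and 30X) is a property of the raw calls, unavailable from
a genotype matrix, and is therefore only expressible through the metadata
column.

The assembled network has typed nodes (snp, transcript, phenotype,
epistasis_junction) and directed predictor-to-target edges annotated with
layer, effect, sign class, sex pattern (`both_same_sign_positive`,
`both_same_sign_negative`, `female_pos_male_neg`, `male_pos_female_neg`),
tier and a width mapping $|\text{effect}|$ linearly onto $[0.5, 5]$ (all
widths 2.75 when effects are all equal). An epistatic pair is a junction
node with two incoming source edges and one outgoing effect-carrying edge,
always degree 3 — the "Y" rendering — because standard graph formats have
no hyperedges. Edges are directed because the statistical model is
asymmetric, even though such networks are often drawn undirected. Sign and
sex-pattern semantics are stored as categorical attributes, not render
colours; plotting is a thin optional layer. Exports (GraphML via igraph,
SIF, JSON node-link) are deterministic and the GraphML/JSON round-trips are
lossless.

## The synthetic-data generator

`sim_config()` + `simulate_genotypes()`/`simulate_expression()`/
`simulate_phenotype()` emulate the structure of a DGRP-like panel at reduced
scale: fully homozygous biallelic calls with no missing data, minor allele
in at least 4 lines (sites are repaired after simulation if a draw falls
below the floor), two sexes, two phenotype replicates per line and sex, and
a phenotype on the scale of the 45 s assay. Defaults are 156 lines — the
panel size of the motivating study — with 500 SNPs and 100 transcripts as a
desk-scale stand-in for its 5.2 M SNPs and 10,122 transcripts.

Design choices:

* **Linkage disequilibrium** is simulated by block-wise copying: SNPs in a
  block share a base minor-line set, each copy flipping lines with a small
  mutation probability. `ld_block_size = 1` gives independent SNPs. This is
  the simplest correlation structure whose strength is directly
  controllable; it makes no attempt at population-genetic realism
  (no selection, demography or recombination maps).
* **Expression truth** is restricted to directed acyclic
  transcript-on-transcript structures, evaluated in topological order: the
  real network is a reported association structure, not a generative model,
  and a DAG is the weakest generative assumption that makes the truth
  well-defined.
* **The phenotype is not clipped by default.** The generating model is
  linear-Gaussian so parameter recovery is exact in expectation; the
  \[0, 45\] s assay bound can be enforced (`bound_phenotype = TRUE`), and a
  warning is raised whenever the truth implies out-of-range means.
* Residual SDs default to 2 s (phenotype) and 1 abundance unit
  (expression) — of the order of the replicate spread in startle assays and
  array noise, and the reference scale for "effects of one residual SD" in
  the recovery experiments.

Because the generator *is* the study condition for every simulation-based
claim, passing tests show parameter recovery and error control under
homozygous, complete, linear-Gaussian data with modest LD. They do not
speak to missing calls, residual heterozygosity, heavy-tailed phenotypes,
strong population structure or microarray normalization artefacts — real
DGRP data are supported through the readers, not re-analyzed here.

## Standing experiments and their problem sizes

Two simulation experiments are packaged as functions so the tests and the
acceptance script run identical code:

* `null_fwer_experiment()`: 200 null panels of 100 lines by 200 SNPs with
  pure Gaussian noise phenotypes, 200 permutations per panel at
  $\alpha_{EW} = 0.05$ — the empirical family-wise error of the full
  two-step scan, required to stay at or below 0.05 plus two binomial SEs.
* `recovery_experiment()`: panels of 300 lines, 100 SNPs, 30 transcripts
  with three additive QTS (2 s at residual SD 2 s), two QTTs driven by
  strong cis effects of two of those QTS, and two transcript-regulator
  edges (1.5 units at expression residual SD 1). Effects are planted at
  common variants (minor allele in at least 25% of lines): at a minor
  allele carried by 4 of 300 lines the $\pm 1$ code has variance near
  0.05, so a nominally one-SD coefficient would contribute almost no
  phenotypic variance and the experiment would be testing the allele draw,
  not the method. Over 25 seeds the pipeline must recover all seven
  planted edges with zero false edges at the reporting tier in at least
  80% of seeds, with per-edge estimator bias (seed-averaged relative
  error) below 5%.

Numerical details worth knowing: degenerate (zero-variance) predictors are
excluded from designs with a warning; rank-deficient final designs are an
error naming the aliased columns, while perfectly collinear candidates are
resolved positionally during selection; permutation counts below 19 are
rejected (an $\alpha = 0.05$ threshold cannot be resolved); and a constant
genotypic prediction reports $R^2 = 0$ with a warning rather than NA.

## A worked example

```{r example, eval = FALSE}
cfg0 <- sim_config(n_lines = 150, n_snps = 80, n_transcripts = 20, seed = 11)
g0 <- simulate_genotypes(cfg0)
ids <- g0$snps$id[c(10, 30, 55)]
truth <- simulation_truth(
  mu = 25,
  qts_effects = setNames(c(2, -2, 1.5), ids),
  sex_effect = 0.5,
  cis_trans_effects = data.frame(snp = ids[1], transcript = "T0003",
                                 effect = 2),
  tt_effects = data.frame(regulator = "T0010", target = "T0003", effect = 1)
)
cfg <- sim_config(n_lines = 150, n_snps = 80, n_transcripts = 20,
                  truth = truth, seed = 11)
g <- simulate_genotypes(cfg)
e <- simulate_expression(g, cfg)
p <- simulate_phenotype(g, cfg)$phenotype

study <- run_full_study(g, e, p,
                        config = scan_config(n_permutations = 200, seed = 5))
study
net <- build_network(study$combined)
net
export_network(net, "startle-network.graphml", "graphml")
```

## Known limitations

* No kinship or relatedness correction: panel lines are treated as
  unrelated, as is standard for the DGRP.
* No REML random-effect estimation of variance components; components are
  plug-in variances of fitted fixed-effect contributions.
* The 2D scan covers candidate pairs only (with a budget), not all genome
  pairs; whether the original analysis scanned all pairs is unstated.
* No FDR-based multiplicity control — the control target is family-wise
  error, as in the original design.
* GO enrichment, literature-mined orthologue overlays and microarray
  normalization are out of scope.
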