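---
title: "Methods: dosage-aware genomic selection for autotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-aware genomic selection for autotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraGS)
```

## Scope

`tetraGS` implements a two-stage genomic-selection analysis for
autotetraploid outcrossing crops evaluated as half-sib polycross progenies in
repeated-harvest field trials. Stage 1 adjusts the longitudinal phenotypes
with a structured mixed model and produces one adjusted entry mean per
genotype; stage 2 regresses those entry means on allele dosages (0–4 copies
of the reference allele) with six whole-genome prediction models, evaluated
by replicated fivefold cross-validation. A synthetic-data module generates
populations with the statistical structure the analysis assumes, so every
stage is testable without external data.

## The simulator and what it emulates

`sim_config()` defaults describe the reference trial: a polycross of 19
recorded dams and 20 sires producing 19 half-sib families of 30
autotetraploid offspring (570 plants), laid out in a split-plot randomized
complete block design with 6 blocks of 22 whole plots (19 families + 3
clonal check cultivars) of 5 plants each — 660 plants in total — phenotyped
over 8 or 4 harvests.

Meiosis is tetrasomic with random bivalent pairing: a gamete receives
`ploidy/2` of the parent's chromosomes drawn without replacement, so gamete
dosage is hypergeometric. Double reduction is available as an option but
defaults to 0, matching the convention of standard autotetraploid pedigree
software. Sires are drawn per offspring with replacement, uniformly over the
sire set excluding the dam: a polycross records no paternity, and the
half-sib family structure only requires known dams. Equal-probability
paternity is a simulator choice, not an empirical claim.

Read depths are negative binomial (Poisson in the default,
`depth_dispersion = Inf`, since GBS depth dispersion is rarely known) with
mean 60; each read miscalls its allele with probability `seq_error`
(default 0.005), giving a reference-read fraction
$q_d = (d/4)(1-\varepsilon) + (1-d/4)\varepsilon$ for dosage $d$.
Missing dosages are introduced completely at random at a configurable rate,
mirroring random GBS coverage.

Phenotypes follow the stage-1 generative model: overall mean, fixed harvest
effects, random block-, parent- and block-by-parent-within-harvest effects,
a genetic value, and residuals with a chosen covariance structure $R_L$
across harvests (default AR1 with unit variance and correlation 0.3).
Genetic values blend a marker-determined additive component $W\beta$ (a
configurable proportion of markers carry nonzero effects, default 10%) with
harvest-specific deviations so that the genetic correlation across harvests
is `genetic_cor` (default 0.8, typical of repeated harvests of the same
plants). The `h2` target (default 0.5) is defined on the *adjusted
entry-mean* scale — genetic variance over genetic-plus-residual variance of
the across-harvest mean — because that is the scale on which stage 2
operates; block and parent variances are excluded from the target since
stage 1 removes them. What the simulator does **not** emulate: linkage
(markers are unlinked; LD diagnostics are exercised on constructed marker
maps), multivalent pairing, genotype-by-harvest-rank interactions beyond
compound symmetry, and non-additive gene action. Passing tests therefore
demonstrate correctness of the machinery under the stated model, not
robustness to every feature of real GBS data.

Every stage derives its RNG stream from the config seed with a fixed small
offset (founders +0, polycross +1, trial +2, read counts +3, imputation +4,
cross-validation +5), which makes full pipeline runs byte-reproducible.

## Dosage calling and marker QC

The caller fits, per marker, a `(ploidy+1)`-component binomial mixture to
the reference read counts by EM: component $d$ has success probability
$q_d = (d/\mathrm{ploidy})(1-2\varepsilon)+\varepsilon$ and free mixing
weights (the population dosage-class frequencies). Individuals are assigned
the maximum-a-posteriori dosage; calls with posterior below `min_posterior`
(default 0.8 — a deliberate trade of missingness for accuracy, with the
missingness filter downstream) or zero depth are set missing, and
non-converged markers are called entirely missing. This is a
fixed-ploidy reformulation of probabilistic polyploid genotyping: with
ploidy known and fits filtered on confidence, the free-weight mixture plays
the same role as a full graphical-model caller.

The QC cascade follows the order: mean population depth ≥ 25 reads
(boundary inclusive; "minimum average depth for the population" is the
operational reading), minor allele frequency ≥ 1% computed from observed
dosages ($p = \sum d_i / (\mathrm{ploidy}\cdot n_{obs})$), missingness
strictly greater than 5% removed, then imputation by random sampling from
each marker's empirical dose frequencies. Dosage counts the VCF REF allele;
only biallelic records are accepted at VCF ingestion. Marker redundancy
groups use exact vector equality including the missing mask — two markers
are only redundant when they agree on where data are absent.

For the tetraploid/diploid comparison, markers whose observed dosages are
confined to {0, 1} are removed *before* diploidization (they carry no extra
tetraploid information), and the diploid coding collapses the three
heterozygote classes: 0→0, 1→1, 2→1, 3→1, 4→2.

## Stage 1: the longitudinal model

For plant $i$ of parent $j$ in block $k$ at harvest $l$:

$$y_{ijkl} = \mu + h_l + b_{k(l)} + p_{j(l)} + bp_{kj(l)} + t_{il} + e_{ijkl}$$

with fixed $\mu$, $h_l$, and fixed cultivar-by-harvest effects $c_{il}$ for
the clonal checks; random $b_{k(l)}$, $p_{j(l)}$, $bp_{kj(l)}$ are
independent with common variances (independent levels per harvest — the
nesting notation is read as iid per harvest, the simplest faithful
interpretation); random genotype effects $g_{il}$ have covariance
$G_L \otimes I$ and residuals $R_L \otimes I$. Nine structures are supported
for $G_L$ and $R_L$ (ID, DIAG, CS, CSHet, AR1, AR1Het, Po, PoHet, US), with
parameter counts 1, $L$, 2, $L{+}1$, 2, $L{+}1$, 2, $L{+}1$, $L(L{+}1)/2$.
Po/PoHet use harvest coordinates defaulting to $1..L$ (calendar dates are
rarely available), in which case Po coincides with AR1.

Estimation is REML by direct quasi-Newton maximization on transformed
parameters: log variances, `atanh` for AR1 correlations, a logistic map onto
$(-1/(L-1), 1)$ for compound symmetry (its PSD bound) and onto $(0,1)$ for
the power model, and a log-Cholesky factorization for US. Because the
fixed-effect structure is identical across covariance candidates, REML
likelihoods are comparable and AIC/BIC are computed from them with
`nPAR` = structure parameters + the three scalar variances (constant across
candidates, so rankings depend only on the structures). The solver exploits
the model's block structure: the plant-level covariance
$G_L \otimes I + R_L \otimes I$ is block diagonal per plant, so the
likelihood is evaluated through the Woodbury identity at
$O(nL^2 + q^3)$ per step ($q$ = block/parent levels) instead of a dense
$O(n^3)$ factorization; the dense restricted likelihood is retained in the
test suite as an independent oracle. Convergence tolerance is $10^{-10}$
relative likelihood change, at most 500 iterations, with a second perturbed
start by default; variance estimates within $10^{-6}$ of zero or
correlations beyond 0.995 are reported with a boundary flag rather than an
error. Records must be complete (every plant at every harvest), which the
simulator guarantees; with one harvest all structures collapse to ID.

Structure selection is hierarchical: all $G_L$ candidates with $R_L = ID$,
then all $R_L$ candidates at the chosen $G_L$. Within a step, if AIC and BIC
disagree, the criterion whose difference between the two disagreeing
candidates is larger governs; an exact tie defers to BIC as the more
parsimonious criterion (a design choice — ties are measure-zero in
practice).

Generalized heritability is $H^2 = 1 - \mathrm{PEV}/(2\sigma^2_G)$ with
$\mathrm{PEV}$ the mean prediction-error variance of pairwise genotype
contrasts on the entry-mean scale and $\sigma^2_G = m'G_L m$
($m = (1/L,\dots,1/L)$), the genetic variance on that same scale; by
convention it is computed from the $G_L = CS$, $R_L = ID$ fit. Adjusted
entry means are $\hat\mu + \overline{\hat h} + \bar g_{i\cdot}$, the
harvest-average of each genotype's predictions — "marginal predicted values
across harvests" made concrete — with checks excluded.

## Relationship matrices

The pedigree matrix is $A = 4\Theta$ with $\Theta$ from the tetrasomic
kinship recursion: a random offspring gene descends from a random gene of
either parent; the self-kinship term distinguishes within-gamete gene pairs
(IBD with probability $\alpha + (1-\alpha)F_{parent}$, $\alpha$ = double
reduction, default 0) from cross-gamete pairs ($\theta_{dam,sire}$).
Non-inbred founders have diagonal 1 and parent–offspring relationship 0.5;
unknown parents are unrelated non-inbred founders. The genomic matrix is
$K = WW^\top / (\mathrm{tr}(WW^\top)/n)$ with $W$ the column-centered dosage
matrix — mean centering is the parameter-free reading of "centered marker
scores"; allele-frequency (VanRaden) centering is available as an option.
The trace normalization makes $\mathrm{tr}(K) = n$ and lets the same formula
serve tetraploid and diploidized codings. The blend
$K^* = 0.99K + 0.01A$ restores positive definiteness; inside
cross-validation, when no pedigree is supplied, a $10^{-8}$ diagonal bump is
used instead. The tetraploid $A$ is used for the blend under both codings.

## Stage 2: prediction models

All Bayesian models share $y = 1\mu + X\beta + \varepsilon$ and a
scaled-inverse-$\chi^2$ residual variance; they differ in the prior on
$\beta_j$: common normal variance (BRR), per-marker variances (BayesA),
spike-and-slab with per-marker slab variances (BayesB) or a common slab
variance (BayesC), and the Bayesian LASSO with
$\beta_j \sim N(0, \sigma^2_\varepsilon \tau^2_j)$,
$\tau^2_j \sim \mathrm{Exp}(\lambda^2/2)$. The spike is implemented as an
exact point mass at zero with binary indicators — the distributional limit
of an infinitesimal-variance normal and numerically stabler. Default
hyperparameters: degrees of freedom 5, scales set so the prior modes split
the phenotypic variance half genetic, half residual (slab variance inflated
by $1/(1-\pi)$ for the mixtures), spike proportion $\pi = 0.5$, and the
LASSO rate given a Gamma hyperprior (shape 1.1) centred on the
half-variance value with a fixed-$\lambda$ option. The Gibbs protocol is
20,000 iterations with 2,000 burn-in and no thinning by default; samplers
run in compiled code under R's RNG so `set.seed()` reproduces chains.
The intercept carries a flat prior and is updated by its Gaussian full
conditional.

GBLUP ($y = 1\mu + g + \varepsilon$, $g \sim N(0, K^*\sigma^2_g)$) is fitted
by REML through the eigendecomposition of $K^*$: the restricted likelihood
profiles analytically over $\sigma^2_g$ and is maximized over the single
variance ratio by one-dimensional search on $\log\delta \in [-12, 12]$.
Narrow-sense (genomic) heritability is
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_\varepsilon)$. Stage 2 uses the
entry means unweighted (no stage-1 PEV weighting), keeping the two stages
cleanly separated.

## Cross-validation and the TD/DD comparison

`run_cv()` repeats a k-fold split (default fivefold; 100 replications for
the Bayesian models and 1,000 for GBLUP in the reference protocol —
configurable, and scaled down in tests): per replication each fold is
predicted from the other four, the pooled out-of-fold predictions are
correlated with the observed entry means (one Pearson correlation per
replication, not per fold), and predictive ability is the mean over
replications. PRESS is $\sum(\hat y - y)^2$; its standardized variant
divides by the observed total sum of squares, a scale-free convention under
which the mean-only predictor scores exactly 1 (the literature leaves this
standardization undefined; this is the package's documented choice).
Replications with undefined correlations (constant predictions) are
excluded with a logged message. Inside cross-validation the genomic matrix
is rebuilt from the training fold only (centering included) to avoid
information leakage.

`compare_td_dd()` applies the informativeness filter, then runs every model
on the tetraploid and the diploidized coding of the *same* marker panel
with *identical* fold assignments, and reports per-model abilities, the
per-coding model averages and the percent superiority
$100(\bar r_{TD}/\bar r_{DD} - 1)$. Stratified (per-family) fold sampling
is available; on unstructured simulated data it performs like random
sampling, as expected when no population structure is present.

## Diagnostics

Short-range LD is the squared Pearson correlation of dosage vectors for
same-chromosome marker pairs within 1,500 bp, computed directly on the 0–4
codes (no phasing), pairwise-complete over non-missing individuals;
zero-variance pairs are skipped. Both the pooled within-window average and
the adjacent-pair average are reported, plus the 90th percentile of the
short-range values as an optional decay-robust summary. PCA operates on the
column-centered dosage matrix.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by the package's
own choice of problem sizes: trials of roughly 100–300 plants with 3–4
harvests for the REML checks (structured-vs-dense equality is asserted at 40
observations), 200–300 genotypes with 500–1,000 markers for prediction,
Gibbs chains of 1,200–50,000 iterations depending on the check, and 8–20
cross-validation replications. Parameter-recovery statements in the tests
are calibrated to these sizes (e.g. the compound-symmetry genetic
correlation is recovered to ±0.15 averaged over replicates at per-harvest
genetic variance 1). Known limitations: the REML solver requires complete
plant-by-harvest records; the US structure at large $L$ is expensive and
weakly identified at trial sizes; the caller assumes a shared, known
sequencing error rate across markers; and predictive-ability magnitudes on
real data depend on LD and family structure the simulator intentionally
simplifies.

## A worked mini-analysis

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_dams = 8, n_sires = 10, family_size = 12, n_blocks = 3,
                   plants_per_plot = 4, n_checks = 2, n_markers = 300,
                   n_harvests = 3, missing_rate = 0.02, seed = 11),
  cv = cv_plan(5, 5), models = c("GBLUP", "BRR"), seed = 11)
out <- run_pipeline(cfg)
print(out)
```

The report lists the marker counts surviving each QC stage, the broad- and
narrow-sense heritabilities, and the per-model tetraploid/diploid predictive
abilities with their percent superiority.
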