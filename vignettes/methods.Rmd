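---
title: "Models and methods behind microtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtraj)
```

# Scope

`microtraj` analyses age trajectories in longitudinal gut-microbiome
surveys of repeatedly sampled hosts — the setting of a wild primate
field study in which ~50 adult females, living in a few social groups,
are each sampled about a dozen times across three seasonal windows
spanning roughly a year and a half. The package covers the downstream
arc of such a study: alpha diversity and its age models, beta-diversity
matrices, the personal compositional signature and its temporal
stability, community-level variance partitioning, per-taxon
relative-abundance trends with core/noncore bookkeeping,
closest-neighbour personalization, and dyadic grooming (social
transmission) models. A synthetic cohort generator with exported ground
truth makes every stage verifiable by calibration and parameter-recovery
simulation, without any access to field data.

# Data preparation

Counts are taxa-by-samples integer matrices. Two cleaning filters are
iterated jointly to a fixed point (so the operation is idempotent):
taxa observed in at most one sample are removed, and any cell whose
within-sample relative abundance falls below 0.25% is zeroed (the
whole-taxon alternative is available via `mode = "per_taxon"`; the
within-sample reading is the default because relative abundance is a
within-sample quantity). A single pass is not idempotent — zeroing can
leave a taxon in exactly one sample — hence the fixed point.

Rarefaction (`rarefy()`) is a single seeded without-replacement draw to
the minimum sample depth, the convention used for beta-diversity work;
repeated-rarefaction means can be scripted on top but are deliberately
not the default.

Adult ages in years are categorized as young adult (6–10, both ends
included), mid-aged (strictly between 10 and 18) and old (18 and
above); ages below 6 are rejected as non-adult.

# Diversity and dissimilarity

Observed richness counts positive taxa. Faith's phylogenetic diversity
is delegated to `picante::pd` on a rooted tree, with the root path
included by default (`include_root = FALSE` exposes the variant).
Shannon evenness is `-sum(p log p)/log(N)` with natural logarithms over
the positive-count taxa; the base cancels in the ratio, `N` counts
positive taxa only (the only reading that keeps the index at or below
1), and a single-taxon sample returns 0 by convention.

Bray-Curtis uses `vegan::vegdist`. Both UniFrac variants are computed
in-package from per-branch descendant abundances obtained by one
postorder accumulation: unweighted UniFrac is unique over shared branch
length, weighted UniFrac is `sum(L |p_x - p_y|) / sum(L (p_x + p_y))`
and is **normalized** by default, because published intra/inter means
near 0.3 for this quantity are only consistent with the bounded
variant; `normalized = FALSE` returns the raw numerator.
Multifurcations are handled naturally since everything is per-branch.
Both variants are verified against exhaustive brute-force branch
enumerations on small random trees.

# Personal signature and stability

The identity Mantel test correlates (Spearman) the dissimilarity matrix
with a same/different-host indicator; r > 0 means intra-host pairs are
less dissimilar. Its permutation null reassigns samples to hosts
(preserving per-host sample counts). We do *not* permute within host
blocks here: within-block permutation maps intra pairs to intra pairs
and inter pairs to inter pairs, leaving the statistic exactly
invariant, so a "restricted" identity test would be vacuous. The
within-host restricted scheme is reserved for the time-gap test, where
it is the natural encoding of "randomization only within individuals":
sample positions are shuffled inside each host's block, the gap
structure stays fixed, and the permutation and observed statistics are
computed with one identical ranking procedure so the comparison is
exchangeable.

Per-host stability coefficients are the Spearman correlation between
intra-host dissimilarity and the day gap between collections (Pearson
available); at least three pairs are required, and degenerate hosts are
flagged rather than dropped. More positive values mean lower stability.
The age comparison across young/mid/old uses the tie-corrected
Kruskal-Wallis test. The 10-day exclusion rule removes pairs collected
at most 10 days apart — the region where dissimilarity rises steeply
before its plateau — and reports exactly which hosts drop out.

# PERMANOVA

`permanova()` Gower-centres the squared distance matrix and partitions
its trace by sequential (Type I) projections of an orthonormalized
model basis, so the R² components and the residual sum to 100% by
construction; sums of squares are verified against explicit hat-matrix
projections. Permutations can be restricted within host strata. A
predictor that is constant within every stratum (host identity itself,
or age when each host has a single age) has a permutation-invariant
statistic under that scheme; the function warns and reports `NA` rather
than an artificial p. Host identity therefore gets its effect size from
an identity-only model with free permutations
(`permanova_identity()`), mirroring the two-model reporting convention
for such designs.

# Variable-dispersion beta regression

The engine behind the evenness model, the per-taxon trends and the
personalization model is a variable-dispersion beta regression fit by
maximum likelihood (`beta_ml()`): `logit(mean) = X b`,
`log(precision) = Z g`, BFGS with analytic gradients, case weights, and
cluster-robust (host-level) sandwich covariance computed from summed
per-host scores. Boundary proportions are first shrunk with the
Smithson–Verkuilen map `(x (n - 1) + 0.5)/n`. The fit is cross-checked
against an independent general-purpose mixed-model engine in the test
suite.

Repeated sampling of hosts is handled throughout by fixed-effects ML
plus host-clustered robust standard errors rather than random-slope
mixed models. The fixed-effect estimands coincide at this design's
scale, the marginal likelihood-ratio test against the no-age reference
keeps the full-versus-reference logic (avoiding cryptic multiple
testing), and every fitted object and pipeline manifest carries the
deviation note. Per-taxon models weight observations by read count
(normalized to mean 1 so the effective sample size stays n), drop age
jointly from mean and precision in the reference (2 df; a mean-only
1-df variant is a flag), and divide the LRT statistic by the Pearson
dispersion ratio when it exceeds 1 — one defensible reading of
"corrected for overdispersion" where the source formula is not spelled
out. FDR control is Benjamini–Hochberg within each taxonomic level;
direction labels (increase/decrease/none) follow the sign of the age
estimate at raw p < 0.05, with the FDR-level call flagged separately.
Core membership is prevalence at or above 90% of samples, boundary
inclusive.

# Personalization and social transmission

Each sample's personalization is its minimum dissimilarity to any
sample from a different host in the same group and season; samples
without an eligible comparator are flagged, never silently dropped, and
ties break by the lexicographically smallest comparator id so the
comparator column is reproducible. The personalization model is the
beta engine with `logit(mean) ~ z(age) * season + group + gestation`
and `log(precision) ~ z(age)`; the reference drops age, season and the
interaction (5 df). A positive precision slope means the spread of
minimum dissimilarity narrows with age. Percentile CIs come from a
seeded parametric bootstrap (default 1000 draws).

Dyadic grooming rates are events (or seconds) per dyadic observation
hour. The dyadic dissimilarity model reports the ML beta-regression
estimate of the grooming effect; inference uses a node-label
permutation null: host identities are shuffled within groups, dyad mean
dissimilarities recomputed, and a correlation statistic re-evaluated.
The statistic partials out group and additive host effects through host
indicator columns — the permutation analogue of a multimembership
random-effects term, whose column space is invariant under within-group
relabeling, so the null stays exact while host-level personalization
differences cancel. `p_neg`, the permutation probability of an effect
at least as negative as observed, mirrors a posterior probability of
social transmission. A full per-permutation ML refit would cost three
orders of magnitude more compute for the same inferential content,
which is why the statistic is the partialled correlation rather than
the refitted coefficient.

Top-partner and group-average grooming summaries are modeled per host
by ordinary least squares on age and group, with influence diagnostics
(DFBETA of the age term) reported.

# The synthetic cohort generator

The generator (`sim_params()`, `simulate_dataset()`) emulates the
study design: 51 females with stratified-uniform ages 6–26 (field
studies deliberately select focal animals across the age range, and
stratification guarantees every cohort spans all age classes), three
balanced groups, three 60-day seasonal windows starting at days 0, 240
and 480, four collection dates per window at least two days apart,
Bernoulli(0.2) gestation with no effect (matching null gestation
results), rainfall tracking season, 300 taxa with a 55% core whose
baselines are tight enough that core taxa keep at least 90% expected
prevalence at lognormal depths around 9000 reads.

The latent log-abundance of taxon t for host i at time tau is

```
base_t + group_{g(i),t} + season_{s(tau),t}
  + u_{i,t} * pers_scale_i            # permanent personal signature
  + eps_{i,t}(tau)                    # temporal turnover
  + sample noise
```

with counts Dirichlet-multinomial at small overdispersion
(`theta = 5e-4`). Design choices that required genuine iteration, and
their rationale:

* **Signatures** are random sign patterns of fixed per-taxon magnitude
  (`sigma_ind`), so a host's effective divergence from the population
  centroid is controlled by `pers_scale` alone rather than by the luck
  of which taxa its signature happens to load on.
  `pers_scale = exp(beta_pers z(age) + eta_i ramp(age))` grows with age
  and carries a between-host heterogeneity term that is largest at the
  young end and decays to zero at the old end: young adults differ in
  how personalized they already are, old hosts converge to a uniformly
  high personalization ceiling. This is what makes the *dispersion* of
  closest-neighbour dissimilarity shrink with age (the positive
  precision-age effect) while its mean rises. The heterogeneity draws
  are quantile-balanced within consecutive age blocks because, with
  half a dozen hosts per age class, i.i.d. draws frequently fail to
  realize their nominal spread; the term is tied to `beta_pers` so null
  cohorts have age-invariant spread, and the multiplier is capped so no
  host wipes out core taxa.
* **Temporal turnover** has two parts. A fast AR(1) component on a few
  host-specific community axes, with correlation `rho^(gap/30)` so
  irregular gaps are handled and a low `rho` reproduces the sharp
  few-day rise of within-host dissimilarity followed by a plateau; its
  scale declines with age (`beta_fast < 0`: young hosts fluctuate more
  day to day, the mirror image of the positive dispersion-age effect).
  And a slow progressive drift along a population-shared compositional
  axis, travelled at speed `sigma_drift * exp(beta_stab z(age))`:
  older hosts keep diverging from their own past composition, which is
  what the per-host stability coefficients detect. A single stationary
  AR(1) with age-scaled innovation cannot reproduce this pattern — its
  correlation statistic is amplitude-free once above the noise floor,
  and its sample-level noise inflates exactly the old-host variance
  that the dispersion effect requires to shrink; the shared axis keeps
  the between-host geometry (and hence personalization) almost
  untouched while the within-host signal grows.
* **Sequencing noise** is split: tiny Dirichlet-multinomial
  overdispersion (large theta zero-inflates low-abundance core taxa and
  breaks the 90% prevalence construction) plus i.i.d. per-sample latent
  noise (`sigma_sample`) forming the dissimilarity floor that no
  covariate explains.
* **Social transmission** blends each host's signature toward its top
  grooming partner's with weight
  `lambda_social * min(1, rate/q90(rates))`; grooming rates decline in
  log with mean dyad age (`beta_groom < 0`) and events are Poisson in
  dyadic observation hours.

Scales were chosen once so that the recovery analyses at the package's
reduced simulation sizes are well powered, and are documented here
rather than revisited; effect-size defaults
(`beta_stab = 0.4, beta_pers = 0.3, lambda_social = 0.5,
beta_groom = -0.3`) represent the study-like condition, and null
analyses set them — together with the group/season shifts, which are
real identity- and gap-correlated signals — explicitly to zero.

What the generator does *not* emulate: sequence-level read error,
realistic taxonomy, demography (births, deaths, migration), diet
records, or any calibration of effect sizes to the magnitudes a field
dataset would show. Passing recovery tests therefore demonstrates that
the estimators detect and sign these mechanisms correctly at realistic
designs, not that any particular published magnitude would be
reproduced.

# Simulation sizes and numerical choices

The test suite runs permutation-calibration sweeps at 20 hosts x 60
taxa x 6 samples each (1000 cohorts, 999 permutations) and recovery
sweeps at 36 hosts x 60 taxa x 12 samples each (100 cohorts) — sizes
chosen so the whole suite runs comfortably on a laptop core while
keeping binomial noise on the reported rates a few percent. The
acceptance script runs the full pipeline once at the study scale
(51 hosts, 300 taxa, 612 samples).

Numerical conventions worth knowing: permutation p-values are
`(exceedances + 1)/(n_perm + 1)`, one-sided in the direction of each
directional hypothesis (two-sided variants by flag); permutation and
observed statistics always share one ranking procedure;
`beta_ml` starts from a logit-scale least-squares fit with a
method-of-moments precision, declares convergence only when the
analytic gradient vanishes, and reports non-convergence as flagged
records (per-taxon models) or errors (primary models); distance
matrices are serialized at 17 significant digits so round trips are
exact; all randomness flows through explicit integer seeds, and the
pipeline derives per-stage seeds from one master seed by fixed offsets
so stage-level reruns reproduce full-run values.

# Known limitations

Fixed-effects-plus-clustered-errors is an approximation to random-slope
mixed models; with few hosts (< ~20) the cluster-robust errors are
anti-conservative. The Mantel identity test cannot distinguish host
identity from any host-constant covariate (group), which is why the
calibration null switches group shifts off — on real data the identity
r should be read as "identity and everything constant within identity".
The overdispersion correction divides by the Pearson ratio, one of
several published conventions. The dyadic model's permutation statistic
is a score-like correlation, not the refitted ML coefficient; the two
are monotone-equivalent in the neighbourhood of the null but can differ
far from it. The 0.25% filter's within-sample reading is a choice; the
whole-taxon alternative is provided and can change rare-taxon trend
counts.
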