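---
title: "Phylogenetic covariation analysis of protein and lipid secretion profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic covariation analysis of protein and lipid secretion profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandcov)
```

## The problem

Lizard femoral glands secrete a waxy blend of proteins and lipids used in
chemical signaling. `glandcov` asks, across a clade of species, whether the
two fractions covary: does the protein composition (summarized as a
normalized one-dimensional electrophoretic profile, an *EPG*, of relative
abundance per molecular-weight bin) track the lipid composition, which
specific lipid compounds drive it, which molecular-weight regions respond,
and whether the *complexity* of the two fractions rises together.

Species are not independent observations: close relatives resemble each
other because of shared ancestry. Every statistical stage therefore works
on phylogenetically transformed data under a Brownian-motion (BM) model of
trait evolution.

## The model

### Brownian covariance and whitening

For a rooted tree with branch lengths, the expected covariance of a
BM-evolving trait between tips $i$ and $j$ is
$C_{ij} = $ (shared branch length from the root to their most recent
common ancestor), with $C_{ii}$ the root-to-tip distance
(`bm_covariance()`, via `ape::vcv.phylo`). Data are decorrelated with the
inverse principal square root $E = U \Lambda^{-1/2} U^\top$ of
$C = U \Lambda U^\top$ (`whitener()`), so that $E C E^\top = I$. The
symmetric eigendecomposition (rather than Cholesky) is used because it
yields a symmetric, rotation-free transform — the convention of the
geometric-morphometrics tooling this analysis style comes from.
Eigenvalues below $10^{-12}$ of the largest raise a conditioning error
rather than being regularized silently. Centering uses the phylogenetic
(GLS) mean $\hat a = (1^\top C^{-1} 1)^{-1} 1^\top C^{-1} Y$
(`gls_mean()`), which reduces to the arithmetic mean when $C \propto I$.
Non-ultrametric trees are accepted as-is; nothing assumes equal root-to-tip
distances.

### Compositional treatment

Profiles, class tables and compound tables are compositions: only relative
information is meaningful. Rows are closed to sum to one (`closure()`),
zeros are replaced multiplicatively (`replace_zeros()`: zeros become
$\delta$, positive parts are rescaled by $1 - k\delta$, preserving their
ratios), and the centred log-ratio transform
$z_{ij} = \ln(x_{ij}/g_i)$, $g_i$ the row geometric mean (`clr()`), maps
the simplex to a zero-sum Euclidean space where linear methods apply.
Results are mapped back with `clr_inverse()` for interpretation, which
subtracts the row maximum before exponentiating so extreme values cannot
overflow. Natural logarithms are used throughout, the convention of
compositional data analysis. The default $\delta$ is half the smallest
positive entry of the matrix — smaller than anything observed, and
deterministic; it is configurable and recorded in the run manifest because
any zero-replacement choice is a modeling decision, not a fact of the data.
The eight-compound matrix is closed, zero-replaced, then CLR'd; profile and
class matrices arrive row-normalized and are zero-replaced and CLR'd. The
complexity scalars ($R_P$, $H_P$, $R_L$, $H_L$) are never transformed.

### Profile complexity

Peak richness $R_P$ counts strict local maxima of the profile in a
centered window of odd width $w$ (default 3), keeping those at least 10%
as high as the tallest detected maximum (`detect_peaks()`). Plateaus are
never peaks and the first and last bins are never peaks; both policies are
explicit and configurable because any peak detector must pick *some*
endpoint/tie rule, and silent choices are not reproducible. The count is
invariant to positive rescaling of the profile, and raising the relative
height threshold can only lower it. Shannon entropy
$H = -\sum_i p_i \ln p_i$ (nats, $0 \ln 0 = 0$) measures profile evenness;
it is zero for a single band and $\ln n$ for a perfectly flat profile.
The minus sign is the standard definition: a quantity that *increases*
with complexity. Lipid richness $R_L$ counts strictly positive compound
abundances; $H_L$ is the entropy of the closed compound profile.

### Two-block phylogenetic PLS

`phylo_pls()` centers each block on its GLS mean, whitens rows with $E$,
forms the cross-block covariance $R_{12} = \tilde X_1^\top \tilde X_2/(n-1)$
and takes its first singular pair. The score correlation
$r_{PLS} = |\mathrm{cor}(\tilde X_1 u, \tilde X_2 v)|$ measures
covariation. Only the $p_1 \times p_2$ cross-covariance is ever formed, so
blocks with far more variables than species (300-bin profiles for a few
dozen species) are handled directly. Significance comes from permuting the
rows of the transformed second block, holding $E$ and the phylogenetic
means fixed: the permutation destroys the cross-block pairing while
leaving each block's phylogenetic structure intact. The p-value is
$(1+b)/(m+1)$ with ties counted as exceedances, so $p \ge 1/(m+1)$ always.
Whether the original tooling permutes raw or transformed rows (and whether
it re-estimates the phylogenetic mean per permutation) is not something we
fix from the outside; this package's scheme is fixed, documented, and
deterministic given the seed.

### Phylogenetic regression, type III tests, RRPP

`pgls_fit()` regresses the (multivariate) transformed response on the
transformed design (intercept plus predictors) by least squares; all
response columns share one design. Marginal (type III) sums of squares
(`anova_type3()`) measure, for each predictor, the increase in residual SS
when that predictor alone is dropped; the pseudo-F is the marginal SS over
the full-model residual mean square. Significance uses residual
randomization (RRPP): reduced-model residuals are row-permuted, added back
to the reduced fitted values, and the statistic recomputed. Reduced-model
(not full-model) residuals are the standard choice for marginal tests: the
permuted data obey the null for the tested term while retaining all other
terms' effects. One permutation-index stream per seed is shared across
terms so term p-values are comparable within a run. For a univariate
response with $C = I$ the pseudo-F is numerically the classical partial F
(verified to $10^{-8}$ in the tests). Perfect fits (residual SS
numerically zero) report a capped pseudo-F of $10^{15}$ and the minimal
attainable p-value rather than failing.

`predict_response()` evaluates the fitted model along one focal predictor
with all others held at their GLS means, on the CLR scale (optionally
mapped back to a composition for display). `responsive_regions()`
formalizes "which molecular-weight regions respond": the difference
profile between predictions at the focal minimum and maximum is
thresholded at a fraction (default 0.5) of its maximum, and maximal runs
of at least `min_run` (default 2) consecutive above-threshold bins are
reported, with kDa bounds when a bin-to-kDa calibration is supplied. The
published analyses delimit such regions visually; the thresholds here make
the rule explicit and reproducible. The default synthetic calibration
(`kda_calibration()`) is log-linear from 250 down to 10 kDa, since
electrophoretic migration is approximately linear in log molecular weight;
a measured calibration should be supplied whenever one exists.

### Flagging compounds: multiplicity

Stage 2 tests eight compounds. At a raw per-term $\alpha = 0.05$ the
chance of at least one false flag among seven null terms is roughly 30%,
so an automated report of "the significant compound" would be wrong nearly
a third of the time on pure noise. `run_full_analysis()` therefore flags
compounds for the region follow-up using Holm-adjusted permutation
p-values by default (`p_adjust = "none"` restores the raw reading used in
single-term interpretations). The ANOVA table always reports the raw
permutation p-values alongside the adjusted ones.

## The synthetic-data generator

`simulate_epg_dataset()` produces datasets with the study's shape and a
known ground truth, so every pipeline claim is testable without external
data. From a single seed it draws:

* a pure-birth (Yule) tree conditioned on the number of tips
  (`ape::rphylo`, zero extinction), rescaled to unit height — time units
  of a simulated clade are arbitrary, and unit height makes BM tip
  variances equal to one, a predictable scale for the other defaults;
* a latent Brownian factor $f$ coupling the blocks with correlation
  `rho`;
* eight compound abundances $\exp(\text{BM latents})$ — lognormal,
  strictly positive, as real abundances are. The factor loadings form a
  signed gradient from $+1$ to $-1$ across compounds: a constant loading
  would move all compounds together and cancel exactly under closure and
  CLR, making the coupling invisible to compositional analysis by
  construction;
* a 300-bin profile obtained by inverse-CLR of: a Brownian baseline, the
  factor loading on a smooth Gaussian bump of bins (unit maximum; a
  constant loading across bins would likewise be annihilated by the CLR),
  the injected effect `beta` $\times$ compound 1 on `effect_bins`
  (defaults: bins 40–45), and iid within-species noise (`noise_sd`);
* an 11-class logistic-normal composition table (closure of exponentiated
  Brownian latents). An earlier folded-normal variant
  ($\mathrm{closure}(|\text{BM}|)$) was rejected: it puts parts
  arbitrarily close to zero, whose logs become heavy outliers under CLR,
  and paired with noisy profiles this inflated the type-I error of the
  class-PLS permutation test to ~0.4. The logistic-normal (Aitchison)
  model is the standard distribution on the simplex, and its CLR is
  exactly matrix-normal on the tree, keeping permutation nulls calibrated
  (measured rejection 0.05–0.06);
* a 60-compound GC-MS pool with a detection limit (the lowest quartile of
  abundances reads as absent), from which lipid richness and entropy are
  computed — richness must count the full detected pool, not the eight
  targets, which are present in every species by design.

Defaults (36 taxa, 300 bins, 8 compounds) mirror the study data;
`rho = 0.5`, `beta = 1`, `noise_sd = 0.25` were fixed once as a
moderate-signal regime in which effects are present but not guaranteed to
reach significance in any single draw.

What the generator does *not* emulate: gel densitometry noise (smearing,
baseline drift, saturation), GC-MS integration error, intraspecific
sampling variance, non-BM evolution (Ornstein–Uhlenbeck pull, rate
shifts), and correlated measurement error between fractions measured on
the same individuals. Passing tests therefore show that the pipeline
recovers what it claims under its stated model, not that the model is true
of any real secretion dataset.

## Numerical and policy choices

* Eigenvalue floor $10^{-12}$ (relative) in `whitener()`; failure is loud.
* Tip-label matching is exact and case-sensitive; any mismatch between a
  table and the tree is an error, never a silent drop. All matrices are
  aligned to the tree's tip order at load time.
* Permutation p-values use $(b+1)/(m+1)$; ties (within $10^{-12}$) count
  as exceedances.
* Zero replacement fails if $\delta$ would reach the smallest positive
  entry.
* Degenerate region reports: if no bin responds positively the report is
  empty (not an error); a perfectly flat positive difference yields one
  region spanning everything, with a warning.
* All randomness flows from a single integer seed; stage seeds inside
  `run_full_analysis()` are `seed + 1 ... seed + 5` in stage order, and
  reruns are byte-identical.

## Problem sizes in the test suite

The simulation-based checks run at sizes chosen to give informative
Monte-Carlo precision while keeping the default suite fast: calibration of
the permutation tests uses 200 replicate 36-tip datasets with 499
permutations (the pooled per-term rejection rate has standard error ~0.011
at a true rate of 0.05); known-truth recovery uses 50 replicates at full
study shape (36 × 300, 8 compounds) with 499 permutations; pipeline-level
null and power checks use 50 replicates with 199 permutations. Separate
larger verification runs (1000–2000 replicates) during development placed
the true type-I rates at 0.048–0.054.

## Known limitations

* Only the first PLS axis pair is tested; later pairs are exposed but
  uninterpreted.
* The regression treats compound abundances as error-free predictors.
* The familywise-adjusted flagging rule is conservative when many
  compounds have real small effects.
* With 36 species, power for weak latent coupling (`rho` ≲ 0.3) is near
  the nominal level; the generator's moderate defaults deliberately sit in
  this hard regime.
* The real-data benchmark (the deposited 36-species dataset) cannot be
  redistributed with the package; the corresponding test runs only when a
  copy is placed under `inst/extdata/zenodo/`.
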