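---
title: "Seed-based voxel-level connectivity association: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based voxel-level connectivity association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`linkfc` implements a hypothesis-based voxel-level functional connectivity
(FC) association analysis for multi-site resting-state fMRI case–control
studies. Instead of averaging a seed region's BOLD signal into one time
series, every voxel of the seed region of interest (ROI) is paired with
every voxel of the brain, and each voxel pair is tested separately. The
chain is:

1. **Per-subject FC.** For each enumerated pair (ROI voxel $i$, brain voxel
   $j$), the Pearson correlation $r_{ij}$ of the two BOLD time series,
   Fisher-z transformed: $z_{ij} = \operatorname{arctanh}(r_{ij})$. The
   pair universe contains each unordered pair once:
   $|ROI|\,(|brain| - |ROI|) + \binom{|ROI|}{2}$ pairs.
2. **Per-site group contrast.** Within each imaging site, a linear model
   $z \sim \text{group} + \text{age} + \text{sex} + \text{FD} +
   \text{education}$ per pair; the group coefficient's $t$ (Student,
   $df = n - p$) and two-tailed $p$. With no covariates this is exactly the
   pooled-variance two-sample $t$-test.
3. **Cross-site combination.** Each site's $p$ becomes a signed score
   $z'_k = \operatorname{sign}(t_k)\,\Phi^{-1}(1 - p_k/2)$, combined as
   $Z = \sum_k w_k z'_k \big/ \sqrt{\sum_k w_k^2}$ with $w_k = \sqrt{n_k}$,
   standard normal under the null; $p = 2(1 - \Phi(|Z|))$.
4. **Multiplicity.** Benjamini–Hochberg step-up at rate $q$ over the whole
   pair family (missing pairs excluded), or uncorrected $p < \alpha$, with
   an optional cluster-extent filter (26-connectivity).
5. **Summaries.** Per voxel, the measure of association
   $MA_v = \#\{\text{significant links at } v\}$ and the signed display
   statistic $S_v = \sum |Z|$ over significant links with the sign of
   $\sum Z$; per cluster, a table of region names, voxel counts,
   $\sum|Z|$ over incident links and the peak world coordinate.
6. **Clinical correlates.** Within patients, cluster-wise mean FC is
   partially correlated with clinical scores (adjusting head motion,
   education, sex, age, medication), per site, then combined across sites
   as in step 3.

## Two deliberate departures from the common printed forms

Two formula choices deserve a note because variants circulate:

* **Signed conversion.** Applying $\Phi^{-1}(1 - p)$ to a *two-tailed* $p$
  discards the direction of the effect and maps $p = 1$ to $-\infty$
  rather than 0. We use the standard signed Stouffer input
  $z' = \operatorname{sign}(t)\,\Phi^{-1}(1 - p/2)$, so that increases and
  decreases combine coherently across sites and $p = 1 \mapsto 0$. Signed
  result maps (red/blue displays) require this.
* **Combination denominator.** The normalization must be
  $\sqrt{\sum w_k^2}$ for $Z$ to be standard normal under the null; the
  plain $\sum w_k^2$ sometimes seen in print deflates $Z$ by
  $\sqrt{\sum w_k^2}$ and is not a valid z-score. Our choice is validated
  empirically by the null-calibration test below.

The $p$ entering the quantile transform is floored at $10^{-300}$ so
underflowing site p-values cannot produce infinite scores.

# The cohort simulator

Real multi-site scans of this size are not redistributable, so validation
runs on a simulator whose ground truth is known *by construction* and whose
effects are injected on the very scale the pipeline tests (Fisher z).

Each region $r$ carries a latent unit-variance AR(1) Gaussian signal
$u_r(t)$ with autocorrelation $\phi$ (default 0.4 — temporal smoothness is
a realistic stressor that inflates correlation sampling variance). Voxel
$i$ of region $r$ observes

$$x_i(t) = \sqrt{c}\, u_r(t) + \sqrt{1-c}\,\varepsilon_i(t),$$

with white Gaussian $\varepsilon_i$ and within-region coherence $c$
(default 0.8, of the order of neighbouring-voxel BOLD correlations). For an
injected effect between the seed region $a$ and a target $b$, the target
latent is the mixture

$$u_b = \rho\, u_a + \sqrt{1-\rho^2}\, v_b,$$

with $v_b$ an independent AR(1) process — a sum of AR(1) processes with a
common $\phi$ is again AR(1), so $u_b$ keeps unit variance and the
configured autocorrelation, and $\operatorname{corr}(u_a, u_b) = \rho$
exactly. The expected cross-region voxel-pair correlation is then
$c\rho$. Setting $\rho = \tanh(\zeta)/c$ gives expected voxel-pair
correlation $\tanh(\zeta)$, i.e. **expected Fisher-z FC equal to
$\zeta$**, where

$$\zeta = \zeta_{base} + \text{site offset} + \Delta_z \cdot
  \mathbb{1}[\text{patient}] + \textstyle\sum_c \beta_c\,
  \tilde{x}_c + \eta,\qquad \eta \sim N(0, \sigma_\zeta^2),$$

with cohort-standardized covariates $\tilde{x}_c$ and per-subject coupling
noise $\eta$ (default SD 0.1). $|\tanh(\zeta)| \ge c$ is rejected as
infeasible; the default $c = 0.8$ leaves ample headroom for
$\zeta_{base} = 0.2$, $\Delta_z = 0.25$ and the noise terms. This
$\rho(\zeta)$ mapping is unit-tested against a Monte-Carlo oracle: across
200 + 200 simulated subjects the patient-minus-control mean of *sample*
Fisher-z FC reproduces the injected $\Delta_z$ within Monte-Carlo error.

Covariate and site effects act on the coupling parameter $\zeta$, never
additively on computed FC values, so the pipeline sees them only through
time series — exactly as it would in real data. Site amplitude differences
(`noise_scale`) scale the whole signal and leave correlations invariant;
FC-level site differences go through `coupling_offset`.

Phenotypes are drawn from documented distributions (age uniform 18–60, sex
Bernoulli(½), education uniform 6–20 years, mean framewise displacement
log-normal around 0.15 mm; HAMD/BDI high in patients and near zero in
controls; medication Bernoulli(½) among patients unless a site is
configured all-medicated; illness duration log-normal, patients only).
Reproducibility: the master seed draws the phenotypes and one private seed
per subject, so cohorts are bit-identical under a fixed seed and each scan
is independent of the order in which the others are generated.

**What the simulator does not model:** hemodynamic response, physiological
noise, spatially correlated noise beyond region coherence, motion
artefacts, registration error. Passing tests therefore demonstrate the
statistical machinery operates as designed under its stated assumptions —
not that those assumptions hold in any particular scanner's data.

# Numerical and policy choices

* **Voxel enumeration** is the ascending column-major (x-fastest) scan of
  the brain mask — one fixed bijection used by scans, pairs and maps alike.
* **Degenerate voxels.** Exactly constant time series become registered
  missing values; every pair touching one is excluded from all tests and
  the exclusion is logged. Numerically degenerate correlations
  ($|r| \ge 1$ from duplicated series) are clipped to $\pm(1 - 10^{-12})$
  before `arctanh` so a stray duplicate cannot inject $\pm\infty$ into the
  site combination.
* **Chunked computation.** The per-subject pair sweep runs in chunks of
  pairs (`chunk_size`); chunking changes peak memory, never results — any
  chunk size is bit-identical.
* **Store format.** HDF5 (`/z`, `/pairs`, `/subjects`, `/zero_variance`
  plus ROI bookkeeping), written at float64 so round-trips are exact.
* **BH ties** reject every $p \le p^*$ (standard step-up), deterministic
  under ties; the attained $p^*$ is reported like a z-test threshold.
* **Cluster connectivity** is 26-neighbourhood, the common volumetric
  default; "cluster size > k" keeps components strictly larger than $k$.
* **Cluster table attribution.** Components are formed over *all* voxels
  incident to a significant link — the seed region's own voxels therefore
  appear as a cluster row, as they should when seed voxels carry
  significant links. A link joining two reported components contributes
  its $|Z|$ to both rows; the table documents presence of evidence per
  component, not a partition of links.
* **Rank-deficiency rule.** Covariates constant within a site (an
  all-medicated site's medication indicator, say) are dropped for that
  site with a message; genuinely collinear designs are an error, because a
  silent pseudo-inverse would misattribute group variance.
* **Clinical stage** uses patients only (its scores and the medication
  covariate are patient measures) and reuses the cluster table as its
  region-set definition — the number of region sets is data-dependent, not
  fixed a priori.

# Validation study designs

The test suite's heavier checks use three synthetic designs, sized to keep
the full suite in the minutes range on one CPU:

* **False-discovery control.** Twenty replicate two-site cohorts
  (20 controls + 20 patients per site, $T = 120$, a 10×10×10 toy atlas of
  1000 brain voxels with a 27-voxel seed region, $\Delta_z = 0.25$ on the
  seed↔one-target block only, covariate slopes zero; 26 622 pairs of which
  729 are truly non-null). The mean false discovery proportion of BH at
  $q = 0.05$ is required to stay within two Monte-Carlo standard errors of
  the nominal rate. The false-positive *count* is heavy-tailed here
  because null pairs sharing a region latent rise and fall together — the
  replicate average, not any single run, is the controlled quantity.
* **Null calibration.** A global-null two-site cohort on a 4096-voxel
  atlas tiled into 64 regions (260 064 pairs). Within-region coherence is
  set to 0.05 in this design: the calibration claim is about the *marginal*
  distribution of the combined $Z$, and near-independent pairs make the
  Kolmogorov–Smirnov test against $N(0,1)$ meaningful; at the default
  coherence the block-correlated empirical CDF would be too lumpy for a
  literal KS test whatever the calibration. Required: $|\bar Z| < 0.02$,
  $|\operatorname{var}(Z) - 1| < 0.05$, KS not rejected at 0.01.
* **Effect recovery.** One fixed-seed cohort at 40 + 40 per site × 2
  sites, $T = 230$: the site-size-weighted mean of the per-link group
  coefficient over the injected block must recover $\Delta_z = 0.25$
  within ±20% (the tolerance covers correlation-estimation bias, coupling
  noise, and the block's shared-latent correlation, which limits how much
  averaging across its 729 links can reduce variance).

Everything else is exact: pair enumeration, the Fisher-z store, BH, MA,
signed summaries, cluster filtering, cluster tables and partial
correlations are each tested against independent brute-force oracles
(double loops, flood fill, the inverse-correlation-matrix identity) to
1e-12 or bit-identity on small instances.

# Known limitations

* Real-data preprocessing (registration, motion correction, filtering,
  nuisance regression) is out of scope; inputs are assumed preprocessed
  and grid-aligned with the atlas.
* The per-pair linear model assumes within-site homoskedastic Gaussian
  residuals on the Fisher-z scale; gross violations (heavy motion
  outliers) are the user's responsibility to handle upstream.
* World coordinates are only as meaningful as the supplied affine: MNI
  peak coordinates require an MNI-space atlas.
* With a single site the combination step reduces to the identity, and
  site-level confounds are indistinguishable from group effects if groups
  are not represented within sites.
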