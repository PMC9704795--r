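---
title: "Extracting aging profiles from structural and functional connectomes"
author: "agingProfiles package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting aging profiles from structural and functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingProfiles)
```

# The problem

In older adults, structural connectivity (SC; white-matter streamline-derived
edge weights between parcellated cortical regions), functional connectivity
(FC; correlated spontaneous BOLD fluctuations) and cognitive performance all
change with age, and they do not change independently. This package
implements a pipeline that asks: *which joint patterns of SC, FC and
cognition are most characteristic of chronological age?* The answer takes
the form of **aging profiles**: latent components of a partial least squares
regression (PLSR) of age on a high-dimensional block of connectivity and
cognition predictors, each profile comprising one signed loading per
predictor plus a loading for a global cognition score.

The pipeline has six analysis stages, each its own module:

1. **Functional connectome** (`pearsonFC`, `edgeSignificance`, `fisherZ`,
   `splitSigned`, `buildFC`): Pearson correlation of node-wise BOLD time
   series; per-edge significance against phase-randomization surrogates
   (non-significant edges set to zero); Fisher r-to-z; split into FC~pos~
   (positive z) and FC~neg~ (absolute negative z) so that strength sums
   cannot cancel.
2. **Structural connectome** (`scTransform`, `triangularize`):
   log~10~-transform of non-negative streamline weights.
3. **Strength features** (`nodeStrengths`, `assembleFeatures`): per node,
   intra- and inter-network strength for each of SC, FC~pos~, FC~neg~ —
   six values per node, 2400 predictors on a 400-node parcellation, plus
   the cognition score COG.
4. **Cognition composite** (`screenAndImpute`, `excludeOutliers`, `kmo`,
   `pcaCog`): a 16-test battery is screened (≥3 missing values exclude a
   subject), sparse missingness is imputed by sex-by-age-decade stratum
   medians, per-test 3-SD outliers are excluded, sampling adequacy is
   quantified by the Kaiser–Meyer–Olkin index, and the first principal
   component of the standardized battery becomes COG.
5. **PLSR core** (`residualize`, `nipalsFit`, `looRmsep`, `selectNcomp`,
   `scrambledNull`, `repeatedSplits`, `varianceAccounting`): predictors are
   residualized for sex and education, decomposed by NIPALS PLS1 against
   age, the component count is chosen by a randomization test on
   leave-one-out errors, and the model is validated against scrambled null
   models and over repeated 80/20 train/test splits.
6. **Profiles** (`alignSigns`, `meanLoadings`, `networkMeanLoadings`,
   `frontalVsRestTest`, `componentAgeCorrelation`): per-split loadings are
   sign/order aligned to a full-sample reference, averaged into profiles,
   summarized per network, and the frontal-lobe emphasis of the structural
   profile is tested with a two-sample t-test.

# The regression model

Let $X$ be the $n \times p$ predictor block (strengths + COG, residualized)
and $y$ chronological age in years. NIPALS PLS1 extracts components
$t_a = E_{a-1} w_a$ with unit-norm weight vectors $w_a$, predictor loadings
$p_a = E_{a-1}^\top t_a / t_a^\top t_a$ and response loadings
$q_a = f_{a-1}^\top t_a / t_a^\top t_a$, deflating
$E_a = E_{a-1} - t_a p_a^\top$ and $f_a = f_{a-1} - q_a t_a$ after each
component. For a single response the inner NIPALS sweep stabilizes after
one refresh; the implementation still iterates the sweep with a $10^{-12}$
convergence tolerance and treats non-convergence as an error. Score vectors
are mutually orthogonal (asserted at $10^{-8}$), predictions at depth $k$
follow from $\beta_k = W_k (P_k^\top W_k)^{-1} q_k$, and at full rank they
coincide with ordinary least squares (a test asserts agreement at
$10^{-8}$, alongside an independent SIMPLS oracle).

**Centering and scaling.** Predictors are centered but *not* unit-scaled by
default (a `scale` flag exists). After the log/z transforms the
connectivity features live on commensurate scales, and unit-scaling would
inflate near-constant features (e.g. FC~neg~ strengths of strongly coupled
networks, which can be exactly zero for every subject and carry no
information). The COG column is standardized by construction.

**Component selection.** RMSEP($k$) is the root mean held-out squared error
of a $k$-component model under leave-one-out cross-validation, $k = 0$
being the mean-only model. Starting from the depth with globally minimal
RMSEP, the selected depth is the smallest $k$ whose per-subject squared
errors are not significantly worse than the minimizer's under a one-sided
sign-randomization test on the paired error differences
($\alpha = 0.01$, 1999 randomizations). This is the van der Voet style
randomization check; it is conservative for small real improvements.

**Null models.** `scrambledNull` permutes every predictor column
independently and permutes the response, preserving all marginals while
destroying both the predictor–response association and the
between-predictor dependence. Null RMSEPs are recomputed at a fixed depth
for comparability across replicates (re-running selection inside every
null replicate would conflate depth choice with performance).

**Split ensembles.** `repeatedSplits` draws `nReps` random train/test
splits (train size `round(fraction * n)`; 573 subjects at 0.8 give
458/115), fits on the training set and records the held-out correlation
between predicted and chronological age at every cumulative depth.
Per-replicate seeds derive deterministically from one master seed.

# Profile aggregation and orientation

PLS component signs are arbitrary, and nothing guarantees that replicate
$r$'s component 2 describes the same pattern as the reference's component
2. `alignSigns` therefore matches each replicate's components one-to-one
to the full-sample reference model by maximal absolute loading correlation
(greedy), jointly flipping weight/loading/response-loading triples when the
correlation is negative — an operation that provably leaves predictions
unchanged. Ambiguous matches (two candidates within $10^{-6}$) fall back to
index order with a warning.

After averaging, one global orientation rule is applied: each component is
flipped so that its full-sample score values correlate *non-positively*
with age. A positive loading then always reads "this predictor's value is
lower at higher ages", and the profile's score–age correlation is reported
with that orientation. The frontal-lobe contrast (`frontalVsRestTest`)
compares node-level mean loadings of one predictor family between frontal
and non-frontal nodes with a pooled-variance two-sample t-test (Welch
variant via a flag); it is run on the component with the strongest
structural signature.

# The synthetic cohort generator

The cohort data this analysis was designed for are not redistributable, so
the package ships a generator (`simulateCohort`) that emulates the
statistical structure the analysis assumes, with planted ground truth for
recovery testing. The generator is part of the tested surface, not a
fixture.

**Design.** Ages are uniform on [55, 85] (uniform rather than
cohort-shaped, to maximize identifiability at moderate $n$); sexes are
balanced; education is drawn on 8–18 years. Two (optionally three) latent
aging components $u_c$ are drawn per subject, each with unit variance and a
fixed correlation with age, mutually uncorrelated by construction:

* $u_1$ — **structural decline**: log edge weights of the streamline
  matrix decrease with $u_1$, at `frontalDeclineRate` per year on
  frontal-incident edges and `otherDeclineRate` elsewhere (defaults
  −0.004 and −0.00133 per year: a few tenths of a percent per year,
  three-fold steeper frontally). Weights are continuous positive
  ("SIFT-2-like") log-normal values around a fixed within-network-weighted
  backbone; tractography itself is out of scope.
* $u_2$ — **functional rebalancing**: every node's BOLD-like signal is a
  mixture of its network's latent AR(1) signal (coupling shrinking with
  $u_2$) and a global AR(1) signal (coupling growing with $u_2$), plus
  white noise — intra-network correlations fall and cross-network
  correlations rise at higher ages, the canonical
  segregation-to-integration shift.
* $u_3$ (optional) — growing cross-network anti-correlations via
  anti-coupled networks.

The 16 cognitive tests share one dominant latent $C$ with per-test
loadings, unique noise, test-native offsets/scales, a small education
effect, and optional completely-at-random missingness. $C$ is coupled to
the *functional* latent, and the functional latent's age correlation
defaults to $|{-0.44}|$ — the target age–cognition correlation — so that
$C = -u_2$ up to a vanishing residual and the calibration
$\mathrm{cor}(C, \mathrm{age}) = -0.44$ holds exactly in expectation. The
structural latent's age correlation defaults to 0.55.

**Why these defaults.** A response-driven bilinear decomposition mixes any
two age-correlated patterns in proportion to their response covariances.
The defaults were chosen, once, so that the two planted profiles are
actually separable by the method under study: the structural block has a
small raw-variance scale (realistic decline rates) so the
covariance-greedy first component is dominated by the
functional/cognitive pattern, while the structural block's high
signal-to-noise ratio supplies a genuine, selectable second component.
Latents are drawn mutually uncorrelated for the same reason. This is a
statement about what the generator emulates — clean, low-rank latent
structure — not about real cohorts, where patterns overlap and component
interpretations are correspondingly less crisp; passing recovery tests
here demonstrates correctness of the machinery, not realism of the data.

**Planted loadings.** The ground truth stores, per component, the analytic
sensitivity of every expected feature to its latent, propagated through
the same transforms the pipeline applies — $\log_{10}(1+w)$ for SC;
Fisher-z of the model-implied correlations for FC, including the
finite-length sampling attenuation of the sign-split means
($\Phi(\bar z/\sigma_z)$ factors with $\sigma_z = 1/\sqrt{T-3}$) — and
aggregated with the very strength formulas used downstream, oriented so
positive = lower at higher age. Recovery tests correlate aligned mean
loadings against these vectors.

**What the generator does not emulate:** hemodynamics, head motion,
scanner drift and physiological noise; spatial autocorrelation on the
cortical sheet; non-MCAR missingness; cohort-shaped age distributions;
tractography biases. Conclusions from passing tests are therefore about
the analysis code, not about brain data.

# Numerical choices and edge cases

* **Surrogates**: independent uniform random phases per positive-frequency
  bin, conjugate-mirrored; DC and (for even length) Nyquist bins untouched,
  so surrogates are real with preserved mean and amplitude spectrum
  (asserted at $10^{-10}$). Both series of an edge are surrogated
  independently. The per-edge p-value is two-sided on $|r|$ with the
  $+1$ permutation correction, and ties count against significance.
* **Fisher guard**: $|r|$ is clipped to $1 - 10^{-7}$ before `atanh`
  (finite-sample $r = \pm 1$ occurs on degenerate synthetic input); with
  clipping disabled a boundary value is an error. Zeros map to zeros, so
  masking and transforming commute.
* **SC log transform**: $\log_{10}(\mathrm{offset} + w)$ with offset 1, so
  absent edges map to exactly 0 and order is preserved; a plain
  $\log_{10} w$ is undefined at $w = 0$. The offset is configurable; a
  transformed matrix is flagged and refuses a second transform.
* **Inter-strength denominator**: the per-node possible-edge count
  $N - n_k$ (symmetric with the per-node sum). The network-total
  alternative $n_k(N - n_k)$ is available via `interDenominator`; the
  intra denominator is the network-level $n_k(n_k-1)/2$ exactly as the
  strength estimate is defined, even though it pairs a per-node sum with a
  network-level count.
* **Decade strata**: 55–64, 65–74, 75–84, 85+ — a contiguous cover; an
  empty imputation stratum is an error naming the stratum.
* **Outlier rule**: per-test mean ± 3 SD on the screened sample, one pass;
  zero-SD tests exclude nobody. One pass is deliberate: iterating the rule
  can cascade on heavy-tailed samples.
* **COG sign**: the first principal component is oriented so the majority
  of test loadings are positive (higher COG = better performance); scores
  are standardized over retained subjects.
* **Selection edge cases**: if the global RMSEP minimum is the mean-only
  model, 0 components are selected; exhausted predictor blocks and
  degenerate scores abort with the component index.

# Problem sizes used by the tests

The packaged checks run the full pipeline at a reduced scale chosen for
test turnaround: cohorts of 300 subjects on a 100-node parcellation
(601 predictors), leave-one-out depths up to 4–5, 200 scrambled nulls,
and split ensembles of 60–200 replicates; component-count recovery is
evaluated over 50 generator seeds. The acceptance script mirrors these
sizes and additionally verifies the structural identities at the full
400-node scale. Edge-level surrogate testing inside the recovery loop is
disabled (`alpha = NULL`): the masking step's error calibration is
validated separately on autocorrelated null signals, and component
recovery is driven by the latent structure, not by the per-edge threshold.

# Known limitations

* PLS1 component interpretations are rotation-sensitive: when two planted
  patterns have comparable response covariance on comparable variance
  scales, the first component is their blend and per-component recovery
  degrades even though the planted *subspace* and the selected component
  *count* remain correct. The generator's defaults avoid this regime by
  construction; real data need not.
* The randomization selection test is conservative near the RMSEP
  plateau; with weak secondary signal it prefers fewer components.
* The surrogate edge test controls the per-edge type-I rate, uncorrected
  across edges, as the construction specifies.
* `runPipeline` caches nothing between runs; reproducibility is handled
  by recording the full configuration and output hashes in the manifest
  and deriving all randomness from the configured seed.
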