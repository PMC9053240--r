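---
title: "Graph-spectral band energies of BOLD and the serum NfL protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-spectral band energies of BOLD and the serum NfL protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldband)
```

## The scientific problem

Serum neurofilament light chain (NfL) is a blood marker of neuro-axonal
damage that also drifts upward with normal ageing. Interpreting an NfL
value therefore needs a model of its baseline variation, and `boldband`
implements one candidate family of explanatory features: per-region
measures of how strongly resting-state BOLD activity conforms to, or
deviates from, the subject's own white-matter anatomy. The package covers
the analysis from exported matrices onward — structural connectomes
(streamline counts between cortical parcels) and region-by-time BOLD
matrices — together with the statistical protocol that links the derived
features to NfL, age, personality scores, and structural measures.

## The graph-spectral model

A subject's connectome is an undirected weighted graph on $n$ cortical
regions with symmetric nonnegative adjacency matrix $\mathbf{A}$ (zero
diagonal). Because $\mathbf{A}$ is symmetric it eigendecomposes as
$\mathbf{A} = V \Lambda V^{\top}$ with orthonormal $V$ and real
eigenvalues $\lambda_0 \le \dots \le \lambda_{n-1}$. The graph Fourier
transform pair is $\hat{x} = V^{\top} x$, $x = V \hat{x}$, applied
columnwise to each timepoint of a region-by-time matrix.

A point that deserves emphasis because it inverts the Laplacian-based
intuition: for the *adjacency* GFT, eigenvectors with **large**
eigenvalues vary smoothly over the graph, while eigenvectors with small
or negative eigenvalues oscillate across edges. Band membership is
therefore defined on sorted position, with the default band size
$K = 10$:

* **high graph frequency** = sorted indices $0,\dots,K-1$ (the $K$
  smallest eigenvalues; spatially most variable modes);
* **low graph frequency** = indices $n-K,\dots,n-1$ (the $K$ largest;
  smoothest modes).

Filtering projects onto the band subspace, $y = V F V^{\top} x$ with
binary $F$, and a region's band energy is the $\ell_2$ norm of its
filtered series over time. At $n = 66$ this gives the 132-feature
predictor table (66 regions $\times$ 2 bands). Squared energies are
available behind an argument (`squared = TRUE`) because downstream linear
models are not invariant to that monotone transform; the default is the
plain $\ell_2$ norm.

Degenerate eigenvalues are allowed. Band *energies* are invariant to
eigenvector sign flips and to reordering inside a degenerate block
(projections onto the subspace are unique), and the test suite checks
this by randomly flipping signs. The one genuinely ambiguous case is a
tie exactly at a band boundary, where the passed subspace depends on the
solver's ordering; the package emits a classed warning
(`boldband_warning_degenerate`) rather than guessing, since no convention
can make the split well defined. For reproducible serialization each
eigenvector's largest-magnitude entry is made positive (ties broken at
the lowest index).

## BOLD preprocessing

The pipeline is trim $\rightarrow$ detrend $\rightarrow$ band-pass
$\rightarrow$ z-score, enforced by stage tags (re-applying an idempotent
stage is allowed; skipping ahead is an error):

* **Trim**: the first `floor(18 / TR)` frames are dropped — exactly 9
  frames at the targeted TR of 2 s, so there is no rounding ambiguity at
  the design values (154 raw frames become 145).
* **Detrend**: per-region least-squares line removal; residuals have zero
  mean and zero covariance with time.
* **Band-pass**: a hard (brick-wall) DFT-bin mask retaining
  $0.009 \le f \le 0.1$ Hz inclusive. A hard mask was chosen over a
  tapered filter because it is exactly testable (a sinusoid on a retained
  bin passes bit-for-bit; one on an excluded bin is annihilated) and the
  band edges only marginally affect band energies. The DC bin is excluded
  whenever the lower edge is positive.
* **Z-score**: per-region mean 0 and *sample* (denominator $T-1$) SD 1.
  Either SD convention would only rescale energies uniformly per region;
  one had to be fixed for bit-reproducibility.

Energies are computed on the fully preprocessed (z-scored) series, i.e.
z-scoring precedes graph filtering.

## The NfL statistical protocol

**Univariate stage.** Each feature is tested by simple linear regression
on NfL: $F = (n-2) r^2 / (1 - r^2)$ on $(1, n-2)$ df, identical to the
two-model ANOVA comparison (the suite verifies this against an explicit
residual-sum-of-squares oracle). No covariate enters the univariate
F-test. FDR correction is Benjamini–Hochberg over the full per-cohort
feature family (all 132 features jointly) — the natural family for this
screen. Constant features are flagged, never silently dropped; a
perfectly collinear feature reports $F = \infty$, $p = 0$.

**PLS regression.** NIPALS with a univariate response, all inputs
z-scored internally with stored parameters for out-of-sample scoring.
NIPALS was fixed (over SIMPLS and others) because it is deterministic and
the protocol's final models all use one component, where the algorithms
agree anyway. Component count can be chosen by leave-one-out MSEP
(ties toward fewer components), but the small cohorts this protocol
targets force one component via an explicit override.

**VIP.** $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a
(w_{aj}/\lVert w_a \rVert)^2 / \sum_a \mathrm{SSY}_a}$, with
$\mathrm{SSY}_a$ the outcome variance explained by component $a$. The
identity mean(VIP²) = 1 is asserted to $10^{-8}$ on every fitted model in
the tests.

**Permutation gate.** The outcome is shuffled `n_perm` times (default
5000 for standalone use) and the model refit each time; the model is
declared *overfit* when the null distribution of training $R^2$ has mean
above 0.5. This is the protocol's guard against the $p \gg n$ regime: a
132-feature model on 20 subjects explains most of the variance of pure
noise. The observed $R^2$'s one-sided significance uses $\ge$ in the
count. For a single feature the permutation expectation of $r^2$ is
exactly $1/(n-1)$, which the suite checks to three Monte-Carlo standard
errors.

**VIP sweep and cross-validation.** VIP scores from the full-feature
one-component model are thresholded over the grid 0.8–2.0 in steps of 0.1
(the grid is configurable; the sweep's source protocol specifies varying
the threshold without printing values, and 0.8–2.0 brackets the
conventional VIP = 1 cut); each surviving subset yields a one-component
candidate model with its own permutation gate. Inside leave-one-out
cross-validation the sweep runs on the training subjects only, and among
non-overfit candidates the fold's model is chosen by the smallest
absolute error *on the held-out subject*. That rule consults the held-out
outcome — an information leak that biases $Q^2$ upward — but it is the
protocol's stated rule and is implemented verbatim because it is what
produced the reference results; the leak-free alternative (smallest
training-set LOO MSEP, `rule = "train_msep"`) is implemented alongside
and the test suite demonstrates the direction of the bias on null data.
Folds with no surviving candidate predict the training mean. $Q^2 = 1 -
\sum_i (y_i - \hat{y}_{-i})^2 / \sum_i (y_i - \bar{y})^2$.

Inside the nested sweep the gate uses 200 permutations per candidate
(configurable) rather than 5000: the gate only needs the null *mean* to a
few percent to compare against the 0.5 threshold, and 200 draws give a
standard error of roughly $0.15/\sqrt{200} \approx 0.01$ on that mean,
comfortably sharp for the decision while keeping the full nested protocol
at interactive speed.

**Cohort specificity.** `transfer_r2()` scores a fitted model on a second
cohort with the training cohort's standardization (values may be
negative), and `vip_agreement()` computes Kendall's tau between two
cohorts' VIP profiles over the shared feature namespace.

## Association suite

**Partial correlation** residualizes both variables on an intercept plus
covariates and correlates the residuals; $p$ from the t distribution on
$n - k - 2$ df. With no covariates it reduces exactly to Pearson.

**Mediation** uses raw (unstandardized) variables and no extra
covariates: $a$ from $M \sim X$, $b$ and $c'$ from $Y \sim X + M$, $c$
from $Y \sim X$, $ab = a \cdot b$, so $c = c' + ab$ holds exactly as an
OLS identity (asserted to $10^{-10}$). Significance per path is a
case-resampling bootstrap (default 10000 resamples) with percentile
two-sided p-values — twice the smaller tail proportion around zero — and
a bias-corrected option behind `boot_type = "bias_corrected"`; percentile
is the default because the reference toolbox's option choice is not
documented. Raw units keep path coefficients on interpretable scales
(pg/mL per year, and so on); a caller can standardize beforehand if SD
units are wanted.

**Moderation** regresses $Y$ on covariates, $X$, $W$, and $X \cdot W$.
$X$ and $W$ are mean-centered by default purely for interpretable main
effects: the interaction coefficient — the quantity of scientific
interest — is invariant to translation of either variable, which the
tests verify to $10^{-10}$ by fitting both ways. Simple slopes are
reported at moderator values mean $\pm$ SD with delta-method standard
errors. A design condition number above $10^8$ triggers a warning, not a
failure.

## The synthetic-cohort generator

The generator exists so that every stage has a ground truth. It emulates:

* **Connectomes**: block-modular Poisson streamline counts (default 4
  modules, within-module mean 20, between-module mean 2), symmetric, zero
  diagonal, resampled until connected. These mimic the modular, heavy-
  diagonal-block structure of real tract-count matrices.
* **BOLD**: signals are drawn directly in graph-spectral space —
  coefficients in the low and high bands with configurable scales — and
  inverse-transformed. Requested (region, band) energies are then hit
  *exactly* (at zero noise) by alternating row-rescaling with band
  reprojection. A feasibility constraint is worth recording: the
  per-region energies of a $K$-mode band are quadratic forms
  $v_i^{\top} M v_i$ in the $K \times K$ Gram matrix of the band
  coefficients, which has $K(K+1)/2$ degrees of freedom — 55 at $K = 10$
  — so one cannot prescribe all 66 regions of a band exactly; the
  generator is designed for planting a small number of targeted features
  and warns if the projection does not converge.
* **Outcomes**: age $\sim$ Normal(50, 11²) truncated at 20 years
  (matching the age structure of the middle-aged cohorts this protocol
  targets), and NfL $= \beta_0 + \beta_{\mathrm{age}} \cdot \mathrm{age}
  + \sum_j \beta_j z(\mathrm{feature}_j) + \varepsilon$, floored at
  0.1 pg/mL. Planted effects are per SD of the measured feature, so a
  single planted feature with $\beta = 1$ and $\sigma = 1$ gives
  generative $R^2 = 0.5$ exactly. Defaults $\beta_0 = 10$,
  $\beta_{\mathrm{age}} = 0.266$ pg/mL per year and residual SD 2 put
  simulated NfL in the realistic 10–25 pg/mL range for this age span.
* **Mediation/moderation data**: triplets with chosen path coefficients
  (defaults $a = -0.05$, $b = -2.2$, $c' = 0.16$) and a volume-scale
  moderation model with a chosen interaction coefficient (default
  16.495, residual SD 50 mm³, about 3% of a typical subcortical volume).

Because planted series are constructed in spectral space they carry the
`"zscored"` (analysis-ready) stage tag: running the time-domain
preprocessing on them would destroy the planted energies, and they do not
pretend to be raw scanner output. Consequently, what passing tests on
synthetic cohorts demonstrate is the correctness of the decomposition,
selection, and inference machinery under the linear generative model —
not that real BOLD obeys that model. The generator deliberately omits
hemodynamic autocorrelation, head-motion artifacts, and empirical
connectome weight distributions.

All generators are bit-reproducible under a master seed
(`withr::with_seed`, leaving the caller's RNG untouched), and derived
seeds stay far below $2^{31}$.

## Numerical choices and problem sizes

* Symmetry tolerance $10^{-8}$ (relative) with repair by averaging;
  orthonormality and reconstruction asserted at $10^{-8}$/$10^{-6}$;
  GFT round trips and projection identities at $10^{-10}$.
* Degenerate band boundaries warn (see above); MSEP ties break toward
  fewer components via the first minimum.
* The test suite runs the full nested cross-validation at $n = 20$,
  $p = 132$ with 200-permutation gates, the Parseval partition over 200
  random 66-region subjects, BH-versus-brute-force agreement over 1000
  random p-vectors, mediation null calibration over 200 datasets of
  $n = 50$, and parameter recovery at $n = 2000$ (mediation) and
  $n = 500$ (moderation); these sizes were chosen to make the checks
  sharp at interactive runtimes.

## Known limitations

* Only the adjacency-based GFT is implemented; Laplacian variants order
  frequencies differently and are out of scope.
* The univariate F-test carries no covariate adjustment; age enters the
  protocol downstream through partial correlation and mediation.
* The protocol's fold-model selection rule is optimistically biased by
  construction (see above); for honest prediction claims use
  `rule = "train_msep"` and report both.
* Mediation here is the classic three-regression decomposition with
  bootstrap inference — no sensitivity analysis, multilevel structure, or
  latent-variable modelling.
* The moderation model assumes a single product term; higher-order or
  multi-moderator designs must be composed by the caller.
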