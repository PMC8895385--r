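---
title: "Modeling orientation adaptation in V1 with a mixture of Gaussian scale mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling orientation adaptation in V1 with a mixture of Gaussian scale mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A V1 neuron's classical receptive field (CRF) is modeled as eight oriented
filters at the patch centre — four orientations (0°, 45°, 90°, 135°) in
quadrature pairs — and its extra-classical surround (nCRF) as eight filter
positions on a ring, again with four orientations and two phases per
position. Filtering a patch gives a centre vector $C \in \mathbb{R}^8$ and
four surround group vectors $N_\theta \in \mathbb{R}^{16}$.

Responses of oriented filters to natural inputs are heavy-tailed and
exhibit multiplicative dependencies, which a Gaussian scale mixture (GSM)
captures: a coefficient group $x$ is generated as $x = v\,g$ with
$g \sim \mathcal{N}(0, \Sigma)$ and a positive mixer $v \sim
\mathrm{Rayleigh}(1)$. Groups that share a mixer are statistically
dependent; groups with separate mixers are independent. The model is a
*mixture* over five sharing configurations $\xi$:

* **non-shared** $\xi_*$: the centre is independent of every surround
  group — $p(C, N \mid \xi_*) = p(C;\Sigma_C)\prod_\theta
  p(N_\theta;\Sigma_{N\theta})$;
* **co-shared** $\xi_\theta$ (one per orientation): the centre and the
  surround group at $\theta$ share one mixer —
  $p(C, N \mid \xi_\theta) = p\big((C,N_\theta);\Sigma_{CN\theta}\big)
  \prod_{\theta' \neq \theta} p(N_{\theta'};\Sigma_{N\theta'})$.

Every co-shared joint block contains the *full* eight-dimensional centre
(all four orientations), not only the centre pair at $\theta$: the
covariance perturbations below act on centre variances of several
orientations inside one joint block, which requires those variances to be
present. The surround-only covariances $\Sigma_{N\theta}$ are required for
the likelihoods to be densities over the same 72-dimensional observation
for every component; without them the components' densities would live on
spaces of different dimension and could not be compared by Bayes' rule.

With $\lambda(x) = \sqrt{x^\top\Sigma^{-1}x}$, the Rayleigh-mixer GSM has
closed forms through modified Bessel functions $K_\nu$:

$$p(x) = (2\pi)^{-d/2}\,|\Sigma|^{-1/2}\,\lambda^{1-d/2}\,
K_{d/2-1}(\lambda), \qquad
\mathbb{E}[v^p \mid x] = \lambda^{p/2}\,
\frac{K_{(2-d+p)/2}(\lambda)}{K_{(2-d)/2}(\lambda)}.$$

All Bessel evaluations are exponentially scaled and log-domain, so
likelihoods are finite from $x = 0$ (where $\lambda$ is floored at
$10^{-12}$; the marginal genuinely diverges there for $d \ge 2$) up to
$\|x\| \sim 10^6$. Every closed form is cross-checked in the test suite
against `gsm_moment_quadrature()`, an independent adaptive-quadrature
evaluation of the defining mixer integrals.

## The readout and its estimator

The model's response at a centre channel $i$ is a posterior-weighted
combination of per-component channel estimates. Before adaptation the
weights are the component posteriors (the mixture readout); after
adaptation a winner-take-all (WTA) rule replaces them with a one-hot
selection.

Two per-component estimators are implemented:

* `"quadratic"` (default): $R_i = x_i \cdot x^\top\Sigma^{-1}x$, the
  component's channel response weighted by its Mahalanobis energy. Under
  this rule, *raising* a channel's variance in a covariance — i.e.
  strengthening the normalisation pool contributed by that orientation —
  *lowers* the responses it drives, and *weakening* surround variance and
  covariance *raises* responses: suppression-by-strengthened-normalisation
  and facilitation-by-disinhibition. These are the directions that
  orientation-adaptation phenomenology (suppression at the adapted
  orientation, repulsive shifts, attraction via increased centre
  normalisation plus weakened surround) requires, and the package's
  acceptance checks verify them end to end.
* `"posterior_mean"`: the Bayesian coefficient estimate
  $\mathbb{E}[g_i \mid x] = x_i\,\mathbb{E}[1/v \mid x]$, the classical
  divisive-normalisation form. It is kept as an option and is fully
  oracle-validated, but it responds to covariance changes with the
  opposite sign (raising a channel's variance shrinks $\lambda$ and so
  *raises* that channel's estimate), and therefore cannot reproduce the
  adaptation directions above. We consider the quadratic form the model's
  operative response rule and the posterior mean a useful comparison
  point.

**WTA scope.** The after-adaptation selection vector is inferred *once*,
from the adapting stimulus under the adapted state, and applied across the
entire tuning curve (a $1\times 5$ one-hot vector multiplying the
$5 \times M$ matrix of component responses over the $M$ grid
orientations). This is why the winning component's posterior is constant —
pinned at 1 — across all test orientations. A per-test-stimulus WTA is
available through `wta_response()` but is not what the tuning-curve
readout uses: with heavy-tailed likelihoods the per-stimulus winner simply
tracks the test orientation and no prior change can pin it.

## Training

`fit_mgsm()` is an exact expectation–maximisation loop. The E-step
computes component responsibilities per patch in the log domain; the
M-step sets priors to mean responsibilities (floored at `min_prior` $=
10^{-4}$ to keep all five components live for the WTA) and each covariance
to the responsibility- and $\mathbb{E}[v^{-2}\mid x]$-weighted second
moment of its coefficient vectors — the GSM-exact update. Stored
covariances are trace-normalised ($\mathrm{tr}\,\Sigma = d$) with the
removed factor kept as an explicit scalar `scale`, so the update remains
the exact unconstrained EM step and the data log-likelihood is
non-decreasing to machine precision (asserted at tolerance $10^{-8}$ in
the tests). A diagonal M-step ridge is available (`cov_ridge`) but
defaults to 0: a ridge perturbs the exact update and measurably breaks
monotonicity; degenerate updates are instead caught by a conditional
eigenvalue guard.

Initialisation is orientation-aligned: each patch is hard-assigned to its
dominant centre orientation and each co-shared covariance starts from its
own cluster's second moment. This anchors component labels to their
orientations; with a label-symmetric initialisation EM converges to
states whose component identities are arbitrary, which makes "the prior
of the 90° component" meaningless.

Convergence is declared at a relative log-likelihood change below
$10^{-6}$ or 200 iterations (both configurable).

## Synthetic stimuli

**Gratings** are deterministic functions of their specification
(orientation mod 180°, 0° = horizontal stripes, counter-clockwise;
contrast in $[0,1]$; phase; spatial frequency fixed by default at the
filter bank's peak, 0.25 cycles/px). The *small* aperture is the centre
kernel footprint plus one pixel (11 px at the default geometry): it covers
the CRF while keeping every surround group's energy below 5% of the centre
energy — but finite. Exactly-zero surround blocks are avoided deliberately,
because the GSM marginal diverges at the origin and an exact zero hands an
unbounded log-density bonus to whichever components model that group
independently. The *large* aperture is the full patch.

**Natural-surrogate textures** emulate the training-relevant statistics of
natural patches: a $1/f$ amplitude spectrum; *local* orientedness (each
patch's spectrum is concentrated around a random dominant orientation,
drawn uniformly so the ensemble is isotropic — as natural patches are
dominated by local contours while scene ensembles are near-isotropic);
heavy tails and centre–surround comodulation from a patch-wide Rayleigh
mixer; and a 25% fraction of *heterogeneous* patches whose centre disk and
surround annulus come from independent fields with independent mixers,
emulating object boundaries. The heterogeneous fraction is what keeps the
non-shared component populated, as it is in natural-image-trained states.
Per-patch orientation concentration (`patch_anisotropy = 0.85`) is strong:
weakly oriented patches are ambiguous between neighbouring orientation
components, and that ambiguity lets component labels drift during long EM
runs.

**The mixed adaptation set** combines textures with full-field gratings
whose orientation is Gaussian around the adaptor (σ = 5°; the stated
spread is read as a standard deviation — a 5 deg² variance would be an
implausibly narrow ±2° band), contrast uniform on $[0.2, 1]$ and phase
uniform on $[0, 2\pi)$. The grating fraction defaults to 0.3: large enough
for the adaptor's component prior to rise visibly, small enough to keep
the natural-statistics structure. Gratings carry a broadband $1/f$ noise
floor (`grating_noise_rms = 0.1`, a third of the texture RMS): a displayed
and sensed grating is never a pure sinusoid, and without the floor the
grating ensemble spans a near-degenerate response manifold whose fitted
covariance collapses, destabilising the whole mixture (the adapted
component then expels its own natural patches). The default ensemble
sizes follow the reference protocol (25 000 baseline patches, 26 000
mixed patches); the package's own tests and the acceptance script run the
same pipelines at 5 000/3 000 patches, which this package treats as its
desk-scale study size.

## Adaptation

Two state-update routes are implemented, and which one carries the signal
depends on the stimulus size:

* **Small gratings (CRF only).** The state is fully retrained from
  scratch on the mixed set. The retrained covariances absorb the
  adaptor's orientation (its variance rises in the centre blocks), and the
  quadratic readout turns that into suppression concentrated at the
  adapted orientation, repulsive peak shifts for flank adaptors, and
  overall non-suppression for orthogonal adaptors. The WTA winner for a
  small adapting grating is the non-shared component: a CRF-only stimulus
  leaves the surround nearly silent, which the factorised components
  explain best regardless of priors.
* **Large gratings (CRF + nCRF).** The retrained *priors* are
  transplanted into the baseline state (prior substitution,
  `freeze_covariance = TRUE`), leaving the natural-trained covariances in
  place. The WTA winner for the large adapting grating is the adaptor's
  co-shared component (stimulus-matched and prior-boosted at once), and
  that single component is read out across the grid: peak responses are
  maintained for an adaptor at the preferred orientation, enhanced for an
  orthogonal one, and the flank case yields repulsion-plus-enhancement
  but *no* attraction — the negative control.
* **Attraction requires the covariance route.** Declarative
  perturbations of the adaptor component's joint covariance implement the
  connectivity change: `center_up` multiplies the centre-block variances
  of the three non-adapted orientations by 2; `surround_down` multiplies
  the surround variances and all surround covariances (including
  centre–surround cross terms) by 0.5; `combined` composes both;
  `combined_double` doubles the centre scaling to 4. The magnitudes are
  free parameters chosen as the smallest round values that realise
  "increase", "weaken" and "double"; all are configurable. Under the
  combined perturbation the tuning-curve peak shifts toward the adaptor
  (attraction), and doubling the centre scaling shifts it at least as
  far. In this implementation the centre-variance increase *alone* does
  not produce the attraction shift — only the combination with surround
  weakening does — which we note as a deviation from the reference
  account of the isolated-centre manipulation. Perturbed matrices are not
  re-normalised (the perturbation is the signal); an eigenvalue floor at
  $10^{-8}\lambda_{\max}$ repairs positive-definiteness, and for all
  shipped presets the repair is a no-op.

## Tuning-curve protocol

Responses are measured on a −90°…+90° grid (15° steps) relative to the
model's preferred orientation (the 90°-preferring centre channel), at
contrast 0.5, averaging the rectified (absolute-value) even- and
odd-channel estimates over 8 equally spaced grating phases — emulating the
drift-averaged firing rates physiological tuning curves report, and making
the reported responses non-negative. Preferred orientations are located by
parabolic interpolation around the grid argmax, so metrics are not
quantised to the 15° grid; `shift_deg` is signed positive toward the
adaptor. The model's components exist only at 45° spacing, so
after-adaptation peaks land near component orientations rather than at
arbitrary angles — adaptation at intermediate orientations (say 30°)
cannot be finely simulated.

## What the synthetic generator does and does not show

The surrogate textures reproduce the spectral, heavy-tail and
centre–surround-dependency statistics the model's training exploits, with
ensemble isotropy verified both analytically (from the spectral mask) and
by Monte Carlo over generated patches. They do not contain occlusions,
curved contours, multi-scale structure, or photometric nonlinearities of
real scenes; passing tests therefore demonstrate that the *pipeline*
(filtering → EM → adaptation → readout) produces the adaptation
phenomenology under the stated statistics, not that the same parameter
values would be recovered from any particular natural-image corpus. The
optional external-image path accepts any grayscale raster converted to a
matrix.

## Numerical choices

* Cholesky-based Mahalanobis forms; log-sum-exp posterior normalisation.
* Exponentially scaled Bessel functions with a small-argument series
  fallback; $\lambda$ floored at $10^{-12}$.
* Quadrature oracle: integrand peak-normalised at its analytic mode
  $v_*^2 = \big(-(d-1)+\sqrt{(d-1)^2+4\lambda^2}\big)/2$, integrated by
  `stats::integrate` at relative tolerance $10^{-10}$.
* WTA ties break toward the lowest component index (non-shared first);
  ties are measure-zero in practice.
* State files are JSON with doubles at 17 significant digits, which
  round-trips IEEE values bit-identically and is endianness-safe.

## Known limitations

* Component labels are meaningful only under the orientation-aligned
  initialisation; restarting EM from symmetric initial conditions can
  converge to permuted or partially merged labelings.
* The magnitude scale of the quadratic readout is not calibrated between
  covariances trained on different ensembles; before/after comparisons
  across a full retrain are therefore interpreted directionally, and the
  large-grating protocol uses prior substitution for exactly this reason.
* Only the four model orientations support co-shared components; no
  near/far surround subdivision; static stimuli only (no drift, colour,
  or plaids).
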