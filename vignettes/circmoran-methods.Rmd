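---
title: "Measuring spatial synchronization with Moran's I and its circular variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial synchronization with Moran's I and its circular variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmoran)
```

## The statistic and its reading

Moran's index for N observations $X_i$ at locations $Z_i$ with spatial
weights $w_{ij}$ is implemented as

$$I \;=\; \frac{N \sum_{ij} w_{ij}\,(X_i-\bar X)(X_j-\bar X)}
             {\sum_{ij} w_{ij}\; \sum_i (X_i-\bar X)^2},$$

the classical form in which the weighted cross-product of deviations is
normalized by the total weight $S_0=\sum_{ij}w_{ij}$ and the total
variance. Typeset presentations of this ratio are easy to misread (the
$N$ can be attached to either the numerator or the denominator); the form
above is pinned down by two exact anchors that the test suite asserts:
a strict binary checkerboard under range-1 von Neumann weights gives
$I=-1$ exactly, and the average of $I$ over all relabelings of any field
is $-1/(N-1)$ (verified exhaustively at $N=4$). No row standardization of
the weights is performed — the $1/S_0$ prefactor already normalizes
globally, and binary von Neumann matrices keep their combinatorial
meaning (each adjacency counts once).

For instantaneous phases the observations live on the circle, where
arithmetic differences misjudge displacement (e.g. $\pi$ and
$-\pi+\epsilon$). The circular variant $I_\theta$ substitutes the signed
shortest angular distance to the circular mean,
$d_\theta(X_i,\bar X)=\operatorname{atan2}(\sin(X_i-\bar X),\cos(X_i-\bar X))$
with $\bar X=\operatorname{atan2}(\bar S,\bar C)$, for the arithmetic
deviation; everything else is unchanged. $I_\theta$ is invariant under a
global phase rotation (the circular mean co-rotates), which the suite
checks to $10^{-9}$.

Phases are canonically wrapped to $(-\pi,\pi]$ on ingestion; the atan2
convention assigns the boundary to $+\pi$. The circular mean is declared
undefined when the resultant length falls below $10^{-9}$ — anti-phase
fields (phases $0$ and $\pi$ in balance) therefore raise an error rather
than receiving an arbitrary mean; the statistic is simply inapplicable
there, and guessing a mean would silently flip signs of all deviations.

## Weights

Three constructors cover the use cases: `grid_von_neumann_weights()`
(binary, Manhattan range $r$, open boundaries, exactly symmetric),
`inverse_distance_weights()` ($\|Z_i-Z_j\|^{-\alpha}$, error on
coincident points, $\alpha=0$ giving uniform off-diagonal weights), and
`distance_band_weights()` (indicator of $d_{lo} < d \le d_{hi}$).
Correlogram bands are half-open so consecutive bands partition the
pairwise distances without double counting; empty bands are flagged and
reported as `NA` rather than dropped, so a correlogram's lag axis stays
honest. Grid cells excluded by a tissue mask are removed from the index
space entirely — not zero-weighted — so that $N$ in the Moran ratio
counts only valid units.

## Monte-Carlo inference

Two null constructions are provided. *Resampling* draws each unit's value
i.i.d. from a reference distribution (fair binary for scalar fields,
uniform on the circle for phases, or any user sampler); *randomization*
permutes the observed values over locations, conditioning on the observed
multiset. The implementation exploits that the Moran denominator is
permutation-invariant, so randomization reduces to permuting a fixed
deviation vector; both paths are validated against literal double-loop
evaluation of the definition to $10^{-12}$ relative error.

One subtlety is worth recording: for circular fields the permutation-null
mean is $(S_1^2/S_2-1)/(N-1)$ with $S_1=\sum_i d_\theta(X_i,\bar X)$ and
$S_2=\sum_i d_\theta(X_i,\bar X)^2$, because the signed circular
deviations need not sum to zero (the circular mean zeroes
$\sum\sin(X_i-\bar X)$, not the wrapped deviations themselves). Only in
the scalar case does this reduce to the textbook $-1/(N-1)$.

P-values use the add-one (pseudo-count) rule
$p=(1+\#\{\text{at least as extreme}\})/(n+1)$, so $p=0$ cannot arise
from a finite sample; two-sided p doubles the smaller tail, capped at 1.
Critical bands are empirical quantile pairs with linear interpolation
between order statistics (`quantile()` type 7). Degenerate resampled
fields (constant draws, or circular draws with undefined mean) are
rejected and redrawn with a cap of $100\,n$ attempts; this conditions the
null on non-degeneracy, a negligible effect at the field sizes in play
but documented here for completeness. Randomization is the default mode
(also in the CLI) because it conditions on the observed values.

## Phase extraction

`hp_detrend()` removes the slow baseline of bioluminescence rundown by
subtracting the Hodrick–Prescott trend, solved as the sparse banded
system $(\mathbf I+\lambda D_2^\top D_2)\tau=s$ per unit. The default
$\lambda = 0.05\,(24\,\mathrm h/\Delta t)^4$ follows the period-scaled
convention of the detrending literature for circadian data (for
$\Delta t = 0.5$ h this is $\lambda \approx 2.65\times10^5$); it is
always user-overridable, and linear baselines are removed exactly for any
$\lambda$. In the $\lambda\to0$ limit the trend follows the data and the
residual vanishes.

`analytic_signal()` forms $z(t)=s(t)+iH(s(t))$ with the discrete FFT
Hilbert transform (one-sided spectrum: positive frequencies doubled, DC
and Nyquist kept, negative frequencies zeroed), then
$\theta(t)=\operatorname{atan2}(\Im z,\Re z)$ and $A(t)=|z(t)|$. The
discrete transform is unreliable near the record ends; the first and last
12 h are flagged via an `edge_mask` attribute so downstream statistics
can exclude them — the window matches roughly half a circadian period,
where cosine-fixture errors empirically exceed the interior error by an
order of magnitude. Phase unwrapping exists (`unwrap_phase()`) only as a
diagnostic; $I_\theta$ and $R$ are wrap-invariant and never use it.

The bimodal von Mises fit runs EM with 10 random restarts
(seed-controlled), tolerance $10^{-8}$ on the relative log-likelihood
change, and concentrations via Fisher's Bessel-ratio inversion capped at
$\kappa=10^3$. On effectively unimodal data the two components coalesce
and EM creeps along a flat ridge before settling — hence the generous
iteration cap (10^4) — and the result is flagged `unimodal` when one
component absorbs $\ge95\%$ weight, the means nearly coincide
($\Delta\mu<0.1$ rad), or the BIC prefers a single von Mises component.
The last criterion is this package's design choice: the first two alone
miss the symmetric straddle solution where two half-weight components sit
on either side of a single mode.

## The lattice Kuramoto simulator

`simulate_lattice()` integrates
$\dot\theta_i=\omega_i+K\sum_{j\in N_1(i)}\sin(\theta_j-\theta_i)$ with
intrinsic periods $\tau_i\sim\mathcal N(24\,\mathrm h, 2\,\mathrm h)$
(truncated at $\tau>1$ h; $\omega_i=2\pi/\tau_i$) and uniform random
initial phases, both fixed by the seed. Design choices, each genuinely
open in the problem statement:

- **Open boundaries.** Edge oscillators have 2–3 neighbors. A finite
  tissue explant has no wraparound, and off-center stable spirals are
  only consistent with non-periodic boundaries. The neighborhood is
  always "the $r=1$ von Neumann neighbors of oscillator $i$".
- **Mean-field normalization.** Global coupling uses $(K/N)\sum_j
  \sin(\theta_j-\theta_i)$ so that $K$ is intensive and comparable
  across lattice sizes; the nearest-neighbor sum is left unnormalized.
- **Integration.** Unwrapped phases on the real line,
  Adams adaptive-step integration (the system is non-stiff), relative
  tolerance $10^{-6}$, absolute $10^{-8}$; wrapping only at output.
  Default output cadence 0.5 h mirrors experimental sampling. The $K=0$
  closed form $\theta_i(t)=\theta_i(0)+\omega_i t$ is reproduced to
  $10^{-5}$ over 120 h.

Known behaviors the suite asserts: identical oscillators phase-lock
($R>0.99$); steady-state $I_{\theta\infty}$ increases strictly over
$K\in\{0, 0.01, 0.1\}$ at 25×25 and 100 days; strong mean-field coupling
drives $R_\infty>0.9$ while $I_{\theta\infty}$ stays inside the 95%
randomization band (global coherence without spatial structure); negative
nearest-neighbor coupling produces significantly negative $I_\theta$ with
low $R$. The coupling thresholds at which stable spirals appear depend on
the specific initial-condition draw and are treated as qualitative, not
numeric, targets.

## Synthetic fixtures: what they emulate and what they do not

`binary_grid()` provides the block / checkerboard / random archetypes
(the block pattern uses a seed-drawn ragged boundary, so its exact index
is a computed, not tabulated, quantity). `phase_pattern()` provides
spiral, plane-wave, uniform-random and two-cluster fields; the spiral
center defaults to an off-node point since the phase is undefined on the
center itself. `synthetic_movie()` builds SCN-like recordings: per ROI,
$\text{offset}\cdot e^{-\text{decay}\,t}+\text{slope}\cdot t
+\text{amplitude}\cos(2\pi t/\text{period}+\phi_i)+\varepsilon$, with
cluster-assigned phase offsets $\phi_i$ and Gaussian noise. The baseline
combines an exponential rundown with a linear drift so that detrending is
genuinely exercised.

These generators emulate the *statistical geometry* of the data —
spatial phase arrangements, bimodal cluster structure, baseline rundown,
uniform 0.5 h sampling — not its physics: no photon shot noise, camera
artifacts, cell movement, amplitude death, or period lability. Passing
recovery tests on fixtures therefore demonstrates correctness of the
estimators under the stated model, not robustness to every failure mode
of real recordings; the Hilbert edge window and the detrending default
in particular should be revisited for recordings much shorter than six
days.

## Problem sizes

The validation suite uses the analyses' native scales where they are
cheap: $10^5$ Monte-Carlo draws for the binary-grid null moments, $10^4$
shuffles for the spiral significance check, four 25×25 / 100-day lattice
integrations for the coupling sweep, 1000 fields for type-I calibration
(rejection rate required in $5\%\pm2\%$), and 20 seeds for the
$\Delta\mu=1.93$ rad cluster-separation recovery (tolerance $\pm0.2$
rad). Oracle-equivalence checks run 50 random instances at $N\le100$
against literal double-loop transcriptions of the definitions.

## Limitations

- No analytic (normal-approximation) variance of $I$; inference is
  Monte-Carlo only, by design.
- No local indicators (LISA) or Geary's C; no k-nearest-neighbor or
  triangulation weights; 2-D only.
- The von Mises mixture is restricted to two components; label switching
  is resolved only through $\Delta\mu$, which is permutation-invariant.
- Period estimation and rhythmicity testing are out of scope; the
  analytic signal presumes a dominant oscillation after detrending.
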