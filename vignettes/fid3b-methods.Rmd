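---
title: "Intensity-guided Bayesian reconstruction of blinking/bleaching microscopy data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-guided Bayesian reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule localization microscopy reaches sub-diffraction resolution by
localizing isolated emitters, which forces sparse activation and long
acquisitions. The Bayesian bleaching-and-blinking (3B) family of methods takes
the opposite regime: a short, *dense* image sequence in which many fluorophores
overlap in every frame. The whole sequence is modeled as a set of blinking and
bleaching fluorophores, and the output is a probability map of fluorophore
positions rather than a list of individual localizations.

This package implements a self-contained engine of that kind together with its
FID3B extension, in which new-fluorophore (birth) proposals are drawn from a
fluorescence-intensity-derived probability map instead of uniformly. It also
ships the matching simulator and the evaluation protocol (structural
similarity, distance-to-structure statistics, retained/discarded accounting)
used to compare the two proposal schemes.

## Photophysical model

Each fluorophore is an independent hidden three-state Markov chain over
*emitting*, *not emitting* and *bleached*:

* emitting → emitting with probability $\alpha$ (else → not emitting),
* not emitting → emitting with probability $\beta$,
* not emitting → bleached with probability $p_\mathrm{bleach}$
  (else it stays dark),
* bleached is absorbing.

The initial distribution is $(1/2, 1/2, 0)$: half of the fluorophores emit in
frame 1. The emissions of all fluorophores combine additively into one image
sequence — a factorial hidden Markov model.

The per-frame transition probabilities are instrument- and probe-dependent and
are not identifiable from the package's defaults alone; $\alpha = 0.84$,
$\beta = 0.1$, $p_\mathrm{bleach} = 0.01$ were chosen once as representative of
a switchable fluorescent protein imaged at tens of milliseconds per frame
(mean on-streak ≈ 6 frames, sizeable dark fraction, most fluorophores bleached
within a 200-frame movie). Every entry point accepts other values, and every
run log echoes the values used.

## Optics and camera

The PSF is an isotropic 2D Gaussian parameterized by $\sigma$ in nanometres
(default 100 nm, i.e. FWHM $= 2\sqrt{2\ln 2}\,\sigma \approx 240$ nm at the
default). Rendering integrates the Gaussian *exactly* over each pixel square
with differences of normal CDFs, so the simulator conserves flux: the summed
image of an emitter equals its brightness up to boundary truncation. Camera
noise is Poisson shot noise around signal-plus-background followed by additive
Gaussian readout noise; counts are rounded and clipped at zero, emulating an
integer camera. Defaults (background 5 counts/px/frame, readout σ = 2 counts,
brightness 500 counts/frame) describe a bright probe on a low-background
TIRF-style acquisition.

Coordinates are continuous in pixel units: pixel $(r, c)$ (0-based) covers the
half-open square $[c, c+1)\times[r, r+1)$, so its center is
$(c + 0.5,\; r + 0.5)$.

## The intensity-distribution prior

The birth prior is a transition-probability-weighted temporal average. For
pixel $x$ and frame $k$,

$$\gamma_k(x) = \sum_{t=1}^{K}\left(\frac{\alpha^{|k-t|}}{\tau_k} +
\frac{\beta}{K}\right) i_t(x), \qquad
\tau_k = \sum_{t=1}^{K} \alpha^{|k-t|},$$

with the convention $0^0 = 1$ so $\alpha = 0$ collapses the first term to the
current frame. The first term captures blinking persistence (frames near $k$
carry exponentially larger weight), the second the possibility of a
dark-to-emitting recovery in any frame. The total
$\gamma(x) = \sum_k \gamma_k(x)$ is max-normalized into
$P(x) = \gamma(x)/\max_x \gamma(x)$.

Two choices here were genuinely open:

* $P(x)$ is a confidence map, not a probability mass function. The sampler
  renormalizes by the sum and draws pixels with probability $P(x)/\sum_x P(x)$,
  then adds a uniform sub-pixel offset — the simplest proper sampling
  distribution that is monotone in the map.
* $\gamma$ is computed from raw counts, once per run, from the full stack.
  An optional constant-background subtraction is available
  (`intensity_prior(..., background_subtract =)`), but raw counts are the
  default so the prior needs no extra estimation step.

The collapsed computation uses per-frame coefficients
$c_t = \beta + \sum_k \alpha^{|k-t|}/\tau_k$ (one $K\times K$ weight matrix and
one matrix product); the test suite pins it to the literal $O(K^2)$ double sum
at $10^{-9}$ relative tolerance.

## The reconstruction engine

The engine holds a set of model fluorophores, each with continuous position,
brightness, and an *implicit* state trajectory that is never sampled: its
marginal likelihood over all $3^K$ state paths is computed with the HMM forward
algorithm (a compiled recursion), using per-frame Gaussian emission densities
of the residual image restricted to a window of about $4\sigma$ around the
fluorophore. Exact factorial-HMM inference is exponential in the number of
fluorophores; the engine instead conditions on the *residual*: every other
fluorophore contributes brightness × PSF × its posterior emitting probability
(from its own forward–backward pass), and candidates are scored against what
remains. The likelihood noise scale defaults to an estimate from the
lowest-intensity quarter of pixels (root mean temporal variance).

One iteration is one model-selection decision, drawn with probabilities
$(0.2, 0.5, 0.3)$:

* **Op_a** — birth at a uniform position,
* **Op_b** — birth drawn from the intensity prior,
* **Op_c** — removal of a uniformly chosen fluorophore.

In 3B mode Op_b's probability is folded into Op_a (0.7/0/0.3), so both modes
propose births at the same rate and differ only in where proposals come from —
which is the comparison the package exists to make.

Births are locally optimized over $(x, y, \log b)$ by Nelder–Mead
*parameterized as displacements from the proposal*, so the initial simplex is
sub-pixel and only grows while the likelihood improves. This is deliberate: it
reproduces the behavior of a gradient-style local optimizer, which cannot
travel across the flat likelihood plateau surrounding an isolated proposal.
A proposal a few PSF widths from any structure therefore stays where it is and
is rejected, rather than being teleported onto the nearest line. The result
never has a lower log-marginal than its start (the start is kept on failure).

A birth is retained iff its penalized evidence gain — optimized log-marginal
minus the no-candidate residual log-density minus a per-fluorophore penalty —
reaches the acceptance threshold (default 0; a gain exactly at threshold
retains). The penalty defaults to a BIC-style $\tfrac{3}{2}\log(K\,P)$ for
three free parameters over $K$ frames and $P$ window pixels; on pure-noise
calibration stacks, optimized births never achieve a positive gain under this
penalty, so background births are rejected essentially always.

Removal re-scores the model the way the acceptance rule defines it — *with
fluorophores at their optimized values*: the chosen fluorophore is tentatively
removed, overlapping neighbors are re-optimized (they absorb any signal it was
explaining), and the removal is kept iff the penalized window fit did not
decrease, with ties removing (prefers the sparser model). Without the neighbor
re-optimization, two model fluorophores that split one emitter's brightness
would protect each other indefinitely.

Every `sweep_interval` (default 10) decisions, the whole model is re-optimized
fluorophore by fluorophore; every `snapshot_interval` (default 40) decisions an
intermediate reconstruction is rendered and stored. All randomness flows from
one seed; identical seeds give identical ledgers.

## Rendering and evaluation

Reconstructions accumulate the *optimized positions of retained births* after a
burn-in (default: the first 25% of iterations) on an upsampled grid (default
10×, i.e. 10 nm rendering pixels at 100 nm camera pixels), each position as a
pixel-integrated Gaussian of width 0.5 camera pixels, max-normalized. Before
normalization the image mass equals the number of rendered positions, so line
intensities reflect how often positions were retained there. Rendering the
position *history* rather than the final model matches the probability-map
character of this method family's output.

Image quality uses the single-window (whole-image) structural similarity
index, with population moments and the conventional constants
$C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ on images normalized to $L = 1$. A
sliding-window variant is available (`ssim(..., window = 11)`), but the global
form is the package's reference statistic. The reference image renders the
ground-truth molecules as impulses on the reconstruction grid, blurred with a
0.5-px Gaussian and max-normalized — the same conventions as the
reconstruction, so the comparison measures structure rather than rendering
style. Proposal quality uses Euclidean distances from each birth proposal's
*initial* position to the nearest true molecule, with the fraction below 1
pixel (100 nm) as the headline number, and the ledger reports retained and
discarded birth counts with the discard rate.

```{r}
library(fid3b)
sim <- simulate_dataset(structure_spec("grid"), n_frames = 200, seed = 7)
state <- run_engine(sim$stack, engine_config(mode = "fid3b"), seed = 3)
distance_to_structure(state$initial_positions_log, sim$structure)$fraction_within
ledger_summary(state)
```

## What the simulator does and does not emulate

The generator reproduces the study conditions of the package's validation
protocol: grid (3 + 3 evenly spaced lines), gradient grid (linear brightness
decay to a 0.2 fraction at the right edge) and concentric-ring structures on a
40 × 40 px field at 100 nm pixels, 200 frames, one three-state fluorophore per
molecule at 50 nm spacing, exact pixel-integrated Gaussian optics, Poisson +
Gaussian noise. It does **not** emulate EM-gain noise statistics, sCMOS
per-pixel noise maps, sample drift, 3D or aberrated PSFs, or spectral
channels. Tests passing on these simulations therefore demonstrate the
engine's inferential behavior under its own generative assumptions, not
robustness to real-camera artifacts.

## Numerical choices and degenerate inputs

* Frame indices in the prior formulas are 1-based to match the summation
  limits; storage is R's native indexing.
* $0^0 = 1$ in the prior weights, so $\alpha = 0$ is well defined
  ($\tau_k = 1$).
* All-zero intensity maps are a degenerate prior: `probability_map()` errors,
  and the engine falls back to uniform proposals with a warning.
* Forward/backward recursions rescale per frame; they are pinned against
  exhaustive $3^K$ path enumeration for $K \le 6$ at $10^{-8}$.
* Optimized positions are confined to the likelihood window; a candidate
  clamped to the field boundary on both axes is discarded.
* Removal of the last fluorophore from an empty model is a logged no-op.
* Count stacks are stored as uint16 TIFF (exact round trip); normalized maps
  as float32, which round-trips to single precision.

## Problem sizes

The package's standard desk-scale study conditions — used throughout the test
suite and the reproduction script — are the 40 × 40 px, 200-frame datasets with
320-decision runs (about half a minute each on one core), plus a reduced
50-frame / 80-decision configuration for multi-seed property checks and small
synthetic stacks (≤ 7 × 7 × 7) wherever an exhaustive oracle is the reference.

## Known limitations

* Residual conditioning is an approximation to factorial-HMM coupling; heavily
  overlapping fluorophores interact only through their posterior-weighted
  contributions.
* The Gaussian likelihood with a single global noise scale ignores the
  signal-dependence of shot noise.
* One decision per iteration is a defined unit, not a universal one: published
  engines of this family bundle many decisions per "iteration", so absolute
  retained/discarded *counts* are comparable only within one convention;
  rates and proposal-position statistics are the transferable quantities.
* Proposal sampling proportional to the intensity map inherits the map's PSF
  blur: the within-1-px proposal fraction is bounded near
  $\mathrm{erf}(1/\sigma\sqrt{2})$ of the structure mass for a σ-wide PSF,
  however sharp the underlying structure.
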