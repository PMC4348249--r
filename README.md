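# fid3b

Bayesian reconstruction of super-resolution images from **dense**
blinking/bleaching fluorescence image sequences, with an
intensity-distribution prior for proposing new fluorophores.

Single-molecule localization microscopy needs sparse emitters per frame;
dense live-cell movies violate that. The 3B approach (Bayesian analysis of
bleaching and blinking) instead models a whole short sequence as a set of
fluorophores, each an independent hidden three-state Markov chain —
*emitting*, *not emitting*, *bleached* (absorbing) — whose Gaussian-PSF
emissions add into the observed frames. The model is adjusted by birth/death
moves scored by marginal likelihood, and the output is a probability map of
positions. FID3B replaces the uniform birth proposal with a map computed from
the data itself: for pixel *x* and frame *k*,

    gamma_k(x) = sum_t ( alpha^|k-t| / tau_k + beta / K ) i_t(x),
    tau_k     = sum_t alpha^|k-t|,
    gamma(x)  = sum_k gamma_k(x),      P(x) = gamma(x) / max_x gamma(x),

where `alpha` and `beta` are the emitting→emitting and dark→emitting
transition probabilities and `i_t(x)` the intensity in frame *t*. Births drawn
from `P(x)` land near real structure far more often than uniform ones, so
fewer proposals are wasted and the reconstruction fills in faster at equal
iteration counts.

The package provides:

* `simulate_dataset()` — grid / gradient-grid / concentric-ring ground truths,
  three-state blinking trajectories, pixel-integrated Gaussian optics,
  Poisson + Gaussian camera noise;
* `intensity_prior()` / `sample_birth_position()` — the birth prior above;
* `run_engine()` — the reconstruction engine, `mode = "fid3b"` or `"3b"`
  (uniform births only), with the three-operation model selection
  (probabilities 0.2 / 0.5 / 0.3 for uniform birth / prior birth / removal);
* `render_reconstruction()`, `ssim()`, `distance_to_structure()`,
  `ledger_summary()` — probability-map rendering and the evaluation protocol;
* a command-line wrapper (`inst/cli/fid3b.R`) with `simulate`, `prior`, `run`,
  `evaluate`, `render` and `experiment` subcommands.

## Worked example

```r
library(fid3b)

sim <- simulate_dataset(structure_spec("grid"), n_frames = 200, seed = 7)
sim$stack
#> frame_stack: 200 frames of 40 x 40 px (1 px = 100 nm)

state <- run_engine(sim$stack, engine_config(mode = "fid3b"), seed = 3)
state
#> reconstruction_state: 320 iterations, 211 fluorophores in model
#>   births: 193 retained / 18 discarded; 109 removal decisions; 8 snapshots

ledger_summary(state)$discard_rate * 100
#> 8.5
distance_to_structure(state$initial_positions_log, sim$structure)$fraction_within * 100
#> 52.6

ref <- reference_image(sim$structure, c(40, 40))
tail(ssim_curve(state, ref), 3)
#>   iteration  ssim
#> 6       240 0.369
#> 7       280 0.481
#> 8       320 0.520
```

The run simulates 480 molecules on six intersecting lines, reconstructs for
320 model-selection decisions, and reports: the discard rate (fraction of
birth proposals rejected — low here because intensity-guided proposals land on
supportable positions), the fraction of proposals within 1 pixel (100 nm) of a
true molecule (52.6%, versus ~26% for uniform proposals in `"3b"` mode), and
the structural-similarity trajectory of the intermediate reconstructions
against the rendered ground truth. `render_reconstruction(state)` returns the
final 400 × 400 probability-map image (10 nm rendering pixels).

The full two-dataset, two-mode comparison (ledgers, SSIM curves, distance
histograms, reconstructions, one `metrics.csv`) is produced by

```r
experiment_comparison("experiment_out", seed = 1)
```

## Methods

The model, priors, acceptance rules, numerical choices and limitations are
documented in `vignettes/fid3b-methods.Rmd`.
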