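---
title: "Methods: wolf-pack training of neural species distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wolf-pack training of neural species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnna)
```

## The model

`gnna` fits presence / pseudo-absence species distribution models with a
three-layer feedforward network: sigmoid activations in the hidden layer
(5 units by default) and in the single output unit, so the output is a
habitat-suitability score in (0, 1).  Predictors are z-scored with
training-set means and standard deviations before entering the network;
the same transform is stored in the model and re-applied at prediction.

Training minimizes the mean squared error between the suitability score
and the 0/1 label.  Two trainers are provided:

* **BPNN** — plain full-batch gradient descent (backpropagation) from
  weights drawn uniformly in [-1, 1].  This baseline is notoriously
  sensitive to its random starting point.
* **GNNA** — the Grey Wolf Optimizer (GWO) searches the space of *all*
  weights and biases, flattened into a single position vector (for the
  default 5-predictor architecture that vector has
  5×5 + 5 + 5×1 + 1 = 31 components, bounded in [-1, 1]); the best
  position found then seeds the same gradient-descent fine-tuning stage.
  The global search removes the dependence on the initial weights, which
  is precisely where the baseline fails.

### The Grey Wolf Optimizer

A pack of 20 wolves (candidate weight vectors) is evaluated for 100
iterations.  The three best wolves — alpha, beta, delta — act as leaders.
Every other (omega) wolf is replaced each iteration by an offspring built
from three leader-guided candidates:

* `C = 2 r1` perturbs the leader's position (`r1`, `r2` uniform in [0, 1],
  drawn fresh per component, per wolf, per leader, per iteration);
* `D = |C ∘ X_leader − X|` is the perturbed distance;
* `A = 2 a r2 − a` with `a = 2(1 − t/T)` decaying linearly from 2 to 0
  moves the pack from exploration (`|A| > 1`) to exploitation;
* candidate `X_i = X_leader − A ∘ D`.

Two combination rules for the three candidates are implemented.  The
**original rule** of this hybrid weights each candidate by its
Euclidean-norm share (`w_i = ‖X_i‖ / Σ‖X_j‖`, so the weights sum to one)
*and* divides the weighted sum by 3.  Because of that extra division
every offspring is contracted toward the origin by roughly a factor of
three; on the weight-search problem the pack collapses onto the zero
network within a few iterations and the best-so-far trace goes flat at
the initial population's best.  The **canonical rule** is the classic
plain GWO mean `(X1 + X2 + X3)/3`.  The low-level operators default to
the original rule (which does converge superbly on problems whose
optimum is the origin), but `gnna_config()` defaults the fitting
pipeline to `mode = "canonical"`, the variant that actually delivers the
global-search behaviour the hybrid needs.  Both modes are exposed and
tested.

Leaders are kept unchanged within an iteration (elitism) and re-selected
from the whole pack afterwards, which guarantees a non-increasing
best-so-far trace.  Offspring are clipped to the [-1, 1] box.  Fitness
ties are broken by wolf index, and non-finite fitness values are treated
as +Inf, so a pathological wolf can never lead the pack.

### Training budgets and their defaults

The stated learning rate (0.01) and training goal (1e-5) drive the
gradient-descent stage.  The goal is effectively aspirational for
overlapping classes — the Bayes mean squared error of a realistic
presence / pseudo-absence problem is orders of magnitude larger — so the
epoch budgets are what actually stop training, and they are asymmetric
by design: a from-scratch BPNN fit gets `max_epochs = 5000` full-batch
epochs (its descent *is* its entire training; at 1000 epochs the
baseline is still badly under-fitted, e.g. AUC 0.78 instead of 0.94 on a
large virtual-species sample), while the GNNA fine-tune gets
`fine_tune_epochs = 1000` — the wolf pack has already placed the weights
well and a longer polish changes the held-out AUC by about 0.002.
Giving the baseline five times more backpropagation than the hybrid is
conservative for every GNNA-versus-BPNN comparison the package reports.
A classical momentum coefficient is available in `train_settings()` but
defaults to 0 (plain gradient descent), and a relative-stagnation stop
(`conv_tol` per `conv_window` epochs) guards against wasted epochs on
problems that do flatten out early.  The best network seen during
descent is returned, so training can never end worse than it started.
Pre-activations are clamped at ±35, the widest symmetric range whose
sigmoid stays strictly inside (0, 1) in double precision.

Whether the original hybrid fine-tunes at all is ambiguous — a learning
rate is specified, yet the optimizer is described as determining the
weights — so `fine_tune = FALSE` gives the pure-GWO variant.

## The evaluation protocol

`evaluate_repeated()` implements the full protocol: stratified 80/20
train/test splits repeated 12 times, a model fitted per split, test-set
scores binarized at the threshold maximizing the true skill statistic
(TSS = sensitivity + specificity − 1), and AUC, Cohen's kappa and TSS
recorded per split with medians reported.  Supporting steps:

* `thin_occurrences()` — greedy 5-km haversine thinning in input order
  (deterministic; thinning twice equals thinning once);
* `sample_pseudo_absences()` — uniform sampling without replacement over
  valid raster cells, excluding presence cells, at 3× the presence count;
* `select_variables()` — greedy Pearson screening: while any pair has
  |r| ≥ 0.7, the member of the worst pair with the larger mean absolute
  correlation is dropped.

Conventions chosen where any fixed rule would do (all documented on the
functions): scores equal to the threshold count as presences; the TSS-max
threshold is computed on test scores by default (`threshold_on = "train"`
switches); splits are stratified so both classes appear on both sides;
candidate thresholds are the distinct observed scores plus 0 and 1, with
ties going to the lowest candidate.  Any external score vector can be fed
to the metric functions directly, so models fitted elsewhere can be
scored under the identical protocol.

## The virtual-species simulator

Real occurrence data cannot ship with a package and would not provide
ground truth anyway, so testing runs on simulated landscapes with a known
niche.

`make_env_stack()` builds each predictor layer as a sum of 30 Gaussian
bumps with random centres, signed amplitudes and widths around 0.12 of
the grid extent, then standardizes the layer to mean 0, sd 1.  On the
default 100×100 grid this yields smooth surfaces (neighbouring-cell
correlation ≈ 0.99) with near-independent layers — enough structure for
model validation, though deliberately *not* a geostatistical climate
model: layers carry no realistic cross-covariance, anisotropy or
elevation gradients, so passing tests demonstrate correct method
behaviour, not real-world transferability.

`virtual_species_spec()` defines the truth as
`suitability = sigmoid(b0 + Σ βj zj + Σ γj zj²)`.  The default
strong-signal species uses β = (2, −2, 2, 0, 0) — three informative
layers among five — with intercept −6.  The intercept matters more than
it looks: presences are drawn with probability proportional to
suitability while pseudo-absences are uniform, so a species suitable over
half the landscape caps the *attainable* AUC near 0.75 no matter the
model.  The default prevalence (~7% of the landscape) mirrors the
restricted-range species real SDM studies target and leaves an attainable
AUC around 0.92.  Presence sampling is probabilistic rather than
thresholded precisely so that test AUCs stay away from degenerate perfect
separation.

## Problem sizes and numerical choices

The validation experiments in the test suite and the acceptance script
use the 100×100 grid, 200 presences + 600 pseudo-absences (50 and 500
presences for the sample-size contrast), 12-split evaluations, and
100-trial (recovery) or 20-trial (paired-comparison) replications —
sizes at which a single evaluation takes seconds and the full suite
minutes on one CPU, while the Monte-Carlo error on a median AUC stays
around 0.01.  The numeric kernels (forward pass, fitness, gradient,
descent loop) are compiled C++ (RcppArmadillo); every random draw happens
in R's RNG, so any result is bit-reproducible from its seed.

Raster I/O uses the ESRI ASCII grid format, written with 17 significant
digits so write/read round trips are value-identical; model files are
JSON at the same precision, so persisted models predict bit-identically.
Cell membership uses half-open [west, east) × (south, north] intervals;
coordinates are geographic degrees and thinning distances are haversine.

## Known limitations

* On the simulated landscapes the hybrid's advantage over the baseline
  does **not** shrink with sample size: under a fixed epoch budget the
  baseline's optimization deficit grows with n, and conversely, if both
  are trained to full convergence (e.g. by Gauss-Newton/LM descent) the
  initialization ceases to matter and the advantage disappears at every
  n.  A sample-size-dependent initialization effect — small samples
  hurting the random-start baseline disproportionately — does not emerge
  in this virtual-species world; claims of that form should be tested on
  heterogeneous real data, not on this simulator.
* The comparison SDMs of the wider literature (GLM, GBM, RF, MaxEnt) are
  out of scope; the metric functions accept any score vector instead.
* One hidden layer of fixed size; no regularization, minibatching or
  early stopping on validation loss — faithful to the method under study,
  not a modern deep-learning stack.
* The simulator's landscapes are exchangeable random fields; conclusions
  about spatially blocked cross-validation cannot be drawn from it.
* GeoTIFF is not read or written; convert to ASCII grids first.
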