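---
title: "Connectome-constrained network models of the fly visual system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained network models of the fly visual system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexdmn)
```

## The model

`hexdmn` builds recurrent network models of the fruit fly optic lobe in
which every unit corresponds to a biological neuron and every connection to
a measured synaptic pathway. Connectivity is consumed as three plain tables:
per-type column coverage, a filter table of average synapse counts
$N_{t_i t_j \Delta u \Delta v}$ between cell types at axial column offsets
$(\Delta u, \Delta v)$, and a sign table $\sigma_{t_i t_j} \in \{-1, +1\}$
(hyper- vs depolarizing, derived upstream from transmitter profiles and
consumed as data).

Voltages follow passive threshold-linear dynamics,

$$\tau_{t_i} \dot V_i = -V_i + \sum_j w_{ij}\, f(V_j) + V^{rest}_{t_i} + e_i,
\qquad w_{ij} = \alpha_{t_i t_j}\, \sigma_{t_i t_j}\, N_{t_i t_j \Delta u \Delta v},$$

with $f(V) = \max(V, 0)$ modelling graded, voltage-gated transmitter
release. The rectification threshold is fixed at 0; the statistics below
(FRI, DSI) also rectify at 0, so the two conventions are consistent.
External input $e_i$ is nonzero only for photoreceptors, which receive the
per-column stimulus luminance (raw values in $[0,1]$; the tuning statistics
are baseline-subtracted or contrast-based, so the absence of mean
subtraction does not affect their signs at fixture scale).

Parameters are shared by biological identity: one time constant and one
resting potential per cell type, and one non-negative unitary synapse
strength $\alpha$ per connected type pair. Within a type pair, weights are
therefore exactly proportional to synapse counts. For the fly tables
($T = 65$ types counting the two CT1 compartments separately, $Q = 604$
signed type pairs) this gives $Q + 2T = 734$ free parameters, versus
$(TC)^2 + 2TC \approx 2.2\times10^9$ for an unconstrained recurrent network
on the same $C = 721$ columns — `count_parameters()` reproduces the full
ladder of sharing assumptions.

Initialization: $\tau = 50$ ms for every type,
$V^{rest} \sim \mathcal N(0.5, 0.05)$, and
$\alpha = 0.01 / \langle N \rangle$ with $\langle N \rangle$ the mean
synapse count over the pair's filter offsets.

## Lattice conventions

Columns live in axial coordinates $(u, v)$ with the third cube coordinate
implicit as $-(u+v)$; a lattice of radius $r$ ("$2r+1$ columns across")
holds $3r(r+1)+1$ columns. The Cartesian embedding is pointy-top,
$x = s(u + v/2)$, $y = s\frac{\sqrt3}{2} v$, the $(1,0)$ axis points along
$+x$, and all direction angles (stimulus motion, preferred directions) are
measured counter-clockwise from $+x$. The source tables do not fix an
orientation convention, so predicted preferred directions are meaningful up
to a global rotation/reflection; tests compare directions only within the
model's own convention. Enumeration is ring-by-ring and angle-sorted within
each ring, making buffer layouts and serializations reproducible.

Assembly (`tile_network()`) instantiates one neuron per covered column and
one connection per filter entry per column pair with both endpoints present.
Connections whose presynaptic column falls outside the lattice are dropped
rather than wrapped; this matches the central-visual-field framing and
avoids padded weights. A brute-force pair-enumeration oracle checks the
tiling in the test suite.

## Stimulus protocols

All protocols run on a grey ($I = 0.5$) background after a grey-screen
steady-state initialization, with luminance in $[0,1]$:

* **Circular flashes** — 1 s grey, then a 1 s ON ($I=1$) or OFF ($I=0$)
  disc of radius 6 columns, 5 ms step. Basis of the flash response index.
* **Moving edges** — half-plane edges at 12 directions (0°–330°, step 30°)
  and 6 speeds (13.92–145 °/s), travelling from −13.5° to +13.5° of visual
  angle, 5 ms step. The angular calibration is 5.8° per column (the
  single-column receptive-field radius); edges are hard luminance steps
  sampled at column centres.
* **Single-ommatidium flashes** — 2 s grey, a flash of 5–300 ms at one
  column, 5 s grey; receptive fields use the 20 ms flash.
* **Fly-eye rendering** — Cartesian video is sampled by columns spaced 13 px
  apart, each reading the mean of the surrounding 13×13 px box.

Training-time augmentation applies random lattice flips and rotations to
input and flow target, pixel noise with standard deviation 0.08 clamped at
0 (the source notation for this value conflates σ and σ²; we read it as a
standard deviation), and the contrast/brightness jitter
$X' = c(X - 0.5) + 0.5 + cb$ with $\log c \sim \mathcal N(0, 0.04)$ and
$b \sim \mathcal N(0, 0.01)$.

## Tuning statistics

* **FRI** (flash response index): with non-negative activities
  $r^{peak}(I) = \max_n V[n](I) + |\min_{n,I} V[n](I)|$,
  $\mathrm{FRI} = (r^{peak}(1) - r^{peak}(0)) / (r^{peak}(1) + r^{peak}(0))$.
  If both peaks vanish the index is returned as `NA` with a flag, mirroring
  the exclusion flag used in normalization.
* **DSI**: per intensity, the speed-average of
  $|\sum_\theta r\, e^{i\theta}| / \max_{I'} |\sum_\theta r|$ over rectified
  peak responses. Speeds with a vanishing denominator are skipped and the
  average is over the remaining speeds (the source is silent on 0/0; this
  avoids `NaN` while preserving the average's meaning). The preferred
  direction is the argument of the complex vector sum at the
  strongest-response condition.
* **Selectivity threshold**: the null distribution $d^*$ is sampled by
  permuting direction labels of symmetric-input cells' peak responses (100
  permutations per condition), pooled, and thresholded at the 99% quantile.
  Whether a type counts as direction selective across an ensemble is a
  one-sided binomial test (null exceedance probability 0.1, $p < 0.05$). The
  full-scale threshold value depends on trained-model response statistics
  and is not reproduced at desk scale; the package exposes the procedure.
* **Receptive fields**: STRFs are baseline-subtracted single-ommatidium
  flash responses (zero at the first sample by construction); the SRF slices
  the STRF at the central-offset extremum and the TRF is the central time
  course.
* **Normalization for averaging**: responses are divided by the RMS of the
  cell's responses to a naturalistic stimulus bank; zero-RMS models are
  flagged excluded. Pearson correlations with fewer than 3 points or zero
  variance are treated as missing, not zero.

## Optic-flow task and training

The decoder is feedforward with no temporal structure: rectified voltages
of the decoder input types (by default every non-photoreceptor type; the
fly model uses the 34 medulla-and-downstream types) are scattered onto a
square grid by the injective axial raster $(u+r+1, v+r+1)$, passed through
a 5×5 convolution to 8 channels, batch normalization, softplus, dropout
(default rate 0.5, not fixed by the source), and a second 5×5 convolution
to 3 channels. Normalization statistics are taken over all frames and grid
positions during training and folded into running averages used at
evaluation, so the evaluated decoder maps each frame independently.
Normalizing within single frames instead would subtract every channel's
spatial mean per frame — deleting exactly the spatially uniform elevation
that a direction-selective population produces under coherent motion — so
the running-statistics semantics is load-bearing, not a convenience. The third
channel acts as a shared normalization: the flow estimate is channels 1–2
divided by a softplus of channel 3 (the source states the role but not the
formula; the implementation is pluggable). Filters start homogeneously at
0.001. Because the decoder has no temporal structure, any motion information
must come from the network dynamics feeding it — a property the test suite
checks by frame-permutation.

Training minimizes the L2 norm $\|Y - \hat Y\|$ by backpropagation through
time through the Euler integration, with adaptive-moment updates
($\beta_1 = 0.9$, $\beta_2 = 0.999$, batches of four 19-frame sequences at
50 Hz, learning rate stepped down by 10× in ten stages). After each step
$\alpha$ is clamped non-negative and $\tau \ge \Delta t$ (projected
gradients); the grey-screen initial state is recomputed from the current
parameters every iteration. A separate optional phase optimizes the resting
potentials alone by plain SGD against the activity regularizer
$R(V) = \frac{\lambda_V}{BT}\sum \{\gamma\,(\bar V - a)^2 \text{ if } \bar V
\le a;\ \delta\,(\bar V - a)^2 \text{ otherwise}\}$ with $\gamma = 1$,
$\delta = 0.01$, $\lambda_V = 0.1$, $a = 5$.

Two numerical choices matter at short training budgets. First, the time
constants are optimized in log space with a learning-rate multiplier
(default 10×): their natural scale (tens of ms) differs from the unitless
synapse scales by orders of magnitude, and with a single shared step size
they would be effectively frozen over a few thousand iterations. Second,
the package's desk-scale experiment configuration uses a learning rate of
$10^{-3} \to 10^{-4}$; the full-scale printed schedule
($5\times10^{-5} \to 5\times10^{-6}$) remains the `train_config()` default
but is matched to runs two orders of magnitude longer.

## Synthetic data

The fixtures make every pipeline testable without downloads and are pure
functions of their seeds.

* **Motion motif** (`make_motion_motif()`): photoreceptor → fast excitatory
  relay (centre) and slow inhibitory relay (one column off-axis) → detector,
  the elementary delayed-flanking-inhibition motion detector. The designed
  preferred direction is recorded as ground truth; the mirrored motif flips
  it by 180° and removing the inhibition abolishes selectivity. Parameters
  put the circuit in the positive, near-linear regime (relay τ 15 ms,
  inhibitory τ 60 ms by the default delay ratio 4).
* **Drifting dataset** (`make_drifting_dataset()`): rigidly drifting random
  sinusoidal plaids (wavelengths 2–6 columns, component amplitudes drawn in
  0.1–0.3, speeds 2–8 columns/s) with analytically exact flow targets in
  columns/frame. Scenes are never split across train and validation. The
  fixture emulates the coarse statistics of rendered naturalistic input —
  band-limited luminance with rigid motion — but not depth discontinuities,
  occlusions, or locally varying flow; passing the desk-scale training test
  therefore shows that the pipeline learns motion decoding, not that it
  matches full-scale naturalistic performance.
* **Digit task** (`make_digit_task()`): ten sparse positive-stroke
  templates (the rectified part of a smooth random field, so most of the
  background is exactly zero), random per-sample translations of up to 2 px
  and pixel noise, clipped to the luminance range. The sparsity and the
  translation jitter are the two properties of handwritten-digit images
  that matter downstream: dense, offset-heavy images couple every unit of a
  sign-constrained network to the common signed input sum, and without
  within-class variability the classification task does not constrain the
  network's internal responses. With zero noise and no jitter,
  nearest-template classification is perfect.

## Identifiability simulation

Ground-truth networks are feedforward rectifier networks (6 hidden layers,
default width 128) obeying Dale's law — one sign per presynaptic unit —
trained on the ten-class image task with the max-variant adaptive-moment
optimizer (lr 0.001, batch 500, decay 0.5/epoch at full scale) under
non-negativity projection, then sparsified to a target connectivity by
iterative magnitude pruning: 20% of surviving weights per round, layer-local,
the 10-way readout never pruned, retraining from the pruned state between
rounds (fine-tuning rather than strict rewinding; the source names the
algorithm but not the schedule). Because all magnitudes are non-negative,
every layer has a common random mode at initialization that can silence it;
`dale_calibrate()` sets each unit's median pre-activation on a probe batch
to a small positive value before training (resting potentials remain free
parameters).

A "measured connectome" copies the adjacency and presynaptic signs, and in
the with-strength regime noisy magnitudes
$\tilde m = m\,\varepsilon$, $\varepsilon \sim U(0.5, 1.5)$. Simulated
networks are refit from scratch with the adjacency and signs frozen; in the
with-strength regime magnitudes start at $\tilde m$ and a squared distance
to $\tilde m$, weighted 10× the task objective, keeps them there. Similarity
between a ground-truth/simulation pair is the median Pearson correlation of
rectified voltages of up to 100 sampled neurons per hidden layer over the
task test set (constant-response neurons excluded with a count). The
desk-scale experiment (3 pairs per density, densities 10/40/80%, both
regimes) reproduces the qualitative result: identifiability falls with
connection density when only connectivity is known, and strength estimates
restore it.

## Problem sizes used by the tests

The suite and the acceptance checks run on sizes chosen for a single CPU:
motif tuning protocols on a radius-6 lattice (508 neurons) with the full
printed direction/speed/intensity grid; the training comparison on a
radius-2 lattice, 16 scenes, 1500 iterations; the identifiability
experiment on 12×12 images, 5000/500 train/test, width 128, 6 hidden
layers, 15 training epochs plus 3 per pruning round and 25 per fit (batch
200, decay 0.95 per epoch), and 3 pairs per density. Full-scale settings
(721-column lattice, 250k iterations, 50-model ensembles, 28×28 images)
remain available through the same function arguments.

Two desk-scale findings deserve explicit statement. First, the
identifiability trend (similarity falling with connection density under
connectivity-only measurements) emerges only once the task genuinely
constrains the refits — with an order of magnitude fewer training images
the fitted networks sit near their initialization and similarity is flat
at a structural floor induced by the shared signs and adjacency. Second,
in the optic-flow comparison the jointly trained network and the
frozen-network control reach validation errors that differ only at
numerical-noise scale: fixture-scale detectors are weakly selective
(pattern-driven response variation dwarfs the direction signal, as a
linear-readout oracle confirms), and rigid-motion scenes provide no
per-column flow diversity, so the validation error is dominated by a
scene-generalization floor that the network parameters cannot move. The
robust, reproducible ordering at desk scale is trained-versus-initial;
recovering the full trained-versus-random-network gap needs the long
full-scale training regime.

## Known limitations

Single-compartment neurons (beyond the two CT1 entries), chemical synapses
only, no electrical coupling, no adaptation or neuromodulation; first-order
Euler integration with divergence detection (abort with diagnostics, never
silent clipping); the ensemble embedding is a pluggable deterministic
contract with a principal-component default, so nonlinear embeddings can be
substituted without changing the clustering interface; desk-scale training
demonstrates the trained-versus-initial ordering, not absolute task errors
(see the problem-sizes section for what the frozen-network comparison can
and cannot show at this scale).
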