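---
title: "Modeling resting-state whole-brain networks with coupled Wendling neural masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling resting-state whole-brain networks with coupled Wendling neural masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbnm)
```

## The model

`wbnm` simulates resting-state whole-brain electrical activity by placing one
Wendling neural mass in each cortical region of the Desikan–Killiany
parcellation (34 regions per hemisphere, 68 in total) and coupling the masses
through a structural connectome. A Wendling mass describes four interacting
neuronal populations — pyramidal cells, excitatory interneurons, slow
(GABA_B-like) and fast (GABA_A-like) inhibitory interneurons — with ten state
variables per region: five second-order synaptic kernels written as pairs of
first-order equations. Each kernel turns a presynaptic pulse density into a
post-synaptic potential through the impulse response

$$h(t) = W\,w\,t\,e^{-wt}, \qquad t \ge 0,$$

with gain $W \in \{A, B, G\}$ (mV) and rate constant $w \in \{a, b, g\}$
(1/s), and each population converts its mean membrane potential into a firing
rate through the sigmoid

$$S(v) = \frac{2 e_0}{1 + e^{r (v_0 - v)}},$$

which saturates at $2 e_0$ and equals $e_0$ at the half-activation potential
$v_0$. The output of region $i$ is the net pyramidal post-synaptic potential
$y_\mathrm{out}^i = y_1^i - y_2^i - y_3^i$ (excitatory minus slow- and
fast-inhibitory kernel outputs), the model's analogue of the local EEG.

Regions interact through a single excitatory pathway: the pyramidal input
kernel of region $i$ receives

$$C \sum_j C_{ij}\, S\!\left(y_\mathrm{out}^j\right),$$

where $C_{ij}$ is the max-normalized structural connectivity weight
(symmetric, zero diagonal, entries in $[0,1]$) and $C$ is a single global
coupling coefficient that rescales all weights at once. Coupling is
instantaneous — the vector field contains no conduction delays — and the zero
diagonal of the connectome is what excludes self-coupling from the sum. All
regions share one parameter set (`wendling_params()`), whose defaults are the
standard values: $A = 3.25$, $B = 22$, $G = 10$ mV; $a = 100$, $b = 50$,
$g = 500$ s$^{-1}$; contact counts $C_1 = 135$, $C_2 = 108$,
$C_3 = C_4 = 33.75$, $C_5 = 40.5$, $C_6 = 13.5$, $C_7 = 108$; $v_0 = 6$ mV,
$e_0 = 2.5$ s$^{-1}$, $r = 0.56$ mV$^{-1}$. Per-region overrides are
deliberately not part of the interface; heterogeneous parameter fitting is
out of scope.

## Integration and noise

Each region is driven by an external pulse density $p(t)$ modeled as Gaussian
noise with mean $\mu = 90$ and variance $\sigma^2 = 30$. The coupled system
is advanced with classic fixed-step fourth-order Runge–Kutta at
$h = 1/f_s$ ($f_s = 1000$ Hz by default, i.e. $h = 1$ ms). The continuous
model does not specify a noise discretization, so the package adopts the
convention common to neural-mass simulation practice: one Gaussian sample per
region per step, held constant across the four RK4 stages, with $\sigma^2$
read as the variance of those per-step samples (no $1/\sqrt{h}$ rescaling).
Under this convention the deterministic limit $\sigma^2 = 0$ shows clean
fourth-order convergence (the error ratio when halving $h$ is measured at
about 15 in the test suite), and simulations are bit-reproducible from the
seed because all randomness is drawn from R's RNG before entering the
compiled integrator.

Defaults follow the resting-state protocol: 2 s of simulation, the first 1 s
discarded as transient, 20 repetitions with different initial values. Initial
state components are drawn uniformly from $[0, 0.1]$ mV per repetition;
repetition $r$ derives an independent substream from `(seed, r)` for both its
initial conditions and its noise (the protocol says only that initial values
differ; redrawing the noise as well is the natural reading for independent
repetitions and is the package's choice). Divergence — possible when coupling
is very strong or the step too large for the fast-inhibition rate constant —
raises an explicit error naming the step and region rather than clipping,
because silently truncated trajectories would corrupt every downstream
statistic.

## Single-node dynamics: bistability

At the standard parameters the isolated node is bistable. There is a low
"background" equilibrium (output near 0.9 mV) around which noise produces
broadband low-frequency fluctuations, and a high equilibrium (output near
6.7 mV) with a sharp resonance near 10 Hz — the alpha rhythm. Which branch a
repetition occupies depends on the noise path in its first few hundred
milliseconds; with the default small initial conditions roughly a quarter to
a third of repetitions reach the alpha branch within the 2 s window. Because
the alpha branch carries far more oscillatory power, the
repetition-*averaged* spectrum of an isolated node peaks in the alpha band
even though many individual repetitions do not. In the coupled network the
picture matches the resting-state phenomenology this model targets: afferent
drive $C \sum_j C_{ij} S(\cdot)$ pushes strongly connected (hub) regions onto
the alpha branch — high baseline potential, ~8–10 Hz dominant frequency —
while weakly connected regions remain in the background state with low
baselines and broadband spectra.

## Functional connectivity and coupling fitting

Functional connectivity is the phase-locking value. Phases come from the
FFT-based analytic signal of each mean-centered regional series (no band-pass
by default, because none is part of the estimator's definition here; an
optional zero-phase Butterworth band-pass exists for sensitivity analyses),
and for regions $i, j$

$$\rho_{ij} = \left| \frac{1}{T_s} \sum_{t=1}^{T_s}
  e^{i(\theta_i(t) - \theta_j(t))} \right| \in [0, 1],$$

equal to 1 for a constant phase difference and near
$\sqrt{\pi / (4 T_s)} \approx 0.028$ (for $T_s = 1000$) for independent
uniform phases. The PLV matrices of the 20 repetitions are averaged
element-wise — mirroring the subject-averaging convention used for empirical
FC — into one simulated FC matrix.

The global coupling coefficient is fitted by sweeping $C$ over an inclusive
grid and maximizing the Pearson correlation between the strictly lower
triangles of the simulated and reference FC matrices (`fc_similarity()`);
ties break toward the smallest $C$, and grid points where the integration
diverges are recorded as `NA` without aborting the sweep. The default grid
(0–80, step 0.1) is sized for 68-region connectomes whose mean row strength
of ~2–3 puts the interesting regime in the tens; tests and examples use
coarse short grids.

## Synthetic connectomes and the recovery experiment

Empirical MRI-derived matrices are inputs the package reads but does not
ship. `make_synthetic_sc()` emulates their stated structure: symmetric,
nonnegative, zero diagonal, max-normalized to 1, with log-normal weight
magnitudes (fiber-count-like heavy tails, sdlog 0.9 by default), a
connection density of 0.6 (so that low thresholds produce complete-graph
behavior), and intra-hemispheric weights stronger on average than
inter-hemispheric ones (meanlog 0 versus −1). What it does **not** emulate:
tractography distance biases, subject-level variability, or the spatial
autocorrelation of real parcellations — so passing tests demonstrate
methodological self-consistency, not empirical validity.

The generator's headline use is the coupling-recovery experiment: generate a
reference FC at a known $C^\*$, then check that the sweep recovers it from
independent seeds. Because the nodes respond to *total* afferent drive, the
experiment's connectome scale and its sweep range must be chosen together.
For the 12-region recovery experiment the connectome is drawn with
sdlog 0.3, giving a mean row strength near 3: with that drive scale the
synchronization transition of the bistable nodes falls inside the 0–10
sweep and $C^\* = 5$ sits at its most informative point. (At the default
dispersion a 12-region max-normalized matrix has row strength near 1.6, the
whole sweep stays in the weak-coupling regime, and the reference contains
nothing recoverable.) At the resting-state protocol's short window (1 s
retained, 20 repetitions) the recovery is a genuinely noisy experiment; the
packaged test runs it at fixed seeds and recovers $C^\*$ exactly, with the
correlation peak well above both grid ends.

## Graph analysis

FC matrices are binarized by absolute thresholding (entries $\ge t$ become
edges; the default grid is 0–0.5 in steps of 0.01, 51 thresholds) and
characterized by: node strength (row sums of the weighted matrix), degree
and average degree, characteristic path length $L$ (mean shortest-path hop
count over ordered pairs), local clustering $2 e_i / (k_i (k_i - 1))$
(defined as 0 for degree < 2, where the ratio is 0/0) with its mean as the
global coefficient, and global efficiency (mean inverse distance, zero for
unreachable pairs). Above the threshold where the graph fragments,
unreachable pairs are excluded from $L$ and counted separately — the
standard brain-connectivity-toolbox convention; below it the conventions
coincide with the textbook definitions. Graph construction, BFS distances,
local transitivity and random-graph sampling are delegated to igraph, with
the conventions above applied on top; the test suite checks every measure
against an independent Floyd–Warshall / triangle-counting implementation on
all 770 connected labeled graphs with up to 5 nodes and on random graphs up
to 12 nodes, at 1e-12.

Small-worldness uses $\sigma = \gamma / \lambda$ with
$\gamma = CC_\mathrm{real}/CC_\mathrm{random}$ and
$\lambda = L_\mathrm{real}/L_\mathrm{random}$, where the random terms are
ensemble means over uniform random graphs with the same node and edge
counts — the literal "matched random network" construction; degree-preserving
rewiring is available as an option. The ensemble size (default 20) and seed
are recorded in the result. For a single random graph the index scatters
around 1 with substantial variance (clustering of a sparse G(n, m) draw is a
noisy quantity), so only ensemble statements — mean near 1 for random
graphs, consistently above 1 for ring-lattice-derived small-world graphs —
are meaningful.

## Signal descriptors

Per-region descriptors summarize the simulated dynamics: the baseline
potential is the temporal mean of the retained output (the natural reading
of a "baseline" measured in mV; regions on the alpha branch sit above ~4 mV,
background regions below), and the dominant frequency is the argmax of a
Welch-style averaged periodogram (512-sample Hann segments, 50% overlap by
default) within a 0.5–45 Hz search band, ties broken toward the lower
frequency. With repetitions, PSDs are averaged across repetitions before
taking the argmax. All estimator settings are arguments, not constants.

## A worked example

A complete scaled-down analysis — synthesize a connectome, fit the coupling
by sweep against a model-generated reference, and characterize the fitted
network — at sizes chosen to run in seconds:

```{r example, eval = FALSE}
sc  <- make_synthetic_sc(n_regions = 12, sdlog = 0.3, seed = 11)
ref <- make_reference_fc(sc, wendling_params(),
                         simulation_config(seed = 101), c_star = 5)
sw  <- sweep_coupling(sc, wendling_params(), simulation_config(seed = 202),
                      ref, c_min = 0, c_max = 10, c_step = 0.5)
sw$best_c   # 5 at these seeds

sys  <- coupled_system(wendling_params(), sc, c_global = sw$best_c)
reps <- simulate_repetitions(sys, simulation_config(seed = 303))
fc   <- average_fc(lapply(reps, fc_matrix))
threshold_metrics(fc, thresholds = c(0.3, 0.5, 0.7), small_world = TRUE)
region_features(reps)
```

## Numerical choices and limitations

* Time is in seconds everywhere; rate constants in 1/s, potentials in mV.
  The 1000 Hz default fixes $h = 1$ ms, comfortably stable for
  $g = 500$ s$^{-1}$ under RK4 ($gh = 0.5$); sampling rates below about
  150 Hz make the fast-inhibition kernel numerically unstable and trigger
  the divergence error by design.
* The inclusive grids (coupling sweep, threshold grid) are built as
  `lo + step * 0:k` with a tolerant endpoint test, so floating-point drift
  cannot drop the last point.
* PLV values are clipped to 1 from above only to absorb last-bit rounding
  of the complex mean.
* The analytic signal is computed on the full retained window without
  tapering; phase estimates near the window edges are less reliable, which
  is immaterial for PLV (a time average) but visible in the phase tests,
  which therefore examine mid-window samples.
* Text output formats use 9 significant digits — enough that write/read
  round-trips are exact at printed precision and files are diff-able.
* The model inherits the Wendling mass's limitations: no gamma-band
  generation, no conduction delays, identical parameters across regions,
  and no hemodynamic forward model — comparisons to BOLD-derived FC compare
  PLV on model output with PLV on BOLD directly.
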