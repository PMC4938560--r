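---
title: "Infomax recurrent networks and the emergence of synaesthetic mappings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infomax recurrent networks and the emergence of synaesthetic mappings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`synmax` simulates two recurrently coupled sensory representations whose
recurrent weights evolve to maximize the network's sensitivity to its
inputs, and asks under which conditions this optimization creates stable,
functional *cross-modal* connections — the network-level signature of
synaesthesia — even though the inputs to the two modalities are
statistically independent.

An input layer with $N$ neurons drives an output layer with $M \ge N$
neurons through fixed feedforward weights $W$; output neurons interact
through recurrent weights $K$ and a logistic squashing nonlinearity
$g(u) = 1/(1+e^{-u})$:

$$\tau \frac{ds_i}{dt} = -s_i + g\Big(\sum_j W_{ij} x_j + \sum_k K_{ik} s_k\Big),$$

so the steady state satisfies $s = g(Wx + Ks)$. The quality of the
representation is the mutual information between $x$ and $s$; because the
dynamics are deterministic this reduces to the output entropy, and
maximizing it is equivalent to minimizing

$$\varepsilon = -\tfrac{1}{2}\,\big\langle \ln\det(\chi^T\chi) \big\rangle_x,
\qquad \chi_{ij} = \partial s_i / \partial x_j .$$

$\chi$ is the susceptibility of the steady state to input changes; with
$G = \mathrm{diag}(g'(u_i))$ and $\phi = (G^{-1}-K)^{-1}$ it factorizes as
$\chi = \phi W$. Gradient descent on $\varepsilon$ gives the recurrent
learning rule

$$\Delta K = \eta\,\big\langle (\chi\Gamma)^T + \phi^T a\, s^T \big\rangle,
\qquad \Gamma = (\chi^T\chi)^{-1}\chi^T\phi,
\qquad a_k = [\chi\Gamma]_{kk}\, g''_k / (g'_k)^3 .$$

This printed rule is the *exact* gradient $-\partial\varepsilon/\partial K$,
including the implicit dependence of the steady state on $K$: the package
derives it that way and `grad_K_numeric()` (brute-force central differences
of $\varepsilon$ with re-solved steady states) agrees with
`grad_K_analytic()` to a relative error of order $10^{-8}$ in the test
suite — far inside the $10^{-4}$ documented contract. This
oracle-equivalence test is the single most load-bearing test in the
package.

# Numerical choices

**Steady-state solver.** Damped fixed-point iteration
$s \leftarrow (1-\alpha)s + \alpha\, g(Wx+Ks)$ (equivalent to explicit
Euler with step $\alpha\tau$), started from the recurrence-free state
$s^0 = g(Wx)$, with defaults $\alpha = 0.1$, tolerance $10^{-9}$ on the
max-abs update, and an iteration cap of $2\cdot 10^5$. The solver always
starts fresh per stimulus, never warm, so that the iteration count is a
comparable measure of relaxation time across learning stages: it is the
operational "convergence time" behind all critical-slowing-down
diagnostics. The inner loop is compiled (Rcpp) because near criticality a
single stimulus can take $10^4$–$10^5$ iterations.

**Saturation-stable derivatives.** $g'$ evaluated as $g(1-g)$ cancels to
exactly zero in double precision once $|u| \gtrsim 37$; the package uses
$e^{-|u|}/(1+e^{-|u|})^2$, and assembles $\phi$ from the equivalent
well-scaled form $(I-GK)^{-1}G$ rather than $(G^{-1}-K)^{-1}$, whose
entries overflow badly at saturating inputs. The vector $a$ is evaluated
with sequential divisions so $(g')^3$ never underflows on its own. A
genuinely singular $(I-GK)$ signals the super-critical, attractor-dominated
regime and raises an error; training skips such samples and counts them.

**Quadrature.** All deterministic expectations over Gaussian inputs use
Gauss–Hermite rules (`pracma::gaussHermite`), tensor-product in two
dimensions. The default order is 128: at large input standard deviations
the integrands approach step functions and low orders (32) misplace the
phase boundary of the two-unit model by up to two grid cells — order 128
reproduces the boundary implied by long quasi-deterministic stochastic
simulations. At moderate variances the rule is converged far below
$10^{-8}$, which the suite checks by doubling the order.

# The two-unit model and its phase diagram

With one input and one output neuron per modality, feedforward gains
$W_{11}, W_{22}$, learnable cross connections $K_{12}, K_{21}$ only
(within-modality entries are structural zeros), and independent zero-mean
Gaussian inputs, the expected learning update $F(K_{12}, K_{21})$ has
$F(0,0) = 0$: no cross-talk is always a fixed point. Its stability decides
whether synaesthesia can develop:

* the diagram is parameterized by the two *output* variances, each in
  $(0, 0.25)$ — the variance of a logistic unit is bounded by the
  Bernoulli$(1/2)$ value $0.25$, and `sigma_for_output_variance()` inverts
  the monotone variance map by bisection;
* `stability_at_origin()` takes a central-difference Jacobian of $F$
  (step $10^{-4}$, between the solver tolerance and the nonlinearity
  scale), classifies the flow ($\eta \to 0$) by eigenvalue real parts, and
  reports the critical learning rate of the discrete map
  $K \leftarrow K + \eta F(K)$,
  $\eta_c = \min_\lambda\, (-2\,\mathrm{Re}\,\lambda / |\lambda|^2)$, the
  point where a multiplier $|1 + \eta\lambda|$ leaves the unit circle;
* lowering one output variance (sensory deprivation) or raising the other
  (sensory flooding) from a suitable starting point carries the pair out
  of the central stable region; along the diagonal $\eta_c$ grows and
  diverges as both variances approach $0.25$.

**Stochastic verification (the learning-outcome grid).** For each variance
pair, `simulate_learning_grid()` initializes $(K_{12}, K_{21})$ uniformly
on a ring around the origin and runs stochastic infomax updates on Gaussian
samples. The design differs deliberately from the deterministic analysis in
one respect: with online updates the weights never approach the origin
closer than a diffusion floor set by the gradient sampling noise
($\sqrt{\eta\sigma_g^2 / 2|\lambda| B}$, empirically 0.03–0.3 for plausible
$\eta$), so "decayed to a tiny fraction of the initial radius" is not an
observable outcome. The shipped defaults are therefore: ring radius 0.5
(clearly above the diffusion floor, still inside the linearization's
basin), batches of 4 samples per update, $\eta = 0.012$, 15000 updates,
and classification thresholds of $4\times$ the initial radius for
"cross-talk developed" versus $0.3\times$ for "none", with the band in
between reported as "undecided" — near the phase boundary the dynamics are
genuinely slow and an undecided point is the honest outcome. Measured
endpoint separation under these conditions is roughly $0.1$–$0.2\times$
at stable points versus $4$–$12\times$ at unstable ones.

# The two-hypercolumn model

Each modality is a ring of `m_per_modality` output neurons with preferred
angles tiling $[0^\circ, 360^\circ)$ and unit-vector feedforward weights,
so a stimulus at angle $\varphi$ and intensity $r$ drives neuron $i$ of its
own modality with $r\cos(\theta_i - \varphi)$ — a hill of activity, as in a
visual-cortex hypercolumn. Stimuli are sampled independently per modality:
uniform angle, Gaussian intensity around a characteristic radius with
standard deviation proportional to the mean (`radius_cv`, default 0.2;
negative draws are clamped to zero — at this CV a negative draw has
probability $\sim 3\times10^{-7}$, so clamping and resampling are
indistinguishable). The full $2m \times 2m$ recurrent matrix, including
self-connections, is learnable and initialized i.i.d. uniform on
$[-10^{-3}, 10^{-3}]$.

Readout uses the population vector $\sum_i s_i e^{i\theta_i}$ per modality
block; with equally spaced angles the $g(0) = 0.5$ baseline cancels
exactly, so the magnitude measures structured response only.
`probe_response()` stimulates one modality alone (at its characteristic
radius by default) and reads the *other* modality's population vector —
the operational inducer/concurrent test. `extract_mapping()` sweeps probes
around the circle in both directions and summarizes:

* **monotonicity** — Spearman correlation between probe angles and
  unwrapped response angles. Unwrapping picks a single cut point on the
  circle minimizing the total variation of the series, so a "shifted
  monotonic" circular mapping (which jumps once when plotted on
  $[0,360)$) becomes a monotone real sequence; unlike cumulative-difference
  unwrapping this cannot accumulate spurious full turns from response
  noise;
* **directionality** — $|m_f - m_r| / (m_f + m_r)$ on the mean
  population-vector magnitudes of the two directions, with
  "unidirectional" requiring the index to exceed 0.8 *and* the weak
  direction to stay below 5% of the strong one ("effectively zero");
* **block structure** — `block_decompose()` splits $K$ into intra- and
  cross-modality blocks, with symmetry defects, signed means, and the
  interaction profile (mean weight versus preferred-angle difference),
  whose peak-to-trough amplitude measures how strongly a modality
  amplifies its own inputs.

# Training dynamics near criticality

A network optimizing its sensitivity moves toward a critical point of its
recurrent dynamics: susceptibility is maximal there. Three consequences
shape the training design:

1. **Convergence times diverge.** Early in training a stimulus relaxes in
   $\sim 10^2$ solver iterations; near the optimum, $10^3$–$10^5$. The
   per-sample iteration record in the `TrainingTrace` is the
   critical-slowing-down measurement, summarized by `slowing_ratio()`
   (median over the last 5% of samples relative to the first 5%). During
   scenario training the solver cap is $3\times10^4$ — above the 99th
   percentile of converged samples measured at desk scale — so truly
   divergent samples are cut off cheaply; capped counts right-censor the
   late-training median, which only understates the slowing ratio.
2. **The objective can rise again.** With a fixed learning rate the
   discrete dynamics overshoot into the super-critical regime, where
   steady states stop converging or the susceptibility becomes singular.
   Training therefore skips unusable samples (averaging each batch over
   its usable part), checkpoints $\varepsilon$ on a frozen evaluation set,
   and keeps the minimum-$\varepsilon$ pattern (`best_K`) as the network's
   optimal interaction pattern; probing is done on `best_K`.
3. **Aborting on non-convergence is wrong here.** The fraction of
   non-converging solves is not a bug indicator but a feature of the
   regime; `train_hypercolumn()` therefore never aborts by default
   (`max_nonconverged_frac = 1`), while the lower-level `train()` keeps a
   stricter default for generic use.

# Scenario presets and desk scale

The shipped presets encode the qualitative regimes: equal moderate
intensities with modest plasticity (stable baseline, no synaesthesia:
$\eta = 0.002$); one modality's intensity reduced tenfold
(deprivation: $r_1 = 0.2$ versus $r_2 = 2$, $\eta = 0.01$) or raised
(flooding, the mirror image); and the baseline input statistics with the
learning rate raised to $\eta = 0.1$ (high plasticity). Desk-scale
defaults use 16 neurons per modality and 1000–3000 batched updates so a
scenario runs in one to a few minutes; `full_scale = TRUE` switches to 71
neurons per modality and long training, which reproduces the cleaner
full-size phenomenology at a cost of many hours to days.

Two desk-scale compromises deserve emphasis. First, stochastic-gradient
noise accumulates in the weights as $\sqrt{\eta/B}$ per unit of weight
movement, which is why the presets use batched updates and why the learned
blocks remain visibly noisy: the residual asymmetric noise component is of
order 0.2 of the block amplitude at affordable sample counts, so
quantitative block statistics (symmetry defects, signed block means, the
exact reverse-direction magnitude) carry that noise. Second, the baseline
learning rate is set well below the deprivation preset's, not "slightly"
below the high-plasticity one: each modality's own infomax optimum is
near-critical, and a near-critical ring amplifies even noise-level
cross weights into a measurable population-vector response, so a
desk-scale baseline run only shows "zero" cross-modal magnitude if it
stays short of full intra-modality amplification. What the desk-scale
tests do show: the deprivation regime develops a functional, strongly
asymmetric (intact-to-deprived) mapping with a monotonic angle
relationship on most seeds, the deprived modality's interaction profile
is the stronger one, cross weights out of the deprived modality are net
inhibitory, raised plasticity alone flips the baseline from no
synaesthesia to synaesthesia, and synaesthetic runs slow down by two
orders of magnitude. What they do not reliably show at 16 neurons and
minutes of training: reverse magnitudes below 5% of forward, net
excitatory mean of the into-deprived block, intra-block symmetry defects
below 0.1, or the clean block images of the full-scale model — nor, of
course, anything about human perception.

# Known limitations

* The learning rule is non-local (it involves matrix inverses of
  network-wide quantities); it models the long-term evolution of the
  system, not moment-to-moment biological plasticity.
* Rate dynamics without noise; no spiking, no conductances, no
  time-varying stimuli.
* Feedforward weights are fixed; only the recurrent matrix learns.
* Gauss–Hermite quadrature loses accuracy as output variances approach the
  0.25 bound (inputs become effectively binary); phase-diagram
  classifications above $v \approx 0.235$ should be treated with caution.
* Small-network stochastic runs are seed-dependent near the phase
  boundary; multi-seed majorities, not single runs, are the supported
  evidence level at desk scale.
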