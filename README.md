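# synmax

Infomax recurrent rate networks and the emergence of synaesthetic
cross-modal mappings.

## The problem

Synaesthesia — a stimulus in one modality (the *inducer*) reliably evoking
a percept in another (the *concurrent*) — is usually described either as
aberrant wiring or as disinhibited feedback. `synmax` implements a
different account: two recurrently coupled sensory representations whose
recurrent weights evolve to **maximize the network's sensitivity to its
inputs** (infomax). Under ordinary input statistics the optimization keeps
the two modalities functionally separate; under *sensory deprivation*,
*sensory flooding*, or *high plasticity*, stable functional cross-modal
connections emerge even though the inputs to the two modalities are
statistically independent. The package is for computational neuroscientists
who want to simulate, analyse, and extend that mechanism.

## The model

Output rates obey
$\tau\, \dot s_i = -s_i + g\big(\textstyle\sum_j W_{ij}x_j + \sum_k K_{ik}s_k\big)$
with the logistic $g$. With deterministic dynamics, maximizing the mutual
information between input $x$ and steady state $s$ is minimizing

$$\varepsilon = -\tfrac12 \langle \ln\det(\chi^T\chi)\rangle_x,
\qquad \chi = \partial s/\partial x = \phi W,
\qquad \phi = (G^{-1}-K)^{-1},$$

and gradient descent on $\varepsilon$ gives the recurrent-weight rule
$\Delta K = \eta \langle (\chi\Gamma)^T + \phi^T a s^T\rangle$ with
$\Gamma = (\chi^T\chi)^{-1}\chi^T\phi$ and
$a_k = [\chi\Gamma]_{kk} g''_k/(g'_k)^3$. The package provides

* the **network core**: steady-state solver (damped fixed-point iteration,
  compiled inner loop) and susceptibility computation;
* **infomax learning**: the analytic rule, a brute-force finite-difference
  gradient oracle it is tested against, and a training loop that
  checkpoints the objective and keeps the minimum-$\varepsilon$ pattern;
* the **two-unit model**: deterministic Gauss–Hermite analysis of the
  learning dynamics around zero cross-talk — phase diagram over output
  variances, critical learning rate $\eta_c$, and a stochastic
  learning-outcome grid to verify the classification;
* the **two-hypercolumn model**: cosine-tuned ring populations, population
  vector readout, probe protocol, synaesthetic-mapping extraction
  (monotonicity, directionality), block decomposition of $K$, and
  critical-slowing-down diagnostics;
* **scenario presets** (`stable-baseline`, `deprivation`, `flooding`,
  `high-plasticity`) with an end-to-end runner and a small CLI
  (`inst/cli/synmax`).

## Worked example

Stability of the no-cross-talk state of the two-unit model, and what the
learning dynamics do to a small perturbation:

```r
library(synmax)

# input sigmas producing output variances (0.20, 0.02): strong sensory
# deprivation of the second modality
spec <- simple_model_spec(sigma_for_output_variance(0.20),
                          sigma_for_output_variance(0.02))
stability_at_origin(spec)
#> <synmax_stability> unstable origin; eigenvalues -0.237744,  0.003765; eta_critical 0
```

The positive eigenvalue says zero cross-talk is unstable: cross-modal
weights will grow (synaesthesia develops). At equal mid-range variances the
origin is stable and the critical learning rate is finite:

```r
spec <- simple_model_spec(sigma_for_output_variance(0.15),
                          sigma_for_output_variance(0.15))
stability_at_origin(spec)
#> <synmax_stability> stable origin; eigenvalues -0.12992, -0.02992; eta_critical 15.39
```

A deprivation scenario of the two-hypercolumn model end to end (16 neurons
per modality; about two minutes):

```r
out <- run_experiment(experiment_config("deprivation", seed = 1,
                                        out_dir = "dep_run"))
str(attr(out, "summary")[c("synaesthesia", "directionality_index",
                           "monotonicity_score", "mean_magnitude_forward",
                           "mean_magnitude_reverse", "slowing_ratio")])
#> List of 6
#>  $ synaesthesia          : logi TRUE
#>  $ directionality_index  : num 0.811
#>  $ monotonicity_score    : num 1
#>  $ mean_magnitude_forward: num 0.712
#>  $ mean_magnitude_reverse: num 0.0741
#>  $ slowing_ratio         : num 233
```

Stimulating the intact modality evokes a structured response in the
deprived one, an order of magnitude stronger than the reverse direction
(directionality index 0.81); the evoked angle is a perfectly monotone
function of the stimulus angle (the sign of the Spearman score only
reflects the arbitrary orientation of the emergent mapping); and
steady-state relaxation at the end of training is roughly 230 times slower
than at the start — the critical-slowing-down signature of a network that
has moved close to a critical point. At this desk scale the directionality
falls short of the clean full-scale "reverse effectively zero"
phenomenology on most seeds (see the vignette on what desk-scale runs do
and do not show). The run directory contains the weight matrices, the
objective trace, per-probe population vectors, and block summaries as
CSV/TSV/JSON.

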