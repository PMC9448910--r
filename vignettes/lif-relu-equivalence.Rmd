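---
title: "Linear LIF neurons as ReLU units: models, mapping and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear LIF neurons as ReLU units: models, mapping and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifmap)
```

# The model

`lifmap` simulates leaky integrate-and-fire (LIF) neurons driven by trains
of Dirac impulses and converts rectified-linear (ReLU) artificial networks
into spiking networks through an exact parameter correspondence.

The membrane obeys

$$C_m \frac{dV}{dt} + g_l\,(V - V_0) = I_{inj}(t),
\qquad \tau_m = C_m / g_l,$$

with injected current a weighted sum of presynaptic impulse trains
$I_{inj}(t) = \sum_i \omega_i \sum_j \delta(t - t_j)$. Between impulses the
potential decays exponentially with time constant $\tau_m$; each impulse of
amplitude $\omega$ steps it by $\omega / C_m$. When the pre-reset potential
$H$ reaches the threshold $V_{th}$ the neuron emits one unit-amplitude
spike and resets. Two reset rules are implemented:

* **linear (soft) reset** — $V \leftarrow H - V_{th}$: the surplus above
  threshold is retained, so no charge is ever discarded;
* **reset-to-zero** — $V \leftarrow V_{reset}$: the surplus is discarded.

The soft-reset neuron is the one that behaves like a ReLU unit; the
reset-to-zero variant is kept for comparison (it systematically under-fires
at high input rates — see `run_experiment("transfer_curve", ...)`).

Under periodic input of amplitude $\omega$ and period $T$ the subthreshold
potential after the $n$-th impulse has the closed form

$$V(nT^+) = \frac{\omega}{C_m}\,\frac{1 - e^{-nT/\tau_m}}{1 - e^{-T/\tau_m}},$$

implemented by `closed_form_potential()` and validated in the tests against
a brute-force integration at a $10^{-5}$ s step.

# Rate coding

A real value $x \in [0, 1]$ is encoded as a periodic unit-amplitude train
at frequency $f = x \cdot f_{max}$: spikes at $t_j = j / f$ for
$j = 1 \dots \lfloor T_w f \rfloor$ (`encode_rate()`). Decoding is the
count readout $f' = N / T$ (`decode_rate()`), so the coding error obeys
$|f - f'| < 1/T$: one spike more or less changes the decoded frequency by
exactly $1/T$. Longer windows mean finer frequency resolution; this single
inequality drives every accuracy trend in the package.

Weights never live in conductances: they ride in the amplitudes of the
spike trains (`weighted_sum_trains()`), so a layer's pre-threshold input is
*exactly* the discrete weighted sum of its input counts — linear algebra on
event counts, with no approximation before the threshold nonlinearity.

# The parameter mapping

For a ReLU unit $y = k \cdot \max(0, \sum_i \omega_i x_i + b)$ and a
soft-reset LIF neuron the correspondence is (`relu_to_lif()`,
`lif_to_relu()`):

| ReLU side              | LIF side                                        |
|------------------------|-------------------------------------------------|
| weights $\omega$       | spike-train amplitudes $\omega$ (unchanged)      |
| slope $k$              | $1 / (V_{th} C_m)$                               |
| bias $b \le 0$         | leak conductance $g_l$ (see below)               |

The slope row is exact: without leak, charge conservation under soft reset
gives output count $N_{out} = \lfloor \sum_i \omega_i N_i / (V_{th} C_m)
\rfloor$ up to the final subthreshold residue, i.e. output frequency
$\approx \frac{1}{V_{th} C_m} \sum_i \omega_i f_i$.

## The bias convention

A leaky neuron cannot fire unless its equal-frequency inputs arrive faster
than a minimum frequency. From the closed form above, requiring the
largest achievable potential within the window $T_w$ to reach $V_{th}$
gives

$$f_{min} = \frac{-1}{\tau_m \,\ln\!\big(1 - A\big)},
\qquad A = \frac{\sum_i \omega_i}{V_{th} C_m}\big(1 - e^{-T_w/\tau_m}\big),$$

valid for $0 < A < 1$, with the leak-free limit
$f_{min} = V_{th} C_m / (\sum_i \omega_i\, T_w)$ recovered continuously as
$g_l \to 0$ (`min_firing_frequency()`; a bisection search on the simulator,
`min_firing_frequency_sim()`, serves as its oracle in the tests). Note the
direction: $f_{min}$ *increases* with $g_l$ and *decreases* as the
combined weight grows — a heavier weight reaches threshold at lower rates
— diverging only as the combined weight vanishes.

The bias is then defined by self-consistency: the ReLU's zero-crossing
frequency must equal the LIF neuron's minimum firing frequency in the
large-window limit,

$$-\,\frac{b}{\sum_i \omega_i} = f_{min}^{\infty}
\quad\Longleftrightarrow\quad
b = \frac{g_l \sum_i \omega_i}{C_m \ln\!\big(1 - \sum_i \omega_i /(V_{th} C_m)\big)} \;\le 0 .$$

This convention was chosen over the alternative algebraic variant
$-(\sum\omega\, g_l / C_m)\ln(1 - \sum\omega/(V_{th}C_m))$ (which has the
opposite sign and a different magnitude, and is still exposed as the
`bias_printed` attribute) because only the self-consistent form makes the
two directions of the mapping mutually inverse and ties $b$ to an
observable of the spiking neuron: with $\omega = (0.3, 0.2)$,
$C_m = V_{th} = 1$, it maps $g_l = 3$ to $b = -2.164$ and back, and the
zero-crossing it predicts coincides with the simulated onset of firing to
within one frequency quantum. It also gives the inverse map a closed form,
so no root finding is needed:

```{r}
r <- lif_to_relu(lif_params(Cm = 1, gl = 3, Vth = 1), c(0.3, 0.2))
c(bias = r$bias, slope = r$slope)
relu_to_lif(r, mapping_config(v_th = 1))$params$gl
```

Positive biases have no LIF counterpart here (they would need a constant
driving current) and are rejected; the bias branch requires
$0 < \sum_i \omega_i < V_{th} C_m$, the domain on which the logarithm is
defined.

## What the mapping does and does not promise

For **bias-free** neurons ($g_l = 0$) the equivalence is tight: charge
conservation makes the decoded output frequency match the ReLU output to
within one frequency quantum $1/T_w$ per layer, and this is what the
package's converted-network checks measure.

For **leaky** neurons the input-output curve of the soft-reset neuron is
convex near the firing onset: it leaves zero at $f_{min}$ with a steep
initial slope and only asymptotically parallels the ReLU line. No straight
line can track the knee of this curve to within $1/T_w$ everywhere, so the
biased single-neuron equivalence is approximate by nature — the transfer
curve experiment reports the full three-model comparison rather than
claiming a uniform bound. The `predicted_output_frequency()` helper makes
the distinction explicit: its `exact` staircase $f/n^\ast$ describes the
reset-to-zero neuron (which restarts from zero and therefore fires exactly
once per $n^\ast$ inputs), is a lower bound for the soft-reset neuron, and
its `approx` value is the proportional law above.

# Layers and networks

Spiking layers operate on `spike_tensor` objects (one train per unit, all
on one grid, columns ordered column-major over height, width, channel —
also the flatten contract, chosen to coincide with R's native array order):

* `snn_dense()` — weighted superposition of all input trains per output
  unit, then per-neuron LIF integration; outputs are re-emitted as
  unit-amplitude trains so that the next layer's weights supply the
  amplitudes;
* `snn_conv2d()` — cross-correlation orientation (no kernel flip), zero
  padding contributes empty trains; the layer is expanded once into an
  explicit weight matrix shared with the reference implementation, which
  makes the pre-threshold linear algebra of the two sides *identical* by
  construction;
* `snn_maxpool2d()` — counts events per window member over the whole
  window and forwards the busiest member's train unchanged (ties go to the
  first member in window order); pooling selects, never edits, timing;
* `ann_forward()` — the non-spiking reference for every layer kind.

`convert()` applies the mapping neuron by neuron (per-channel for
convolutions, where each filter's weight sum plays the role of
$\sum\omega$) and records which network layer each spiking layer came
from. `snn_infer()` rate-encodes an input, propagates it, and reads out
the class as the argmax of output spike counts, ties toward the smallest
index; an all-silent output yields label 1 plus a `silent` flag rather
than an error. Softmax output layers are not simulated — the spike-count
argmax readout replaces them.

Network descriptions round-trip through a JSON manifest (`save_spec()`,
`load_spec()`); doubles are written with 17 significant digits, which
reproduces them bit-exactly.

# Equivalence metrics

`correlation()` implements the product-moment coefficient in raw-sums
form; a zero-variance vector (a unit silent on every input) is an error at
this level, and `correlation_matrices()` excludes such units automatically
and reports their indices, so analyses remain reproducible.
`agreement()` builds the confusion matrix (reference in rows) and its
trace-over-total rate. `frequency_error_report()` compares decoded output
frequencies with their targets against the $1/T$ bound; units beyond the
bound are flagged, not fatal, because through a cascade of $L$ layers the
per-layer quantisation deficits compound (each layer contributes a
fraction of one spike, weighted by the next layer's weights). Error
normalisation: absolute errors in Hz against $1/T$; relative errors as a
percentage of $f_{max}$.

# Fixtures: what they emulate and what they do not

No external data is used anywhere. `gen_network()` draws random networks
(documented draw order; per-neuron $\sum|\omega|$ capped at 0.8 by
default, which keeps biased mappings inside their validity region and
spike counts well conditioned), `gen_images()` renders Gaussian blobs and
oriented bars, and `gen_two_class_dataset()` builds a left-blob /
right-blob classification problem together with a *hand-constructed*
conv–pool–dense reference network (averaging filter, left-half vs
right-half readout). Nothing is trained: the package's claims concern
conversion fidelity, not network quality, so a reference network that is
correct by construction is the cleanest instrument.

Consequently, passing fixture tests demonstrates that conversion preserves
behaviour on well-separated, low-dimensional synthetic inputs with modest
weight magnitudes. They do not probe trained-weight statistics, deep
architectures, saturated units, or natural-image correlations; conclusions
about real datasets require running the same pipeline on real networks.

# Numerical choices

* **Integration is exact, not Euler.** Per grid step the potential is
  decayed by $e^{-\Delta t\, g_l / C_m}$ and the step's summed event
  amplitude is injected instantaneously. For Dirac-train inputs on the
  grid this reproduces the continuous solution exactly; the integration
  scheme adds no error beyond event-time snapping.
* **Grid and snapping.** Default $\Delta t = 0.01$ s, window 3 s (2, 4 or
  10 s in specific experiments; the sampling ceiling is one spike per
  step). Encoded spike times are snapped to the nearest step with ties
  toward the earlier step, making spike counts bit-reproducible.
* **One spike per step.** If a pathological amplitude drives
  $H \ge 2 V_{th}$ in one step, one spike is emitted and, under soft
  reset, the surplus carries forward (it typically fires the next step);
  reset-to-zero discards it.
* **Initial condition** $V(0) = V_{reset} = 0$; resting potential 0; no
  refractory period, no noise currents.
* **Tie-breaks** are all deterministic and documented: earlier grid step
  on snapping ties, first window member in max-pooling, smallest index in
  argmax readouts.
* **Problem sizes.** The shipped tests and experiments use desk-scale
  configurations — single neurons, dense nets of 16–8–4 units, 8×8 images
  through a conv–pool–dense stack, windows of 1–10 s — chosen so the whole
  suite runs in well under a minute per experiment while still exercising
  every code path at meaningful spike counts.

# Known limitations

* Only non-positive biases convert; positive biases would require a
  tonic input current that the impulse-train front end does not model.
* The biased (leaky) single-neuron transfer curve matches its ReLU line
  only asymptotically (see above); bias-free conversion is the regime
  with per-layer $1/T_w$ guarantees.
* Cascaded layers compound quantisation deficits, so a whole network's
  worst-case output error can slightly exceed the single-stage $1/T$
  bound at short windows; it still scales as $1/T$.
* Max-pooling selects by total count over the window; a unit that fires
  late but often can win over one that fires early — frequency semantics,
  not latency semantics.
* Simulation cost grows linearly in window length over step size and in
  the number of units; the engine is vectorised over neurons but steps
  sequentially over the grid.
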