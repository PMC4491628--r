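---
title: "A generative neural model of biological motion perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generative neural model of biological motion perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biological motion — the movement of an articulated living body — is
recognizable from remarkably sparse input, and the brain maps motion it
*sees* onto the motor and proprioceptive codes of its *own* body even when
the other person is viewed from a vantage point never experienced during
self-observation. This correspondence problem is what the model in this
package addresses: it learns visuo-proprioceptive motion patterns from
simulated self-observation and later recognizes the same motions in
others, deduces the visual perspective onto them by active inference, and
fills in unobservable (proprioceptive) state from vision alone.

The package implements the model as a three-stage processing cascade plus
a growing pattern memory, together with a synthetic articulated-gait
generator that stands in for motion-capture recordings, and desk-scale
versions of the six evaluation experiments.

## The model

### Inputs

The model is driven by $N$ relative visual features and $M$
proprioceptive features per frame. Visual feature $n$ is a relative 3D
position between two labelled landmarks, $p_a - p_b$; proprioceptive
feature $m$ is the angle between two segment vectors, computed by
$\arccos$ of their normalized inner product, hence in $[0, \pi]$. With
the default $N = 12$, $M = 8$ the input layer has $3N + M = 44$ scalar
channels. The feature-to-input assignment is static and supplied as a
`body_feature_spec`; automatic assignment is out of scope (it is genuinely
hard, and nothing below depends on the particular choice as long as the
features are expressive). The coordinate convention is right-handed with
$y$ vertical; "rotations about the vertical axis" are rotations about
$y$, and the depth coordinate removed by 2D projection is $z$.

### Stage I — scaling, smoothing, directional velocity

Each scalar input is scaled by $\alpha$ and exponentially smoothed,
$s(t) = \lambda\, s(t-1) + (1-\lambda)\,\alpha\, x(t)$. The per-feature
velocity is the one-step difference of the smoothed signal, grouped into
3-vectors for visual features and scalars for angles, and each feature's
velocity $v$ is softly normalized to a *direction*

$$d = v \cdot \min(1/\lVert v\rVert,\ 1), \qquad
  \lVert d \rVert = \min(\lVert v \rVert, 1).$$

Saturated features (raw velocity magnitude at least $1/\alpha$ per frame)
carry a pure direction — this is where the invariances to translation,
scale, speed, and body morphology come from — while sub-threshold features
keep their magnitude, which protects the code against noise on nearly
static features. One rendering note: the normalizer neuron is specified
through its net input $\sum o^2$, and a literal gain $\min(1/\sum o^2, 1)$
would not produce unit length; the stated behaviour ("normalized to
length 1") requires the gain $\min(1/\sqrt{\sum o^2}, 1)$, which is what
`stage1_directions()` implements. Angle velocities are plain differences
without circular unwrapping: angles live in $[0, \pi]$ and cannot wrap.

The smoothing buffer is seeded with the first scaled input, so frame 1 has
zero velocity rather than a startup transient.

### Stage Ic — perspective-taking

All visual directions (never the 1D angles) are rotated by a shared
internal rotation $R_\mu = R_x(\mu_x) R_y(\mu_y) R_z(\mu_z)$ (z-y-x Euler
sequence acting on column vectors). The three biases $\mu$ adapt by
gradient descent with momentum on the top-down prediction error energy
$E = \tfrac12 \lVert \delta \rVert^2$:

$$v \leftarrow m_\mu v - \eta_\mu \frac{\partial E}{\partial \mu}, \qquad
  \mu \leftarrow \mu + v.$$

The angles are left unbounded; convergence is measured by the wrap-safe
orientation difference (below). Because the rotation sits *downstream* of
the Stage I normalization and the population tuning is isotropic (next
section), the backpropagated gradient with respect to $\mu$ is exact —
no approximation is involved on this path. The finite-difference
equivalence is asserted in the test suite at $10^{-4}$ relative error in
the sub-threshold regime (away from the static-neuron clip, where
finite differences themselves are ill-conditioned).

### Stage II — population coding

Each feature's direction is recoded by a bank of direction-selective
neurons whose preferred directions are all sign patterns in
$\{-1,0,1\}^D$ except the origin, normalized and scaled by $\beta$: 26
neurons for a 3D feature, 2 for an angle. The combinatorial tuning set
satisfies

$$W^\top W = \beta^2 \frac{3^D - 1}{D} I,$$

so the response $W d$ to any direction has norm proportional to
$\lVert d \rVert$ regardless of its orientation. Choosing
$\beta = L\sqrt{D/(3^D-1)}$ therefore gives every saturated feature's
population response norm exactly $L$ — this isotropy argument resolves an
ambiguous rendering of the $\beta$ formula in the source material, and is
verified analytically in the tests. Each population carries one further
*static* (no-motion) neuron $o_s = \sqrt{\max(0,\ L^2 - l^2)}$, with $l$
the norm of the direction-selective part (the clip at zero guards
rounding when $l \approx L$), so every available feature slice has norm
exactly $L$. With $L = 1/\sqrt{N+M}$ the concatenation of all populations
— $12\cdot27 + 8\cdot3 = 348$ neurons by default — has unit norm, the
prerequisite for cosine-based pattern matching downstream. An exogenous
gain $g_n \in \{0,1\}$ marks features unavailable (e.g. proprioception
while observing someone else); dropped slices are exactly zero and the
total norm becomes the square root of the available fraction.

### Stage III — growing pattern memory

Pattern neurons cluster the population stream. Each pattern $j$ holds an
instar weight vector $w_j$; its stimulus net input is the cosine
similarity between $w_j$ and the activation (the presynaptic process
divides by $\max(\lVert w_j \rVert, r)$, and activations are unit
vectors). Activations are Cauchy-noisy: trained patterns fire
$\mathcal{C}(\gamma, \mathrm{net}_j)$, the single *free* pattern fires
$\mathcal{C}(\gamma, \theta)$. The winner (argmax; ties, a measure-zero
event, break to the lowest index) is trained by
$w_k \mathrel{+}= \eta\, (o - w_k)$. A free pattern that wins is thereby
recruited — $\eta > r$ guarantees one update crosses the trained
threshold — and a fresh zero-instar free pattern is appended, so exactly
one free pattern exists at all times and the layer grows on demand. The
probability that the free pattern beats the best trained pattern has the
closed form

$$p = \tfrac12 + \tfrac1\pi \arctan\!\Big(\frac{\theta -
  \mathrm{net}_g}{2\gamma}\Big),$$

which equals $0.5$ at $\mathrm{net}_g = \theta$; the noise scale is
calibrated from a remainder $\epsilon$ and breadth $b$ via
$\gamma = \tan(\epsilon\pi)\, b / 2$, so that $p = \epsilon$ at
$\theta + b$. The free/trained threshold $r$ is only constrained by
$0 < r < \eta$; we fix $r = \eta/2$.

**Lateral sequence learning.** The previous winner $k$ inhibits every
other trained pattern $j$ through its outgoing lateral weight $w_{kj}$
(initialized 0.5, free pattern neither sends nor receives). The
inhibition term is

$$s(w) = \tanh\!\big(2\gamma \tan((w - \tfrac12)\pi)\big)\ \text{for}\
   w < \tfrac12, \qquad s(w) = 0\ \text{otherwise},$$

which satisfies the two anchors the mechanism is defined by: no
inhibition at the 0.5 initialization, and — under noise-only drive — the
probability that $j$ out-fires $k$ is approximately $w_{kj}$ (asserted by
Monte Carlo in the tests). The formula as printed in the source reads
$\tanh(-2\gamma\tan(w\pi))$, which is maximally inhibiting at $w = 0.5$
and contradicts both anchors; we treat that as a typesetting defect and
keep the printed form available behind `compat_printed_inhibition = TRUE` for
comparison. Weights above 0.5 clamp to zero inhibition (no facilitation).
On every winner transition out of $k$, the outgoing weights move toward
the window-averaged closed-form probability that each $j$ beats $k$,
at rate $\eta_l$, using the net inputs buffered since the previous
transition (including the lateral terms then in effect, and including the
transition step).

### Self-supervision

The winner's instar is a top-down prediction of the population
activation; the error $\delta_i = w_{ik} - o_i$ (zeroed on unavailable
slices) is propagated back through the population tuning (transpose of
$W$), through the static neurons (via $l$), and through
$\partial R_\mu / \partial \mu$ applied to the pre-rotation directions,
to the three Euler biases. Angle features are not rotated and contribute
nothing to this gradient. Minimizing the error by rotating the whole
visual percept is the model's active-inference account of visuo-spatial
perspective-taking; reading out $\mu$ after convergence yields the
orientation of the observed actor.

Convergence is scored by the orientation difference between a trained
view $P_i$ and the derived orientation. The stimulus reaches the model
already rotated by the exogenous $R_\nu$ and is then internally rotated
by $R_\mu$, so the derived orientation is the composition $R_\mu R_\nu$
and

$$\mathrm{OD}_i = \arccos\!\Big(\frac{\mathrm{tr}(P_i^\top R_\mu R_\nu)
  - 1}{2}\Big) \in [0, \pi].$$

(The printed formula in the source places a factor $\tfrac12$ outside the
$\arccos$ and composes the rotations in the opposite order; the standard
axis-angle identity and the composition order implied by the processing
path — which the source's own prose states as $R_\mu R_\nu$ — are used
here, verified against a quaternion oracle.)

## Reference parameterization

| parameter | symbol | default | role |
|---|---|---|---|
| input scaling | $\alpha$ | 5000 | sets the velocity saturation point $1/\alpha$ (per frame, input units) |
| smoothing factor | $\lambda$ | 0.95 | exponential smoothing of scaled inputs |
| instar learning rate | $\eta$ | 0.01 | winner adaptation per step |
| perspective learning rate | $\eta_\mu$ | 0.0075 | gradient step on the Euler biases (rad) |
| perspective momentum | $m_\mu$ | 0.85 | momentum on the bias updates |
| recruitment threshold | $\theta$ | $\cos 60^\circ$ | cosine level of even-odds recruitment |
| threshold breadth | $b$ | 0.034 | recruitment sigmoid breadth |
| recruitment remainder | $\epsilon$ | 0.001 | recruitment probability at $\theta + b$ |
| lateral learning rate | $\eta_l$ | 0.6 | batch update of transition weights |
| free/trained threshold | $r$ | $\eta/2$ | instar norm below which a pattern is free |

All defaults are wired into `run_config()` and `bm_model()`; any override
is carried in the returned objects.

## The synthetic motion generator

No motion-capture recordings are distributed with the model, so every
experiment runs on `generate_motion()`: a two-level kinematic chain
(pelvis/chest/head trunk, two arms, two legs; 15 landmarks, segment
lengths in meters) driven by sinusoidal joint angles at 120 Hz. Three
motion kinds differ in cycle frequency (6, 8 and 5 cycles per 360 frames
for `gaitA`, `gaitB`, `gaitC`), amplitude pattern, and the strength of an
asymmetric right-arm component (a lateral, out-of-sagittal oscillation
plus a larger swing gain); the walk-like `gaitA` cadence matches the
reference condition of about 6 cycles per 360-frame interval.
"Subjects" are emulated by log-normal per-segment morphology scaling
(sd 0.08) and posture-control noise on the joint angles. The posture
noise is a low-pass AR(1) process (time constant about 0.25 s) with
stationary sd 0.02 rad: postural variability is a low-frequency
phenomenon, and white noise at the sampling rate would put energy into
single-frame direction reversals that no real recording contains.
Trunk bob, sway and shoulder counter-twist amplitudes scale with their
segment lengths, so uniform morphology scaling is an exact similarity
transform and extracted angles are exactly invariant to it — one of the
tested invariances.

What the generator does *not* emulate: ground contact and biomechanical
realism, foot-strike transients, inter-subject differences in style
beyond morphology and smooth postural noise, marker occlusion or gaps.
Passing tests on this generator therefore show that the *model* behaves
as specified on periodic, articulated, noisily-controlled motion; they do
not certify performance on real mocap with labeling errors or gaps.

## Experiment design choices

Training always runs with the visual frame frozen at $\mu = 0$
(self-observation does not require perspective correction); testing
disables all pattern learning. Recruitment is part of learning, so with
learning disabled the free pattern does not compete — otherwise a free
pattern firing around $\theta = 0.5$ would dominate any noise-driven free
run. $\mu$ is reset to zero at each test-trial start (configurable).

*Single-motion learning* trains one `gaitA` trial for 20 repetitions of
360 frames and then free-runs the layer for the same duration with all
gains zero. The free-run check compares winner *successor structure*, not
raw sequences: patterns with an unambiguous stimulus-driven successor
must reproduce it as their free-run modal successor. Hub patterns that
win two different phases of the cycle have context-dependent successors,
which first-order lateral weights represent only probabilistically — the
free run mixes at such hubs, and the check excludes them.

*Multiview encoding* trains 3 kinds × 4 views (rotations about the
vertical by 0°, 90°, 180°, 270°) × 20 repetitions and scores winning
exclusiveness on held-out subjects of the same conditions.

*Perspective-taking* applies Haar-uniform random rotations (sampled via
normalized Gaussian quaternions) to held-out subjects and adapts $\mu$
for 5000 steps; a run succeeds when the OD to at least one trained view
drops below 35°. The desk-scale study uses 50 runs (the full-scale
reference used 500; `run_config(n_test_runs = )` restores it).

*Bistability* trains the egocentric and facing views of the asymmetric
walker with full visuo-proprioceptive drive, then presents the same data
again as a point-light observation — vision only, because watching
another walker yields no proprioceptive input. This matters: with
proprioceptive drive the second-trained view group acquires slightly
diluted proprioceptive templates (its frames are partly captured by
already-trained patterns of the first view), and that small
group-level bias swamps the genuinely discriminative visual signal for
projected stimuli. Patterns are assigned to view groups from the
training record (excluding the first two repetitions), since off-manifold
2D stimuli are won largely by patterns that never win a clean 3D replay.
Perspective adaptation is frozen here: a projection or mirror cannot be
undone by a rotation, and recognition is the claim under test.

*Feature inference* trains the egocentric walker, then observes a
held-out subject rotated 180° about the walking direction followed by
45° about the vertical — near-worst-case — and tracks the RMS prediction
error on the proprioceptive population slices with full drive, with
vision-only drive, and with vision-only drive under a frozen perspective
(negative control). On this generator the vision-only error settles
within about 1.5× of the full-drive level (the full-drive level is
essentially the pattern quantization floor), and the frozen control
stays well above both; the reference data showed a narrower gap, which
we attribute to richer per-phase feature structure in real recordings.

## Numerical and degenerate-input choices

- Zero velocity yields the zero direction (gain 1, no division).
- A zero-length angle segment flags the feature unavailable for that
  frame rather than raising an error.
- `encode_feature()` rejects direction magnitudes above $1 + 10^{-6}$ —
  that is an upstream contract violation, not data.
- The static-neuron error path divides by $o_s$ and is skipped when
  $o_s \le 10^{-9}$ (the clip region, where the true contribution along
  the rotation manifold is zero anyway).
- Winner ties break to the lowest index; under Cauchy noise they have
  probability zero.
- The pattern layer owns its RNG stream (saved and restored around every
  draw), so layer behaviour is reproducible independently of other
  consumers of the global generator, and snapshots
  (`save_pattern_layer()`) restore draw-for-draw identical behaviour.
- Problem sizes in the shipped tests and acceptance script: 360-frame
  intervals, 20 training repetitions, 50 perspective runs × 5000 steps,
  $10^5$ Monte-Carlo draws — chosen to estimate every quantity well
  inside its comparison tolerance.

## Known limitations

- First-order lateral weights cannot encode context at hub patterns;
  learned sequences with shared states replay probabilistically.
- Euler-angle descent has the usual gimbal degeneracies; the momentum
  term and the four-view attractor layout make failures rare in the
  tested conditions, but single-view training offers a far sparser
  attractor landscape.
- The scale threshold $1/\alpha$ is fixed; motions whose raw velocities
  fall below it lose the scale/speed invariances by design.
- Feature-to-input assignment is manual; observing an unlabelled point
  cloud is outside the model's scope.
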