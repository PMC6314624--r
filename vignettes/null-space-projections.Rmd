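---
title: "Null-space projections for redundant musculoskeletal systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-space projections for redundant musculoskeletal systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msknull)
```

## The problem

A musculoskeletal system is redundant at two levels. *Kinematic*
redundancy: the task (say, the planar position of the hand, dimension
$d = 2$) is controlled through more joints than it needs ($n = 3$ here).
*Dynamic* redundancy: each joint is actuated by more muscles than there are
joints ($m = 9$ here), so infinitely many muscle-force vectors produce the
same joint torques. Any analysis that picks a single solution — for example
minimum-effort static optimization — silently discards the rest of the
solution space, and quantities computed downstream of the muscle forces
(joint reaction loads above all) inherit that bias.

`msknull` models both kinds of redundancy explicitly with linear projection
operators, and computes the *entire* feasible muscle-force set instead of a
point estimate.

## Operators and equations

For any matrix $A$ with Moore–Penrose pseudoinverse $A^+$, the package
builds the four orthogonal projectors

$$T_A = AA^+,\quad F_A = A^+A,\quad N_{T_A} = I - T_A,\quad N_{F_A} = I - F_A,$$

which project onto the column space, row space, left null space and right
null space of $A$ respectively (`projectors()`). Rank is fixed by an
explicit relative singular-value cutoff (`rtol`, default $10^{-10}$,
applied as $\sigma_i > \texttt{rtol}\,\sigma_{\max}$): without a hard
cutoff, the idempotence and symmetry of the projectors degrade silently
near rank deficiency. All four projectors come from one SVD and are cached
in a `projector_bundle`.

The rigid-body dynamics $M(q)\ddot q + f(q,\dot q) = \tau$ are projected
onto two operational spaces:

* **Task space** (`task_projection()`): task inertia
  $\Lambda_t = (J_t M^{-1} J_t')^{-1}$, bias $b_t = -\dot J_t\dot q$, and
  the *dynamically consistent* generalized inverse
  $\bar J_t' = \Lambda_t J_t M^{-1}$. Among all generalized inverses only
  this one makes null-space generalized forces invisible to the task
  acceleration; the plain pseudoinverse-based projector
  $I - J_t^+ J_t$ does *not* decouple (the package exposes both and the
  test-suite checks the residual of each).
* **Muscle space** (`muscle_projection()`): muscle-space inertia
  $\Lambda_m = (R M^{-1} R')^+$ (a pseudoinverse — the matrix has rank
  $n < m$ by construction), bias
  $b_m = -\dot R \dot q - \dot N_{T_R}\dot l_{m0}$, and the moment-arm
  null-space projector $N_{T_R} = I - RR^+$, where $R = \partial l_m /
  \partial q$ is the (tall) moment-arm matrix. Muscle forces decompose as
  $f_m = -R^{+\prime}\tau + N_{T_R} f_{m0}$: the second term changes
  co-contraction but not the delivered torque, because $R' N_{T_R} = 0$
  identically.

`particular_muscle_forces()` evaluates the particular (null-free) solution
through any of the three routes — task, joint or muscle space — and the
tests pin the routes against each other.

## The bundled analytic arm

The reference model (`build_planar_arm()`, `default_arm_parameters()`) is a
planar chain with three revolute joints (shoulder, elbow, wrist) and nine
muscles: an antagonist mono-articular pair per joint plus three
bi-articular muscles. Segment lengths, masses and rod inertias follow
50th-percentile arm anthropometry (0.31 / 0.27 / 0.15 m, 1.96 / 1.18 /
0.45 kg). Every model quantity — $M$, Coriolis terms, gravity gradient,
$l_m$, $R$, $\dot R$, $x_t$, $J_t$, $\dot J_t$ — is an exact closed form
derived from the chain's point kinematics (the Jacobian of a point carried
by segment $s$ has columns $\hat z \times (p - j_i)$ for $i \le s$, and all
higher derivatives follow by the product rule). No numerical
differentiation is used anywhere in the model; finite differences appear
only in the test-suite as an independent oracle, and in
$\dot N_{T_R}$ (below).

### Muscle routing and moment-arm sign windows

Muscle paths are straight polylines through points fixed in segment frames.
A straight chord crossing a revolute joint between two via points at equal
radii keeps the sign of its moment arm only over a 180° window of joint
angle; outside it the chord crosses the joint center and the muscle would
switch from flexor to extensor. The default geometry therefore routes each
crossing through a via-point pair at along-offset $d$ and perpendicular
offset $h$ chosen per joint: flexors use $d > h$ (a chord spanning the
front of the bend), extensors $d < h$ (a chord hugging the back of the
joint, pulley-like), with the windows sized to cover each joint's
admissible range with margin. This emulates anatomical wrapping without
curved-surface geometry. Only joint-crossing chords contribute moment arms;
path segments between points on the same body add constant length. The
admissible ranges are ±the declared `q_range` (shoulder $[-1.0, 1.6]$ rad —
a single chord cannot cover a range wider than 180° — elbow $[0.2, 2.4]$,
wrist $[-1, 1]$); the wrist windows extend to $(-0.77, 2.37)$ rad because
the posture experiment transiently swings the light wrist well past its
nominal range.

The default posture `q_ref = c(-0.397, 1.935, 0)` places the hand at
$(0.30, 0.30)$ m, chosen so that all four 0.3 m reaching targets stay
comfortably inside the annulus of reachable, well-conditioned postures.
Gravity defaults to zero (horizontal-plane experiments); it is a parameter.

### $\dot N_{T_R}$

The theory uses the time derivative of the null-space projector in the
muscle bias term, but at fixed rank there is no canonical cheap closed
form. The package computes it by central differences of $N_{T_R}$ along
the instantaneous velocity (step $10^{-5}$ s; $N_{T_R}$ depends on $q$
only), and the test-suite validates it against the analytic derivative
$\dot N_{T_R} = -\dot R R^+ - R\,\mathrm{d}R^+\!/\mathrm{d}t$ with
$\mathrm{d}R^+\!/\mathrm{d}t = -R^+\dot R R^+ + (R'R)^{-1}\dot R' N_{T_R}$
(valid at full column rank). Since the default $\dot l_{m0} = 0$ (the
"unbiased" strategy), the term usually drops out; it is exposed for
completeness.

## The feasible muscle-force set

For a commanded torque $\tau$, physiological bounds
$l \preceq f_m \preceq u$ (linear model: $[0, f_{\max}]$; Hill-type hook:
$[c_0, c_1 + c_0]$ with user-supplied force–length/velocity/passive
curves — the bundled curve shapes are generic stand-ins, not fits) turn the
null-space freedom into a bounded convex polytope.
`build_force_inequalities()` first reduces $N_{T_R}$ to an orthonormal
basis $B$ of its range (dimension $r = m - n = 6$ here; in the full $m$
coordinates every system is unbounded along the removed directions) and
encodes $Z y \preceq \beta$ with $Z = [B; -B]$ ($2m$ rows) and
$\beta = (u - f_{m\parallel},\; f_{m\parallel} - l)$.

Vertex enumeration (`enumerate_vertices()`) has two independent backends
pinned against each other in the tests:

* an **exhaustive combinatorial oracle** — solve every $r$-subset of the
  hyperplanes, keep feasible intersections (cost $\binom{2m}{r}$);
* an **incremental halfspace-insertion** method (double-description style):
  start from a certified bounding box, insert one halfspace at a time,
  generate new vertices on edges between kept and cut vertices (adjacency
  by shared active sets, rank-checked in degenerate cases), and finally
  discard any point not supported by $r$ independent true constraints.

The bounding box is certified by Lagrange duality: any $\lambda \succeq 0$
with $Z'\lambda = c$ proves $\max\{c'y : Zy \preceq \beta\} \le
\beta'\lambda$; the multiplier comes from a ridge-regularized nonnegative
least-squares QP, and failure to represent a direction certifies an
unbounded recession direction (the loud error the theory's boundedness
condition demands). For the $[B; -B]$ systems the package itself builds,
the multiplier has a closed form. Vertices are deduplicated at $10^{-9}$
absolute tolerance; the midpoint refinement of `sample_polytope()`
deduplicates too (coincident midpoints would otherwise bias the summary
statistics). Depth 0 returns the vertices; each level adds all pairwise
midpoints, so the axis cube of half-width 0.5 yields 8, then 27 points.

`feasible_force_set()` assembles $f_m^\oplus = \{f_{m\parallel} +
N_{T_R} f_{m0,i}\}$; every sample reproduces $\tau$ to machine precision
and respects the bounds. `force_space_summary()` reports per-muscle
box-plot statistics and the Pearson correlation matrix across samples
(zero-variance muscles are flagged `defined = FALSE` rather than
propagating `NaN`). Note a structural fact the tests encode: for a
single-joint antagonist pair the null direction *raises both forces
together* (their opposite moment arms cancel), so antagonists correlate at
+1 across the feasible set, while two muscles pulling the same way trade
off at −1. Correlation is Pearson on raw forces; rank alternatives are
deliberately not guessed at.

## Controllers and the mixed-dynamics simulator

Two experiment-level controllers are included:

* **Segmental reflex** (`run_reflex_experiment()`): the muscle-space law
  $\ddot l_m^{\text{goal}} = k_p(l_{md} - l_m(t - \tau_{so})) -
  k_d \dot l_m(t - \tau_{so})$ on delayed spindle-like signals
  (defaults $k_p = k_d = 10$, $\tau_{so} = 20$ ms), realized by
  inverse dynamics in muscle space plus a minimum-norm null-space
  correction that keeps the forces inside the muscle-model bounds
  (`muscle_space_controller()`, a strictly convex QP in the reduced
  null coordinates). The perturbation is a Gaussian task-space force
  impulse (defaults 15 N, $t_0 = 0.1$ s, $\sigma = 10$ ms, along $-x$).
* **Task-space reaching** (`run_reaching_experiment()`): operational-space
  inverse dynamics with PD tracking (defaults $k_p = 50$, $k_d = 5$,
  $\tau_0 = 0$, i.e. no secondary joint-space objective) along a smooth
  sigmoid with bell-shaped speed profile (displacement 0.3 m, steepness
  4 s$^{-1}$, midpoint 1 s, direction angle $\gamma$).

`simulate_arm()` couples the inverse-dynamics controller to a
forward-dynamics plant: fixed-step RK4 at $dt = 1$ ms, the controller
evaluated once per step, a dense state history at $dt$ resolution with
linear interpolation for the delayed signals (pre-history equals the
initial state), and a divergence guard. Runs are bit-reproducible.

Two numerical choices deserve emphasis:

* The controller's generalized force is **held constant over each RK4
  step**. Re-evaluating $-R(q)'f_m$ at intermediate stage states would
  leak a torque of order $\|f_{m0}\|\cdot\|\Delta R\|$ as the posture
  moves within the step, making heavily co-contracted solutions falsely
  movement-visible in discrete time.
* Muscle controllers hand the plant the torque assembled from the
  **particular** force solution. The null component's torque is zero
  *identically* ($R' N_{T_R} = 0$), so evaluating it as exactly zero is
  the faithful discretization; numerically re-accumulating
  $-R'(f_{m\parallel} + N_{T_R}f_{m0})$ with hundreds of newtons of
  co-contraction leaves catastrophic-cancellation noise (~$10^{-14}$
  N·m) which the disturbance phase of the reflex loop amplifies by
  roughly an order of magnitude per millisecond step — enough to turn
  rounding noise into a visibly different movement. With the exact-zero
  evaluation, simulations that differ only in the null-space sample
  produce identical trajectories, which is precisely the theoretical
  claim.

### Experiment horizons

The experiment defaults state the problem sizes used throughout the
documentation and tests: reflex runs 6 s (the default gains
$k_p = k_d = 10$ give a slow return pole near $k_p/k_d = 1$ s$^{-1}$, and
the 15 N impulse swings the light wrist by ~1.5 rad, so recovery to better
than 0.01 rad needs ~5.5 s); the damping-only variant ($k_p = 0$) runs
2 s; reaching runs 2 s (the sigmoid is centered at 1 s). Feasible-set and
reaction analyses decimate the reaching movement to 6–10 time points.

## Joint reaction loads

`joint_reaction_forces()` propagates planar Newton–Euler balances from the
distal segment inward, with every muscle applied as equal-and-opposite
tensions along its path at the attachment points of its host segments (pin
joints transmit no planar constraint moment, so reactions follow from force
balance alone). Because reactions are affine in the muscle forces and the
feasible set is convex, the component-wise envelope over the vertex samples
(`joint_reaction_bounds()`) brackets the reaction of *every* feasible
realization — the minimum-norm solution included. The envelope is reported
component-wise for exactly that reason: a magnitude envelope would not
inherit the convexity guarantee at its lower edge. On a gravity-loaded
static pendulum, a co-contracted feasible sample raises the joint reaction
severalfold at identical torque — the concrete demonstration of why
ignoring null-space forces biases reaction-load estimates.

## What the synthetic models do and do not show

All validation runs on analytic planar linkages with straight-polyline
muscles, a linear (or affine Hill-hook) muscle model, no activation
dynamics, no tendon elasticity, no wrapping surfaces, and no motor noise.
Passing tests therefore demonstrate the correctness of the projection
algebra, the polytope machinery, and the controllers *on models satisfying
the theory's assumptions* — full-rank moment arms, smooth dynamics. They do
not certify behaviour on anatomical models with muscle-path discontinuities
or near rank deficiency, where the loud-failure policy (no damped
least-squares regularization anywhere) will raise errors rather than return
plausible-looking numbers. That policy is deliberate: silent regularization
would mask exactly the rank conditions the theory depends on.

Other known limitations: the task controller with $\tau_0 = 0$ leaves the
kinematically redundant degree of freedom ungoverned, so long reaching
movements can drift joints outside their nominal ranges (the feasible-set
analysis then fails loudly if a torque leaves the capacity zonotope);
vertex enumeration is exact but exponential in principle — the default
model's $r = 6$, 18-halfspace systems enumerate in tens of milliseconds,
but many-muscle models would need the randomized samplers that are
deliberately out of scope here.
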