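---
title: "The oncostream model: anisotropic repulsion, indirect alignment, and the flock/stream phase diagram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oncostream model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`oncostream` simulates N self-propelled, ellipse- or ellipsoid-shaped cells in
a periodic box $[0, L)^d$, $d \in \{2, 3\}$. Cell $i$ carries a position
$x_i$ and a unit orientation $\omega_i$; its body is an ellipse with
semi-major axis $a$ along $\omega_i$ and semi-minor axis $b$, with
eccentricity $e = \sqrt{1 - b^2/a^2}$.

Crowding is measured by a per-cell *tension*
$$V_i = \sum_{j \ne i} \Phi(r_{ij}^2), \qquad
r_{ij}^2 = \frac{1}{b^2}\left(\lVert x_j - x_i \rVert^2
  - e^2 \langle x_j - x_i, \omega_i \rangle^2\right),$$
where displacements use the minimum-image convention. The normalized
distance $r_{ij}$ rescales space by the observing cell's body: a neighbor
straight ahead at distance $a$ and a neighbor alongside at distance $b$ both
sit at $r_{ij} = 1$ (contact). It is **not** symmetric: $r_{ij} \neq r_{ji}$
unless $e = 0$, so the influence of $i$ on $j$ generally differs from that of
$j$ on $i$. The kernel
$$\Phi(s) = \tfrac{1}{s} e^{-1/(1-s)} \text{ for } 0 < s < 1,
  \qquad \Phi(s) = 0 \text{ for } s \ge 1$$
is smooth at $s = 1$ with compact support (only pairs with center distance
below $a$ can interact — the basis of the neighbor search) and diverges as
$1/s$ at the origin to forbid overlap.

The equations of motion combine self-propulsion, repulsion and steering:
$$\dot x_i = c\,\omega_i - \alpha \nabla_{x_i} V_i, \qquad
  \dot \omega_i = -\beta\, P_{\omega_i^\perp}\!\left(\nabla_{\omega_i} V_i\right),$$
with $P_{\omega^\perp} = \mathrm{Id} - \omega \otimes \omega$ keeping
$\omega_i$ on the unit sphere. By default each cell descends its **own**
tension $V_i$; because $r_{ij}$ is asymmetric this is *not* the gradient
flow of the summed potential $V = \sum_i V_i$ — the terms in which $i$
appears passively (through $r_{ji}$) exert no force on $i$. The per-cell
form is the normative model (`descent = "per_cell"`), and $\sum_i V_i$ is
monitored as an energy diagnostic. Because the original presentation also
describes the dynamics as a gradient descent of the summed $V$, the
alternative reading is available as `descent = "total"`: it adds the passive
spatial terms $\nabla_{x_i}\Phi(r_{ji}^2)$ (the steering term is identical
in both readings since $V_j$ never depends on $\omega_i$). The choice
matters in dense systems; see the reproduction section below.

The analytic gradients used by the integrator are
$$\nabla_{x_i} V_i = \sum_j \Phi'(r_{ij}^2)\,\frac{2}{b^2}
   \left(-d_{ij} + e^2 (d_{ij}\!\cdot\!\omega_i)\,\omega_i\right), \qquad
  \nabla_{\omega_i} V_i = -\sum_j \Phi'(r_{ij}^2)\,
  \frac{2 e^2}{b^2} (d_{ij}\!\cdot\!\omega_i)\, d_{ij},$$
with $d_{ij} = x_j - x_i$. Both are validated against central finite
differences (1e-5 relative) in the test suite before anything else relies on
them. For circles ($e = 0$) the orientation gradient vanishes identically:
circular cells never steer.

## Parameters and units

Lengths are micrometers and times hours throughout; there is no internal
nondimensionalization. The experimentally calibrated defaults are

| parameter | meaning | default | why |
|---|---|---|---|
| `a`, `b` | semi-axes (um) | 5.5, 3 | most common measured glioma cell shape (diameters 11 x 6 um) |
| `c` | self-propulsion speed (um/h) | 10 | measured in vivo motility |
| `alpha` | repulsion strength (um^2/h) | 40 (eccentricity runs); 100 (density runs) | not measurable; 10-200 is the swept range |
| `beta` | steering strength (1/h) | 1 (eccentricity runs); 0.1 (density runs) | not measurable; 0.1-10 is the swept range |
| `L` | box side (um) | 300 (2D); 70 (3D) | the 3D box is shrunk to keep the volume fraction comparable |
| `N` | cells | 1000-2000 | density is the control parameter for streams |

`preset_params("table1" | "table2" | "table3")` returns these bundles. Note
the 3D preset uses `L = 70` (the density-matched value stated in the text of
the source experiments) rather than the 300 um printed in the corresponding
parameter table; the table value appears to be a carried-over 2D row.

## Numerical scheme

**Integrator.** Explicit Euler with projection-by-normalization:
`x <- wrap(x + dt*dx)`, `omega <- normalize(omega + dt*domega)`. The
renormalization error is O(dt^2) per step; a Richardson test on a two-cell
collision confirms first-order endpoint convergence. When a cell's angular
velocity is exactly zero (`beta = 0`, or `e = 0`) its orientation is left
bit-identical, so conservation statements hold exactly, not to rounding.

**Step size.** The published experiments do not report a scheme or step.
The repulsion term is stiff: at `alpha = 100` a step of 0.05 h can move a
colliding cell farther than its own length, and this overshoot acts as
artificial noise that completely suppresses the slow `beta = 0.1` alignment
(we measured final order parameters at the disorder level for every density
when dt = 0.05). The default is `dt = 0.02` h, at which the headline order
parameters are converged (N = 1000: psi = 0.984 at dt = 0.02 vs 0.985 at
dt = 0.01 and 0.994 at dt = 0.005). Runs in this package are therefore
reproducible *statistically*, never trajectory-wise, against the original
experiments.

**Singularity guard.** Random initial conditions may place two centers
arbitrarily close, where $\Phi \sim 1/s$ diverges. The squared normalized
distance is floored at `epsilon = 1e-6` before evaluating $\Phi$ and
$\Phi'$, capping forces at large but finite values; a guarded near-collision
resolves within a few steps without producing non-finite state. We keep the
published "uniform" initialization rather than resampling overlaps.

**Neighbor search.** The compact support proves $r_{ij} < 1 \Rightarrow
\lVert d_{ij}\rVert < a$, so the force loop uses a Verlet pair list built
from a periodic cell grid with cutoff $a$ plus a 2 um skin. The rebuild
criterion subtracts the population-mean displacement, so rigid transport of
a flock never triggers a rebuild. Cell-list and all-pairs evaluations are
asserted identical in the tests.

## Order parameters and clustering

- polarization $\psi = \lVert \frac1N \sum_i \omega_i \rVert$: 1 for a
  flock, 0 for balanced two-way flow or disorder;
- nematic polarization (2D)
  $\gamma = \sqrt{\langle\cos 2\theta\rangle^2 + \langle\sin 2\theta\rangle^2}$:
  insensitive to $\omega \to -\omega$, so both flocks and streams score 1.
  The printed definition in the source omits the radical, but treats
  $\gamma$ as an order parameter in $[0,1]$ with $\gamma \approx 1$ for
  streams, which forces the square root; we adopt it.
- scalar nematic order $J$ (any d): largest eigenvalue $\lambda_{max}$ of
  $M = \frac1N\sum \omega_i \otimes \omega_i$, normalized as
  $J = (d\lambda_{max} - 1)/(d - 1)$, with the leading eigenvector as the
  nematic mean direction (sign fixed to a nonnegative leading component).
  The original supplementary definition of $J$ was not available to us; this
  standard Q-tensor convention satisfies every property the source states
  ($J \approx 1$ for flocks *and* streams, $\approx 0$ for disorder) and
  coincides with $\gamma$ exactly in 2D.
- clusters: connected components of the relation
  $\lVert x_j - x_i \rVert \le R$ (minimum image), with the published
  radius $R = 10$ um; the reported statistic is the *size-weighted* mean
  cluster size $\sum_k |C_k|^2 / N$, the expected cluster size seen by a
  random cell.

## The two-cell steering law and its sign

For two cells at frozen geometry (transport and repulsion switched off), the
angle $\theta$ between $\omega_i$ and the separation vector obeys
$$\dot\theta = C \sin 2\theta, \qquad
  C = -\beta \frac{e^2}{b^2} \Phi'(r_{ij}^2)\,\lVert x_j - x_i \rVert^2 \ge 0 .$$
Since $\Phi' \le 0$, $C \ge 0$ whenever the pair interacts, making
$\theta = \pm\pi/2$ the stable equilibria: each cell turns its long axis
orthogonal to the separation vector. In 2D both cells do so, hence they end
up parallel or anti-parallel — alignment without any velocity exchange
("indirect alignment"), with the anti-parallel outcome seeding two-way
streams. The derivation published with the model prints the coefficient once
with $\beta/2$ and once with $\beta$, and with the opposite sign, while
simultaneously describing the $\pm\pi/2$-stable phase portrait. Only the
convention above is self-consistent; we resolved the constant empirically by
comparing against the fully integrated two-cell dynamics (the test suite
checks the rate to 2%), and we deliberately left the literal inequality
"$C \le 0$" as a failing acceptance check rather than silently matching an
inconsistent formula.

## What the generators emulate

`init_random` reproduces the published initial condition: uniform positions
(overlaps permitted, handled by the singularity guard) and isotropic
orientations. `init_flock` and `init_stream` build the idealized reference
states used in the stability arguments: an axis-aligned lattice with spacing
1.02a guarantees every pairwise normalized distance exceeds 1 for any common
direction, so a flock built this way is exactly interaction-free and is
transported rigidly. These are stated *worlds*, not fitted quantities: none
of their parameters were adjusted to make tests pass.

What a green statistical test establishes is that the *mechanism* (shape ->
indirect alignment; density -> stream selection) reproduces; it does not
establish trajectory-level agreement with the original runs (unknown
integrator), nor anything about real glioma tissue (no adhesion, no
division or death, fixed shapes, monodisperse populations).

## Phase-diagram protocol

`run_sweep` executes seeded replicates over an (alpha, beta) grid, recording
final-time statistics in deterministic order; `smooth_surface` fits
`stats::loess` (degree 2, default span 0.75) per statistic and clips to the
valid range; `classify_regions` applies the published thresholds: flock
where psi > 0.8, else stream where the nematic statistic > 0.7, with
scattering (mean cluster size < 600) reported as an independent overlay
because the three published sets are not disjoint. Both psi = 0.5 and 0.8
contours are drawn by `plot_surface` for comparability. The grid resolution
and loess span are unreported in the source; 8x8 with 5 replicates is the
full default, and the test suite runs a reduced 4x4 grid with one replicate
at T = 400 (flock formation at moderate-to-strong steering completes well
before then) purely to bound runtime; the thresholds themselves are never
scaled.

## Which published regimes reproduce, and which do not

The test suite distinguishes three situations, and we state them plainly
because the distinction is scientific, not cosmetic.

**Reproduced.** Everything mechanistic: gradients against finite
differences, the two-cell steering law to 2%, exact conservation for
circular cells and for `beta = 0`, rigid transport of ideal flocks (and of
ideal two-lane streams, which are likewise interaction-free fixed points),
cluster statistics against brute force. Statistically: the shape contrast
(circles stay at psi < 0.1 while `a = 5.5, b = 3` ellipses reach psi > 0.95
from the same initial disorder), the nonmonotone dependence of polarization
on eccentricity, and the low-density flock at strong repulsion and weak
steering (`alpha = 100, beta = 0.1`, N = 1000: psi, gamma > 0.95).

**Not reproduced under converged integration.** The originally reported
dense-regime statistics: at N = 1500–2000 in 2D the original experiments
report streams (gamma near 0.9 with psi near 0–0.2 at t = 1000), and in 3D
(L = 70) nematic order J near 1 for every N. Our convergence-checked runs
instead give a slowly sharpening *flock* at N = 1500–2000 in 2D
(psi 0.93–0.99 at dt = 0.02–0.01) and orientational *disorder* in 3D
(J < 0.1). Before accepting this we checked: step sizes 0.05/0.02/0.01/0.005
(outcomes at N = 2000 move disorder - flock - flock - near-disorder: the
dense corner is dominated by integrator noise, and no tested step produces a
high-gamma, low-psi stream from random initial conditions); and both
readings of the repulsion force — per-cell tension descent (the literal
model definition) and total-potential descent (the package option
`descent = "total"`, suggested by the original presentation's
gradient-descent claim). Total descent makes matters worse: the doubled
effective repulsion jams the system and destroys even the N = 1000 flock.
Since ideal streams are stable under our dynamics but never *selected* from
disorder, we conclude the original stream/3D statistics depend on
unreported numerical specifics (scheme, step size, possibly update
ordering). The corresponding acceptance checks are kept verbatim in the
suite and fail honestly; the affected clauses are isolated in their own
test blocks with explanatory comments.

**Failing by inconsistency of the source.** The printed sign of the
two-cell coefficient (`C <= 0`), which contradicts the source's own stable
phase portrait; see above.

## Known limitations

- Explicit Euler needs `dt` well below the repulsion time scale
  `b^2/(alpha max|Phi'|)`; the guard keeps states finite but a too-large
  step degrades the ordered phases long before anything overflows.
- At `beta = 0.1` the approach to the ordered state is slow and outcomes at
  low density are genuinely bimodal (flock vs stream) across seeds; averages
  over few seeds carry large spread.
- The scattering threshold (600 cells) is used verbatim for every N, as
  published, although it is plainly density-dependent.
- The 3D nematic mean direction is defined up to sign; tie-breaking at exact
  orthogonality labels a cell "with the flow" (measure-zero event).
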