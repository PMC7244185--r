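# oncostream

Agent-based simulation of collective migration of elongated glioma cells.

Malignant gliomas contain elongated multicellular structures — *oncostreams*
— in which cells' axes align and traffic flows in both directions. This
package implements a minimal mechanistic model asking whether cell *shape*
alone can self-organize such patterns: N self-propelled ellipses/ellipsoids
in a periodic box, with **no** adhesion, **no** velocity exchange and **no**
division. It is aimed at computational biologists and active-matter
modellers who want to reproduce, probe or extend the flock/stream/scatter
phase behavior of this model.

## Model

Each cell has position $x_i \in [0,L)^d$ and unit orientation
$\omega_i \in S^{d-1}$ ($d = 2, 3$), with body semi-axes $a \ge b$ (major
axis along $\omega_i$, eccentricity $e = \sqrt{1-b^2/a^2}$). The crowding
tension on cell $i$ is

$$V_i = \sum_{j\neq i} \Phi(r_{ij}^2), \quad
r_{ij}^2 = \tfrac{1}{b^2}\big(\|x_j-x_i\|^2 - e^2\langle x_j-x_i,\,\omega_i\rangle^2\big), \quad
\Phi(s) = \tfrac1s e^{-1/(1-s)}\,\mathbf{1}_{s<1},$$

and the overdamped dynamics are

$$\dot x_i = c\,\omega_i - \alpha\,\nabla_{x_i} V_i, \qquad
\dot\omega_i = -\beta\,P_{\omega_i^\perp}\big(\nabla_{\omega_i} V_i\big).$$

Steering turns each cell's long axis orthogonal to the separation vector of
a near neighbor (*indirect alignment*): in 2D interacting pairs end up
parallel or anti-parallel, producing flocks (polarization $\psi \approx 1$)
or bidirectional streams (nematic order $\gamma, J \approx 1$, $\psi$ low)
depending on repulsion $\alpha$, steering $\beta$ and density $N$. Circular
cells ($e=0$) never steer and stay disordered.

Units: micrometers and hours (`c` um/h, `alpha` um^2/h, `beta` 1/h).

## Worked example

Elongated versus circular cells, started from the same uniform disorder:

```r
library(oncostream)
params <- preset_params("table1")$params   # elongated: a = 5.5, b = 3 um
sim <- sim_config(T_final = 300, record_every = 100, seed = 42)
traj <- simulate_cells(params, sim, N = 1000)
trajectory_stats(traj)[, c("time", "psi", "gamma", "mean_cluster_size")]
#>   time       psi       gamma mean_cluster_size
#> 1    0 0.0201882 0.002492394            56.382
#> 2  100 0.8455312 0.599443688           101.584
#> 3  200 0.9892785 0.957975114           344.808
#> 4  300 0.9969157 0.987726440           630.910

order_stats(final_configuration(traj), params)
#> order_stats (t = 300 h): psi = 0.997, gamma = 0.988, J = 0.988,
#>   mean cluster = 630.9, potential = 0.761

circle <- model_params(a = 4, b = 4, c = 10, alpha = 40, beta = 1, L = 300, d = 2)
order_stats(final_configuration(simulate_cells(circle, sim, 1000)), circle)
#> order_stats (t = 300 h): psi = 0.020, gamma = 0.002, J = 0.002,
#>   mean cluster = 221.9, potential = 7.34
```

The elongated population polarizes ($\psi$ 0.02 → 0.997) and condenses into
large aligned clusters, while the circular population stays disordered —
shape alone drives the ordering. `render_snapshot()` draws the
corresponding frames with cells colored by travel direction relative to the
nematic axis; `run_sweep()` / `classify_sweep()` map the flock, stream and
scattering regions over an $(\alpha, \beta)$ grid.

A command-line front end ships in `inst/exec/oncostream`
(`simulate`, `stats`, `sweep`, `render`, `demo`), e.g.

```sh
Rscript inst/exec/oncostream demo --T 300 --outdir figures/
```

## Acceptance script

`scripts/acceptance.R` re-runs the headline experiments from scratch with
the installed package — the 2D density series (N = 1500 polarization,
N = 2000 nematic polarization, N = 1000 flocking) and the 3D runs at L = 70
(nematic order across N, seed-averaged polarization at N = 1000), all at
t = 1000 h from random initial conditions — and writes the resulting order
parameters as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Expect a runtime of roughly 15–20 minutes on one core.

A note on fidelity: the mechanistic results (gradient oracles, the two-cell
steering law, the shape-driven flocking contrast, the eccentricity optimum)
reproduce robustly. The originally reported dense-regime statistics (2D
streams at N = 1500–2000 and 3D nematic ordering) turn out to be sensitive
to unreported integration details and are *not* recovered by a
convergence-checked integration of the stated equations under either
reading of the repulsion force; the methods vignette documents the
evidence, and the corresponding checks in the test suite are kept verbatim
and fail honestly.
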