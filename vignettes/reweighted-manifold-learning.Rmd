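---
title: "Reweighted manifold learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reweighted manifold learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwmanifold)
```

## The problem

Manifold-learning methods for molecular simulation data build a Markov
chain over high-dimensional samples: a kernel turns pairwise distances into
transition probabilities $p_{kl}$, and either the eigenvectors of the
transition matrix (diffusion maps) or a divergence-optimized parametric map
(stochastic neighbor embeddings) provide low-dimensional collective
variables (CVs). When the training samples come from an *enhanced-sampling*
simulation — here well-tempered metadynamics — they are drawn from a biased
distribution $P_V \propto e^{-\beta(U + V)}$ rather than the Boltzmann
distribution $P \propto e^{-\beta U}$. A transition matrix built naively
from such data describes a biased random walk: its stationary density, its
spectrum, and the embedding geometry all inherit the bias.

`rwmanifold` implements *diffusion reweighting*: a pairwise factor
$r(\mathbf{x}_k, \mathbf{x}_l)$ applied to the kernel before row
normalization,
$$
M_{kl} = \frac{r_{kl}\, G_\varepsilon(\mathbf{x}_k, \mathbf{x}_l)}
  {\sum_m r_{km}\, G_\varepsilon(\mathbf{x}_k, \mathbf{x}_m)},
\qquad
G_\varepsilon(\mathbf{x}_k, \mathbf{x}_l) =
  \exp\!\Big({-\tfrac{\|\mathbf{x}_k - \mathbf{x}_l\|^2}{2\varepsilon}}\Big),
$$
chosen so that $M$ models the *unbiased* chain although every sample was
drawn under the bias.

## Statistical weights from well-tempered metadynamics

Each sample carries a statistical weight
$w_k = e^{\beta\,(V(\mathbf{z}_k) - c)}$, where $V$ is the metadynamics
bias acting on the biased CVs $\mathbf{z}$ and $c$ is the time-dependent
normalization constant, estimated on a CV grid as
$$
c = \frac{1}{\beta}\,\ln
  \frac{\sum_{\text{grid}} e^{\beta \gamma V/(\gamma - 1)}}
       {\sum_{\text{grid}} e^{\beta V/(\gamma - 1)}} .
$$
We adopt the quasi-stationary convention: after the run, $c$ and the
weights are computed once from the **final** bias evaluated at all retained
samples. This is justified once the relative bias $V - c$ has converged,
which is why a burn-in fraction (default 20%) of each trajectory is
discarded first. A per-deposition-time $c(t)$ estimator is deliberately out
of scope for this version; for converged runs the quasi-stationary weights
are the standard choice.

## The reweighting factor

Starting from the anisotropic diffusion kernel
$A_{kl} = G_{kl} / (\rho_k^\alpha \rho_l^\alpha)$ with the *unbiased*
density $\rho$ estimated by the weighted kernel sum
$\rho(\mathbf{x}_k) = \sum_l w_l G_{kl}$, the reweighting factor at general
$\alpha$ is
$$
r_{kl} = \frac{w_l}{\rho_k^\alpha\, \rho_l^\alpha}.
$$
At $\alpha = 1/2$ — the value that asymptotically models Fokker–Planck
dynamics and is the package default — substituting
$\rho \approx w\,\rho_V$ with the biased density
$\rho_V(\mathbf{x}_k) = \sum_l G_{kl}$ gives the final working form
$$
r_{kl} = \frac{w_l}
  {\sqrt{w_k\, \rho_V(\mathbf{x}_k)\; w_l\, \rho_V(\mathbf{x}_l)}}.
$$
Every factor that depends only on the row index $k$ cancels under row
normalization, a property the test suite asserts directly. The stochastic
embedding methods use two documented approximations of this factor:
$r_{kl} = \sqrt{w_k w_l}$ (mrse; drops the biased densities) and
$r_{kl} = \sqrt{\rho_k \rho_l}$ (stke; valid when landmarks are resampled
to near-uniform coverage, as the farthest-point selection here provides).

All four modes have the separable form $r_{kl} = \phi_k \psi_l$. The
package exploits this twice. First, the transition matrix is assembled in
log space from $\log G_{kl} + \log \psi_l$ with a per-row max shift, so
weights spanning hundreds of orders of magnitude (a 50 $k_BT$ landscape at
$\gamma = 10$ produces weights spanning $e^{45}$) are handled exactly.
Second, it makes the chain reversible with the closed-form stationary
distribution $\pi_k \propto u_k \psi_k$ ($u$ = unnormalized row sums), so
the spectral decomposition can go through the symmetric conjugate
$S = D^{1/2} M D^{-1/2}$, $D = \mathrm{diag}(\pi)$: the spectrum is
guaranteed real, $\lambda_0 = 1$, and the stationary density is recovered
without a nonsymmetric eigensolve. A relative asymmetry of $S$ above
$10^{-6}$ aborts with an error, since it signals an inconsistent
reweighting factor.

On the density-carrying coordinate: for a row-stochastic matrix the right
eigenvector at $\lambda_0 = 1$ is constant, so density-vs-coordinate plots
need the *left* eigenvector at $\lambda = 1$. The API exposes it as
`left_eigenvector_0`, and `diffusion_coordinates(..., density_coordinate =
TRUE)` substitutes it for the (constant) zeroth coordinate.

## The data engine

The package generates its own study data: a single particle under
underdamped Langevin dynamics (BAOAB splitting) on analytic sums of
negative Gaussian wells, biased on the fly by well-tempered metadynamics
acting on the particle position. BAOAB was fixed because it has the exact
$T = 0$ velocity contraction $e^{-\gamma_f \Delta t}$ per step and accurate
configurational sampling at finite $\Delta t$; both limits are tested
(harmonic-well variance to within 5% at $5\times10^5$ steps). The bias is
accumulated on a 2048-point grid with linear interpolation, as grid-based
metadynamics codes do; individual hills are logged so the exact bias can be
reconstructed and written to a HILLS file. Escapes beyond the declared
domain are restrained by half-harmonic walls ($k = 1000$) and counted.

The packaged benchmark landscape `three_well_potential()` has three wells
of depths 50.29, 30 and 20 $k_BT$ at $x = -3, 0, 3$ (widths 0.4, 0.5,
0.6, domain $[-4.5, 4.5]$). The deepest-well depth was calibrated by
dense-grid extremum search so the escape barrier from the deepest minimum
is 50.00 $k_BT$: transitions out of that state are far beyond the reach of
unbiased sampling at $T = 1$, which is precisely the regime where learning
CVs requires biased data.

Default sampling conditions mirror the benchmark experiment: $T = 1$,
friction 10, $\Delta t = 0.005$, $\gamma = 10$, $5\times10^6$ steps, hills
of initial height 1.2 $k_BT$ and width 0.2 (about half the narrowest well)
deposited every 500 steps. Height and width follow the usual metadynamics
rules of thumb — height of order $k_BT$, width a fraction of the feature
to be filled; the deposition pace (2.5 time units) is slow enough that the
bias stays quasi-adiabatic. With these settings the log-density of the
sampled marginal regressed on $-\beta U$ recovers $1/\gamma$ to a few
percent, which the acceptance suite checks end to end.

What the generator does *not* emulate: atomistic force fields,
high-dimensional intrinsic geometry (test data reach higher dimension only
by Gaussian cluster fixtures and noise-lifted 1D trajectories), multiple
biased CVs, and bias-history artifacts of under-converged runs. Passing
tests therefore demonstrate correctness of the reweighting machinery under
controlled sampling, not robustness to every pathology of production
trajectories.

## Stochastic embeddings

`train_embedding()` fits a neural map $\xi_\theta: R^n \to R^d$ (two
hidden tanh layers of 64 units by default) by minimizing the row-wise
Kullback–Leibler divergence between the reweighted high-dimensional
transition matrix $P$ and a low-dimensional kernel $Q$ — a unit-bandwidth
Gaussian (stke) or a one-degree-of-freedom t-distribution (mrse, which
counteracts crowding). Choices worth knowing:

* $P$ and $Q$ have their diagonals zeroed before row normalization;
  self-transitions carry no embedding information.
* $Q$ is normalized row-wise, mirroring how the loss sums a divergence per
  row — a documented departure from classic t-SNE's matrix-global
  normalization.
* The Gaussian $Q$ has fixed unit bandwidth: the map absorbs the scale.
* mrse bandwidths default to a deterministic geometric grid between the
  5th and 75th percentile of off-diagonal distances (`select_bandwidths()`);
  the original automatic estimator is not public, so this transparent rule
  is used instead and can be overridden.
* Landmarks (default 1000) are selected by farthest-point sampling seeded
  at the highest-weight sample, giving near-uniform coverage — the regime
  assumed by stke's density approximation. Dense $K \times K$ matrices are
  used throughout; landmarking is the sanctioned route to large $K$.
* Optimization is minibatch Adam (rows of $P$, batches of 256, learning
  rate $10^{-3}$, 1000 epochs by default); every epoch visits each row
  exactly once, and a fixed seed makes the whole loss trace bit-for-bit
  reproducible. The training record stores the loss per epoch and the
  entropy floor $H(P,P)$, since $D_{KL} = H(P,Q) - H(P,P)$.

Because hyperparameter prescriptions for the original methods are not
public either, the defaults above are fixed package choices, isolated
behind `embedding_config()`.

## Numerical and degenerate-input conventions

* Kernel convention: $G = e^{-d^2/(2\varepsilon)}$, with
  $\varepsilon$ defaulting to the median off-diagonal pairwise distance.
  The $2\varepsilon$-vs-$\varepsilon$ choice is a single constant used
  consistently everywhere; eigenvalues and embeddings are insensitive to it
  up to a rescaling of $\varepsilon$.
* Densities are floored at $10^{-300}$ before exponentiation (warning).
* An isolated sample whose off-diagonal kernel row underflows entirely is
  reported by index with advice to increase $\varepsilon$.
* Eigenvectors are signed so their largest-magnitude entry is positive.
* Timescales use $t_l = -\tau/\ln\lambda_l$ with $\tau$ the sampling
  interval; $\lambda = 1$ reports $+\infty$, non-positive $\lambda$ report
  0 with a warning.
* Weights are only ever meaningful up to a constant; if
  $\beta(V - c) > 700$ the whole set is shifted with a warning rather than
  overflowing.

## Problem sizes used in the checks

The test and acceptance suites run the full benchmark at $5\times10^6$
steps (about a second in the compiled integrator), diffusion maps on
$K = 2000$ subsampled points, embedding training on 300–400 landmarks for
120–150 epochs, and oracle comparisons against naive loop implementations
at $K \le 50$. The spectral-agreement check uses a mild four-well
landscape: a three-well system has only two slow modes, so a three-way
eigenvalue comparison needs four metastable states to be meaningful.

## Known limitations

* The Langevin/metadynamics engine is one-dimensional. Everything
  downstream is dimension-agnostic; high-dimensional inputs come from
  lifted trajectories or external COLVAR files.
* In the extreme-bias regime (barriers of tens of $k_BT$ biased at high
  $\gamma$, weights spanning $e^{40}$ and more) the 1D mrse/stke
  embeddings do not resolve the metastable states: the reweighted chain is
  kinetically dominated by the deepest state at any kernel scale, and the
  divergence objective follows it. The diffusion-map route handles this
  regime well (it is exercised at 50 $k_BT$, $\gamma = 10$ in the
  acceptance suite); the embedding methods are exercised in the moderate
  regime they were designed for (weight ranges up to about $e^{10}$).
* No Nyström out-of-sample extension for diffusion maps (the parametric
  embeddings cover out-of-sample mapping), no sparse kernels, no
  variable-bandwidth kernels, and no iterative learn-then-bias loop.

## A compact example

```{r example, eval = FALSE}
pot <- three_well_potential()
cfg <- langevin_config(n_steps = 5e6, stride = 10, seed = 1)
ds <- run_biased_simulation(pot, cfg, metad_config())

sub <- subset_dataset(ds, sort(sample.int(n_samples(ds), 2000)))
model <- build_markov_model(sub, kernel_spec(reweighting = "diffusion"))
emb <- spectral_decomposition(model, m = 8)
emb$eigenvalues
plot(sub$samples[, 1], emb$left_eigenvector_0,
     xlab = "x", ylab = "stationary density")
```
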