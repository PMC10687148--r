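---
title: "Number fluctuations, compressibility and hydrogen-bond networks in molecular liquids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Number fluctuations, compressibility and hydrogen-bond networks in molecular liquids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctnet)
```

## The problem

A liquid's isothermal compressibility $\kappa_T$ — its relative volume
response to pressure at constant temperature — is encoded in its density
fluctuations. In a monohydroxy alcohol cooled toward the supercooled regime,
hydrogen-bonded chains and clusters of molecules form, long-wavelength
density fluctuations grow, and $\kappa_T$ can turn from the normal
(decreasing on cooling) to an anomalous (increasing) branch. Detecting that
behaviour from particle simulations requires estimators that control
finite-size effects carefully, because the emerging structures are
nanometric while the simulation box is only an order of magnitude larger.

`fluctnet` implements the full estimator chain on particle trajectories with
cubic periodic boxes, plus synthetic-trajectory generators with recorded
ground truth, so every stage can be validated without any molecular-dynamics
input. Molecule positions are always represented by the hydroxyl oxygen
site; all internal units are nm, ps, K and bar, and the only physical
constant is $k_B = 1.380649 \times 10^{-23}$ J/K (`fluct_constants`).

## Estimators

### Structure factor and the $k \to 0$ limit

The static structure factor is evaluated directly on the reciprocal lattice
of the box,
$$S(\mathbf k) = \Big\langle \tfrac{1}{N}\big|\textstyle\sum_j
e^{-i \mathbf k\cdot \mathbf r_j}\big|^2 \Big\rangle, \qquad
\mathbf k = \frac{2\pi}{L}(n_x, n_y, n_z),$$
over all nonzero integer triples with $\max|n| \le n_\mathrm{max}$
(default 70), deduplicated by the $\mathbf k \to -\mathbf k$ symmetry. The
squared-modulus single sum is algebraically identical to the double sum over
particle pairs; the tests hold the implementation to the double sum at
$10^{-10}$ relative on small systems. Shells are grouped by the *exact
integer norm* $n_x^2+n_y^2+n_z^2$ rather than by floating-point $|k|$: the
low-$k$ behaviour lives in the first few shells and must not be smeared, and
integer indexing keeps shells well defined when the box edge fluctuates
across frames (the reported $|k|$ then uses the mean box edge).

A Fourier-transform route from the radial distribution function,
$S(k) = 1 + 4\pi\rho \int_0^{r_\mathrm{max}} dr\, r^2
\frac{\sin kr}{kr}\,(g(r)-1)$, is provided for cross-checking only; it is
truncation-sensitive for $k < 2\pi/r_\mathrm{max}$ and the $k \to 0$
extrapolation always uses the direct route. For a homogeneous liquid
$\lim_{k\to 0} S(k) = \rho k_B T \kappa_T$, evaluated in practice at
$k_\mathrm{min} = 2\pi/L$ (0.48 nm$^{-1}$ for a 13 nm box, 1.26 nm$^{-1}$
for a 5 nm box).

### Spatial block analysis

Inside a closed box of volume $V_0$, the variance-to-mean ratio of molecule
counts in subvolumes $V$,
$\chi_T(\lambda) = \Delta^2(N)/\langle N\rangle$ with
$\lambda = (V/V_0)^{1/3}$, is depressed below its bulk value both by the
total-number constraint and by a surface term. The finite-size model
$$\lambda\,\chi_T(\lambda) = \chi_T^{\infty}\,(1-\lambda^3)\,\lambda +
\frac{\rho\,\alpha}{V_0^{1/3}}$$
lets the bulk value $\chi_T^{\infty} = \rho k_B T \kappa_T$ be read off as a
slope. `sba_fit()` regresses $y = \lambda\chi$ on the model's exact
regressor $x = \lambda(1-\lambda^3)$ — identical to regressing on $\lambda$
in the small-$\lambda$ limit where $\lambda^3 \approx 0$, but free of the
$O(\lambda^3)$ slope bias at the upper end of the fit window. For the
binomial gas, where $\chi(\lambda) = 1-\lambda^3$ holds exactly at *every*
$\lambda$, the model with $\chi^\infty = 1,\ \alpha = 0$ is then exact over
the full range, which the suite uses as its strongest end-to-end test.

Sampling choices:

* **Subvolume placement** is uniform random with periodic wrapping
  (unbiased under periodic boundary conditions); a deterministic cubic-grid
  option exists for tests. A single integer seed makes the curve
  bit-reproducible.
* **$\lambda$ grid**: 24 points uniform on $[0.05, 1]$ by default. Analyses
  that extrapolate (the acceptance protocol, `analysis/` scripts) refine the
  grid to steps of 0.0125 inside the fit window: the slope estimate is
  frame-noise-limited, and resolving the window is the one sampling axis
  that still helps once placements saturate (about 128 per frame).
* **Fit window** $[0.05, 0.30]$, where $\lambda^3 \le 0.027$. Points with
  mean occupancy $\langle N\rangle < 5$ are excluded from the fit (counting
  noise dominates) with a message, never silently.
* **Errors** by block averaging over frames, 10 blocks by default.
* A negative fitted slope is physically meaningless and returns a *flagged*
  result with a warning rather than an error, so a temperature sweep can
  record and continue.

### Volume fluctuations

For constant-pressure input the package also implements
$\kappa_T = (\langle V_0^2\rangle - \langle V_0\rangle^2)/(k_B T \langle
V_0\rangle)$ with a block-averaged standard error. A constant series gives
exactly zero — a valid result, not an error. This estimator converges slowly
on small boxes at low temperature; the package only asserts its agreement
with the other routes on homogeneous synthetic data, where all three
estimates of the reduced fluctuation level ($S(k_\mathrm{min})$, SBA
$\chi^\infty$, planted variance) coincide within combined errors.

## Hydrogen-bond network analysis

A donation $i \to j$ is a hydrogen bond when the donor–acceptor O$\cdots$O
minimum-image distance is $\le$ 0.35 nm **and** the H–donor–acceptor angle is
$\le$ 30°. Both cutoffs are inclusive. The angle vertex sits at the *donor
oxygen*, between the O$\to$H and O$\to$acceptor vectors; the reverse
convention (vertex at the hydrogen) accepts different geometries and would
change every downstream number, so the choice is stated prominently here and
in `detect_hbonds()`.

Two bookkeeping conventions coexist deliberately:

* The undirected graph binarises mutual double donations into a single edge
  ($A_{ij}$ is an indicator), which is what degrees, clusters and modularity
  consume.
* $n_H$ counts *donation events* per molecule. For single-hydroxyl molecules
  each molecule donates at most once, so $n_H \le 1$, with $n_H \to 1$ the
  saturation limit of a fully chained liquid. Counting bond endpoints
  incident on oxygens and dividing by $2N$ yields the same number; the tests
  verify the two routes coincide on planted networks.

Clusters are the connected components (union-find, labels deterministic by
smallest member index); no community-detection optimiser is involved — the
clusters *are* the communities, and the modularity
$$Q = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \frac{k_i k_j}{2m}\Big]
\delta_{c_i c_j}$$
of that partition (evaluated over all ordered pairs including the diagonal)
measures how sharply bounded they are: $Q \approx 0$ for homogeneous random
structure, $0.3 < Q \le 1$ for strong community structure
(`modularity_regime()`). The implementation uses per-community sums; a
literal double-sum evaluation (`modularity_naive()`) serves as the
brute-force reference, and igraph as an independent cross-check in the test
suite. The mean degree restricted to molecules in clusters of size $\ge 2$
is reported separately because isolated molecules would otherwise dilute it;
whether to include them is a genuine convention choice, and this package
excludes them.

Analysis is strictly intra-frame: no bond lifetime or continuity tracking
across frames.

## Synthetic data and what it does (not) show

Every generator is a pure function of its parameters and seed, and stores
its ground truth next to the data so downstream tests never recompute
oracles.

* **Binomial gas** — i.i.d. uniform points; the analytic oracle for both
  fluctuation routes ($S(k) = 1$, $\chi = 1-\lambda^3$, $\chi^\infty = 1$).
* **Clustered fluid** — emulates nanometric density domains: cluster centers
  are re-placed uniformly every frame; per-center Poisson occupancies are
  drawn *once* and held fixed, so the total $N$ is constant across frames
  (a closed box) while the per-center statistics stay Poisson. The bulk
  fluctuation level is then $\sum k_i^2 / \sum k_i$ over the quenched
  occupancies ($\approx 1 + \mu$). Because a finite counting window of edge
  $w$ loses the exact fraction $1-(1-a/w)^3$ of same-cluster pair covariance
  ($a = 2\sigma/\sqrt{\pi}$, the mean component separation of a Gaussian
  pair), the stored ground truth is measured by an *open-window oracle*:
  unwrapped realisations of the same process, counted in windows of several
  sizes, each excess Fano factor divided by its exact surface factor, and
  precision-weight averaged. This is the open-system counterpart of the
  surface extrapolation the block analysis itself performs.
* **Toy alcohol** — straight planted donor chains with bonds at 0.30 nm / 0°
  by default (comfortably inside the 0.35 nm / 30° criterion) and every
  non-bonded O pair at $\ge$ 0.4 nm or $\ge$ 45°, so detection must recover
  the planted set exactly; boundary fixtures at 0.349/0.351 nm probe the
  inclusive cutoff. Exact cutoff values (0.35) are not representable in
  binary floating point, which is why the margins exist.
* **Volume series** — Gaussian i.i.d. volumes with planted
  $\kappa_T = \sigma_V^2/(k_B T \bar V)$.
* **Planted-partition graphs** — stochastic block model with the planted
  partition's modularity stored via the brute-force sum.

What passing on these fixtures does *not* show: real alcohols have molecular
structure (alkyl tails, excluded volume, force-field energetics), correlated
frames, bond-lifetime dynamics, and cluster geometries far richer than
straight chains or Gaussian blobs. The fixtures validate the *estimators* —
normalisation, finite-size extrapolation, counting conventions, graph
bookkeeping — not any statement about propan-1-ol itself.

## Numerical and design choices

* Coordinates are stored unwrapped as read; each consumer wraps on demand
  (H-bond geometry and subvolume counting need different conventions).
  Minimum-image components live in $[-L/2, L/2)$; wrapped coordinates in
  $[0, L)$.
* Only cubic boxes are supported; non-cubic input raises an explicit
  unsupported-feature error rather than a wrong answer.
* $g(r)$ bins are half-open $[r, r+\Delta r)$ and require
  $r_\mathrm{max} \le L/2$.
* At $\lambda = 1$ the subvolume is the box and $\chi = 0$ is returned
  exactly, bypassing floating-point wrap comparisons.
* GRO I/O is fixed-column with the format's 0.001 nm precision; extended
  XYZ carries the box in a `Lattice="..."` comment and round-trips at full
  double precision. Hydroxyl topology is inferred from `OH`/`HO` (or
  `O`/`H`) atom names — grouped by residue in GRO, paired in file order in
  XYZ — and anything ambiguous requires an explicit side-car site map,
  because atom naming is force-field dependent.
* The temperature-series driver derives one placement seed per temperature
  from the config seed, records every effective parameter in its log, and
  records per-temperature failures in the summary instead of aborting the
  sweep.

## Problem sizes

The validation protocol uses $N = 5000$ particles over 100 independent
frames for the ideal-gas closure, a clustered fluid of $\approx 1600$
particles (400 centers, $\mu = 4$, $\sigma = 0.15$ nm, $L = 10$ nm) over 100
frames for parameter recovery, $10^5$ samples for the volume-fluctuation
estimator, and graphs of up to 100 nodes for the exact oracle equivalences.
The `analysis/` scripts run a five-temperature cooling series at the same
scale. These sizes were chosen so each statistical acceptance band sits at
3–5 standard errors of the corresponding estimator.

## Known limitations

* The SBA slope estimator is frame-noise-limited: at $N = 5000$, 100
  frames, its seed-to-seed spread is about 0.03 on $\chi^\infty = 1$, so a
  $\pm 0.05$ recovery band is a 1.7-sigma statement and an occasional
  excursion is expected statistics, not a defect.
* The surface constant $\alpha$ is treated purely as a fitted intercept; no
  physical interpretation is attached.
* $S(k)$ at $n_\mathrm{max} = 70$ on large systems is expensive in pure R
  (the per-frame cost scales as $n_\mathrm{max}^2 N$ matrix work);
  analyses here use $n_\mathrm{max} \le 8$, which already resolves the
  low-$k$ region of interest for the box sizes involved.
* Reproducing the volume-fluctuation estimator's known low-temperature
  failure on small boxes would require genuinely supercooled trajectories
  and is out of scope; only the estimator itself is implemented.
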