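# fluctnet

Isothermal compressibility from number fluctuations, and hydrogen-bond
network statistics, for molecular-liquid trajectories with cubic periodic
boxes.

Cooling a monohydroxy alcohol builds hydrogen-bonded chains and clusters;
long-wavelength density fluctuations grow with them, and the isothermal
compressibility κ_T can cross from normal (decreasing on cooling) to
anomalous (increasing) behaviour. Measuring that from particle simulations
needs estimators with explicit finite-size control. `fluctnet` is for
simulators and method developers who want that estimator chain as tested,
reusable R functions:

* **Pair structure** — oxygen–oxygen g(r); static structure factor on the
  reciprocal lattice, S(k) = ⟨|Σ_j e^(−i k·r_j)|²/N⟩ with
  k = 2π(n_x,n_y,n_z)/L (plus a g(r)-transform cross-check route); and the
  long-wavelength limit lim_{k→0} S(k) = ρ k_B T κ_T evaluated at
  k_min = 2π/L.
* **Spatial block analysis (SBA)** — subvolume number fluctuations
  χ_T(λ) = Δ²(N)/⟨N⟩ at block ratio λ = (V/V₀)^{1/3}, extrapolated to the
  bulk with the finite-size model
  λχ_T(λ) = χ_T^∞(1−λ³)λ + ρα/V₀^{1/3}, so the fitted slope gives
  χ_T^∞ = ρ k_B T κ_T; plus the NPT estimator
  κ_T = (⟨V₀²⟩−⟨V₀⟩²)/(k_B T⟨V₀⟩) for comparison.
* **Hydrogen-bond networks** — geometric detection (O···O ≤ 0.35 nm,
  H–donor–acceptor angle ≤ 30° at the donor oxygen), the bond graph,
  connected-component clusters, bonds per molecule n_H = ⟨N_H⟩/N, cluster
  size statistics, and the modularity
  Q = (1/2m) Σ_ij [A_ij − k_i k_j/2m] δ(c_i,c_j) of the cluster partition.
* **Synthetic data** — binomial gas, clustered fluid with a planted
  open-window Fano factor, toy-alcohol chains with planted bond sets,
  Gaussian volume series, planted-partition graphs; each generator records
  its ground truth so every estimator is testable with no simulation input.
* **Trajectory I/O and pipeline** — native GRO and extended-XYZ readers and
  writers (cubic boxes), hydroxyl topology inference with a side-car site
  map, and a temperature-series driver producing one summary row per
  temperature.

## Worked example

```r
library(fluctnet)

# an ideal (binomial) gas: the analytic reference where chi_inf = 1 exactly
gas <- gen_binomial_gas(N = 2000, L = 10, n_frames = 50, seed = 42,
                        temperature = 300)

fc  <- subvolume_fluctuations(gas$trajectory, placements = 64, seed = 43)
fit <- sba_fit(fc, temperature = 300)
print(fit)
#> SBA fit on lambda in [0.05, 0.3] (4 points)
#>   chi_inf = 0.998433 +- 0.01   alpha = -0.003284 nm   R^2 = 0.9998
#>   kappa_T = 1.205e-07 Pa^-1 (0.01205 bar^-1) at T = 300 K

sk <- structure_factor_direct(gas$trajectory, n_max = 5)
sprintf("S(k_min = %.3f nm^-1) = %.3f +- %.3f",
        attr(sk, "k_min"), sk$S[1], sk$stderr[1])
#> "S(k_min = 0.628 nm^-1) = 1.002 +- 0.080"
kappa_from_sk(sk$S[1], rho = 2, temperature = 300)$kappa_bar
#> [1] 0.01209315

# planted hydrogen-bond chains: 4 + 10 + 10 molecules plus one isolated
ta  <- gen_toy_alcohol(chain_lengths = c(4, 10, 10, 1), L = 12)
rpt <- analyze_hbond_network(ta$trajectory)
sprintf("n_H = %.2f, mean largest cluster = %d, Q = %.3f (%s)",
        rpt$n_H, rpt$clusters$mean_largest, rpt$Q, rpt$regime)
#> "n_H = 0.84, mean largest cluster = 10, Q = 0.612 (community)"
```

The two compressibility routes agree (χ_inf ≈ S(k_min) ≈ 1, both κ_T within
one standard error of the ideal-gas value 1/(ρ k_B T) = 0.0121 bar⁻¹ at
ρ = 2 nm⁻³), and the planted bond set is recovered exactly: 21 donations
over 25 molecules give n_H = 0.84, the largest chains have 10
molecules, and the cluster partition is strongly modular.

## Analysis workflow

`analysis/` holds the numbered drivers for the synthetic cooling study
(300 K → 200 K, clustering and chain length increasing as temperature
drops); each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # synthetic trajectories + ground truth
Rscript analysis/02_compressibility.R     # S(k_min) and SBA kappa_T per T
Rscript analysis/03_hbond_network.R       # n_H, cluster sizes, modularity per T
Rscript analysis/04_run_pipeline.R        # end-to-end pipeline + summary table
```

On this series κ_T rises from 0.019 to 0.109 bar⁻¹ on cooling while the two
routes stay within ~1 combined standard error of each other, and n_H climbs
from 0.50 toward its saturation bound 1.

## Documentation

The methods vignette (`vignettes/fluctuation-network-methods.Rmd`) documents
the estimators and their assumptions, every tunable parameter with its
default and rationale, the synthetic generators and what passing on them
does and does not demonstrate, and the numerical conventions (shell binning,
wrapping, inclusive cutoffs, degenerate inputs).
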