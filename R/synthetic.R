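# Synthetic trajectory generators with recorded ground truth. Each generator
# is a pure function of its parameters and seed, and stores alongside the
# data everything downstream tests compare against (planted fluctuation
# levels, bond lists, partitions, modularity), so oracles run once, at
# generation time.

new_synthetic_spec <- function(generator, params, truth) {
  structure(list(generator = generator, params = params, truth = truth),
            class = "synthetic_spec")
}

#' Serialise / load a synthetic-data spec
#'
#' @param spec A `synthetic_spec`.
#' @param path JSON file path.
#' @return `write_synthetic_spec` returns `path` invisibly;
#'   `read_synthetic_spec` the spec.
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_synthetic_spec(x$generator, x$params, x$truth)
}

#' Binomial (ideal) gas trajectory
#'
#' N points i.i.d. uniform in the cubic box, frames independent. The exact
#' closed-box law is chi(lambda) = 1 - lambda^3 at every lambda (binomial
#' subvolume counts), S(k) = 1 at every k, and the bulk fluctuation level is
#' chi_inf = 1 with zero surface term — the analytic oracle for the
#' structure-factor and block-analysis estimators.
#'
#' @param N Particles per frame (>= 2).
#' @param L Box edge, nm.
#' @param n_frames Number of independent frames.
#' @param seed Integer seed (same seed, same trajectory, bit for bit).
#' @param temperature Metadata temperature in K.
#' @return List with `trajectory` and `spec` (ground truth: `chi_inf = 1`,
#'   `alpha = 0`, `S_k = 1`).
#' @export
gen_binomial_gas <- function(N, L, n_frames, seed, temperature = 300) {
  if (N < 2) stop("N must be >= 2")
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(fi)
      frame(matrix(stats::runif(3 * N, 0, L), ncol = 3), L, time = fi - 1))
  })
  traj <- trajectory(frames, temperature = temperature, pressure = 1)
  spec <- new_synthetic_spec(
    "binomial_gas",
    list(N = N, L = L, n_frames = n_frames, seed = seed,
         temperature = temperature),
    list(chi_inf = 1, alpha = 0, S_k = 1, rho = N / L^3)
  )
  list(trajectory = traj, spec = spec)
}

#' Clustered fluid with a planted asymptotic Fano factor
#'
#' Emulates a liquid developing nanometric density domains, which raise the
#' k -> 0 structure factor and the bulk fluctuation level above the ideal-gas
#' value. Per-center occupancies are drawn once, Poisson(`mean_per_center`),
#' and then held fixed (quenched) so every frame carries the same total
#' particle number N; each frame places the `n_centers` cluster centers
#' uniformly at random and scatters each center's particles with an isotropic
#' Gaussian of width `cluster_radius`, wrapped into the box. For counting
#' windows much larger than the cluster radius the Fano factor of open-window
#' counts approaches sum(k^2)/sum(k) over the quenched occupancies
#' (~ 1 + mean_per_center for Poisson draws), but the finite cluster radius
#' shifts the plateau; the ground truth stored in the spec is therefore
#' measured by an open-window counting oracle over independent unwrapped
#' realisations (window edge `oracle_window`, one count per realisation),
#' not taken from the asymptote.
#'
#' @param n_centers Cluster centers per frame.
#' @param mean_per_center Poisson mean occupancy per center.
#' @param cluster_radius Gaussian displacement sigma, nm (must be << L).
#' @param L Box edge, nm.
#' @param n_frames Frames.
#' @param seed Integer seed.
#' @param temperature Metadata temperature in K.
#' @param oracle_realisations Independent realisations per oracle window.
#' @param oracle_windows Open counting-window edges in nm for the oracle's
#'   infinite-window extrapolation; default `L * c(0.1, 0.15, 0.2, 0.3, 0.4)`.
#'   A window of edge w keeps only the fraction (1 - a/w)^3 of same-cluster
#'   pair covariance, with a = 2 * cluster_radius / sqrt(pi) the mean
#'   component separation of a Gaussian pair; the oracle divides each
#'   window's excess Fano by that exact surface factor and reports the
#'   precision-weighted mean — the open-system counterpart of the surface
#'   extrapolation the block analysis performs.
#' @return List with `trajectory` and `spec` (truth: `fano` — the
#'   extrapolated open-window oracle value — plus `fano_se`, the per-window
#'   oracle table `fano_by_window`, the quenched
#'   `fano_quenched = sum(k^2)/sum(k)` and the naive asymptote
#'   `fano_asymptote = 1 + mean_per_center`).
#' @export
gen_clustered_fluid <- function(n_centers, mean_per_center, cluster_radius,
                                L, n_frames, seed, temperature = 300,
                                oracle_realisations = 1500,
                                oracle_windows = NULL) {
  if (cluster_radius >= L / 10)
    stop("cluster_radius must be well below L (cluster_radius << L)")
  if (is.null(oracle_windows)) oracle_windows <- L * c(0.1, 0.15, 0.2, 0.3, 0.4)
  out <- with_seed(seed, {
    counts <- stats::rpois(n_centers, mean_per_center)
    while (sum(counts) < 2)
      counts <- stats::rpois(n_centers, mean_per_center)
    idx <- rep.int(seq_len(n_centers), counts)
    frames <- lapply(seq_len(n_frames), function(fi) {
      centers <- matrix(stats::runif(3 * n_centers, 0, L), ncol = 3)
      p <- centers[idx, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(idx), 0, cluster_radius), ncol = 3)
      frame(wrap_positions(p, L), L, time = fi - 1)
    })
    fano <- clustered_fano_oracle(counts, n_centers / L^3, cluster_radius,
                                  oracle_windows, oracle_realisations)
    list(frames = frames, fano = fano, counts = counts)
  })
  traj <- trajectory(out$frames, temperature = temperature, pressure = 1)
  spec <- new_synthetic_spec(
    "clustered_fluid",
    list(n_centers = n_centers, mean_per_center = mean_per_center,
         cluster_radius = cluster_radius, L = L, n_frames = n_frames,
         seed = seed, temperature = temperature,
         oracle_windows = oracle_windows,
         oracle_realisations = oracle_realisations),
    list(fano = out$fano$fano, fano_se = out$fano$se,
         fano_by_window = out$fano$by_window,
         fano_quenched = sum(out$counts^2) / sum(out$counts),
         fano_asymptote = 1 + mean_per_center,
         N = sum(out$counts))
  )
  list(trajectory = traj, spec = spec)
}

# Open-window Fano oracle: independent unwrapped realisations of the cluster
# process (center number Poisson at the box's center density, occupancies
# resampled from the quenched count vector), one window count per
# realisation. Only centers within 6 sigma of a window can contribute, so
# generation is restricted to that slab, exact up to the neglected Gaussian
# tail. A window of edge w retains the exact fraction (1 - a/w)^3 of
# same-cluster pair covariance (a = 2 sigma / sqrt(pi), valid for w >> sigma),
# so each window's excess Fano is divided by that factor and the asymptote is
# the precision-weighted mean over windows.
clustered_fano_oracle <- function(quenched_counts, center_density, sigma,
                                  windows, R) {
  margin <- 6 * sigma
  one_window <- function(w) {
    lam <- center_density * (w + 2 * margin)^3
    counts <- vapply(seq_len(R), function(r) {
      n_slab <- stats::rpois(1, lam)
      if (n_slab == 0) return(0L)
      centers <- matrix(stats::runif(3 * n_slab, -margin, w + margin),
                        ncol = 3)
      k <- sample(quenched_counts, n_slab, replace = TRUE)
      idx <- rep.int(seq_len(n_slab), k)
      if (length(idx) == 0) return(0L)
      pos <- centers[idx, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(idx), 0, sigma), ncol = 3)
      sum(pos[, 1] >= 0 & pos[, 1] < w &
          pos[, 2] >= 0 & pos[, 2] < w &
          pos[, 3] >= 0 & pos[, 3] < w)
    }, integer(1))
    c(fano = stats::var(counts) / mean(counts),
      se = stats::var(counts) / mean(counts) * sqrt(2 / (R - 1)))
  }
  tab <- t(vapply(windows, one_window, numeric(2)))
  by_window <- data.frame(w = windows, fano = tab[, 1], se = tab[, 2])
  surface <- (1 - (2 * sigma / sqrt(pi)) / windows)^3
  A <- (by_window$fano - 1) / surface
  wt <- surface^2 / by_window$se^2
  list(fano = 1 + sum(wt * A) / sum(wt),
       se = sqrt(1 / sum(wt)),
       by_window = by_window)
}

#' Toy-alcohol frame with planted hydrogen-bond chains
#'
#' Places single-hydroxyl molecules (O-H site pairs) as straight chains in
#' which molecule i donates to molecule i+1: the O...O distance is
#' `bond_distance` and the H-donor-acceptor angle is `bond_angle`, both kept
#' inside the detection criterion with margin by default (<= 0.32 nm,
#' <= 15 degrees); all non-planted O pairs are at least 0.4 nm apart and the
#' chain-end hydrogens point away from every acceptor. The generator rejects
#' geometries that do not fit in the box with those margins. Ground truth
#' (directed bond list, component partition, brute-force modularity of that
#' partition) is stored in the spec; bonds whose planted geometry violates
#' the default 0.35 nm / 30 degree criterion (boundary studies) are planted
#' but excluded from the expected bond list.
#'
#' @param chain_lengths Integer vector: molecules per chain (1 = isolated).
#' @param L Box edge, nm.
#' @param seed Integer seed (chains are deterministic; the seed only sets
#'   frame metadata and is kept for interface uniformity).
#' @param bond_distance Planted donor-acceptor O...O distance, nm.
#' @param bond_angle Planted H-donor-acceptor angle, degrees.
#' @param oh_length O-H bond length, nm (0.098, hydroxyl).
#' @return List with `trajectory` (1 frame, hydroxyl topology) and `spec`
#'   (truth: `bonds` data.frame, `partition`, `Q`, `n_H`).
#' @export
gen_toy_alcohol <- function(chain_lengths, L, seed = 1, bond_distance = 0.30,
                            bond_angle = 0, oh_length = 0.098) {
  n_mol <- sum(chain_lengths)
  spacing_y <- 0.8
  n_chains <- length(chain_lengths)
  max_len <- (max(chain_lengths) - 1) * bond_distance
  if (max_len > L - 0.6 || n_chains * spacing_y > L - 0.4)
    stop("generation error: requested chains do not fit in the box ",
         "with non-bond margins")
  pos <- matrix(0, 2 * n_mol, 3)
  donor <- integer(0); acceptor <- integer(0)
  theta <- bond_angle * pi / 180
  mol <- 0L
  for (ci in seq_len(n_chains)) {
    y <- 0.3 + (ci - 1) * spacing_y
    len <- chain_lengths[ci]
    for (k in seq_len(len)) {
      mol <- mol + 1L
      O <- c(0.3 + (k - 1) * bond_distance, y, L / 2)
      # donor H: rotated by bond_angle off the O -> next-O (+x) axis, in the
      # xz-plane; chain ends point along +x (180 degrees from the previous O)
      u <- c(cos(theta), 0, sin(theta))
      pos[2 * mol - 1, ] <- O
      pos[2 * mol, ] <- O + oh_length * u
      if (k < len) {
        donor <- c(donor, mol)
        acceptor <- c(acceptor, mol + 1L)
      }
    }
  }
  topo <- topology(seq(1, 2 * n_mol, by = 2), seq(2, 2 * n_mol, by = 2))
  frm <- frame(pos, L, time = 0)
  traj <- trajectory(list(frm), topology = topo, temperature = NA_real_,
                     pressure = NA_real_)
  planted <- data.frame(donor = donor, acceptor = acceptor,
                        distance = rep(bond_distance, length(donor)),
                        angle = rep(bond_angle, length(donor)))
  expected <- planted[planted$distance <= 0.35 & planted$angle <= 30, ,
                      drop = FALSE]
  g <- build_graph(expected, n_mol)
  part <- find_clusters(g)
  Q <- if (g$m >= 1) modularity_naive(as_adjacency(g), part) else NA_real_
  spec <- new_synthetic_spec(
    "toy_alcohol",
    list(chain_lengths = chain_lengths, L = L, seed = seed,
         bond_distance = bond_distance, bond_angle = bond_angle,
         oh_length = oh_length),
    list(bonds = expected, partition = part, Q = Q,
         n_H = nrow(expected) / n_mol, n_molecules = n_mol)
  )
  list(trajectory = traj, spec = spec)
}

#' Gaussian NPT-like volume time series with planted compressibility
#'
#' @param mean_V Mean box volume, nm^3.
#' @param variance Volume variance, nm^6 (>= 0).
#' @param n_samples Series length.
#' @param seed Integer seed.
#' @param temperature Temperature in K at which the planted kappa_T holds.
#' @return List with `volumes` (nm^3) and `spec` (truth: `kappa_Pa`).
#' @export
gen_volume_series <- function(mean_V, variance, n_samples, seed,
                              temperature = 300) {
  if (variance < 0) stop("variance must be >= 0")
  volumes <- with_seed(seed,
    stats::rnorm(n_samples, mean_V, sqrt(variance)))
  kappa <- variance / mean_V * fluct_constants$nm3_to_m3 /
    (fluct_constants$kB * temperature)
  spec <- new_synthetic_spec(
    "volume_series",
    list(mean_V = mean_V, variance = variance, n_samples = n_samples,
         seed = seed, temperature = temperature),
    list(kappa_Pa = kappa)
  )
  list(volumes = volumes, spec = spec)
}

#' Planted-partition random graph
#'
#' Standard stochastic block model: vertices split into communities of the
#' given sizes; within-community pairs are connected with probability `p_in`,
#' across with `p_out`. The modularity of the planted partition, evaluated by
#' the brute-force double sum, is stored as ground truth.
#'
#' @param sizes Integer vector of community sizes.
#' @param p_in,p_out Edge probabilities in [0, 1].
#' @param seed Integer seed.
#' @return List with `graph` (an `hbond_graph`), `partition` (planted
#'   labels) and `spec` (truth: `Q`).
#' @export
gen_planted_partition_graph <- function(sizes, p_in, p_out, seed) {
  if (any(c(p_in, p_out) < 0 | c(p_in, p_out) > 1))
    stop("p_in and p_out must be probabilities in [0, 1]")
  n <- sum(sizes)
  labels <- rep.int(seq_along(sizes), sizes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  edges <- with_seed(seed, {
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(nrow(pairs)) < p
    pairs[keep, , drop = FALSE]
  })
  bonds <- data.frame(donor = edges[, 1], acceptor = edges[, 2])
  g <- build_graph(bonds, n)
  Q <- if (g$m >= 1) modularity_naive(as_adjacency(g), labels) else NA_real_
  spec <- new_synthetic_spec(
    "planted_partition_graph",
    list(sizes = sizes, p_in = p_in, p_out = p_out, seed = seed),
    list(Q = Q, m = g$m)
  )
  list(graph = g, partition = labels, spec = spec)
}

#' Brute-force modularity by the literal double sum
#'
#' Reference evaluation of Q = (1/2m) sum_ij [A_ij - k_i k_j / 2m]
#' delta(c_i, c_j) over all ordered vertex pairs, including the diagonal.
#' Used as the independent oracle for [modularity_q()] and by the
#' synthetic-graph generators when recording ground truth.
#'
#' @param A Symmetric 0/1 adjacency matrix with zero diagonal.
#' @param partition Community labels, length nrow(A).
#' @return Q.
#' @export
modularity_naive <- function(A, partition) {
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m < 1) stop("modularity is undefined for an edgeless graph (m = 0)")
  same <- outer(partition, partition, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}
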