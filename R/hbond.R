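#' Geometric hydrogen-bond detection
#'
#' A directed donation i -> j is recorded when the donor-acceptor
#' oxygen-oxygen minimum-image distance is at most `d_max` and the angle at
#' the donor oxygen between the O->H and O->acceptor vectors (the
#' H-donor-acceptor angle) is at most `theta_max`. Both directions of every
#' pair are tested independently; both cutoffs are inclusive (<=).
#'
#' The angle vertex sits at the DONOR oxygen. The reverse convention (vertex
#' at the hydrogen) accepts different geometries and changes results.
#'
#' @param frm A [frame()].
#' @param topo A [topology()] mapping molecules to hydroxyl O/H sites.
#' @param d_max Donor-acceptor O...O cutoff in nm (default 0.35).
#' @param theta_max H-donor-acceptor angle cutoff in degrees (default 30).
#' @return An `hbond_list` data.frame with columns `donor`, `acceptor`
#'   (molecule indices), `distance` (nm), `angle` (degrees).
#' @export
detect_hbonds <- function(frm, topo, d_max = 0.35, theta_max = 30) {
  stopifnot(inherits(frm, "fluct_frame"))
  if (is.null(topo) || !inherits(topo, "fluct_topology"))
    stop("topology error: hydroxyl site map required for H-bond detection")
  L <- frm$box_edge
  O <- frm$positions[topo$o_index, , drop = FALSE]
  H <- frm$positions[topo$h_index, , drop = FALSE]
  N <- nrow(O)
  voh <- minimum_image_displacement(O, H, L)          # donor O -> its H
  noh <- sqrt(rowSums(voh^2))
  if (any(noh == 0))
    stop("topology error: hydroxyl H coincides with its O")
  d <- minimum_image_dist_matrix(O, L)
  diag(d) <- Inf
  cand <- which(d <= d_max, arr.ind = TRUE)           # (donor, acceptor)
  if (nrow(cand) == 0)
    return(empty_hbond_list())
  i <- cand[, 1]; j <- cand[, 2]
  voo <- minimum_image_displacement(O[i, , drop = FALSE],
                                    O[j, , drop = FALSE], L)
  cosang <- rowSums(voh[i, , drop = FALSE] * voo) /
    (noh[i] * d[cand])
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  keep <- ang <= theta_max
  out <- data.frame(donor = i[keep], acceptor = j[keep],
                    distance = d[cand][keep], angle = ang[keep])
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_list", "data.frame"))
}

empty_hbond_list <- function() {
  structure(data.frame(donor = integer(0), acceptor = integer(0),
                       distance = numeric(0), angle = numeric(0)),
            class = c("hbond_list", "data.frame"))
}

#' Build the undirected H-bond graph from a donation list
#'
#' The adjacency indicator sets A_ij = 1 when at least one donation links
#' (i, j) in either direction: a mutual double bond binarises to a single
#' edge. Degrees are k_i = sum_j A_ij and the edge count m = sum_ij A_ij / 2.
#' The directed donation list is preserved separately by callers that count
#' donation events (n_H).
#'
#' @param bonds An `hbond_list` (or data.frame with `donor`, `acceptor`).
#' @param N Number of molecules (graph order).
#' @return An `hbond_graph` list with `n`, `edges` (m x 2 matrix, i < j,
#'   unique), `degree` (length-N integer), `m`.
#' @export
build_graph <- function(bonds, N) {
  if (nrow(bonds) > 0 && max(bonds$donor, bonds$acceptor) > N)
    stop("bond indices exceed molecule count N")
  if (nrow(bonds) > 0 && any(bonds$donor == bonds$acceptor))
    stop("self-bonds are not allowed (donor == acceptor)")
  e <- cbind(pmin(bonds$donor, bonds$acceptor),
             pmax(bonds$donor, bonds$acceptor))
  e <- unique(e)
  if (is.null(dim(e))) dim(e) <- c(length(e) / 2, 2)
  storage.mode(e) <- "integer"
  deg <- tabulate(e, nbins = N)
  structure(list(n = as.integer(N), edges = e, degree = deg,
                 m = nrow(e)), class = "hbond_graph")
}

#' Dense adjacency matrix of an H-bond graph
#'
#' @param graph An `hbond_graph`.
#' @return N x N symmetric 0/1 matrix with zero diagonal.
#' @export
as_adjacency <- function(graph) {
  A <- matrix(0L, graph$n, graph$n)
  if (graph$m > 0) {
    A[graph$edges] <- 1L
    A[graph$edges[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

#' Connected components of the H-bond graph
#'
#' Molecules are classified into disjoint clusters connected via H-bonds:
#' the connected components of the adjacency graph, found by union-find.
#' Labelling is deterministic: each molecule's label is the smallest
#' molecule index in its component.
#'
#' @param graph An `hbond_graph`.
#' @return Integer vector of length N of component labels.
#' @export
find_clusters <- function(graph) {
  parent <- seq_len(graph$n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (graph$m > 0) {
    for (k in seq_len(nrow(graph$edges))) {
      ra <- find(graph$edges[k, 1])
      rb <- find(graph$edges[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(graph$n), find, integer(1))
}

#' Cluster-size statistics over a trajectory
#'
#' Aggregates per-frame cluster partitions into the mean largest-cluster
#' size (per-frame maximum averaged over frames) and the cluster-size
#' distribution (all clusters over all frames, normalised to a probability
#' density over raw integer sizes).
#'
#' @param partitions List of per-frame label vectors (from [find_clusters()]).
#' @return A `cluster_report` list: `mean_largest`, `largest_per_frame`,
#'   `size_distribution` (data.frame `size`, `count`, `density`),
#'   `n_frames`.
#' @export
cluster_statistics <- function(partitions) {
  if (length(partitions) < 1) stop("need at least one analysed frame")
  sizes_all <- integer(0)
  largest <- numeric(length(partitions))
  for (fi in seq_along(partitions)) {
    sz <- as.integer(table(partitions[[fi]]))
    largest[fi] <- max(sz)
    sizes_all <- c(sizes_all, sz)
  }
  tab <- table(sizes_all)
  dist <- data.frame(size = as.integer(names(tab)),
                     count = as.integer(tab),
                     density = as.integer(tab) / length(sizes_all))
  structure(list(mean_largest = mean(largest), largest_per_frame = largest,
                 size_distribution = dist, n_frames = length(partitions)),
            class = "cluster_report")
}

#' Average number of hydrogen bonds per molecule
#'
#' n_H = <N_H> / N, the frame-averaged count of donation events divided by
#' the number of molecules. Each donor-acceptor donation counts once; for
#' single-hydroxyl molecules each molecule donates at most once, so
#' n_H <= 1, approaching 1 at saturation. Counting all bond endpoints
#' incident on oxygens and dividing by 2N gives the same number.
#'
#' @param bond_counts Numeric vector: donation events per frame.
#' @param N Number of molecules.
#' @return n_H (dimensionless).
#' @export
n_h_per_molecule <- function(bond_counts, N) {
  if (N <= 0) stop("N must be positive")
  mean(bond_counts) / N
}

#' Newman modularity of a partition of the H-bond graph
#'
#' Q = (1/2m) sum_ij [A_ij - k_i k_j / (2m)] delta(c_i, c_j), evaluated over
#' all ordered pairs including the i = j diagonal (which contributes
#' -k_i^2 / (2m) per vertex, every vertex sharing its own community).
#' Q = 0 for the trivial one-community partition and for homogeneous random
#' structure; 0.3 < Q <= 1 signals strong community structure.
#'
#' @param graph An `hbond_graph` with at least one edge.
#' @param partition Integer (or factor) labels of length N.
#' @return Q in [-1, 1].
#' @export
modularity_q <- function(graph, partition) {
  if (graph$m < 1)
    stop("modularity is undefined for an edgeless graph (m = 0)")
  if (length(partition) != graph$n)
    stop("partition length must equal the molecule count")
  part <- as.integer(factor(partition))
  m <- graph$m
  intra <- part[graph$edges[, 1]] == part[graph$edges[, 2]]
  m_c <- tabulate(part[graph$edges[, 1]][intra], nbins = max(part))
  K_c <- as.numeric(rowsum(graph$degree, part))
  sum(m_c / m - (K_c / (2 * m))^2)
}

#' Classify a modularity value against the community-structure regime
#'
#' @param Q Modularity value.
#' @return One of `"random"` (Q <= 0.3) or `"community"` (0.3 < Q <= 1).
#' @export
modularity_regime <- function(Q) {
  if (Q > 0.3 && Q <= 1) "community" else "random"
}

#' Full hydrogen-bond network analysis of a trajectory
#'
#' Per frame: geometric bond detection, graph construction, connected-
#' component clustering and modularity of the component partition (the
#' clusters are the communities). Aggregates n_H, mean largest cluster,
#' the size distribution and the frame-averaged modularity.
#'
#' @param traj A [trajectory()] with a hydroxyl topology.
#' @param d_max,theta_max H-bond cutoffs (nm, degrees).
#' @return An `hbond_report` list: `n_H`, `bond_counts`, `Q` (frame mean,
#'   NA if every frame is edgeless), `Q_per_frame`, `clusters` (a
#'   [cluster_statistics()] report), `mean_degree_bonded` (mean degree over
#'   molecules in clusters of size >= 2), `regime`.
#' @export
analyze_hbond_network <- function(traj, d_max = 0.35, theta_max = 30) {
  stopifnot(inherits(traj, "fluct_trajectory"))
  topo <- traj$topology
  N <- topo$n_molecules
  n_frames <- length(traj$frames)
  bond_counts <- numeric(n_frames)
  Qs <- rep(NA_real_, n_frames)
  partitions <- vector("list", n_frames)
  degsum_bonded <- 0
  n_bonded <- 0
  for (fi in seq_len(n_frames)) {
    bonds <- detect_hbonds(traj$frames[[fi]], topo, d_max, theta_max)
    bond_counts[fi] <- nrow(bonds)
    g <- build_graph(bonds, N)
    part <- find_clusters(g)
    partitions[[fi]] <- part
    if (g$m >= 1) Qs[fi] <- modularity_q(g, part)
    csize <- table(part)[as.character(part)]
    in_cluster <- as.integer(csize) >= 2
    degsum_bonded <- degsum_bonded + sum(g$degree[in_cluster])
    n_bonded <- n_bonded + sum(in_cluster)
  }
  Q <- if (all(is.na(Qs))) NA_real_ else mean(Qs, na.rm = TRUE)
  structure(list(
    n_H = n_h_per_molecule(bond_counts, N),
    bond_counts = bond_counts,
    Q = Q, Q_per_frame = Qs,
    clusters = cluster_statistics(partitions),
    partitions = partitions,
    mean_degree_bonded = if (n_bonded > 0) degsum_bonded / n_bonded
                         else NA_real_,
    regime = if (is.na(Q)) NA_character_ else modularity_regime(Q)
  ), class = "hbond_report")
}
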