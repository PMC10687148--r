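# Shared fixture builders; everything is generated in code at test time.

# two-site frame: one donor molecule (O at `o`, H at `h`) and one acceptor
# molecule whose O sits at `acc` (its own H points away along -z)
donor_acceptor_frame <- function(o, h, acc, L = 5) {
  pos <- rbind(o, h, acc, acc + c(0, 0, -0.098))
  list(frame = frame(pos, L),
       topo = topology(o_index = c(1, 3), h_index = c(2, 4)))
}

empty_bond_df <- function() data.frame(donor = integer(0),
                                       acceptor = integer(0))

# undirected random graph as an hbond_graph, Erdos-Renyi G(n, p)
random_graph <- function(n, p, seed) {
  with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    build_graph(data.frame(donor = pairs[keep, 1], acceptor = pairs[keep, 2]),
                n)
  })
}

# independent transitive-closure component oracle (boolean matrix powers)
components_by_closure <- function(graph) {
  A <- as_adjacency(graph) > 0
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # label = smallest reachable index
  apply(A, 1, function(row) min(which(row)))
}

# brute-force direct structure factor: literal double sum over pairs,
# averaged per shell of equal integer norm
sk_brute_force <- function(traj, n_max) {
  pos <- oxygen_positions(traj)
  L <- vapply(traj$frames, `[[`, numeric(1), "box_edge")
  acc <- list()
  for (fi in seq_along(pos)) {
    p <- pos[[fi]]
    N <- nrow(p)
    for (nx in -n_max:n_max) for (ny in -n_max:n_max) for (nz in -n_max:n_max) {
      if (nx == 0 && ny == 0 && nz == 0) next
      k <- 2 * pi * c(nx, ny, nz) / L[fi]
      ph <- as.vector(p %*% k)
      s <- sum(outer(ph, ph, function(a, b) cos(a - b))) / N
      key <- as.character(nx^2 + ny^2 + nz^2)
      acc[[key]] <- c(acc[[key]], s)
    }
  }
  nsq <- as.integer(names(acc))
  data.frame(nsq = nsq, S = vapply(acc, mean, numeric(1)))[order(nsq), ]
}

with_seed <- fluctnet:::with_seed
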