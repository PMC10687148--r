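test_that("the geometric criterion gates on distance and angle at the donor", {
  # aligned donor-H-acceptor at 0.28 nm: bond with angle 0
  fx <- donor_acceptor_frame(c(1, 1, 1), c(1.1, 1, 1), c(1.28, 1, 1))
  b <- detect_hbonds(fx$frame, fx$topo)
  expect_equal(nrow(b), 1)
  expect_equal(b$donor, 1)
  expect_equal(b$acceptor, 2)
  expect_equal(b$distance, 0.28, tolerance = 1e-12)
  expect_equal(b$angle, 0, tolerance = 1e-9)

  # same geometry but acceptor beyond the distance cutoff
  fx <- donor_acceptor_frame(c(1, 1, 1), c(1.1, 1, 1), c(1.40, 1, 1))
  expect_equal(nrow(detect_hbonds(fx$frame, fx$topo)), 0)

  # close acceptor but 45 degrees off the O-H axis
  acc <- c(1, 1, 1) + 0.30 * c(cos(pi / 4), sin(pi / 4), 0)
  fx <- donor_acceptor_frame(c(1, 1, 1), c(1.1, 1, 1), acc)
  expect_equal(nrow(detect_hbonds(fx$frame, fx$topo)), 0)

  # just inside both cutoffs (exact cutoff values are not representable
  # in binary floating point; boundary semantics are covered by the
  # 0.349 / 0.351 planted fixtures)
  fx <- donor_acceptor_frame(c(1, 1, 1), c(1.1, 1, 1), c(1.3499, 1, 1))
  expect_equal(nrow(detect_hbonds(fx$frame, fx$topo)), 1)
})

test_that("detection honours periodic boundaries", {
  # donor near the box face donating across it
  fx <- donor_acceptor_frame(c(0.05, 1, 1), c(4.97, 1, 1),
                             c(4.80, 1, 1), L = 5)
  b <- detect_hbonds(fx$frame, fx$topo)
  expect_equal(nrow(b), 1)
  expect_equal(b$distance, 0.25, tolerance = 1e-12)
})

test_that("graph construction follows the adjacency indicator", {
  g <- build_graph(empty_bond_df(), 4)
  expect_equal(g$degree, rep(0L, 4))
  expect_equal(g$m, 0)

  chain <- data.frame(donor = 1:3, acceptor = 2:4)
  g <- build_graph(chain, 4)
  expect_equal(g$degree, c(1, 2, 2, 1))
  expect_equal(g$m, 3)

  # mutual donation binarises to one edge
  mutual <- data.frame(donor = c(1, 2), acceptor = c(2, 1))
  g <- build_graph(mutual, 2)
  expect_equal(g$m, 1)
  expect_equal(g$degree, c(1, 1))
})

test_that("clusters are the connected components, labelled deterministically", {
  chain <- data.frame(donor = 1:3, acceptor = 2:4)
  g <- build_graph(chain, 6)
  part <- find_clusters(g)
  expect_equal(sort(as.integer(table(part)), decreasing = TRUE), c(4, 1, 1))
  expect_equal(part[1:4], rep(1L, 4))

  full <- expand.grid(donor = 1:5, acceptor = 1:5)
  full <- full[full$donor < full$acceptor, ]
  g <- build_graph(full, 5)
  expect_equal(find_clusters(g), rep(1L, 5))
})

test_that("components match a transitive-closure oracle on random graphs", {
  for (seed in 1:5) {
    g <- random_graph(50, 0.03, seed)
    expect_identical(find_clusters(g), components_by_closure(g))
  }
})

test_that("cluster statistics aggregate sizes and the largest cluster", {
  # all isolated
  rep_iso <- cluster_statistics(list(1:8, 1:8))
  expect_equal(rep_iso$mean_largest, 1)
  expect_equal(rep_iso$size_distribution$size, 1)
  expect_equal(rep_iso$size_distribution$density, 1)

  # frames alternating largest 10 and largest 6
  p1 <- rep(c(1, 11, 12, 13, 14, 15), times = c(10, 1, 1, 1, 1, 1))
  p2 <- rep(c(1, 7, 13), times = c(6, 6, 4))
  rep_alt <- cluster_statistics(list(p1, p2))
  expect_equal(rep_alt$mean_largest, 8)
  expect_equal(sum(rep_alt$size_distribution$density), 1)
})

test_that("n_H counts donation events per molecule", {
  expect_equal(n_h_per_molecule(3, 4), 0.75)
  expect_equal(n_h_per_molecule(rep(10, 5), 10), 1)  # saturated ring
  expect_equal(n_h_per_molecule(0, 10), 0)
})

test_that("modularity reproduces its closed forms", {
  tri2 <- build_graph(data.frame(donor = c(1, 2, 3, 4, 5, 6),
                                 acceptor = c(2, 3, 1, 5, 6, 4)), 6)
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)            # one community
  expect_equal(modularity_q(tri2, find_clusters(tri2)), 0.5)
  e <- build_graph(data.frame(donor = 1, acceptor = 2), 2)
  expect_equal(modularity_q(e, c(1, 2)), -0.5)              # singletons
  # c disconnected equal-edge communities: Q = 1 - 1/c
  for (c_comm in c(3, 5)) {
    bonds <- do.call(rbind, lapply(seq_len(c_comm) - 1, function(o)
      data.frame(donor = 3 * o + c(1, 2, 3), acceptor = 3 * o + c(2, 3, 1))))
    g <- build_graph(bonds, 3 * c_comm)
    expect_equal(modularity_q(g, find_clusters(g)), 1 - 1 / c_comm)
  }
  expect_error(modularity_q(build_graph(empty_bond_df(), 3), rep(1, 3)),
               "edgeless")
})

test_that("modularity equals the brute-force double sum on random graphs", {
  for (seed in 1:6) {
    g <- random_graph(100, 0.04, seed)
    if (g$m < 1) next
    part <- find_clusters(g)
    expect_equal(modularity_q(g, part),
                 modularity_naive(as_adjacency(g), part), tolerance = 1e-12)
    # and on an arbitrary (non-component) partition
    rnd <- with_seed(seed + 50, sample(1:4, g$n, replace = TRUE))
    expect_equal(modularity_q(g, rnd),
                 modularity_naive(as_adjacency(g), rnd), tolerance = 1e-12)
  }
})

test_that("modularity agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    g <- random_graph(60, 0.05, seed)
    if (g$m < 1) next
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
    part <- find_clusters(g)
    expect_equal(modularity_q(g, part),
                 igraph::modularity(ig, as.integer(factor(part))),
                 tolerance = 1e-12)
  }
})

test_that("component partitions never have negative modularity", {
  for (seed in 7:16) {
    g <- random_graph(40, 0.05, seed)
    if (g$m < 1) next
    expect_gte(modularity_q(g, find_clusters(g)), 0)
  }
})

test_that("random partitions of random graphs have modularity near zero", {
  qs <- vapply(1:30, function(seed) {
    g <- random_graph(60, 0.2, seed)
    rnd <- with_seed(seed + 100, sample(1:3, g$n, replace = TRUE))
    modularity_q(g, rnd)
  }, numeric(1))
  expect_lt(abs(mean(qs)), 3 * stats::sd(qs) / sqrt(length(qs)) + 0.01)
  expect_equal(modularity_regime(mean(qs)), "random")
  expect_equal(modularity_regime(0.6), "community")
})

test_that("trajectory-level network analysis matches planted ground truth", {
  ta <- gen_toy_alcohol(c(4, 10, 10, 1), L = 12)
  rpt <- analyze_hbond_network(ta$trajectory)
  truth <- ta$spec$truth
  expect_equal(rpt$n_H, truth$n_H)
  expect_equal(rpt$partitions[[1]], truth$partition)
  expect_equal(rpt$Q, truth$Q, tolerance = 1e-12)
  expect_equal(rpt$clusters$mean_largest, 10)
  # single-hydroxyl bound: n_H <= 1
  expect_lte(rpt$n_H, 1)
  # both bond-counting routes coincide: donations vs endpoint count / 2
  g <- build_graph(truth$bonds, truth$n_molecules)
  expect_equal(rpt$n_H, sum(g$degree) / (2 * truth$n_molecules))
  # isolated molecules excluded from the per-cluster mean degree
  expect_gte(rpt$mean_degree_bonded, 1)
})
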