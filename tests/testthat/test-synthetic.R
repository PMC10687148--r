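test_that("generators are pure functions of their seed", {
  a <- gen_binomial_gas(50, 5, 3, seed = 17)
  b <- gen_binomial_gas(50, 5, 3, seed = 17)
  expect_identical(a$trajectory$frames[[3]]$positions,
                   b$trajectory$frames[[3]]$positions)
  c1 <- gen_clustered_fluid(60, 3, 0.1, 6, 2, seed = 4,
                            oracle_realisations = 50)
  c2 <- gen_clustered_fluid(60, 3, 0.1, 6, 2, seed = 4,
                            oracle_realisations = 50)
  expect_identical(c1$trajectory$frames[[1]]$positions,
                   c2$trajectory$frames[[1]]$positions)
  expect_identical(c1$spec$truth$fano, c2$spec$truth$fano)
  v1 <- gen_volume_series(100, 4, 10, seed = 3)
  v2 <- gen_volume_series(100, 4, 10, seed = 3)
  expect_identical(v1$volumes, v2$volumes)
  g1 <- gen_planted_partition_graph(c(10, 10), 0.6, 0.05, seed = 2)
  g2 <- gen_planted_partition_graph(c(10, 10), 0.6, 0.05, seed = 2)
  expect_identical(g1$graph$edges, g2$graph$edges)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_binomial_gas(20, 5, 1, seed = 99))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("binomial-gas positions fill the box uniformly", {
  g <- gen_binomial_gas(500, 4, 2, seed = 5)
  for (f in g$trajectory$frames) {
    expect_true(all(f$positions >= 0 & f$positions < 4))
  }
  expect_equal(g$spec$truth$chi_inf, 1)
})

test_that("planted toy-alcohol bonds are detected exactly, with margins", {
  ta <- gen_toy_alcohol(c(4), L = 6)
  b <- detect_hbonds(ta$trajectory$frames[[1]], ta$trajectory$topology)
  expect_equal(b$donor, ta$spec$truth$bonds$donor)
  expect_equal(b$acceptor, ta$spec$truth$bonds$acceptor)
  expect_equal(ta$spec$truth$n_H, 0.75)

  # boundary behaviour: the criterion is <=, so 0.349 bonds and 0.351 not
  near <- gen_toy_alcohol(c(2), L = 6, bond_distance = 0.349)
  b_near <- detect_hbonds(near$trajectory$frames[[1]],
                          near$trajectory$topology)
  expect_equal(nrow(b_near), 1)
  expect_equal(nrow(near$spec$truth$bonds), 1)
  far <- gen_toy_alcohol(c(2), L = 6, bond_distance = 0.351)
  b_far <- detect_hbonds(far$trajectory$frames[[1]], far$trajectory$topology)
  expect_equal(nrow(b_far), 0)
  expect_equal(nrow(far$spec$truth$bonds), 0)

  expect_error(gen_toy_alcohol(c(40), L = 5), "do not fit")
})

test_that("toy-alcohol ground-truth modularity comes from the brute force", {
  ta <- gen_toy_alcohol(c(10, 10), L = 8)
  g <- build_graph(ta$spec$truth$bonds, 20)
  expect_equal(ta$spec$truth$Q,
               modularity_naive(as_adjacency(g), ta$spec$truth$partition),
               tolerance = 1e-15)
  expect_equal(find_clusters(g), ta$spec$truth$partition)
})

test_that("clustered fluid reduces to the ideal gas at low occupancy", {
  cf <- gen_clustered_fluid(2500, 0.5, 0.1, L = 8, n_frames = 30, seed = 6,
                            oracle_realisations = 400)
  expect_lt(abs(cf$spec$truth$fano - cf$spec$truth$fano_quenched), 0.15)
  fc <- subvolume_fluctuations(cf$trajectory, placements = 64, seed = 7)
  fit <- suppressMessages(sba_fit(fc))
  expect_lt(abs(fit$chi_inf - cf$spec$truth$fano), 0.2)
})

test_that("clustered fluid raises S(k) at low k above the structural region", {
  cf <- gen_clustered_fluid(400, 4, 0.15, L = 10, n_frames = 30, seed = 8,
                            oracle_realisations = 50)
  sk <- structure_factor_direct(cf$trajectory, n_max = 8)
  expect_gt(sk$S[1], mean(sk$S[sk$k > 4]))
  expect_gt(sk$S[1], 2)  # well above the ideal-gas level
})

test_that("volume-series truth follows the fluctuation formula", {
  vs <- gen_volume_series(1000, 0, 100, seed = 1)
  expect_identical(unique(vs$volumes), 1000)
  expect_equal(vs$spec$truth$kappa_Pa, 0)
  k <- kappa_from_volume_fluctuations(vs$volumes, 300)
  expect_equal(k$kappa_Pa, 0)
})

test_that("planted-partition graphs store brute-force modularity", {
  # p_out = 0, two equal communities of equal edge weight: Q near 1/2
  g <- gen_planted_partition_graph(c(20, 20), 0.5, 0, seed = 11)
  expect_equal(g$spec$truth$Q,
               modularity_naive(as_adjacency(g$graph), g$partition),
               tolerance = 1e-15)
  expect_lt(abs(g$spec$truth$Q - 0.5), 0.02)
  # single community: Q = 0 exactly
  g1 <- gen_planted_partition_graph(30, 0.3, 0.3, seed = 12)
  expect_equal(g1$spec$truth$Q, 0)
})

test_that("p_in = p_out makes the planted partition unmodular on average", {
  qs <- vapply(1:20, function(s)
    gen_planted_partition_graph(c(15, 15), 0.3, 0.3, seed = s)$spec$truth$Q,
    numeric(1))
  expect_lt(abs(mean(qs)), 3 * stats::sd(qs) / sqrt(length(qs)) + 0.01)
})

test_that("synthetic specs serialise to JSON and back", {
  ta <- gen_toy_alcohol(c(3, 2), L = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_spec(ta$spec, path)
  back <- read_synthetic_spec(path)
  expect_equal(back$generator, "toy_alcohol")
  expect_equal(back$truth$Q, ta$spec$truth$Q)
  expect_equal(back$truth$partition, ta$spec$truth$partition)
})
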