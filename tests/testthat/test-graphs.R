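test_that("graph measures reproduce closed-form cases", {
  n <- 19
  complete <- binary_network(matrix(1, n, n) - diag(n))
  m <- graph_measures(complete)
  expect_identical(unname(m$degrees), rep(n - 1, n))
  expect_identical(m$mean_degree, n - 1)
  expect_identical(m$degree_variance, 0)
  expect_identical(unname(m$local_cc), rep(1, n))

  # triangle plus a pendant attached to node 3
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 3] <- adj[1, 3] <- adj[3, 4] <- 1
  adj <- pmax(adj, t(adj))
  mt <- graph_measures(binary_network(adj))
  expect_identical(unname(mt$degrees), c(2, 2, 3, 1))
  expect_identical(mt$mean_degree, 2)
  expect_identical(unname(mt$local_cc), c(1, 1, 1 / 3, 0))

  # weighted degrees scale linearly
  half <- functional_network(0.5 * (matrix(1, 4, 4) - diag(4)))
  expect_identical(graph_measures(half)$mean_degree, 0.5 * 3)

  asym <- matrix(0, 3, 3); asym[1, 2] <- 1
  expect_error(graph_measures(asym), "symmetric")
  loops <- diag(3)
  expect_error(graph_measures(loops), "diagonal")
})

test_that("binary local clustering matches a triangle-counting oracle", {
  set.seed(17)
  for (k in 1:100) {
    n <- sample(3:7, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, runif(1, 0.2, 0.8))
    adj <- adj + t(adj)
    cc <- graph_measures(binary_network(adj))$local_cc
    expect_equal(unname(cc), brute_force_local_cc(adj), tolerance = 1e-12)
  }
})

test_that("MD-preserving binarization hits the one-edge-increment bound", {
  # already-binary input is returned unchanged
  b <- random_binary_network(10, 4, seed = 2)
  fn <- functional_network(b$adjacency)
  again <- binarize_preserving_md(fn)
  expect_identical(again$adjacency, b$adjacency)
  expect_identical(again$provenance$md_gap, 0)

  set.seed(23)
  for (k in 1:100) {
    fn <- random_weighted_network(19)
    bn <- binarize_preserving_md(fn)
    gap <- abs(graph_measures(bn)$mean_degree -
                 graph_measures(fn)$mean_degree)
    expect_lte(gap, 2 / 19 + 1e-9)
  }
  flat <- functional_network(0.5 * (matrix(1, 5, 5) - diag(5)))
  expect_error(binarize_preserving_md(flat), "equal")
})

test_that("raising the binarization threshold never increases mean degree", {
  set.seed(29)
  fn <- random_weighted_network(12)
  w <- sort(unique(fn$adjacency[upper.tri(fn$adjacency)]))
  mds <- vapply(c(0, w), function(t)
    2 * sum(fn$adjacency[upper.tri(fn$adjacency)] > t) / 12, numeric(1))
  expect_true(all(diff(mds) <= 0))
})

test_that("degree-preserving randomization preserves degrees exactly", {
  set.seed(31)
  for (k in 1:10) {
    b <- random_binary_network(19, sample(3:10, 1), seed = 300 + k)
    r <- degree_preserving_randomize(b, seed = k)
    expect_identical(rowSums(r$adjacency), rowSums(b$adjacency))
    m_b <- graph_measures(b); m_r <- graph_measures(r)
    expect_identical(m_r$mean_degree, m_b$mean_degree)
    expect_identical(m_r$degree_variance, m_b$degree_variance)
    expect_identical(sum(r$adjacency), sum(b$adjacency))
  }
  # a star admits no valid double-edge swap
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- pmax(star, t(star))
  sb <- binary_network(star)
  expect_identical(degree_preserving_randomize(sb, seed = 1)$adjacency,
                   sb$adjacency)
  lone <- matrix(0, 3, 3); lone[1, 2] <- lone[2, 1] <- 1
  expect_error(degree_preserving_randomize(binary_network(lone)),
               "2 edges")
  # reproducibility
  b <- random_binary_network(19, 6, seed = 8)
  expect_identical(degree_preserving_randomize(b, seed = 5)$adjacency,
                   degree_preserving_randomize(b, seed = 5)$adjacency)
})

test_that("spectra follow classical identities and detect rewiring", {
  n <- 7
  complete <- binary_network(matrix(1, n, n) - diag(n))
  expect_equal(adjacency_spectrum(complete), c(n - 1, rep(-1, n - 1)),
               tolerance = 1e-9)
  expect_identical(adjacency_spectrum(binary_network(matrix(0, 4, 4))),
                   rep(0, 4))
  # permuting labels leaves the spectrum unchanged
  b <- random_binary_network(12, 4, seed = 9)
  perm <- sample(12)
  expect_equal(adjacency_spectrum(b),
               adjacency_spectrum(binary_network(b$adjacency[perm, perm])),
               tolerance = 1e-9)
  # randomization scrambles the spectrum of a swappable network
  r <- degree_preserving_randomize(b, seed = 10)
  expect_gt(max(abs(adjacency_spectrum(b) - adjacency_spectrum(r))), 1e-8)
})

test_that("artificial ensembles share the binarized mean degree exactly", {
  set.seed(37)
  fn <- random_weighted_network(19)
  ens <- make_artificial_ensemble(fn, n = 8, seed = 3)
  expect_length(ens, 8)
  md0 <- graph_measures(binarize_preserving_md(fn))$mean_degree
  for (b in ens)
    expect_identical(graph_measures(b)$mean_degree, md0)
  # reproducible for a fixed seed
  e1 <- make_artificial_ensemble(fn, n = 1, seed = 77)[[1]]
  e2 <- make_artificial_ensemble(fn, n = 1, seed = 77)[[1]]
  expect_identical(e1$adjacency, e2$adjacency)
})
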