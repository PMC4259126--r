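test_that("node drift matches hand-evaluated values", {
  p <- paper_params()
  expect_identical(node_drift(0 + 0i, p), 0 + 0i)
  # (a + b + c) * 1 + i*omega at z = 1
  expect_equal(node_drift(1 + 0i, p), 0.1 + 1i, tolerance = 1e-12)
  # on a radial equilibrium the radial component of the drift vanishes
  for (r in radial_equilibria(p)$radius[-1]) {
    z <- complex(modulus = r, argument = 0.7)
    expect_lt(abs(Re(Conj(z) * node_drift(z, p))), 1e-9)
  }
  expect_error(node_drift(NaN + 0i, p), "non-finite")
})

test_that("radial equilibria match the closed form and a flow-sign oracle", {
  cases <- list(
    list(p = node_parameters(-1, 2, -0.9, 1),
         radius = c(0, sqrt(0.68377223), sqrt(1.31622777)),
         stability = c("stable", "unstable", "stable")),
    list(p = node_parameters(-1, 2, 0.5, 1),
         radius = c(0, sqrt((2 + sqrt(6)) / 2)),
         stability = c("unstable", "stable")),
    list(p = node_parameters(-1, 0, -1, 1),
         radius = 0, stability = "stable")
  )
  for (cs in cases) {
    eq <- radial_equilibria(cs$p)
    expect_equal(eq$radius, cs$radius, tolerance = 1e-6)
    expect_identical(eq$stability, cs$stability)
    bf <- brute_force_radial_equilibria(cs$p)
    expect_equal(nrow(bf), nrow(eq))
    expect_equal(bf$radius, eq$radius, tolerance = 1e-3)
    expect_identical(bf$stability, eq$stability)
  }
  expect_error(node_parameters(a = 0), "non-zero")
  expect_true(is_bistable(paper_params()))
  expect_false(is_bistable(node_parameters(-1, 0, -1, 1)))
})

test_that("node frequency jitter is uniform around the center", {
  expect_equal(sample_node_frequencies(1, 0, n = 19, seed = 1), rep(1, 19))
  f <- sample_node_frequencies(1, 0.2, n = 1e5, seed = 7)
  expect_true(all(f >= 0.8 & f <= 1.2))
  # CLT bound: sd of the mean of Uniform(-0.2, 0.2) draws
  expect_lt(abs(mean(f) - 1), 3 * (0.2 / sqrt(3)) / sqrt(1e5))
  expect_identical(sample_node_frequencies(1, 0.2, n = 5, seed = 3),
                   sample_node_frequencies(1, 0.2, n = 5, seed = 3))
})

test_that("noise-free simulation respects the attractor structure", {
  p <- paper_params()
  cfg <- sim_config(dt = 0.005, duration = 100, seed = 1)
  still <- simulate_network(p, NULL, noise_spec(0), cfg, frequencies = 1,
                            init_state = 0 + 0i)
  expect_true(all(still$states == 0))
  # on the stable limit cycle the modulus stays put (up to first-order
  # Euler bias, which shrinks with dt)
  r_lc <- lc_radius(p)
  on_lc <- simulate_network(p, NULL, noise_spec(0), cfg, frequencies = 1,
                            init_state = complex(modulus = r_lc, argument = 0))
  expect_lt(max(abs(Mod(on_lc$states) - r_lc)), 3e-3)
  fine <- simulate_network(p, NULL, noise_spec(0),
                           sim_config(dt = 0.001, duration = 20, seed = 1),
                           frequencies = 1,
                           init_state = complex(modulus = r_lc, argument = 0))
  expect_lt(max(abs(Mod(fine$states) - r_lc)), 1e-3)
})

test_that("with zero noise no trajectory crosses between basins", {
  p <- paper_params()
  cfg <- sim_config(dt = 0.005, duration = 100, seed = 1)
  r_u <- unstable_radius(p)
  below <- simulate_network(p, NULL, noise_spec(0), cfg, frequencies = 1,
                            init_state = complex(modulus = 0.95 * r_u,
                                                 argument = 1))
  expect_lt(Mod(below$states[1, ncol(below$states)]), 1e-3)
  expect_true(all(Mod(below$states) < r_u))
  above <- simulate_network(p, NULL, noise_spec(0), cfg, frequencies = 1,
                            init_state = complex(modulus = 1.05 * r_u,
                                                 argument = 1))
  expect_equal(unname(Mod(above$states[1, ncol(above$states)])),
               lc_radius(p), tolerance = 1e-2)
  expect_true(all(Mod(above$states) > r_u))
})

test_that("noise-free trajectories are rotationally equivariant", {
  p <- paper_params()
  cfg <- sim_config(dt = 0.005, duration = 10, seed = 1)
  z0 <- 0.9 + 0i
  base <- simulate_network(p, NULL, noise_spec(0), cfg, frequencies = 1,
                           init_state = z0)
  for (theta in c(0.3, 2.2)) {
    rot <- simulate_network(p, NULL, noise_spec(0), cfg, frequencies = 1,
                            init_state = z0 * exp(1i * theta))
    expect_lt(max(Mod(rot$states - base$states * exp(1i * theta))), 1e-9)
  }
})

test_that("the integrator converges at first order in dt", {
  p <- paper_params()
  run <- function(dt) {
    tr <- simulate_network(p, NULL, noise_spec(0),
                           sim_config(dt = dt, duration = 5, seed = 1),
                           frequencies = 1, init_state = 1 + 0i)
    tr$states[1, ncol(tr$states)]
  }
  ref <- run(0.02 / 16)
  e1 <- Mod(run(0.02) - ref)
  e2 <- Mod(run(0.01) - ref)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.6)
})

test_that("zero coupling decouples the network into independent copies", {
  p <- paper_params()
  cfg <- sim_config(dt = 0.01, duration = 10, seed = 99)
  g0 <- coupling_matrix(matrix(0, 2, 2))
  z0 <- c(0.4 + 0.2i, 1.2 - 0.1i)
  freq <- c(0.95, 1.1)
  net <- simulate_network(p, g0, noise_spec(0), cfg, frequencies = freq,
                          init_state = z0)
  for (i in 1:2) {
    solo <- simulate_network(p, NULL, noise_spec(0), cfg,
                             frequencies = freq[i], init_state = z0[i])
    expect_identical(unname(net$states[i, ]), unname(solo$states[1, ]))
  }
  # determinism contract under noise
  a <- simulate_network(p, g0, noise_spec(0.3), cfg, frequencies = c(1, 1))
  b <- simulate_network(p, g0, noise_spec(0.3), cfg, frequencies = c(1, 1))
  expect_identical(a$states, b$states)
})

test_that("divergence guard reports step and node", {
  bad <- node_parameters(a = 1, b = 0, c = 1, omega = 0)  # expanding flow
  expect_error(
    simulate_network(bad, NULL, noise_spec(0),
                     sim_config(dt = 0.05, duration = 50, seed = 1),
                     frequencies = 0, init_state = 2 + 0i),
    "diverged")
})

test_that("coupling matrix validation rejects malformed input", {
  m <- matrix(runif(9), 3, 3)
  expect_error(coupling_matrix(m), "symmetric|diagonal")
  s <- (m + t(m)) / 2; diag(s) <- 0
  expect_silent(coupling_matrix(s))
  s[1, 2] <- s[2, 1] <- -0.1
  expect_error(coupling_matrix(s), "non-negative")
})
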