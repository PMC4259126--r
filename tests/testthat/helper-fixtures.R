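# shared fixtures built in code

paper_params <- function() node_parameters(-1, 2, -0.9, 1)

lc_radius <- function(params = paper_params()) {
  eq <- radial_equilibria(params)
  max(eq$radius[eq$stability == "stable"])
}

unstable_radius <- function(params = paper_params()) {
  eq <- radial_equilibria(params)
  eq$radius[eq$stability == "unstable"][1]
}

# random symmetric zero-diagonal weighted matrix with iid Uniform(0,1)
# weights
random_weighted_network <- function(n = 19) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2)
  functional_network(a + t(a))
}

# hand-built trajectory container for classification tests
manual_trajectory <- function(states, dt = 0.01, omega = 1) {
  structure(list(states = states, dt = dt,
                 times = seq(0, ncol(states) - 1) * dt,
                 node_frequencies = rep(omega, nrow(states)),
                 labels = paste0("node_", seq_len(nrow(states)))),
            class = "complex_trajectory")
}

# brute-force radial-flow classifier: scans the sign of the radial drift
# Re(conj(z) * dz/dt)/|z| over a grid of radii and reports sign-change
# equilibria with stability from the flow direction on either side
brute_force_radial_equilibria <- function(params, r_max = 2, n_grid = 1e4) {
  r <- seq(r_max / n_grid, r_max, length.out = n_grid)
  u <- r^2
  flow <- r * (params$a * u^2 + params$b * u + params$c)
  sgn <- sign(flow)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- (r[idx] + r[idx + 1]) / 2
  stab <- ifelse(sgn[idx] > 0 & sgn[idx + 1] < 0, "stable", "unstable")
  origin <- if (sgn[1] < 0) "stable" else "unstable"
  data.frame(radius = c(0, roots), stability = c(origin, stab),
             stringsAsFactors = FALSE)
}

# direct-summation PLF oracle
plf_brute_force <- function(phi_i, phi_j) {
  acc <- 0 + 0i
  for (k in seq_along(phi_i)) acc <- acc + exp(1i * (phi_i[k] - phi_j[k]))
  Mod(acc) / length(phi_i)
}

# triangle-counting local clustering oracle for binary graphs
brute_force_local_cc <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (p in seq_len(k - 1))
      for (q in (p + 1):k)
        links <- links + adj[nb[p], nb[q]]
    2 * links / (k * (k - 1))
  }, numeric(1))
}

two_group_cohort <- function(n_per_group = 20, seed = 42) {
  ctrl <- generate_weighted_cohort(
    cohort_spec(n_per_group, md_range = c(4, 6), seed = seed))
  pat <- generate_weighted_cohort(
    cohort_spec(n_per_group, md_range = c(7, 9), seed = seed + 1000))
  list(networks = c(ctrl, pat),
       groups = rep(c("control", "patient"), each = n_per_group))
}
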