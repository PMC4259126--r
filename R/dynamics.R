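#' Node parameters of the bistable oscillator
#'
#' Coefficients of the abstract bistable unit
#' \deqn{dZ/dt = (a|Z|^4 + b|Z|^2 + c + i\omega)\,Z + \epsilon(t),}
#' a complex-valued normal form whose radial dynamics can place a stable
#' fixed point at the origin (the "background" state) alongside a stable
#' limit cycle (the "seizure" state).  The operating point used throughout
#' the package is `a = -1, b = 2, c = -0.9, omega = 1`, which is bistable:
#' see [radial_equilibria()].
#'
#' @param a real coefficient of the quartic radial term; must be non-zero
#'   (negative for a globally contracting flow).
#' @param b real coefficient of the quadratic radial term.
#' @param c real part of the complex linear coefficient; its sign sets the
#'   stability of the origin.
#' @param omega imaginary part of the linear coefficient: the angular
#'   frequency of rotation, in radians per unit model time.
#' @return An object of class `node_parameters`.
#' @examples
#' p <- node_parameters()
#' radial_equilibria(p)
#' @export
node_parameters <- function(a = -1, b = 2, c = -0.9, omega = 1) {
  out <- list(
    a = check_scalar(a, "a"), b = check_scalar(b, "b"),
    c = check_scalar(c, "c"), omega = check_scalar(omega, "omega")
  )
  if (out$a == 0) stop("`a` must be non-zero: the model is quartic in |Z|^2")
  structure(out, class = "node_parameters")
}

#' @export
print.node_parameters <- function(x, ...) {
  cat(sprintf("<node_parameters> a=%g b=%g c=%g omega=%g\n",
              x$a, x$b, x$c, x$omega))
  invisible(x)
}

#' Noise specification for stochastic simulation
#'
#' The stochastic input to each node is complex white noise with
#' independent Gaussian real and imaginary increments; `sigma` is the
#' standard deviation per unit model time of each component, so a step of
#' size `dt` adds `sigma * sqrt(dt) * (N(0,1) + i N(0,1))`.
#'
#' @param sigma noise amplitude, `>= 0`.  The default 0.3 is calibrated so
#'   that a single uncoupled node at the default [node_parameters()] escapes
#'   the background state within the default simulation length, but not
#'   instantly (see the package vignette).
#' @param seed optional integer; when supplied, [simulate_network()] seeds
#'   the noise stream with it (after initial conditions are drawn).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.3, seed = NULL) {
  sigma <- check_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(sigma = sigma, seed = seed), class = "noise_spec")
}

#' Coupling matrix wrapper
#'
#' Wraps a weighted, undirected, zero-diagonal adjacency matrix for use as
#' the connectivity of the network model, together with the global scale
#' factor applied uniformly before simulation (default 0.1, which keeps
#' coupled nodes inside the bistable regime so that state transitions are
#' preserved).
#'
#' @param weights square, symmetric, non-negative numeric matrix with zero
#'   diagonal.  A `functional_network` or `binary_network` is also accepted.
#' @param scale global multiplier applied to `weights` at simulation time.
#' @param labels optional node labels (defaults to matrix dimnames or
#'   `node_1 ...`).
#' @return An object of class `coupling_matrix`.
#' @export
coupling_matrix <- function(weights, scale = 0.1, labels = NULL) {
  if (inherits(weights, c("functional_network", "binary_network"))) {
    if (is.null(labels)) labels <- weights$labels
    weights <- weights$adjacency
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("`weights` must be square")
  if (!isSymmetric(unname(weights), tol = 1e-10))
    stop("`weights` must be symmetric (undirected network)")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be finite and non-negative")
  if (any(diag(weights) != 0)) stop("`weights` must have a zero diagonal")
  n <- nrow(weights)
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("node_", seq_len(n))
  if (length(labels) != n) stop("`labels` length must match matrix size")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, scale = check_scalar(scale, "scale"),
                 labels = as.character(labels)),
            class = "coupling_matrix")
}

#' Simulation configuration
#'
#' @param dt integration step in model time units.
#' @param duration total simulated time; `floor(duration/dt)` steps are
#'   taken.
#' @param init_mode how initial conditions are drawn: `"random_disk"`
#'   (uniform over the disk of radius `init_radius`, independently per
#'   node — covers both basins of attraction), `"at_steady_state"` (all
#'   nodes at the origin) or `"on_limit_cycle"` (all nodes at the stable
#'   limit-cycle radius, with independent uniform phases).
#' @param init_radius disk radius for `"random_disk"`.
#' @param seed integer seed controlling initial conditions, node
#'   frequencies, and (unless overridden via [noise_spec()]) the noise
#'   stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 500,
                       init_mode = c("random_disk", "at_steady_state",
                                     "on_limit_cycle"),
                       init_radius = 1.5, seed = NULL) {
  dt <- check_scalar(dt, "dt"); duration <- check_scalar(duration, "duration")
  if (dt <= 0) stop("`dt` must be > 0")
  if (duration < dt || floor(duration / dt) < 2)
    stop("`duration` must allow at least 2 steps")
  init_radius <- check_scalar(init_radius, "init_radius")
  if (init_radius < 0) stop("`init_radius` must be >= 0")
  structure(list(dt = dt, duration = duration,
                 init_mode = match.arg(init_mode),
                 init_radius = init_radius, seed = seed),
            class = "sim_config")
}

#' Deterministic drift of one node
#'
#' Evaluates the noise-free right-hand side
#' `(a|z|^4 + b|z|^2 + c + i*omega) * z + coupling_input`.
#'
#' @param z complex state of the node.
#' @param params a [node_parameters()] object.
#' @param coupling_input complex input summed from coupled nodes
#'   (`sum_j G_ij Z_j`); 0 for an uncoupled node.
#' @return Complex time derivative.
#' @examples
#' node_drift(1 + 0i, node_parameters())  # 0.1 + 1i
#' @export
node_drift <- function(z, params, coupling_input = 0 + 0i) {
  stopifnot(inherits(params, "node_parameters"))
  if (any(!is.finite(z)) || any(!is.finite(coupling_input)))
    stop("non-finite state or coupling input")
  u <- Mod(z)^2
  (params$a * u^2 + params$b * u + complex(real = params$c,
                                           imaginary = params$omega)) * z +
    coupling_input
}

#' Radial equilibria and their stability
#'
#' The modulus `r = |Z|` of an uncoupled, noise-free node obeys
#' `dr/dt = r (a r^4 + b r^2 + c)`, so with `u = r^2` the non-trivial
#' equilibria are the non-negative roots of `a u^2 + b u + c = 0`.  The
#' origin is stable when `c < 0`; a circular orbit at radius `sqrt(u)` is a
#' stable limit cycle when the radial derivative `2au + b` is negative
#' there, and an unstable separatrix otherwise.  Bistability — a stable
#' origin plus a stable limit cycle separated by an unstable circle — is
#' the regime in which noise alone can switch a node between background and
#' seizure states.
#'
#' @param params a [node_parameters()] object (`a` must be non-zero).
#' @return A data frame with columns `radius` (ascending) and `stability`
#'   (`"stable"` or `"unstable"`), always including the origin.
#' @examples
#' radial_equilibria(node_parameters(-1, 2, -0.9, 1))
#' @export
radial_equilibria <- function(params) {
  stopifnot(inherits(params, "node_parameters"))
  a <- params$a; b <- params$b; c <- params$c
  radius <- 0
  stability <- if (c < 0) "stable" else "unstable"
  disc <- b^2 - 4 * a * c
  if (disc >= 0) {
    roots <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
    roots <- roots[roots > 0]
    for (u in roots) {
      radius <- c(radius, sqrt(u))
      stability <- c(stability,
                     if (2 * a * u + b < 0) "stable" else "unstable")
    }
  }
  data.frame(radius = radius, stability = stability,
             stringsAsFactors = FALSE)
}

#' Is the node bistable?
#'
#' TRUE when the noise-free node has both a stable origin and a stable
#' limit cycle.
#'
#' @inheritParams radial_equilibria
#' @export
is_bistable <- function(params) {
  eq <- radial_equilibria(params)
  eq$stability[eq$radius == 0] == "stable" &&
    any(eq$stability[eq$radius > 0] == "stable")
}

#' Draw per-node angular frequencies
#'
#' Node frequencies are jittered as `omega_i = omega0 + U[-half_width,
#' half_width]` so that identical phase velocities do not produce
#' artificial phase locking across the network.
#'
#' @param omega0 center frequency (radians per unit model time).
#' @param half_width half-width of the uniform jitter interval (default
#'   0.2).
#' @param n number of nodes.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` frequencies.
#' @export
sample_node_frequencies <- function(omega0 = 1, half_width = 0.2, n, seed = NULL) {
  omega0 <- check_scalar(omega0, "omega0")
  half_width <- check_scalar(half_width, "half_width")
  if (half_width < 0) stop("`half_width` must be >= 0")
  if (n < 1) stop("`n` must be >= 1")
  with_seed(seed, omega0 + runif(n, -half_width, half_width))
}

#' Simulate the coupled stochastic network
#'
#' Integrates
#' \deqn{dZ_i = [(a|Z_i|^4 + b|Z_i|^2 + c + i\omega_i) Z_i +
#'   s \sum_j G_{ij} Z_j]\,dt + \sigma\sqrt{dt}\,(\eta_1 + i\eta_2)}
#' by the Euler–Maruyama scheme, with white noise generated independently
#' for each node and `s` the global coupling scale.  Given the seed(s) the
#' trajectory is fully reproducible.
#'
#' @param params a [node_parameters()] object (shared `a`, `b`, `c`;
#'   frequencies may vary per node).
#' @param coupling a [coupling_matrix()], or `NULL` for a single uncoupled
#'   node.
#' @param noise a [noise_spec()].
#' @param config a [sim_config()].
#' @param frequencies optional numeric vector of per-node angular
#'   frequencies; when omitted they are drawn via
#'   [sample_node_frequencies()] with half-width `freq_half_width`.
#' @param freq_half_width jitter half-width used when `frequencies` is
#'   omitted.
#' @param init_state optional complex vector of explicit initial
#'   conditions (one per node, or one value recycled), overriding
#'   `config$init_mode`.
#' @param guard divergence guard: integration aborts with an error if any
#'   `|Z_i|` exceeds this (only reachable for user-supplied non-contracting
#'   parameter sets, since `a < 0` makes the drift contracting at large
#'   `|Z|`).
#' @return An object of class `complex_trajectory` with fields `states`
#'   (N x T complex matrix), `dt`, `times`, `node_frequencies`, `labels`.
#' @examples
#' tr <- simulate_network(node_parameters(), NULL, noise_spec(0.3),
#'                        sim_config(duration = 50, seed = 1))
#' dim(tr$states)
#' @export
simulate_network <- function(params, coupling = NULL, noise = noise_spec(),
                             config = sim_config(), frequencies = NULL,
                             freq_half_width = 0.2, init_state = NULL,
                             guard = 10) {
  stopifnot(inherits(params, "node_parameters"),
            inherits(noise, "noise_spec"),
            inherits(config, "sim_config"))
  if (is.null(coupling)) {
    G <- matrix(0, 1, 1)
    labels <- "node_1"
  } else {
    stopifnot(inherits(coupling, "coupling_matrix"))
    G <- coupling$weights * coupling$scale
    labels <- coupling$labels
  }
  n <- nrow(G)
  nsteps <- floor(config$duration / config$dt)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  if (is.null(frequencies)) {
    frequencies <- params$omega + runif(n, -freq_half_width, freq_half_width)
  } else {
    if (length(frequencies) == 1L) frequencies <- rep(frequencies, n)
    if (length(frequencies) != n)
      stop("`frequencies` must have one entry per node")
  }

  z0 <- if (!is.null(init_state)) {
    init_state <- as.complex(init_state)
    if (length(init_state) == 1L) init_state <- rep(init_state, n)
    if (length(init_state) != n)
      stop("`init_state` must have one entry per node")
    init_state
  } else switch(config$init_mode,
    at_steady_state = rep(complex(real = 0, imaginary = 0), n),
    on_limit_cycle = {
      eq <- radial_equilibria(params)
      r_lc <- eq$radius[eq$radius > 0 & eq$stability == "stable"]
      if (length(r_lc) == 0) stop("no stable limit cycle at these parameters")
      complex(modulus = max(r_lc), argument = runif(n, 0, 2 * pi))
    },
    random_disk = complex(modulus = config$init_radius * sqrt(runif(n)),
                          argument = runif(n, 0, 2 * pi))
  )

  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  states <- em_simulate_cpp(G, params$a, params$b, params$c,
                            as.numeric(frequencies), noise$sigma,
                            config$dt, nsteps, z0, guard)
  rownames(states) <- labels
  structure(list(states = states, dt = config$dt,
                 times = seq(0, nsteps) * config$dt,
                 node_frequencies = as.numeric(frequencies),
                 labels = labels),
            class = "complex_trajectory")
}

#' @export
print.complex_trajectory <- function(x, ...) {
  cat(sprintf("<complex_trajectory> %d nodes x %d samples, dt=%g (T=%g)\n",
              nrow(x$states), ncol(x$states), x$dt, max(x$times)))
  invisible(x)
}
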