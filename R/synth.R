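#' Specification of a synthetic weighted-network cohort
#'
#' Describes one group of subjects, each represented by a 19-node weighted
#' functional network whose weighted mean degree is drawn uniformly from a
#' target range.  The shipped presets emulate the kind of group separation
#' reported for resting-state functional networks — controls around MD
#' 4-6, patients around MD 7-9 on 19 nodes — as a documented emulation,
#' not as measured clinical values.
#'
#' @param n_subjects subjects in the group.
#' @param n_nodes nodes per network (default 19, the scalp-EEG montage
#'   size).
#' @param md_range length-2 numeric: uniform range of target weighted mean
#'   degree; must lie in `(0, n_nodes - 1)`.
#' @param weight_concentration shape parameter of the symmetric Beta
#'   distribution of raw edge weights; larger values concentrate weights
#'   around 0.5 (default 2).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_nodes = 19, md_range = c(4, 6),
                        weight_concentration = 2, seed = 1) {
  stopifnot(n_subjects >= 1, n_nodes >= 3, length(md_range) == 2)
  md_range <- sort(as.numeric(md_range))
  if (md_range[1] <= 0 || md_range[2] >= n_nodes - 1)
    stop("`md_range` must lie strictly inside (0, n_nodes - 1)")
  if (weight_concentration <= 0)
    stop("`weight_concentration` must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes), md_range = md_range,
                 weight_concentration = weight_concentration,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a cohort of weighted networks with targeted mean degree
#'
#' For each subject a target mean degree is drawn uniformly from
#' `md_range`; symmetric Beta-distributed weights in `[0, 1]` are then
#' rescaled so the weighted mean degree matches the target to within 1e-6.
#' If rescaling would push any weight above 1 the draw is retried (up to
#' 100 times per subject) before erroring, so targets near the feasibility
#' boundary still resolve.
#'
#' @param spec a [cohort_spec()].
#' @return List of `n_subjects` [functional_network()] objects; each
#'   carries its target MD as attribute `target_md`.
#' @export
generate_weighted_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_nodes
  seeds <- derive_seeds(spec$seed, spec$n_subjects)
  lapply(seq_len(spec$n_subjects), function(s) {
    with_seed(seeds[s], {
      target <- runif(1, spec$md_range[1], spec$md_range[2])
      for (attempt in seq_len(100)) {
        w <- rbeta(n * (n - 1) / 2, spec$weight_concentration,
                   spec$weight_concentration)
        # weighted MD = 2 * sum(w) / n; rescale to hit the target exactly
        fac <- target * n / (2 * sum(w))
        if (all(w * fac <= 1)) {
          a <- matrix(0, n, n)
          a[upper.tri(a)] <- w * fac
          a <- a + t(a)
          net <- functional_network(a)
          attr(net, "target_md") <- target
          return(net)
        }
      }
      stop(sprintf("could not realize target mean degree %.3f in [0,1] %s",
                   target, "weights after 100 attempts"))
    })
  })
}

#' Specification of phase-coupled synthetic signals
#'
#' Describes a set of narrow-band oscillatory channels with a programmed
#' pairwise phase-coupling structure, used as ground truth for PLF
#' estimation.  All channels share a common carrier at the center of
#' `carrier_band`; independence between channels comes from per-channel
#' phase diffusion, and dependence from Kuramoto-style phase pulling with
#' pairwise strengths `coupling[i, j]` in `[0, 1]`.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param duration record length (seconds).
#' @param carrier_band length-2 Hz range; the common carrier frequency is
#'   its midpoint (default `c(6, 9)`, carrier 7.5 Hz).
#' @param coupling symmetric zero-diagonal matrix of coupling strengths
#'   `kappa` in `[0, 1]`, or a single number applied to all pairs.
#' @param noise_level scales both the per-channel phase diffusion
#'   (`noise_level` rad per sqrt(second)) and the additive broadband
#'   observation noise (`0.1 * noise_level` amplitude units).  Default 1.
#' @param coupling_gain phase-pulling rate (rad/s) at `kappa = 1`
#'   (default 5): the phase-difference concentration grows with
#'   `coupling_gain * kappa / noise_level^2`.
#' @param seed integer seed.
#' @return An object of class `coupled_signal_spec`.
#' @export
coupled_signal_spec <- function(n_channels, fs = 256, duration = 20,
                                carrier_band = c(6, 9), coupling = 0,
                                noise_level = 1, coupling_gain = 5,
                                seed = 1) {
  stopifnot(n_channels >= 1, fs > 0, duration > 0)
  if (length(coupling) == 1) {
    k <- matrix(coupling, n_channels, n_channels)
    diag(k) <- 0
    coupling <- k
  }
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != n_channels || ncol(coupling) != n_channels)
    stop("`coupling` must be n_channels x n_channels")
  if (!isSymmetric(unname(coupling), tol = 1e-10) ||
      any(diag(coupling) != 0))
    stop("`coupling` must be symmetric with zero diagonal")
  if (any(coupling < 0 | coupling > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (noise_level < 0) stop("`noise_level` must be >= 0")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration,
                 carrier_band = sort(as.numeric(carrier_band)),
                 coupling = coupling, noise_level = noise_level,
                 coupling_gain = coupling_gain, seed = seed),
            class = "coupled_signal_spec")
}

#' Generate phase-coupled narrow-band signals
#'
#' Each channel is `sin(theta_i(t))` plus broadband observation noise,
#' where the phases follow coupled stochastic dynamics
#' \deqn{d\theta_i = 2\pi f_0\,dt + g \sum_j \kappa_{ij}
#'   \sin(\theta_j - \theta_i)\,dt + \sigma_\theta \sqrt{dt}\,\eta_i}
#' with common carrier `f_0`, pulling gain `g = coupling_gain`, and phase
#' diffusion `sigma_theta = noise_level`.  All phases start at 0, so with
#' `kappa = 1` everywhere and zero noise the channels are identical; with
#' `kappa = 0` the phases diffuse independently and the PLF between
#' channels decays toward its small-sample floor.
#'
#' @param spec a [coupled_signal_spec()].
#' @return A [signal_set()].
#' @export
generate_coupled_signals <- function(spec) {
  stopifnot(inherits(spec, "coupled_signal_spec"))
  n <- spec$n_channels
  dt <- 1 / spec$fs
  nt <- round(spec$duration * spec$fs)
  f0 <- mean(spec$carrier_band)
  with_seed(spec$seed, {
    theta <- matrix(0, n, nt)
    ph <- rep(0, n)
    sig_step <- spec$noise_level * sqrt(dt)
    for (k in seq_len(nt)) {
      pull <- vapply(seq_len(n), function(i)
        sum(spec$coupling[i, ] * sin(ph - ph[i])), numeric(1))
      ph <- ph + 2 * pi * f0 * dt + spec$coupling_gain * pull * dt +
        sig_step * rnorm(n)
      theta[, k] <- ph
    }
    x <- sin(theta)
    if (spec$noise_level > 0)
      x <- x + matrix(rnorm(n * nt, sd = 0.1 * spec$noise_level), n, nt)
    signal_set(x, spec$fs)
  })
}

#' Random binary network with exact mean degree
#'
#' Uniformly samples a simple undirected graph with a fixed number of
#' edges (Erdős–Rényi G(n, m)) so that the binary mean degree
#' `2 m / n` hits the requested value exactly; used for degree sweeps
#' where the target MD lies outside what `[0, 1]`-weighted networks can
#' reach.
#'
#' @param n_nodes number of nodes.
#' @param mean_degree target binary mean degree; `mean_degree * n_nodes / 2`
#'   is rounded to the nearest integer edge count.
#' @param seed optional integer seed.
#' @return A [binary_network()].
#' @export
random_binary_network <- function(n_nodes, mean_degree, seed = NULL) {
  stopifnot(n_nodes >= 2)
  m <- round(mean_degree * n_nodes / 2)
  if (m < 1 || m > n_nodes * (n_nodes - 1) / 2)
    stop("`mean_degree` out of range for this node count")
  g <- with_seed(seed, igraph::sample_gnm(n_nodes, m))
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  binary_network(adj, provenance = list(model = "gnm", m = m, seed = seed))
}
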