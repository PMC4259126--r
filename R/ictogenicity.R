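#' Label background vs seizure samples of a trajectory
#'
#' A node is in the model seizure state when its oscillation has local
#' extrema of magnitude greater than `threshold` (default 0.5, which
#' separates the background fixed point from the stable limit cycle at the
#' default operating point).  Because the limit cycle is circular (`|Z|`
#' constant on it), the extrema of the real part exceed the threshold
#' exactly when the envelope `|Z|` does, so the default `"modulus"` method
#' labels sample `t` of node `i` seizure when `|Z_i(t)| > threshold`.  The
#' `"extrema"` method implements the windowed local-extrema criterion
#' literally on the real part, for non-circular regimes.
#'
#' @param trajectory a `complex_trajectory` from [simulate_network()].
#' @param threshold magnitude threshold (default 0.5).
#' @param method `"modulus"` (default) or `"extrema"`.
#' @param window for `"extrema"`: width, in samples, of the centered window
#'   within which a suprathreshold extremum marks a sample as seizure.
#'   Defaults to one oscillation period `round(2*pi/omega/dt)` of the
#'   node's own frequency.
#' @return An object of class `state_labels`: list with `labels` (N x T
#'   logical matrix), `threshold`, `method`, `dt`.
#' @export
classify_states <- function(trajectory, threshold = 0.5,
                            method = c("modulus", "extrema"),
                            window = NULL) {
  stopifnot(inherits(trajectory, "complex_trajectory"))
  method <- match.arg(method)
  threshold <- check_scalar(threshold, "threshold")
  if (threshold <= 0) stop("`threshold` must be > 0")
  st <- trajectory$states
  if (any(!is.finite(Re(st))) || any(!is.finite(Im(st))))
    stop("trajectory contains non-finite values")
  nt <- ncol(st)
  if (method == "modulus") {
    labels <- Mod(st) > threshold
  } else {
    labels <- matrix(FALSE, nrow(st), nt)
    for (i in seq_len(nrow(st))) {
      w <- window
      if (is.null(w))
        w <- round(2 * pi / abs(trajectory$node_frequencies[i]) /
                     trajectory$dt)
      w <- max(1L, as.integer(w))
      if (w > nt) stop("`window` exceeds trajectory length")
      x <- Re(st[i, ])
      d <- diff(x)
      ext <- which(d[-length(d)] * d[-1] <= 0 & (d[-length(d)] != 0)) + 1L
      ext <- ext[abs(x[ext]) > threshold]
      if (length(ext)) {
        half <- w %/% 2L
        hit <- logical(nt)
        for (e in ext)
          hit[max(1L, e - half):min(nt, e + half)] <- TRUE
        labels[i, ] <- hit
      }
    }
  }
  dimnames(labels) <- dimnames(st)
  structure(list(labels = labels, threshold = threshold, method = method,
                 dt = trajectory$dt),
            class = "state_labels")
}

#' Brain network ictogenicity of labeled trajectories
#'
#' For each node, the fraction of simulation time spent in the seizure
#' (limit-cycle) state; the BNI is the mean of these fractions over nodes —
#' the probability that a node picked at random at a random time is in the
#' seizure state.
#'
#' @param labels a `state_labels` object from [classify_states()].
#' @return An object of class `bni_result`: `node_fractions` (per-node time
#'   fractions in `[0, 1]`), `bni` (their mean), `n_sims = 1`.
#' @export
compute_bni <- function(labels) {
  stopifnot(inherits(labels, "state_labels"))
  if (length(labels$labels) == 0) stop("empty state labels")
  frac <- rowMeans(labels$labels)
  structure(list(node_fractions = frac, bni = mean(frac), n_sims = 1L,
                 per_sim_bni = mean(frac)),
            class = "bni_result")
}

#' @export
print.bni_result <- function(x, ...) {
  cat(sprintf("<bni_result> BNI = %.4f over %d node(s), %d simulation(s)\n",
              x$bni, length(x$node_fractions), x$n_sims))
  invisible(x)
}

#' Ensemble BNI of a network
#'
#' Runs `n_sims` independent simulations of the network (fresh initial
#' conditions, node-frequency jitter and noise for each, under seeds
#' derived deterministically from `seed`), scores each with
#' [classify_states()] + [compute_bni()], and averages.
#'
#' @inheritParams simulate_network
#' @param n_sims number of replicate simulations.
#' @param seed master integer seed for the ensemble.
#' @param threshold seizure-state magnitude threshold.
#' @return A `bni_result` whose `bni` is the ensemble mean, with
#'   `per_sim_bni` (length `n_sims`) and `node_fractions` averaged over
#'   replicates.
#' @export
bni_ensemble <- function(coupling, params = node_parameters(),
                         noise = noise_spec(), config = sim_config(),
                         n_sims = 30, seed = 1, threshold = 0.5,
                         freq_half_width = 0.2) {
  stopifnot(n_sims >= 1)
  seeds <- derive_seeds(seed, n_sims)
  per_sim <- numeric(n_sims)
  frac_sum <- NULL
  for (k in seq_len(n_sims)) {
    cfg <- config
    cfg$seed <- seeds[k]
    tr <- tryCatch(
      simulate_network(params, coupling, noise, cfg,
                       freq_half_width = freq_half_width),
      error = function(e)
        stop(sprintf("simulation replicate %d failed: %s", k,
                     conditionMessage(e)), call. = FALSE)
    )
    res <- compute_bni(classify_states(tr, threshold = threshold))
    per_sim[k] <- res$bni
    frac_sum <- if (is.null(frac_sum)) res$node_fractions
                else frac_sum + res$node_fractions
  }
  structure(list(node_fractions = frac_sum / n_sims, bni = mean(per_sim),
                 n_sims = as.integer(n_sims), per_sim_bni = per_sim),
            class = "bni_result")
}
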