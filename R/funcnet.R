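#' Multichannel signal container
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param labels channel names (defaults to rownames or `ch_1 ...`).
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  fs <- check_scalar(fs, "fs")
  if (fs <= 0) stop("`fs` must be > 0")
  if (any(!is.finite(data))) stop("`data` contains non-finite samples")
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("ch_", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("`labels` must match channel count")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

butter_filter <- function(signals, low, high, type) {
  stopifnot(inherits(signals, "signal_set"))
  low <- check_scalar(low, "low"); high <- check_scalar(high, "high")
  nyq <- signals$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                 low, high, nyq))
  filt <- signal::butter(4, c(low, high) / nyq, type = type)
  out <- t(apply(signals$data, 1, function(x) signal::filtfilt(filt, x)))
  signal_set(out, signals$fs, signals$labels)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass.
#'
#' @param signals a [signal_set()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return Filtered `signal_set` of the same shape.
#' @export
bandpass <- function(signals, low, high) {
  butter_filter(signals, low, high, "pass")
}

#' Zero-phase notch (band-stop) filter
#'
#' Forward-backward 4th-order Butterworth band-stop, e.g. 48-52 Hz to
#' remove mains interference.
#'
#' @inheritParams bandpass
#' @export
notch <- function(signals, low, high) {
  butter_filter(signals, low, high, "stop")
}

# analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of each channel and returns its phase,
#' wrapped to `(-pi, pi]`.  Signals should be band-limited first (see
#' [bandpass()]); the phase of a broadband signal is not meaningful.
#'
#' @param signals a [signal_set()].
#' @return An object of class `phase_series`: `phases` (channels x samples,
#'   radians), `fs`, `labels`, `n_samples`.
#' @export
instantaneous_phase <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  sds <- apply(signals$data, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant channel(s) %s: instantaneous phase undefined",
                 paste(signals$labels[sds == 0], collapse = ", ")))
  phases <- t(apply(signals$data, 1, function(x) Arg(analytic_signal(x))))
  rownames(phases) <- signals$labels
  structure(list(phases = phases, fs = signals$fs, labels = signals$labels,
                 n_samples = ncol(phases)),
            class = "phase_series")
}

#' Phase-locking factor between two channels
#'
#' The PLF (also called phase-locking value or mean phase coherence) is the
#' modulus of the time-averaged unit phasor of the instantaneous phase
#' difference,
#' \deqn{c_{ij} = \left|\frac{1}{N_s}\sum_{k=1}^{N_s}
#'   e^{i\Delta\phi_{ij}(t_k)}\right|,}
#' equal to 1 for a constant phase lag and near 0 for independent phases.
#'
#' @param phases a `phase_series` from [instantaneous_phase()].
#' @param i,j channel indices or labels.
#' @return PLF value in `[0, 1]`; symmetric in `(i, j)`.
#' @export
plf <- function(phases, i, j) {
  stopifnot(inherits(phases, "phase_series"))
  if (phases$n_samples < 1) stop("empty phase series")
  if (is.character(i)) i <- match(i, phases$labels)
  if (is.character(j)) j <- match(j, phases$labels)
  dphi <- phases$phases[i, ] - phases$phases[j, ]
  Mod(mean(exp(1i * dphi)))
}

plf_matrix <- function(phases) {
  e <- exp(1i * phases$phases)
  m <- Mod(e %*% Conj(t(e))) / phases$n_samples
  m <- pmin(m, 1)
  diag(m) <- 0
  m <- (m + t(m)) / 2
  dimnames(m) <- list(phases$labels, phases$labels)
  m
}

#' Build a PLF functional network from multichannel signals
#'
#' Pipeline: optional broadband preprocessing (band-pass + notch), analysis
#' band-pass, Hilbert instantaneous phase, edge trimming, then pairwise PLF
#' for every channel pair.  Nodes are channels; edge weights are PLF
#' values.  The self-PLF (identically 1) is excluded: the diagonal is zero
#' so that node degrees count only true edges.
#'
#' @param signals a [signal_set()].
#' @param band analysis band in Hz, e.g. `c(6, 9)` for the low-alpha band.
#' @param preproc_band optional broadband band-pass applied first (e.g.
#'   `c(1, 70)`); `NULL` to skip.
#' @param notch_band optional band-stop applied after `preproc_band` (e.g.
#'   `c(48, 52)` for mains); `NULL` to skip.
#' @param edge_trim seconds discarded from each end of the phase series
#'   before PLF, to suppress Hilbert/filter end transients (default 0.5 s).
#' @return A [functional_network()].
#' @export
build_functional_network <- function(signals, band = c(6, 9),
                                     preproc_band = NULL, notch_band = NULL,
                                     edge_trim = 0.5) {
  stopifnot(inherits(signals, "signal_set"))
  if (nrow(signals$data) < 2)
    stop("at least 2 channels are required to build a network")
  if (!is.null(preproc_band))
    signals <- bandpass(signals, preproc_band[1], preproc_band[2])
  if (!is.null(notch_band))
    signals <- notch(signals, notch_band[1], notch_band[2])
  signals <- bandpass(signals, band[1], band[2])
  ph <- instantaneous_phase(signals)
  trim <- round(edge_trim * signals$fs)
  if (2 * trim >= ph$n_samples)
    stop("`edge_trim` leaves no samples")
  if (trim > 0) {
    keep <- (trim + 1):(ph$n_samples - trim)
    ph$phases <- ph$phases[, keep, drop = FALSE]
    ph$n_samples <- length(keep)
  }
  functional_network(plf_matrix(ph), labels = signals$labels)
}
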