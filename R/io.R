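#' Read / write square connectivity matrices as CSV
#'
#' The shared matrix dialect: a square CSV with a header row of node
#' labels and the labels repeated in the first column.
#'
#' @param path file path.
#' @param network a `functional_network`, `binary_network`, or bare matrix.
#' @return `read_network_csv()` returns a [functional_network()] when any
#'   weight is fractional, otherwise a [binary_network()].
#' @export
read_network_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (is_binary_adj(m)) binary_network(m, labels = rownames(m))
  else functional_network(m, labels = rownames(m))
}

#' @rdname read_network_csv
#' @export
write_network_csv <- function(network, path) {
  a <- if (is.matrix(network)) network else network$adjacency
  write.csv(as.data.frame(a), path, row.names = TRUE)
  invisible(path)
}

#' Read / write multichannel signals as CSV
#'
#' Rows are channels (first column the channel label); the sampling rate
#' travels in a `# fs: <Hz>` comment on the first line.
#'
#' @param path file path.
#' @param signals a [signal_set()].
#' @return `read_signals_csv()` returns a [signal_set()].
#' @export
read_signals_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*fs:", first))
    stop("signals CSV must start with a '# fs: <Hz>' line")
  fs <- as.numeric(sub("^#\\s*fs:\\s*", "", first))
  df <- read.csv(path, skip = 1, header = FALSE, row.names = 1)
  signal_set(as.matrix(df), fs, labels = rownames(df))
}

#' @rdname read_signals_csv
#' @export
write_signals_csv <- function(signals, path) {
  stopifnot(inherits(signals, "signal_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", signals$fs), con)
  utils::write.table(signals$data, con, sep = ",", col.names = FALSE,
                     row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as CSV with a JSON config sidecar
#'
#' Writes `time, node_<label>_re, node_<label>_im, ...` columns, and a
#' `<path>.json` sidecar echoing the provenance supplied in `config` so a
#' run can be reproduced.
#'
#' @param trajectory a `complex_trajectory`.
#' @param path output CSV path.
#' @param config optional list echoed to the JSON sidecar.
#' @export
write_trajectory_csv <- function(trajectory, path, config = NULL) {
  stopifnot(inherits(trajectory, "complex_trajectory"))
  st <- trajectory$states
  out <- data.frame(time = trajectory$times)
  for (i in seq_len(nrow(st))) {
    out[[paste0("node_", trajectory$labels[i], "_re")]] <- Re(st[i, ])
    out[[paste0("node_", trajectory$labels[i], "_im")]] <- Im(st[i, ])
  }
  write.csv(out, path, row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
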