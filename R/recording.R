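#' Multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, µV.
#' @param sampling_rate Hz.
#' @param channels character channel labels (defaults to `Ch01`...).
#' @param referenced logical; average reference applied.
#' @param band optional 2-vector recording the band-pass applied (Hz).
#'
#' @return An object of class `irritmap_recording`.
#' @export
new_recording <- function(data, sampling_rate, channels = NULL,
                          referenced = FALSE, band = NULL) {
  data <- as.matrix(data)
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (!all(is.finite(data))) {
    stop_irritmap("Recording data must be finite.", "irritmap_config_error")
  }
  if (is.null(channels)) channels <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channels) != nrow(data)) {
    stop_irritmap("Channel labels must match the channel count.",
                  "irritmap_config_error")
  }
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = as.character(channels),
                 referenced = isTRUE(referenced), band = band),
            class = "irritmap_recording")
}

#' @export
print.irritmap_recording <- function(x, ...) {
  cat(sprintf("<irritmap_recording> %d channels x %d samples @ %g Hz%s%s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              if (!is.null(x$band)) sprintf(", band %g-%g Hz", x$band[1],
                                            x$band[2]) else "",
              if (x$referenced) ", average-referenced" else ""))
  invisible(x)
}

#' Convert a recording to a long tibble
#'
#' @param x an `irritmap_recording`.
#' @param ... unused.
#' @return A tibble with columns `time_s`, `channel`, `value_uV`.
#' @export
as_tibble.irritmap_recording <- function(x, ...) {
  nt <- ncol(x$data)
  tibble::tibble(
    time_s = rep((seq_len(nt) - 1L) / x$sampling_rate, each = nrow(x$data)),
    channel = rep(x$channels, nt),
    value_uV = as.vector(x$data))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Butterfly plot of a recording
#'
#' @param object an `irritmap_recording`.
#' @param channels optional subset of channel labels.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.irritmap_recording <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value_uV,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "potential (µV)") +
    ggplot2::theme_minimal()
}

#' Read / write a recording as a delimited matrix
#'
#' Tab-separated text with one row per channel; the first column holds the
#' channel label. The sampling rate is stored on a `# sampling_rate_hz:`
#' comment line.
#'
#' @param path file path.
#' @return `read_recording()` returns an `irritmap_recording`.
#' @export
read_recording <- function(path) {
  first <- readLines(path, n = 1L)
  fs <- as.numeric(sub("^#\\s*sampling_rate_hz:\\s*", "", first))
  tab <- utils::read.table(path, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE)
  new_recording(as.matrix(tab[, -1L]), fs, channels = tab[, 1L])
}

#' @rdname read_recording
#' @param rec an `irritmap_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "irritmap_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate), con)
  utils::write.table(data.frame(rec$channels, rec$data), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
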