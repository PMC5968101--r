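#' Lead-field container
#'
#' A lead field is the linear map from dipole source moments (nA·m) to scalp
#' electrode potentials (µV). For free-orientation source spaces the gain
#' matrix has one column triplet (x, y, z moment) per source; for
#' fixed-orientation spaces one column per source.
#'
#' @param gain numeric matrix, electrodes x (sources * 3) or electrodes x
#'   sources.
#' @param n_sources number of sources the columns describe.
#' @param orientation `"free"` or `"fixed"`.
#' @param referenced logical; `TRUE` once the average reference has been
#'   applied (every column then sums to zero).
#' @param electrodes character vector of electrode labels (optional).
#'
#' @return An object of class `irritmap_leadfield`.
#' @export
new_leadfield <- function(gain, n_sources, orientation = c("free", "fixed"),
                          referenced = FALSE, electrodes = NULL) {
  orientation <- match.arg(orientation)
  gain <- as.matrix(gain)
  if (!all(is.finite(gain))) {
    stop_irritmap("Lead-field gain must be finite.", "irritmap_model_error")
  }
  expected <- if (orientation == "free") 3L * n_sources else n_sources
  if (ncol(gain) != expected) {
    stop_irritmap("Gain column count does not match the source space.",
                  "irritmap_model_error")
  }
  structure(
    list(gain = gain, n_sources = as.integer(n_sources),
         orientation = orientation, referenced = isTRUE(referenced),
         electrodes = electrodes,
         units = list(position = "mm", moment = "nA*m", potential = "uV")),
    class = "irritmap_leadfield")
}

#' @export
print.irritmap_leadfield <- function(x, ...) {
  cat(sprintf("<irritmap_leadfield> %d electrodes x %d sources (%s orientation)%s\n",
              nrow(x$gain), x$n_sources, x$orientation,
              if (x$referenced) ", average-referenced" else ""))
  invisible(x)
}

#' Apply the average reference
#'
#' Removes the common mode across electrodes: recordings have the per-sample
#' across-channel mean subtracted, lead fields have the per-column mean
#' subtracted. The operation is idempotent and is required before solving the
#' EEG inverse problem (the inverse is only well posed up to a reference).
#'
#' @param x an `irritmap_leadfield` or `irritmap_recording`.
#' @return The same type of object, average-referenced.
#' @export
apply_average_reference <- function(x) {
  UseMethod("apply_average_reference")
}

#' @export
apply_average_reference.irritmap_leadfield <- function(x) {
  if (nrow(x$gain) < 2L) {
    stop_irritmap("Average reference needs at least 2 electrodes.",
                  "irritmap_reference_error")
  }
  x$gain <- sweep(x$gain, 2L, colMeans(x$gain))
  x$referenced <- TRUE
  x
}

#' @export
apply_average_reference.irritmap_recording <- function(x) {
  if (nrow(x$data) < 2L) {
    stop_irritmap("Average reference needs at least 2 electrodes.",
                  "irritmap_reference_error")
  }
  x$data <- sweep(x$data, 2L, colMeans(x$data))
  x$referenced <- TRUE
  x
}

#' @export
apply_average_reference.default <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2L) {
    stop_irritmap("Average reference needs at least 2 electrodes.",
                  "irritmap_reference_error")
  }
  sweep(m, 2L, colMeans(m))
}

#' Save / load a lead field
#'
#' The gain matrix is stored as little-endian doubles with a JSON sidecar
#' (`<path>.json`) recording the shape, units and referenced flag, so cached
#' lead fields are portable across platforms.
#'
#' @param lf an `irritmap_leadfield`.
#' @param path file path for the binary payload.
#' @return `save_leadfield()` returns `path` invisibly; `load_leadfield()`
#'   returns the restored `irritmap_leadfield`.
#' @export
save_leadfield <- function(lf, path) {
  stopifnot(inherits(lf, "irritmap_leadfield"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(lf$gain), con, size = 8L, endian = "little")
  meta <- list(n_electrodes = nrow(lf$gain), n_columns = ncol(lf$gain),
               n_sources = lf$n_sources, orientation = lf$orientation,
               referenced = lf$referenced, electrodes = lf$electrodes,
               units = lf$units)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_leadfield
#' @export
load_leadfield <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- meta$n_electrodes * meta$n_columns
  g <- readBin(con, "double", n = n, size = 8L, endian = "little")
  gain <- matrix(g, nrow = meta$n_electrodes, ncol = meta$n_columns)
  new_leadfield(gain, n_sources = meta$n_sources,
                orientation = meta$orientation, referenced = meta$referenced,
                electrodes = unlist(meta$electrodes))
}
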