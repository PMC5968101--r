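#' Electrode montage
#'
#' @param names character vector of unique electrode labels.
#' @param positions numeric matrix (electrodes x 3) of positions in mm.
#'
#' @return An object of class `irritmap_montage`.
#' @export
montage <- function(names, positions) {
  positions <- as.matrix(positions)
  if (anyDuplicated(names)) {
    stop_irritmap("Electrode labels must be unique.", "irritmap_config_error")
  }
  if (nrow(positions) != length(names) || ncol(positions) != 3L ||
      !all(is.finite(positions))) {
    stop_irritmap("`positions` must be a finite (electrodes x 3) matrix.",
                  "irritmap_config_error")
  }
  structure(list(names = as.character(names), positions = positions),
            class = "irritmap_montage")
}

#' @export
print.irritmap_montage <- function(x, ...) {
  cat(sprintf("<irritmap_montage> %d electrodes\n", length(x$names)))
  invisible(x)
}

#' Read / write a montage file
#'
#' Plain whitespace-delimited `label x y z` coordinate files (mm).
#'
#' @param path file path.
#' @return `read_montage()` returns an `irritmap_montage`.
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' @rdname read_montage
#' @param m an `irritmap_montage`.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "irritmap_montage"))
  df <- data.frame(label = m$names, m$positions)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Spherical-cap electrode layout
#'
#' Places `n` electrodes quasi-uniformly (Fibonacci lattice) on the upper cap
#' of a sphere, emulating a rodent EEG mini-cap. Used to build simulation and
#' test geometries.
#'
#' @param n number of electrodes.
#' @param radius sphere radius (mm).
#' @param center sphere center (mm).
#' @param cap_fraction fraction of the sphere's polar angle covered by the cap
#'   (1 = full upper hemisphere and a bit below; default 0.95).
#' @return An `irritmap_montage`.
#' @export
cap_montage <- function(n = 32, radius = 9.2, center = c(0, 0, 0),
                        cap_fraction = 0.95) {
  i <- seq_len(n) - 0.5
  # z spans the upper cap; golden-angle azimuths avoid alignment artifacts
  z <- 1 - cap_fraction * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(s * cos(phi), s * sin(phi), z)
  pos <- sweep(pos, 2L, -center)
  montage(sprintf("E%02d", seq_len(n)), pos)
}
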