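#' Discretized cortical source space
#'
#' @param positions numeric matrix (sources x 3), mm.
#' @param orientations optional numeric matrix (sources x 3) of unit dipole
#'   orientations; `NULL` for free-orientation sources.
#' @param parcel_ids integer region id per source (cortical-structure
#'   convention: right ids 1-48, left ids 49-96).
#'
#' @return An object of class `irritmap_source_space`.
#' @export
source_space <- function(positions, orientations = NULL, parcel_ids = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !all(is.finite(positions))) {
    stop_irritmap("`positions` must be a finite (sources x 3) matrix.",
                  "irritmap_config_error")
  }
  n <- nrow(positions)
  if (!is.null(orientations)) {
    orientations <- as.matrix(orientations)
    if (!all(dim(orientations) == c(n, 3L))) {
      stop_irritmap("`orientations` must match `positions` in shape.",
                    "irritmap_config_error")
    }
    nrm <- row_norms(orientations)
    if (any(abs(nrm - 1) > 1e-6)) {
      stop_irritmap("`orientations` must be unit vectors.",
                    "irritmap_config_error")
    }
  }
  if (is.null(parcel_ids)) parcel_ids <- rep(NA_integer_, n)
  structure(list(positions = positions, orientations = orientations,
                 parcel_ids = as.integer(parcel_ids), n = n),
            class = "irritmap_source_space")
}

#' @export
print.irritmap_source_space <- function(x, ...) {
  cat(sprintf("<irritmap_source_space> %d sources (%s orientation), %d parcels\n",
              x$n, if (is.null(x$orientations)) "free" else "fixed",
              length(unique(stats::na.omit(x$parcel_ids)))))
  invisible(x)
}

#' Mirrored-parcel source space on a spherical shell
#'
#' Builds a toy cortical source space on the upper cap of a sphere, split into
#' left/right mirrored parcels whose ids follow the atlas pairing convention
#' (right ids 1-48, left partner = right id + 48). Sources sit at a fixed
#' eccentricity with radial orientations (optional). Used for simulations and
#' fixtures where no template head geometry is available.
#'
#' @param n_per_parcel sources per parcel.
#' @param parcels_per_hemi number of parcels per hemisphere (<= 48).
#' @param radius source shell radius (mm).
#' @param center sphere center.
#' @param fixed logical; if `TRUE`, sources get radial unit orientations.
#' @param right_ids atlas ids to use for the right-hemisphere parcels
#'   (defaults to `1:parcels_per_hemi`); left partners are `right_ids + 48`.
#' @return A list with the `irritmap_source_space` and its
#'   [parcellation()] table.
#' @export
mirrored_source_space <- function(n_per_parcel = 12, parcels_per_hemi = 8,
                                  radius = 6.3, center = c(0, 0, 0),
                                  fixed = FALSE,
                                  right_ids = seq_len(parcels_per_hemi)) {
  stopifnot(parcels_per_hemi <= 48, length(right_ids) == parcels_per_hemi)
  # parcel seeds: bands of azimuth on the y > 0 (left) cap, mirrored to y < 0
  pos <- NULL; ids <- NULL
  for (p in seq_len(parcels_per_hemi)) {
    # deterministic lattice within an azimuthal wedge of the left upper cap
    k <- seq_len(n_per_parcel) - 1L
    rows <- ceiling(sqrt(n_per_parcel))
    cols <- ceiling(n_per_parcel / rows)
    i <- k %% rows
    j <- k %/% rows
    theta <- acos(0.40 + 0.50 * (i + 0.5) / rows)
    # keep parcels in a lateral band (azimuth 30-150 deg) so left/right
    # mirrored parcels never abut the midline
    phi <- pi / 6 + (2 * pi / 3) * ((p - 1) + (j + 0.5) / cols) /
      parcels_per_hemi
    left <- radius * cbind(cos(phi) * sin(theta), sin(phi) * sin(theta),
                           cos(theta))
    right <- left * matrix(rep(c(1, -1, 1), each = n_per_parcel), ncol = 3)
    pos <- rbind(pos, left, right)
    ids <- c(ids, rep(right_ids[p] + 48L, n_per_parcel),
             rep(right_ids[p], n_per_parcel))
  }
  pos <- sweep(pos, 2L, -as.numeric(center))
  orient <- if (fixed) sweep(pos, 2L, as.numeric(center)) / radius else NULL
  ss <- source_space(pos, orientations = orient, parcel_ids = ids)
  list(sources = ss, parcellation = parcellation(used_ids = sort(right_ids)))
}
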