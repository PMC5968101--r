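#' Boundary-element lead field
#'
#' Computes the electrodes x sources gain matrix for a nested-compartment
#' head model by a double-layer collocation BEM. Surface potentials are
#' interpolated linearly from vertex values; the rank-1 null space of the
#' exterior Neumann problem (potentials defined up to a constant) is removed
#' by deflation. Electrodes are snapped to the nearest vertex of the
#' outermost (scalp) surface.
#'
#' @param surfaces an [surface_set()], innermost surface first.
#' @param montage an [montage()].
#' @param sources an [source_space()]; all sources must be strictly inside
#'   the innermost surface.
#' @param snap_tol_mm maximum allowed electrode snap distance (mm).
#' @param reference apply the average reference to the result (default TRUE).
#' @param verbose log electrode snap distances.
#' @return An [new_leadfield()] (µV per nA·m).
#' @export
bem_leadfield <- function(surfaces, montage, sources, snap_tol_mm = 2,
                          reference = TRUE, verbose = FALSE) {
  stopifnot(inherits(surfaces, "irritmap_surface_set"),
            inherits(montage, "irritmap_montage"),
            inherits(sources, "irritmap_source_space"))
  ns <- length(surfaces$surfaces)
  sigma <- surfaces$conductivities
  inner <- surfaces$surfaces[[1L]]
  w <- winding_fraction(inner, sources$positions)
  if (any(abs(w - 1) > 1e-6)) {
    stop_irritmap("All sources must be strictly inside the innermost surface.",
                  "irritmap_geometry_error")
  }

  verts <- do.call(rbind, lapply(surfaces$surfaces, function(m) m$vertices))
  nvert <- vapply(surfaces$surfaces, function(m) nrow(m$vertices), integer(1))
  offs <- cumsum(c(0L, nvert))
  faces <- do.call(rbind, lapply(seq_len(ns), function(k) {
    surfaces$surfaces[[k]]$faces + offs[k]
  }))
  vert_surface <- rep.int(seq_len(ns), nvert)
  face_surface <- rep.int(seq_len(ns), vapply(surfaces$surfaces,
                                              function(m) nrow(m$faces),
                                              integer(1)))

  D <- bem_assemble_dl(verts, faces - 1L, vert_surface, face_surface)
  # sigma inside surface k is sigma[k]; outside surface k it is sigma[k+1]
  # (0 beyond the scalp)
  sigma_out <- c(sigma[-1L], 0)
  dsig <- sigma - sigma_out
  A <- -D %*% diag(dsig[vert_surface] / (4 * pi))
  diag(A) <- diag(A) + sigma[vert_surface]
  # deflation of the constant null space
  A <- A + mean(sigma) / nrow(A)

  # snap electrodes to scalp vertices
  scalp_idx <- which(vert_surface == ns)
  scalp <- verts[scalp_idx, , drop = FALSE]
  eidx <- integer(nrow(montage$positions))
  for (e in seq_along(eidx)) {
    d2 <- colSums((t(scalp) - montage$positions[e, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > snap_tol_mm) {
      stop_irritmap(sprintf(
        "Electrode %s is %.2f mm from the scalp mesh (tolerance %.2f mm).",
        montage$names[e], sqrt(d2[j]), snap_tol_mm),
        "irritmap_geometry_error")
    }
    if (verbose) {
      message(sprintf("electrode %s snapped by %.3f mm", montage$names[e],
                      sqrt(d2[j])))
    }
    eidx[e] <- scalp_idx[j]
  }

  # transfer matrix: rows of A^-1 at electrode vertices
  E <- matrix(0, nrow(A), length(eidx))
  E[cbind(eidx, seq_along(eidx))] <- 1
  Tm <- tryCatch(t(solve(t(A), E)), error = function(e) {
    stop_irritmap("BEM system is singular after deflation.",
                  "irritmap_numerical_error")
  })

  # primary (infinite-medium) potentials at collocation points, unit moments
  npt <- nrow(verts)
  nsrc <- sources$n
  V0 <- matrix(0, npt, 3L * nsrc)
  for (s in seq_len(nsrc)) {
    d <- sweep(verts, 2L, sources$positions[s, ])
    r3 <- row_norms(d)^3
    V0[, (3 * s - 2):(3 * s)] <- d / r3 / (4 * pi)
  }
  gain <- Tm %*% V0
  lf <- collapse_orientation(gain, sources)
  lf <- new_leadfield(lf$gain, nsrc, lf$orientation,
                      electrodes = montage$names)
  if (reference) lf <- apply_average_reference(lf)
  lf
}
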