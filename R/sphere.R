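#' Multi-shell sphere head model
#'
#' Concentric-shell conductor model (e.g., brain / skull / scalp). Shell
#' `radii` are the outer radii of each compartment, innermost first;
#' `conductivities` are per-compartment values in S/m. Potentials are computed
#' from the truncated Legendre-series solution of the Poisson problem with an
#' insulating exterior.
#'
#' @param center sphere center, mm.
#' @param radii strictly increasing outer shell radii, mm.
#' @param conductivities per-shell conductivities, S/m (same length as
#'   `radii`).
#' @param series_terms truncation order of the Legendre series (terms are also
#'   dropped early once their contribution falls below 1e-12 of the running
#'   sum).
#' @return An object of class `irritmap_sphere_model`.
#' @export
sphere_model <- function(center = c(0, 0, 0), radii = c(7.9, 8.6, 9.2),
                         conductivities = c(0.33, 0.165, 0.33),
                         series_terms = 100L) {
  if (length(radii) != length(conductivities) || length(radii) < 1L) {
    stop_irritmap("`radii` and `conductivities` must have equal length >= 1.",
                  "irritmap_model_error")
  }
  if (any(diff(radii) <= 0)) {
    stop_irritmap("Shell radii must be strictly increasing.",
                  "irritmap_model_error")
  }
  if (any(conductivities <= 0)) {
    stop_irritmap("Conductivities must be strictly positive.",
                  "irritmap_model_error")
  }
  if (series_terms < 1L) {
    stop_irritmap("`series_terms` must be >= 1.", "irritmap_model_error")
  }
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 conductivities = as.numeric(conductivities),
                 series_terms = as.integer(series_terms)),
            class = "irritmap_sphere_model")
}

#' @export
print.irritmap_sphere_model <- function(x, ...) {
  cat(sprintf("<irritmap_sphere_model> %d shells, radii %s mm\n",
              length(x$radii), paste(signif(x$radii, 4), collapse = "/")))
  invisible(x)
}

# Per-degree surface transfer coefficients u_n for a multi-shell sphere.
# In units of the outermost radius: compartment j potential is
# A_j rho^n + B_j rho^-(n+1); compartment 1 carries the unit primary term
# rho^-(n+1). Returns u_n = A_N + B_N at rho = 1 for n = 1..n_max.
shell_transfer <- function(radii, sigma, n_max) {
  nshell <- length(radii)
  rho <- radii / radii[nshell]
  u <- numeric(n_max)
  for (n in seq_len(n_max)) {
    if (nshell == 1L) {
      # insulating exterior: sigma * (n A - (n+1) B) = 0 with B = 1
      u[n] <- (n + 1) / n + 1
      next
    }
    # unknowns: A_1, A_2, B_2, ..., A_N, B_N  -> 2*nshell - 1
    m <- matrix(0, 2 * nshell - 1, 2 * nshell - 1)
    b <- numeric(2 * nshell - 1)
    idxA <- function(j) if (j == 1L) 1L else 2L * j - 2L
    idxB <- function(j) 2L * j - 1L  # j >= 2
    row <- 0L
    for (j in seq_len(nshell - 1L)) {
      r <- rho[j]
      pr <- r^n; qr <- r^-(n + 1)
      dpr <- n * r^(n - 1); dqr <- -(n + 1) * r^-(n + 2)
      # continuity of V
      row <- row + 1L
      m[row, idxA(j)] <- pr
      if (j > 1L) m[row, idxB(j)] <- qr
      m[row, idxA(j + 1L)] <- -pr
      m[row, idxB(j + 1L)] <- -qr
      b[row] <- if (j == 1L) -qr else 0
      # continuity of sigma dV/dr
      row <- row + 1L
      m[row, idxA(j)] <- sigma[j] * dpr
      if (j > 1L) m[row, idxB(j)] <- sigma[j] * dqr
      m[row, idxA(j + 1L)] <- -sigma[j + 1L] * dpr
      m[row, idxB(j + 1L)] <- -sigma[j + 1L] * dqr
      b[row] <- if (j == 1L) -sigma[1L] * dqr else 0
    }
    # insulating exterior at rho = 1
    row <- row + 1L
    m[row, idxA(nshell)] <- n
    m[row, idxB(nshell)] <- -(n + 1)
    coef <- solve(m, b)
    u[n] <- coef[idxA(nshell)] + coef[idxB(nshell)]
  }
  u
}

#' Sphere-model lead field
#'
#' Computes the electrodes x sources gain matrix of a [sphere_model()] by the
#' truncated Legendre series. Electrodes must lie on the outermost shell
#' (within `tol_mm`; they are projected radially). Sources must be strictly
#' inside the innermost shell.
#'
#' @param model an `irritmap_sphere_model`.
#' @param montage an [montage()] object.
#' @param sources an [source_space()].
#' @param tol_mm tolerance for electrode distance from the outer shell.
#' @param reference apply the average reference to the result (default TRUE).
#' @return An [new_leadfield()] object (µV per nA·m).
#' @export
sphere_leadfield <- function(model, montage, sources, tol_mm = 2,
                             reference = TRUE) {
  stopifnot(inherits(model, "irritmap_sphere_model"),
            inherits(montage, "irritmap_montage"),
            inherits(sources, "irritmap_source_space"))
  ctr <- model$center
  elec <- sweep(montage$positions, 2L, ctr)
  src <- sweep(sources$positions, 2L, ctr)
  R <- model$radii[length(model$radii)]
  er <- row_norms(elec)
  if (any(abs(er - R) > tol_mm)) {
    stop_irritmap("Electrodes are not on the outer shell (within tolerance).",
                  "irritmap_geometry_error")
  }
  if (any(row_norms(src) >= model$radii[1L])) {
    stop_irritmap("All sources must lie strictly inside the innermost shell.",
                  "irritmap_geometry_error")
  }
  eh <- elec / er  # unit electrode directions
  u <- shell_transfer(model$radii, model$conductivities, model$series_terms)
  ne <- nrow(eh); ns <- nrow(src)
  gain <- matrix(0, ne, 3L * ns)
  scale0 <- 1 / (4 * pi * model$conductivities[1L] * R^2)
  for (s in seq_len(ns)) {
    b <- sqrt(sum(src[s, ]^2))
    rh <- if (b > 1e-9) src[s, ] / b else c(0, 0, 1)
    f <- b / R
    x <- as.vector(eh %*% rh)            # cos(gamma) per electrode
    qv <- eh - outer(x, rh)              # t_hat * sin(gamma), per electrode
    # accumulators for the three unit moments: radial part and tangential part
    Vrad <- matrix(0, ne, 3L)  # n * m_r * P_n
    Vtan <- matrix(0, ne, 3L)  # (m . q) * P_n'
    p_nm1 <- rep(1, ne); p_n <- x        # P_0, P_1
    dp_nm1 <- rep(0, ne); dp_n <- rep(1, ne)
    fpow <- 1                            # f^(n-1)
    total <- 0
    for (n in seq_len(model$series_terms)) {
      w <- u[n] * fpow
      term_r <- (w * n) * p_n            # multiplies m_r
      term_t <- w * dp_n                 # multiplies (m . q)
      for (d in 1:3) {
        Vrad[, d] <- Vrad[, d] + term_r * rh[d]
        Vtan[, d] <- Vtan[, d] + term_t * qv[, d]
      }
      mag <- max(abs(term_r)) + max(abs(term_t))
      total <- max(total, mag)
      if (mag < 1e-12 * total || f == 0) break
      # advance Legendre recurrences to degree n+1
      p_np1 <- ((2 * n + 1) * x * p_n - n * p_nm1) / (n + 1)
      dp_np1 <- dp_nm1 + (2 * n + 1) * p_n
      p_nm1 <- p_n; p_n <- p_np1
      dp_nm1 <- dp_n; dp_n <- dp_np1
      fpow <- fpow * f
    }
    gain[, (3 * s - 2):(3 * s)] <- scale0 * (Vrad + Vtan)
  }
  lf <- collapse_orientation(gain, sources)
  lf <- new_leadfield(lf$gain, ns, lf$orientation, electrodes = montage$names)
  if (reference) lf <- apply_average_reference(lf)
  lf
}

# Collapse a free-orientation gain to fixed orientation when the source space
# has orientations.
collapse_orientation <- function(gain, sources) {
  if (is.null(sources$orientations)) {
    return(list(gain = gain, orientation = "free"))
  }
  ns <- sources$n
  out <- matrix(0, nrow(gain), ns)
  for (s in seq_len(ns)) {
    out[, s] <- gain[, (3 * s - 2):(3 * s)] %*% sources$orientations[s, ]
  }
  list(gain = out, orientation = "fixed")
}

#' Closed-form dipole potential in a homogeneous sphere
#'
#' Analytic surface potential of a current dipole inside a homogeneous
#' conducting sphere with insulating exterior. This is the classical
#' closed-form solution (image-series summed in closed form via Legendre
#' generating functions); it serves as the independent oracle for the
#' multi-shell series with equal conductivities.
#'
#' @param dipole_pos dipole position (3-vector, mm, relative to `center`).
#' @param moment dipole moment (3-vector, nA·m).
#' @param electrodes matrix (n x 3) of electrode positions on the sphere
#'   surface, mm.
#' @param radius sphere radius, mm.
#' @param conductivity S/m.
#' @param center sphere center, mm.
#' @return Potentials in µV at the electrodes (unreferenced).
#' @export
homogeneous_sphere_potential <- function(dipole_pos, moment, electrodes,
                                         radius, conductivity,
                                         center = c(0, 0, 0)) {
  elec <- sweep(as.matrix(electrodes), 2L, center)
  r0 <- as.numeric(dipole_pos)
  er <- row_norms(elec)
  eh <- elec / er
  b <- sqrt(sum(r0^2))
  R <- radius
  f <- b / R
  rh <- if (b > 1e-9) r0 / b else c(0, 0, 1)
  x <- as.vector(eh %*% rh)
  qv <- eh - outer(x, rh)          # in-plane tangential direction * sin(gamma)
  m_r <- sum(moment * rh)
  m_q <- as.vector(qv %*% moment)  # m_t * sin(gamma)
  scale0 <- 1 / (4 * pi * conductivity * R^2)
  if (f < 1e-12) {
    return(scale0 * (3 * m_r * x + 3 * m_q))
  }
  g <- sqrt(1 - 2 * f * x + f^2)
  rad <- 2 * (x - f) / g^3 + (1 / f) * (1 / g - 1)
  tan_ <- 2 / g^3 + (g + 1) / (g * (1 - f * x + g))
  scale0 * (m_r * rad + m_q * tan_)
}
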