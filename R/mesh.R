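#' Triangulated surface mesh
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices, consistently
#'   oriented with outward normals.
#' @return An object of class `irritmap_mesh`.
#' @export
mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L || !all(is.finite(vertices))) {
    stop_irritmap("`vertices` must be a finite (n x 3) matrix.",
                  "irritmap_geometry_error")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop_irritmap("Face indices out of range.", "irritmap_geometry_error")
  }
  structure(list(vertices = vertices, faces = faces), class = "irritmap_mesh")
}

#' @export
print.irritmap_mesh <- function(x, ...) {
  cat(sprintf("<irritmap_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Each edge of a closed, consistently oriented mesh appears exactly twice,
# once in each direction.
mesh_is_closed <- function(m) {
  e <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  rkey <- paste(e[, 2], e[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

# Signed volume via divergence theorem; positive for outward orientation.
mesh_volume <- function(m) {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
      v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
      v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])) / 6
}

#' Nested surface set for the BEM
#'
#' Ordered inside-out list of closed, outward-oriented triangulated surfaces
#' (e.g., inner skull, outer skull, scalp) with per-compartment
#' conductivities. `conductivities[k]` is the conductivity inside surface `k`
#' (between surface `k-1` and `k`); the exterior is insulating.
#'
#' @param surfaces list of [mesh()] objects, innermost first.
#' @param conductivities numeric vector, S/m, one per surface.
#' @return An object of class `irritmap_surface_set`.
#' @export
surface_set <- function(surfaces, conductivities) {
  if (length(surfaces) != length(conductivities) || length(surfaces) < 1L) {
    stop_irritmap("One conductivity per surface is required.",
                  "irritmap_model_error")
  }
  if (any(conductivities <= 0)) {
    stop_irritmap("Conductivities must be strictly positive.",
                  "irritmap_model_error")
  }
  for (k in seq_along(surfaces)) {
    m <- surfaces[[k]]
    if (!inherits(m, "irritmap_mesh")) {
      stop_irritmap("All surfaces must be `irritmap_mesh` objects.",
                    "irritmap_geometry_error")
    }
    if (!mesh_is_closed(m)) {
      stop_irritmap(sprintf("Surface %d is not closed/consistently oriented.", k),
                    "irritmap_geometry_error")
    }
    if (mesh_volume(m) <= 0) {
      stop_irritmap(sprintf("Surface %d normals are not outward.", k),
                    "irritmap_geometry_error")
    }
  }
  # nesting: every vertex of surface k strictly inside surface k+1 (checked
  # via winding number = total solid angle / 4pi)
  if (length(surfaces) > 1L) {
    for (k in seq_len(length(surfaces) - 1L)) {
      inner <- surfaces[[k]]; outer <- surfaces[[k + 1L]]
      idx <- unique(round(seq(1L, nrow(inner$vertices), length.out = 25L)))
      w <- winding_fraction(outer, inner$vertices[idx, , drop = FALSE])
      if (any(abs(w - 1) > 1e-6)) {
        stop_irritmap(sprintf("Surface %d is not nested inside surface %d.",
                              k, k + 1L), "irritmap_geometry_error")
      }
    }
  }
  structure(list(surfaces = surfaces,
                 conductivities = as.numeric(conductivities)),
            class = "irritmap_surface_set")
}

# Fraction of full solid angle (1 inside, 0 outside) of a closed mesh as seen
# from each query point.
winding_fraction <- function(m, points) {
  sa <- bem_solid_angle_total(m$vertices, m$faces - 1L, as.matrix(points))
  sa / (4 * pi)
}

#' Icosphere mesh
#'
#' Geodesic sphere obtained by subdividing an icosahedron `order` times and
#' projecting onto the sphere. Orders 0..4 give 12, 42, 162, 642 and 2562
#' vertices.
#'
#' @param order subdivision order.
#' @param radius sphere radius, mm.
#' @param center sphere center, mm.
#' @return An [mesh()] with outward-oriented triangles.
#' @export
icosphere <- function(order = 3, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (it in seq_len(order)) {
    env <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(env[[key]])) return(env[[key]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      env[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  m <- mesh(sweep(v * radius, 2L, -as.numeric(center)), f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Read / write ASCII mesh files (OFF, PLY)
#'
#' Minimal readers and writers for ASCII OFF and PLY triangle meshes.
#'
#' @param path file path.
#' @return `read_mesh()` returns an [mesh()]; writers return `path`
#'   invisibly. Format is chosen from the file extension.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = read_off(path),
         ply = read_ply(path),
         stop_irritmap("Unsupported mesh format (use .off or .ply).",
                       "irritmap_io_error"))
}

#' @rdname read_mesh
#' @param m an [mesh()].
#' @export
write_mesh <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = write_off(m, path),
         ply = write_ply(m, path),
         stop_irritmap("Unsupported mesh format (use .off or .ply).",
                       "irritmap_io_error"))
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") {
    stop_irritmap("Not an OFF file.", "irritmap_io_error")
  }
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nfc <- counts[2]
  vdat <- scan(text = paste(lines[3:(2 + nv)], collapse = "\n"), quiet = TRUE)
  verts <- matrix(vdat, ncol = 3L, byrow = TRUE)
  fdat <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nfc)],
                                   collapse = "\n"), quiet = TRUE),
                 ncol = 4L, byrow = TRUE)
  if (any(fdat[, 1] != 3)) {
    stop_irritmap("Only triangle meshes are supported.", "irritmap_io_error")
  }
  mesh(verts, fdat[, 2:4] + 1L)
}

write_off <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(m$vertices), nrow(m$faces)), con)
  utils::write.table(format(m$vertices, digits = 12, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, m$faces - 1L), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(trimws(lines) == "end_header")[1]
  header <- lines[seq_len(endh)]
  if (!grepl("^ply", header[1])) {
    stop_irritmap("Not a PLY file.", "irritmap_io_error")
  }
  if (!any(grepl("format ascii", header))) {
    stop_irritmap("Only ASCII PLY is supported.", "irritmap_io_error")
  }
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  vdat <- scan(text = paste(lines[(endh + 1):(endh + nv)], collapse = "\n"),
               quiet = TRUE)
  nprop <- length(vdat) / nv
  verts <- matrix(vdat, ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
  fdat <- matrix(scan(text = paste(lines[(endh + nv + 1):(endh + nv + nf)],
                                   collapse = "\n"), quiet = TRUE),
                 ncol = 4L, byrow = TRUE)
  if (any(fdat[, 1] != 3)) {
    stop_irritmap("Only triangle meshes are supported.", "irritmap_io_error")
  }
  mesh(verts, fdat[, 2:4] + 1L)
}

write_ply <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(m$vertices, digits = 12, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, m$faces - 1L), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
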