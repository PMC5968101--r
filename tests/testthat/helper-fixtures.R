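# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fix_geom <- function() fixture("geom", study_geometry)

# small spherical BEM fixture (nested icospheres); order 2 = 162 vertices
fix_bem_surfaces <- function(order = 2) {
  fixture(paste0("surf", order), function() {
    radii <- c(7.9, 8.6, 9.2)
    surface_set(lapply(radii, function(r) icosphere(order, r)),
                c(0.33, 0.165, 0.33))
  })
}

# montage whose electrodes sit exactly on icosphere vertices shared by all
# subdivision orders >= 2 (subdivision keeps parent vertices)
fix_vertex_montage <- function() {
  fixture("vmontage", function() {
    scalp <- icosphere(2, 9.2)$vertices
    cap <- cap_montage(32, radius = 9.2)$positions
    idx <- unique(apply(cap, 1, function(p) {
      which.min(colSums((t(scalp) - p)^2))
    }))
    montage(sprintf("E%02d", seq_along(idx)), scalp[idx, ])
  })
}

# random dipoles: positions at given eccentricities inside radius r1, with
# random (tangential if asked) unit moments
random_dipoles <- function(n, r1, ecc_max = 0.9, tangential = FALSE,
                           seed = 1) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    pos <- u * runif(1, 0.1, ecc_max) * r1
    m <- rnorm(3)
    if (tangential) m <- m - sum(m * u) * u
    out[[i]] <- list(pos = pos, moment = m / sqrt(sum(m^2)))
  }
  out
}

rdm <- function(a, b) {
  sqrt(sum((a / sqrt(sum(a^2)) - b / sqrt(sum(b^2)))^2))
}

# tiny exact rank-f tensor with constraint-compatible factors (orthonormal
# spatial atoms, non-negative sample signatures — the default modes)
make_rank_tensor <- function(dims, f, seed = 1, ortho_spatial = TRUE,
                             nonneg_sample = TRUE) {
  set.seed(seed)
  a <- matrix(rnorm(dims[1] * f), dims[1], f)
  if (ortho_spatial) a <- qr.Q(qr(a))[, seq_len(f), drop = FALSE]
  b <- matrix(rnorm(dims[2] * f), dims[2], f)
  cc <- matrix(rnorm(dims[3] * f), dims[3], f)
  if (nonneg_sample) cc <- abs(cc) + 0.2
  x <- array(0, dims)
  for (j in seq_len(f)) x <- x + outer(outer(a[, j], b[, j]), cc[, j])
  list(tensor = x, factors = list(a, b, cc))
}

# brute-force two-sided signed-rank p over all 2^n sign assignments
wilcoxon_brute <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d < 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
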