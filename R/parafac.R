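# Three-way PARAFAC with per-mode constraints, fitted by alternating least
# squares. The IED tensor V (electrodes x time x samples) is modeled as
#   V = sum_f  f_e(f) o f_t(f) o f_s(f)  +  E
# with optional orthonormality (Procrustes update) or non-negativity (NNLS
# update) per mode.

# mode-n matricization (mode-1 columns ordered with mode-2 fastest, etc.)
unfold_tensor <- function(x, mode) {
  d <- dim(x)
  switch(mode,
         matrix(x, d[1], d[2] * d[3]),
         matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
         matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]))
}

# columnwise Khatri-Rao with the second argument's index varying fastest
khatri_rao <- function(x, y) {
  out <- matrix(0, nrow(x) * nrow(y), ncol(x))
  for (f in seq_len(ncol(x))) out[, f] <- kronecker(x[, f], y[, f])
  out
}

# Exact small-F non-negative least squares for many right-hand sides:
# minimize 0.5 x'Gx - x'b over x >= 0, one problem per column of B. The
# global optimum equals the unconstrained solution on its support, so for
# small F all supports are enumerated and the feasible one with the best
# objective is kept (vectorized across right-hand sides).
nnls_gram <- function(g, b) {
  f <- nrow(g)
  n <- ncol(b)
  if (f > 12L) {
    ch <- chol(g)
    z <- solve(t(ch), b)
    out <- vapply(seq_len(n), function(j) pracma::lsqnonneg(ch, z[, j])$x,
                  numeric(f))
    return(matrix(out, f, n))
  }
  best_obj <- rep(0, n)            # empty support: x = 0, objective 0
  best_x <- matrix(0, f, n)
  for (mask in seq_len(2^f - 1L)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(f) - 1L)) > 0L)
    xs <- tryCatch(solve(g[s, s, drop = FALSE], b[s, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(xs)) next
    feas <- colSums(xs < 0) == 0L
    obj <- 0.5 * colSums(xs * b[s, , drop = FALSE])
    upd <- feas & obj > best_obj + 1e-300
    if (any(upd)) {
      best_obj[upd] <- obj[upd]
      best_x[, upd] <- 0
      best_x[s, upd] <- xs[, upd]
    }
  }
  best_x
}

# one constrained least-squares update of a factor matrix:
#   min ||Xn - F kr' || subject to the mode constraint
update_factor <- function(xn, kr, gram, constraint) {
  mtm <- xn %*% kr  # (dim_n x F)
  if (constraint == "ortho") {
    sv <- svd(mtm)
    return(sv$u %*% t(sv$v))
  }
  g <- gram + diag(1e-12 * max(diag(gram)), ncol(gram))
  if (constraint == "nonneg") {
    return(t(nnls_gram(g, t(mtm))))
  }
  mtm %*% solve(g)
}

#' Constrained three-way PARAFAC of an IED tensor
#'
#' Decomposes an electrodes x time x samples tensor into `n_factors` rank-1
#' atoms (spatial x temporal x sample signatures) by alternating least
#' squares with per-mode constraint projections: `"ortho"` modes are updated
#' by an orthogonal Procrustes step (orthonormal columns), `"nonneg"` modes
#' by non-negative least squares, `"none"` by ordinary least squares. The
#' best of `restarts` seeded initializations (by explained variance) is
#' returned; within each run the fit is non-decreasing across iterations.
#'
#' @param tensor 3-d array or `irritmap_ied_tensor`.
#' @param n_factors number of atoms F (>= 1, <= each tensor dimension).
#' @param constraints named character vector over modes
#'   `c(electrode=, time=, sample=)` with values `"none"`, `"ortho"`,
#'   `"nonneg"`. Defaults to orthonormal spatial atoms and non-negative
#'   sample signatures: distinct cortical generators project near-orthogonal
#'   scalp patterns after average referencing, whereas discharge waveforms of
#'   one duration class are nearly parallel in time — an orthogonality
#'   constraint on the temporal mode would forbid exactly the
#'   same-waveform/different-generator subtype structure the decomposition
#'   is meant to separate.
#' @param seed integer seed for the restarts.
#' @param restarts number of seeded initializations.
#' @param max_iter maximum ALS iterations per restart.
#' @param tol stop when the relative fit change falls below this.
#' @return An `irritmap_factor_model`: list with `spatial` (electrodes x F),
#'   `temporal` (time x F), `sample` (samples x F), `fit` (explained-variance
#'   fraction), `fit_history`, `converged`, `constraints`, `n_factors`.
#' @export
parafac <- function(tensor, n_factors,
                    constraints = c(electrode = "ortho", time = "none",
                                    sample = "nonneg"),
                    seed = 1L, restarts = 10L, max_iter = 500L, tol = 1e-8) {
  x <- unclass(tensor)
  attributes(x) <- list(dim = dim(tensor))
  d <- dim(x)
  if (length(d) != 3L) {
    stop_irritmap("`tensor` must be a 3-d array.", "irritmap_config_error")
  }
  if (n_factors < 1L || n_factors > min(d)) {
    stop_irritmap("`n_factors` must be in [1, min(dim(tensor))].",
                  "irritmap_config_error")
  }
  modes <- c("electrode", "time", "sample")
  cons <- setNames(rep("none", 3L), modes)
  cons[names(constraints)] <- unname(constraints)
  if (!all(cons %in% c("none", "ortho", "nonneg"))) {
    stop_irritmap("Constraints must be 'none', 'ortho' or 'nonneg'.",
                  "irritmap_config_error")
  }
  xn <- list(unfold_tensor(x, 1), unfold_tensor(x, 2), unfold_tensor(x, 3))
  xnorm2 <- sum(x^2)
  if (xnorm2 == 0) {
    stop_irritmap("Cannot decompose an all-zero tensor.",
                  "irritmap_config_error")
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    fac <- with_seed(derive_seed(seed, r), {
      lapply(seq_len(3L), function(m) {
        f0 <- matrix(rnorm(d[m] * n_factors), d[m], n_factors)
        if (cons[m] == "nonneg") f0 <- abs(f0)
        if (cons[m] == "ortho") f0 <- qr.Q(qr(f0))[, seq_len(n_factors),
                                                   drop = FALSE]
        f0
      })
    })
    fit_hist <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (m in 1:3) {
        others <- setdiff(3:1, m)
        a2 <- fac[[max(others)]]
        a1 <- fac[[min(others)]]
        kr <- khatri_rao(a2, a1)
        gram <- crossprod(a2) * crossprod(a1)
        fac[[m]] <- update_factor(xn[[m]], kr, gram, cons[m])
      }
      # guard against collapsed (all-zero) non-negative columns
      for (m in which(cons == "nonneg")) {
        dead <- colSums(abs(fac[[m]])) == 0
        if (any(dead)) {
          fac[[m]][, dead] <- with_seed(derive_seed(seed, 1000L + it),
                                        abs(matrix(rnorm(d[m] * sum(dead)),
                                                   d[m])))
        }
      }
      kr <- khatri_rao(fac[[3]], fac[[2]])
      resid2 <- xnorm2 - 2 * sum(xn[[1]] * (fac[[1]] %*% t(kr))) +
        sum((crossprod(fac[[1]]) * crossprod(fac[[2]]) *
               crossprod(fac[[3]])))
      fit <- 1 - max(resid2, 0) / xnorm2
      fit_hist <- c(fit_hist, fit)
      if (it > 1L && abs(fit - prev) < tol * max(abs(prev), 1e-12)) {
        converged <- TRUE
        prev <- fit
        break
      }
      prev <- fit
    }
    if (is.null(best) || prev > best$fit) {
      best <- list(fac = fac, fit = prev, fit_history = fit_hist,
                   converged = converged)
    }
  }
  if (!best$converged) {
    warn("PARAFAC did not converge within `max_iter`; returning best model.")
  }
  structure(list(spatial = best$fac[[1]], temporal = best$fac[[2]],
                 sample = best$fac[[3]], n_factors = as.integer(n_factors),
                 fit = best$fit, fit_history = best$fit_history,
                 converged = best$converged, constraints = cons,
                 dims = d),
            class = "irritmap_factor_model")
}

#' @export
print.irritmap_factor_model <- function(x, ...) {
  cat(sprintf(
    "<irritmap_factor_model> F = %d, fit = %.4f%s\n  constraints: %s\n",
    x$n_factors, x$fit, if (x$converged) "" else " (not converged)",
    paste(names(x$constraints), x$constraints, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Core-consistency diagnostic (CORCONDIA)
#'
#' Measures how close the least-squares Tucker core implied by the PARAFAC
#' factors is to the ideal superidentity: 100 for a perfectly trilinear
#' model, dropping sharply when the rank is overestimated. Used for rank
#' selection.
#'
#' @param model an `irritmap_factor_model` fitted to `tensor`.
#' @param tensor the tensor the model was fitted to.
#' @return The percentage score (<= 100; can be negative for badly
#'   over-factored models). `n_factors = 1` returns 100 by definition.
#' @export
core_consistency <- function(model, tensor) {
  stopifnot(inherits(model, "irritmap_factor_model"))
  f <- model$n_factors
  if (f == 1L) return(100)
  facs <- list(model$spatial, model$temporal, model$sample)
  for (m in facs) {
    if (any(!is.finite(m)) || any(colSums(m^2) == 0)) {
      stop_irritmap("Degenerate (zero or non-finite) factors; CORCONDIA undefined.",
                    "irritmap_diagnostic_error")
    }
  }
  x <- unclass(tensor)
  attributes(x) <- list(dim = dim(tensor))
  # least-squares core: G = X x1 pinv(A) x2 pinv(B) x3 pinv(C)
  g <- x
  for (m in 1:3) {
    gm <- unfold_tensor(g, m)
    gm <- MASS::ginv(facs[[m]]) %*% gm
    dg <- dim(g)
    dg[m] <- f
    perm <- switch(m, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    g <- aperm(array(gm, dg[perm]), order(perm))
  }
  target <- array(0, c(f, f, f))
  for (i in seq_len(f)) target[i, i, i] <- 1
  100 * (1 - sum((g - target)^2) / f)
}

#' Select the PARAFAC rank by core consistency
#'
#' Fits models for each candidate rank and returns the largest rank whose
#' core consistency stays at or above `threshold` (CORCONDIA is 100 by
#' definition at rank 1, so the *largest* acceptable rank is the informative
#' choice).
#'
#' @param tensor 3-d array.
#' @param max_rank largest candidate rank (capped at 8 and at the tensor
#'   dimensions).
#' @param threshold acceptance level for the diagnostic (default 80).
#' @param stability_threshold minimum split-half factor stability: each
#'   factor must replicate (spatial x temporal congruence) across models
#'   fitted on disjoint halves of the samples. Noise factors do not
#'   replicate, so this guards against over-factoring on noisy data where
#'   the core diagnostic alone is permissive.
#' @param seed,restarts passed to [parafac()] for the final fit.
#' @param diag_restarts restarts of the (unconstrained) scan fits — the
#'   diagnostic is computed on unconstrained models because constraint
#'   projections regularize the core and mask over-factoring.
#' @param ... passed to [parafac()] for the final fit (e.g. `constraints`).
#' @return A list with `n_factors` (selected rank), `model` (the fitted
#'   model at that rank) and `diagnostics` (tibble of rank, fit, corcondia,
#'   stability).
#' @export
select_rank <- function(tensor, max_rank = 8, threshold = 80,
                        stability_threshold = 0.6, seed = 1L,
                        restarts = 10L, diag_restarts = 3L, ...) {
  x <- unclass(tensor)
  attributes(x) <- list(dim = dim(tensor))
  max_rank <- min(max_rank, 8L, min(dim(x)[1:2], floor(dim(x)[3] / 2)))
  ns <- dim(x)[3]
  halves <- with_seed(derive_seed(seed, 777L), {
    idx <- sample(ns)
    list(idx[seq_len(floor(ns / 2))], idx[(floor(ns / 2) + 1L):ns])
  })
  unconstr <- c(electrode = "none", time = "none", sample = "none")
  rows <- list()
  for (f in seq_len(max_rank)) {
    m <- suppressWarnings(
      parafac(x, f, constraints = unconstr, seed = seed,
              restarts = diag_restarts, max_iter = 200L, tol = 1e-7))
    cc <- tryCatch(core_consistency(m, x), error = function(e) -Inf)
    stab <- if (f == 1L) 1 else {
      ms <- lapply(halves, function(h) {
        suppressWarnings(
          parafac(x[, , h, drop = FALSE], f, constraints = unconstr,
                  seed = seed, restarts = diag_restarts, max_iter = 200L,
                  tol = 1e-7))
      })
      min(match_congruence(list(ms[[1]]$spatial, ms[[1]]$temporal),
                           list(ms[[2]]$spatial, ms[[2]]$temporal)))
    }
    rows[[f]] <- tibble::tibble(n_factors = f, fit = m$fit, corcondia = cc,
                                stability = stab)
  }
  diag_tab <- dplyr::bind_rows(rows)
  ok <- which(diag_tab$corcondia >= threshold &
                diag_tab$stability >= stability_threshold)
  sel <- if (length(ok)) max(ok) else 1L
  model <- parafac(x, sel, seed = seed, restarts = restarts, ...)
  list(n_factors = sel, model = model, diagnostics = diag_tab)
}

# Greedy congruence matching of two factor sets over the supplied modes;
# returns the per-matched-pair geometric-mean congruence.
match_congruence <- function(a, b) {
  normcol <- function(m) sweep(m, 2L, pmax(sqrt(colSums(m^2)), 1e-300), "/")
  an <- lapply(a, normcol)
  bn <- lapply(b, normcol)
  prod_c <- Reduce(`*`, lapply(seq_along(a), function(m) {
    abs(crossprod(an[[m]], bn[[m]]))
  }))
  f <- ncol(prod_c)
  out <- numeric(f)
  for (step in seq_len(f)) {
    ij <- which(prod_c == max(prod_c), arr.ind = TRUE)[1, ]
    out[step] <- prod_c[ij[1], ij[2]]
    prod_c[ij[1], ] <- -Inf
    prod_c[, ij[2]] <- -Inf
  }
  out^(1 / length(a))
}

#' Tucker congruence between fitted and reference factors
#'
#' Greedily matches the model's atoms to a reference factor set (by the
#' product of absolute congruences across modes, resolving permutation and
#' sign) and returns the mean absolute congruence per mode. Used to score
#' recovery of known simulation atoms.
#'
#' @param model an `irritmap_factor_model`.
#' @param truth list of three reference factor matrices (electrode, time,
#'   sample), each with `n_factors` columns.
#' @return Named numeric vector: mean matched congruence per mode.
#' @export
factor_congruence <- function(model, truth) {
  est <- list(model$spatial, model$temporal, model$sample)
  f <- model$n_factors
  normcol <- function(m) sweep(m, 2L, pmax(sqrt(colSums(m^2)), 1e-300), "/")
  en <- lapply(est, normcol)
  tn <- lapply(truth, normcol)
  # product of absolute congruences across modes drives the matching
  # prod_c[i, j]: estimated column i vs true column j
  prod_c <- Reduce(`*`, lapply(1:3, function(m) abs(crossprod(en[[m]],
                                                              tn[[m]]))))
  perm <- integer(f)
  for (step in seq_len(f)) {
    ij <- which(prod_c == max(prod_c), arr.ind = TRUE)[1, ]
    perm[ij[2]] <- ij[1]
    prod_c[ij[1], ] <- -Inf
    prod_c[, ij[2]] <- -Inf
  }
  vapply(1:3, function(m) {
    mean(vapply(seq_len(f), function(j) {
      abs(sum(en[[m]][, perm[j]] * tn[[m]][, j]))
    }, numeric(1)))
  }, numeric(1)) |> setNames(c("electrode", "time", "sample"))
}
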