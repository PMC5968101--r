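#' sLORETA inverse solution for one scalp topography
#'
#' Standardized minimum-norm estimate: the minimum-norm current estimate
#' `j = G' (G G' + lambda H)^+ v` (with `H` the average-reference operator
#' and `lambda = lambda_rel * trace(G G') / n_electrodes`) is standardized by
#' the diagonal (blocks) of the resolution kernel
#' `S = G' (G G' + lambda H)^+ G`, giving per-source power
#' `j_i' S_ii^-1 j_i`. In the noiseless, small-lambda limit the power
#' maximum coincides with a true single source (zero localization error).
#'
#' @param lf an average-referenced [new_leadfield()].
#' @param topography electrode potential vector (µV), average-referenced.
#' @param lambda_rel relative Tikhonov regularization (>= 0); defaults to
#'   1e-4 (use ~1e-2 for noisy data).
#' @param subtype optional subtype id stored in the result.
#' @return An `irritmap_source_map`: list with `power` (per source, >= 0),
#'   `lambda`, `lambda_rel`, `latency_ms` (NA here; filled by
#'   [localize_subtypes()]), `subtype`.
#' @export
sloreta <- function(lf, topography, lambda_rel = 1e-4, subtype = NA) {
  stopifnot(inherits(lf, "irritmap_leadfield"))
  if (!lf$referenced) {
    stop_irritmap("The lead field must be average-referenced (see `apply_average_reference()`).",
                  "irritmap_contract_error")
  }
  v <- as.numeric(topography)
  if (length(v) != nrow(lf$gain)) {
    stop_irritmap("Topography length does not match the lead field.",
                  "irritmap_contract_error")
  }
  if (max(abs(v)) > 0 && abs(mean(v)) > 1e-6 * max(abs(v))) {
    stop_irritmap("The topography must be average-referenced.",
                  "irritmap_contract_error")
  }
  if (lambda_rel < 0) {
    stop_irritmap("`lambda_rel` must be >= 0.", "irritmap_contract_error")
  }
  g <- lf$gain
  n <- nrow(g)
  h <- diag(n) - matrix(1 / n, n, n)
  lambda <- lambda_rel * sum(g * g) / n
  minv <- MASS::ginv(g %*% t(g) + lambda * h)
  tm <- t(g) %*% minv          # (p x n) minimum-norm inverse operator
  j <- as.vector(tm %*% v)
  if (lf$orientation == "fixed") {
    s_diag <- rowSums(tm * t(g))
    if (any(s_diag <= 1e-300)) {
      stop_irritmap(paste0(
        "Singular resolution block; increase `lambda_rel` or check the ",
        "lead field for zero columns."), "irritmap_regularization_error")
    }
    power <- j^2 / s_diag
  } else {
    ns <- lf$n_sources
    power <- numeric(ns)
    for (s in seq_len(ns)) {
      cols <- (3 * s - 2):(3 * s)
      sblock <- tm[cols, , drop = FALSE] %*% g[, cols, drop = FALSE]
      ok <- tryCatch({
        power[s] <- drop(crossprod(j[cols], solve(sblock, j[cols])))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        stop_irritmap(paste0(
          "Singular 3x3 resolution block at source ", s,
          "; increase `lambda_rel` or check the lead field."),
          "irritmap_regularization_error")
      }
    }
  }
  power <- pmax(power, 0)
  structure(list(power = power, lambda = lambda, lambda_rel = lambda_rel,
                 latency_ms = NA_real_, subtype = subtype),
            class = "irritmap_source_map")
}

#' @export
print.irritmap_source_map <- function(x, ...) {
  cat(sprintf(
    "<irritmap_source_map> %d sources, peak %d%s\n", length(x$power),
    which.max(x$power),
    if (is.finite(x$latency_ms)) sprintf(", latency %.1f ms", x$latency_ms)
    else ""))
  invisible(x)
}

#' Global field power of a mean IED
#'
#' Across-channel standard deviation at each time point.
#'
#' @param mean_ied an `irritmap_mean_ied`.
#' @return Numeric vector, one value per time point.
#' @export
global_field_power <- function(mean_ied) {
  apply(mean_ied$time_course, 2L, sd)
}

#' Two-thirds-of-peak latency
#'
#' Latency at which the global field power first crosses two thirds of its
#' peak on the rising phase of the main peak (the early part of the
#' discharge, where propagation has not yet smeared the topography). The
#' crossing is linearly interpolated, then snapped to the nearest sample.
#'
#' @param mean_ied an `irritmap_mean_ied`.
#' @param phase `"rising"` (default) or `"falling"`.
#' @return Latency in ms relative to the epoch start.
#' @export
twothirds_latency <- function(mean_ied, phase = c("rising", "falling")) {
  phase <- match.arg(phase)
  gfp <- global_field_power(mean_ied)
  if (max(gfp) <= 0) {
    stop_irritmap("Flat epoch: the global field power is zero.",
                  "irritmap_latency_error")
  }
  fs <- mean_ied$sampling_rate
  peak <- which.max(gfp)
  target <- 2 / 3 * gfp[peak]
  if (phase == "rising") {
    i <- peak
    while (i > 1L && gfp[i - 1L] >= target) i <- i - 1L
    if (i == 1L) {
      warn("GFP never falls below 2/3 of its peak before the peak; using the epoch start.")
      return(0)
    }
    frac <- (target - gfp[i - 1L]) / (gfp[i] - gfp[i - 1L])
    cross <- (i - 1L) + frac  # 1-based fractional sample
  } else {
    i <- peak
    while (i < length(gfp) && gfp[i + 1L] >= target) i <- i + 1L
    if (i == length(gfp)) {
      warn("GFP never falls below 2/3 of its peak after the peak; using the epoch end.")
      return((length(gfp) - 1L) / fs * 1000)
    }
    frac <- (gfp[i] - target) / (gfp[i] - gfp[i + 1L])
    cross <- i + frac
  }
  (round(cross) - 1L) / fs * 1000
}

#' Localize each IED subtype with sLORETA
#'
#' Inverts each cluster-mean topography at its two-thirds-of-peak latency
#' and assigns a peak parcel (parcel power = mean standardized power over
#' member sources).
#'
#' @param lf average-referenced lead field.
#' @param means list of `irritmap_mean_ied` (from [cluster_means()]).
#' @param sources the [source_space()] behind the lead field (provides the
#'   source-to-parcel mapping).
#' @param parc a [parcellation()].
#' @param lambda_rel regularization passed to [sloreta()] (default 1e-2,
#'   suited to noisy averages).
#' @param parcel_stat statistic pooling member-source power into parcel
#'   power: `"mean"` (default; stabler under discretization) or `"max"`.
#' @param phase passed to [twothirds_latency()].
#' @return A list, one element per subtype: `map` (the source map),
#'   `peak_parcel`, `parcel_power` (tibble), `kind`, `n_events`.
#' @export
localize_subtypes <- function(lf, means, sources, parc, lambda_rel = 1e-2,
                              parcel_stat = c("mean", "max"),
                              phase = "rising") {
  parcel_stat <- match.arg(parcel_stat)
  pool <- if (parcel_stat == "mean") mean else max
  stopifnot(inherits(lf, "irritmap_leadfield"),
            inherits(sources, "irritmap_source_space"))
  if (!length(means)) return(list())
  out <- vector("list", length(means))
  for (k in seq_along(means)) {
    mi <- means[[k]]
    if (nrow(mi$time_course) != nrow(lf$gain)) {
      stop_irritmap("Channel count of the mean IED does not match the lead field.",
                    "irritmap_contract_error")
    }
    lat <- twothirds_latency(mi, phase = phase)
    topo <- topography_at(mi, lat)
    topo <- topo - mean(topo)
    map <- sloreta(lf, topo, lambda_rel = lambda_rel, subtype = k)
    map$latency_ms <- lat
    pp <- tibble::tibble(parcel_id = sources$parcel_ids,
                         power = map$power) |>
      dplyr::filter(!is.na(.data$parcel_id)) |>
      dplyr::group_by(.data$parcel_id) |>
      dplyr::summarise(power = pool(.data$power), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$power))
    out[[k]] <- list(map = map, peak_parcel = pp$parcel_id[1],
                     parcel_power = pp, kind = mi$kind,
                     n_events = mi$n_events)
  }
  out
}
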