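#' Cluster IED samples by their PARAFAC sample signatures
#'
#' Runs k-means on the rows of the sample-signature matrix. When `k_range`
#' includes 1, the gap statistic (Tibshirani's reference-dispersion test,
#' which — unlike the silhouette — can prefer a single cluster) first
#' decides whether there is any cluster structure at all; given structure,
#' the cluster count is the silhouette-maximizing k over `k_range`. A
#' single candidate value fixes k.
#'
#' @param model an `irritmap_factor_model`.
#' @param k_range candidate cluster counts (a single value fixes k).
#' @param seed integer seed for the k-means restarts and gap references.
#' @param nstart k-means restarts per candidate k.
#' @param gap_B bootstrap reference sets for the gap statistic.
#' @param normalize cluster on unit-normalized signature rows (default):
#'   a subtype is a *direction* in atom space — which atoms express the
#'   event — while the row norm carries per-event amplitude and noise that
#'   would otherwise dominate the Euclidean distance.
#' @return An `irritmap_cluster_assignment`: list with `labels` (1-based,
#'   per sample), `k`, `silhouette` (mean score; `NA` for k = 1),
#'   `centroids`, `diagnostics` (tibble of k, silhouette).
#' @export
cluster_samples <- function(model, k_range = 1:6, seed = 1L, nstart = 10L,
                            gap_B = 50L, normalize = TRUE) {
  stopifnot(inherits(model, "irritmap_factor_model"))
  s <- model$sample
  if (normalize) {
    nrm <- sqrt(rowSums(s^2))
    s <- s / pmax(nrm, 1e-300)
    if (any(nrm == 0) && any(nrm > 0)) {
      # events with no expression carry no direction; give them the mean
      # direction so they cannot form a spurious cluster of their own
      mu <- colMeans(s[nrm > 0, , drop = FALSE])
      s[nrm == 0, ] <- matrix(mu, sum(nrm == 0), ncol(s), byrow = TRUE)
    }
  }
  n <- nrow(s)
  if (max(k_range) > n) {
    stop_irritmap("`k_range` cannot exceed the number of samples.",
                  "irritmap_config_error")
  }
  n_distinct <- nrow(unique(round(s, 12)))
  cand <- sort(unique(pmin(k_range, n_distinct)))
  if (identical(cand, 1L) || n_distinct == 1L) {
    return(new_assignment(rep(1L, n), 1L, NA_real_,
                          matrix(colMeans(s), 1L), NULL))
  }
  if (length(cand) == 1L) {
    km <- with_seed(derive_seed(seed, cand),
                    kmeans(s, centers = cand, nstart = nstart,
                           iter.max = 100L))
    sil <- mean(cluster::silhouette(km$cluster, stats::dist(s))[,
                                                                "sil_width"])
    return(new_assignment(km$cluster, as.integer(cand), sil, km$centers,
                          NULL))
  }
  if (1L %in% cand) {
    k_gap <- with_seed(derive_seed(seed, 999L), {
      gp <- cluster::clusGap(s, FUN = function(x, k) {
        kmeans(x, k, nstart = nstart, iter.max = 100L)
      }, K.max = max(cand), B = gap_B, verbose = FALSE)
      cluster::maxSE(gp$Tab[, "gap"], gp$Tab[, "SE.sim"],
                     method = "Tibs2001SEmax")
    })
    if (k_gap == 1L) {
      return(new_assignment(rep(1L, n), 1L, NA_real_,
                            matrix(colMeans(s), 1L), NULL))
    }
  }
  dmat <- stats::dist(s)
  rows <- list()
  fits <- list()
  for (k in cand[cand >= 2L]) {
    km <- with_seed(derive_seed(seed, k),
                    kmeans(s, centers = k, nstart = nstart, iter.max = 100L))
    sil <- mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
    fits[[as.character(k)]] <- km
    rows[[length(rows) + 1L]] <- tibble::tibble(k = k, silhouette = sil,
                                                inertia = km$tot.withinss)
  }
  diag_tab <- dplyr::bind_rows(rows)
  best <- diag_tab$k[which.max(diag_tab$silhouette)]
  km <- fits[[as.character(best)]]
  new_assignment(km$cluster, as.integer(best), max(diag_tab$silhouette),
                 km$centers, diag_tab)
}

new_assignment <- function(labels, k, silhouette, centroids, diagnostics) {
  structure(list(labels = as.integer(labels), k = k, silhouette = silhouette,
                 centroids = centroids, diagnostics = diagnostics),
            class = "irritmap_cluster_assignment")
}

#' @export
print.irritmap_cluster_assignment <- function(x, ...) {
  cat(sprintf("<irritmap_cluster_assignment> k = %d (mean silhouette %s)\n",
              x$k, ifelse(is.na(x$silhouette), "-",
                          sprintf("%.3f", x$silhouette))))
  invisible(x)
}

#' Cluster-mean IEDs
#'
#' Averages the tensor samples of each cluster into one mean IED per subtype
#' (the representative time course used for source localization). Event
#' counts are conserved: cluster sizes sum to the tensor sample count.
#'
#' @param tensor an `irritmap_ied_tensor`.
#' @param assignment an `irritmap_cluster_assignment` covering all samples.
#' @return A list of `irritmap_mean_ied` objects, one per cluster, each with
#'   `time_course` (electrodes x time), `kind` (majority event kind, if the
#'   tensor carries events), `n_events`, `sampling_rate`, `channels`.
#' @export
cluster_means <- function(tensor, assignment) {
  stopifnot(inherits(assignment, "irritmap_cluster_assignment"))
  d <- dim(tensor)
  labels <- assignment$labels
  if (length(labels) != d[3]) {
    stop_irritmap("Assignment does not cover all tensor samples.",
                  "irritmap_assignment_error")
  }
  events <- attr(tensor, "events")
  out <- vector("list", assignment$k)
  for (cl in seq_len(assignment$k)) {
    idx <- which(labels == cl)
    if (!length(idx)) {
      stop_irritmap(sprintf("Cluster %d is empty.", cl),
                    "irritmap_assignment_error")
    }
    tc <- apply(unclass(tensor)[, , idx, drop = FALSE], c(1, 2), mean)
    kind <- if (!is.null(events) && nrow(events)) {
      names(sort(table(events$kind[idx]), decreasing = TRUE))[1]
    } else NA_character_
    out[[cl]] <- structure(
      list(time_course = tc, kind = kind, n_events = length(idx),
           sampling_rate = attr(tensor, "sampling_rate"),
           channels = attr(tensor, "channels"), cluster = cl,
           sample_index = idx),
      class = "irritmap_mean_ied")
  }
  out
}

#' @export
print.irritmap_mean_ied <- function(x, ...) {
  cat(sprintf("<irritmap_mean_ied> cluster %d (%s), %d events, %d x %d\n",
              x$cluster, x$kind %||% "?", x$n_events,
              nrow(x$time_course), ncol(x$time_course)))
  invisible(x)
}

#' Scalp topography of a mean IED at a latency
#'
#' @param mean_ied an `irritmap_mean_ied`.
#' @param latency_ms latency relative to the epoch start, ms.
#' @return Named numeric vector of channel potentials (µV).
#' @export
topography_at <- function(mean_ied, latency_ms) {
  stopifnot(inherits(mean_ied, "irritmap_mean_ied"))
  fs <- mean_ied$sampling_rate
  idx <- round(latency_ms / 1000 * fs) + 1L
  idx <- max(1L, min(ncol(mean_ied$time_course), idx))
  setNames(mean_ied$time_course[, idx],
           mean_ied$channels %||%
             sprintf("Ch%02d", seq_len(nrow(mean_ied$time_course))))
}

#' Butterfly plot of a cluster-mean IED
#'
#' @param object an `irritmap_mean_ied`.
#' @param ... unused.
#' @return A ggplot; the dashed line marks the two-thirds-of-peak latency on
#'   the global-field-power curve.
#' @export
autoplot.irritmap_mean_ied <- function(object, ...) {
  fs <- object$sampling_rate
  nt <- ncol(object$time_course)
  df <- tibble::tibble(
    time_ms = rep((seq_len(nt) - 1L) / fs * 1000,
                  each = nrow(object$time_course)),
    channel = rep(seq_len(nrow(object$time_course)), nt),
    value = as.vector(object$time_course))
  lat <- tryCatch(twothirds_latency(object), error = function(e) NA_real_)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                        group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "potential (µV)",
                  title = sprintf("Cluster %d (%s, %d events)",
                                  object$cluster, object$kind %||% "?",
                                  object$n_events)) +
    ggplot2::theme_minimal()
  if (is.finite(lat)) {
    p <- p + ggplot2::geom_vline(xintercept = lat, linetype = "dashed",
                                 color = "red")
  }
  p
}
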