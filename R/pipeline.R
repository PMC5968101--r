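#' Full irritative-zone mapping pipeline
#'
#' Runs the complete analysis on a broadband recording: average reference,
#' threshold detection on the spike (15-50 Hz) and sharp-wave (5-15 Hz)
#' streams, duration-band split, per-stream tensor construction, constrained
#' PARAFAC with rank selection, k-means subtype clustering on the sample
#' signatures, cluster means, sLORETA localization at the two-thirds-of-peak
#' latency, and target/control selection.
#'
#' @param rec broadband `irritmap_recording`.
#' @param lf average-referenced lead field for the montage.
#' @param sources the [source_space()] behind the lead field.
#' @param parc a [parcellation()] covering the source parcels.
#' @param k_sd detection threshold (robust SDs).
#' @param window_ms epoch window.
#' @param max_rank largest PARAFAC rank scanned per stream.
#' @param restarts PARAFAC restarts.
#' @param k_range candidate subtype counts per stream.
#' @param lambda_rel sLORETA regularization.
#' @param silence_ratio contralateral-silence threshold.
#' @param refine_iter nearest-centroid consolidation passes: after the
#'   per-stream clustering, every epoch is reassigned to the cluster mean
#'   (across both streams) it correlates with best, which recovers events
#'   whose noisy duration estimate routed them into the wrong stream; 0
#'   disables.
#' @param seed integer seed for decomposition/clustering restarts.
#' @return A list with `events`, `streams` (per-stream tensor, model,
#'   assignment), `means` (consolidated cluster means, each carrying its
#'   member `events`), `localized`, `report` (an `irritmap_iz_report`), or
#'   `NULL` report when no events survive.
#' @export
map_irritative_zones <- function(rec, lf, sources, parc = parcellation(),
                                 k_sd = 4, window_ms = 300, max_rank = 4,
                                 restarts = 5, k_range = 1:4,
                                 lambda_rel = 0.05, silence_ratio = 0.2,
                                 refine_iter = 3, seed = 1L) {
  rec <- apply_average_reference(rec)
  events <- detect_ieds(rec, k_sd = k_sd)
  split <- split_by_kind(events)
  streams <- list()
  means <- list()
  for (stream in c("spikes", "sharp_waves")) {
    ev <- split[[stream]]
    if (nrow(ev) < 4L) next
    # epochs are cut from the broadband recording: the duration bands have
    # already separated the kinds, and narrowband epochs ring and discard
    # most of the discharge energy
    tensor <- extract_epochs(rec, ev, window_ms = window_ms)
    sel <- select_rank(tensor, max_rank = max_rank, seed = seed,
                       restarts = restarts)
    # a subtype expresses a dominant atom: the stability-gated rank bounds
    # the number of credible subtypes in this stream
    kr <- k_range[k_range <= max(sel$n_factors, 1L)]
    if (!length(kr)) kr <- 1L
    assign <- cluster_samples(sel$model, k_range = kr, seed = seed)
    streams[[stream]] <- list(tensor = tensor, rank = sel$n_factors,
                              model = sel$model,
                              diagnostics = sel$diagnostics,
                              assignment = assign)
  }
  if (!length(streams)) {
    return(list(events = events, streams = streams, means = list(),
                localized = list(), report = NULL))
  }
  means <- consolidate_clusters(streams, refine_iter = refine_iter)
  localized <- localize_subtypes(lf, means, sources, parc,
                                 lambda_rel = lambda_rel)
  report <- select_target(localized, parc, silence_ratio = silence_ratio)
  list(events = events, streams = streams, means = means,
       localized = localized, report = report)
}

# Pool the stream tensors, seed global cluster labels from the per-stream
# assignments, and run nearest-centroid reassignment passes (correlation with
# each cluster-mean time course). Returns the consolidated cluster means.
consolidate_clusters <- function(streams, refine_iter = 3) {
  arrs <- lapply(streams, function(s) unclass(s$tensor))
  evs <- lapply(streams, function(s) attr(s$tensor, "events"))
  fs <- attr(streams[[1]]$tensor, "sampling_rate")
  channels <- attr(streams[[1]]$tensor, "channels")
  d <- dim(arrs[[1]])
  ns <- vapply(arrs, function(a) dim(a)[3], integer(1))
  x <- array(0, c(d[1], d[2], sum(ns)))
  off <- 0L
  labels <- integer(sum(ns))
  lab_off <- 0L
  for (i in seq_along(arrs)) {
    x[, , off + seq_len(ns[i])] <- arrs[[i]]
    labels[off + seq_len(ns[i])] <- streams[[i]]$assignment$labels + lab_off
    off <- off + ns[i]
    lab_off <- lab_off + streams[[i]]$assignment$k
  }
  events <- dplyr::bind_rows(evs)
  epochs <- matrix(x, d[1] * d[2], sum(ns))  # one column per sample

  for (it in seq_len(max(0L, refine_iter))) {
    ids <- sort(unique(labels))
    cents <- vapply(ids, function(cl) {
      rowMeans(epochs[, labels == cl, drop = FALSE])
    }, numeric(nrow(epochs)))
    newlab <- ids[max.col(stats::cor(epochs, cents), ties.method = "first")]
    if (identical(newlab, labels)) break
    labels <- newlab
  }
  # clusters whose mean time courses coincide up to averaging noise are
  # duplicate views of one subtype: compare cross-correlations after
  # disattenuating by each cluster's split-half reliability
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2L) break
    cents <- vapply(ids, function(cl) {
      rowMeans(epochs[, labels == cl, drop = FALSE])
    }, numeric(nrow(epochs)))
    rel <- vapply(ids, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) return(0.05)
      h1 <- idx[seq(1L, length(idx), by = 2L)]
      h2 <- setdiff(idx, h1)
      r <- stats::cor(rowMeans(epochs[, h1, drop = FALSE]),
                      rowMeans(epochs[, h2, drop = FALSE]))
      max(2 * r / (1 + abs(r)), 0.05)  # Spearman-Brown to the full mean
    }, numeric(1))
    cc <- stats::cor(cents) / sqrt(outer(rel, rel))
    diag(cc) <- -Inf
    if (max(cc) <= 0.9) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    labels[labels == ids[ij[2]]] <- ids[ij[1]]
  }
  ids <- sort(unique(labels))
  lapply(seq_along(ids), function(k) {
    idx <- which(labels == ids[k])
    tc <- matrix(rowMeans(epochs[, idx, drop = FALSE]), d[1], d[2])
    kinds <- events$kind[idx]
    structure(
      list(time_course = tc,
           kind = names(sort(table(kinds), decreasing = TRUE))[1],
           n_events = length(idx), sampling_rate = fs, channels = channels,
           cluster = k, sample_index = idx, events = events[idx, ]),
      class = "irritmap_mean_ied")
  })
}

#' @export
tidy.irritmap_factor_model <- function(x, ...) {
  modes <- list(electrode = x$spatial, time = x$temporal, sample = x$sample)
  dplyr::bind_rows(lapply(names(modes), function(m) {
    mat <- modes[[m]]
    tibble::tibble(mode = m,
                   index = rep(seq_len(nrow(mat)), ncol(mat)),
                   factor = rep(seq_len(ncol(mat)), each = nrow(mat)),
                   value = as.vector(mat))
  }))
}

#' @export
glance.irritmap_factor_model <- function(x, ...) {
  tibble::tibble(n_factors = x$n_factors, fit = x$fit,
                 iterations = length(x$fit_history),
                 converged = x$converged,
                 constraints = paste(names(x$constraints), x$constraints,
                                     sep = "=", collapse = ","))
}

#' Plot PARAFAC sample signatures colored by cluster
#'
#' Scatter plot of the first two sample-signature dimensions (the space in
#' which IED subtypes separate).
#'
#' @param model an `irritmap_factor_model`.
#' @param assignment optional `irritmap_cluster_assignment`.
#' @return A ggplot.
#' @export
plot_sample_signatures <- function(model, assignment = NULL) {
  s <- model$sample
  df <- tibble::tibble(
    f1 = s[, 1],
    f2 = if (ncol(s) >= 2) s[, 2] else 0,
    cluster = factor(if (is.null(assignment)) 1L else assignment$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2,
                                   color = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample signature 1", y = "sample signature 2") +
    ggplot2::theme_minimal()
}
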