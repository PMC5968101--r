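#' IED waveform template
#'
#' Builds a unit-peak interictal-discharge waveform: an asymmetric bi-Gaussian
#' with a fast rise and a slower decay, parameterized so that the
#' full-width-at-half-maximum equals `duration_ms` exactly. Spikes must have
#' durations in \[20, 70\] ms and sharp-waves in \[70, 200\] ms.
#'
#' @param kind `"spike"` or `"sharp_wave"`.
#' @param duration_ms waveform duration (FWHM), ms.
#' @param sampling_rate Hz.
#' @param asymmetry ratio of decay to rise time constants (> 0; default 2).
#' @return An object of class `irritmap_ied_template` with elements
#'   `waveform` (unit-peak numeric vector), `peak_index`, `kind`,
#'   `duration_ms`, `sampling_rate`, `asymmetry`.
#' @export
make_ied_template <- function(kind = c("spike", "sharp_wave"), duration_ms,
                              sampling_rate, asymmetry = 2) {
  kind <- match.arg(kind)
  assert_scalar_number(duration_ms, "duration_ms", positive = TRUE)
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_number(asymmetry, "asymmetry", positive = TRUE)
  band <- if (kind == "spike") c(20, 70) else c(70, 200)
  if (duration_ms < band[1] || duration_ms > band[2]) {
    stop_irritmap(sprintf(
      "A %s must have duration in [%g, %g] ms (got %g).", kind, band[1],
      band[2], duration_ms), "irritmap_template_error")
  }
  # FWHM of the bi-Gaussian is (sigma_rise + sigma_decay) * sqrt(2 log 2)
  sigma_rise <- duration_ms / 1000 / ((1 + asymmetry) * sqrt(2 * log(2)))
  sigma_decay <- asymmetry * sigma_rise
  half <- ceiling(3.5 * sigma_decay * sampling_rate)
  t <- (-half:half) / sampling_rate
  w <- ifelse(t < 0, exp(-t^2 / (2 * sigma_rise^2)),
              exp(-t^2 / (2 * sigma_decay^2)))
  structure(list(kind = kind, duration_ms = duration_ms,
                 sampling_rate = sampling_rate, asymmetry = asymmetry,
                 waveform = w, peak_index = half + 1L),
            class = "irritmap_ied_template")
}

#' @export
print.irritmap_ied_template <- function(x, ...) {
  cat(sprintf("<irritmap_ied_template> %s, FWHM %g ms @ %g Hz (%d samples)\n",
              x$kind, x$duration_ms, x$sampling_rate, length(x$waveform)))
  invisible(x)
}

#' Simulation configuration
#'
#' Describes a synthetic scalp EEG recording containing IED subtypes from
#' known sources. Each subtype is a list with elements `template`
#' (an [make_ied_template()]), `source` (index into the lead-field source
#' space), `n_events`, `amplitude` (nA·m) and, for free-orientation lead
#' fields, `orientation` (unit 3-vector).
#'
#' @param subtypes list of subtype descriptions (see above).
#' @param sampling_rate Hz.
#' @param duration_s recording length, s.
#' @param snr target ratio of mean event peak (best channel) to background
#'   noise SD; ignored when `noise_sd` is given explicitly.
#' @param noise_sd explicit background noise SD (µV); `NULL` to derive from
#'   `snr`. Zero gives a noiseless recording.
#' @param pink_fraction fraction of the background taken from a temporally
#'   correlated AR(1) process (the remainder is white).
#' @param ar_coef AR(1) coefficient of the correlated component.
#' @param min_gap_ms minimum separation between consecutive events, enforced
#'   globally across subtypes so that extraction epochs never overlap.
#' @param seed integer seed; every random draw in the simulation derives from
#'   it.
#' @return An object of class `irritmap_sim_config`.
#' @export
sim_config <- function(subtypes, sampling_rate = 500, duration_s = 120,
                       snr = 5, noise_sd = NULL, pink_fraction = 0.5,
                       ar_coef = 0.95, min_gap_ms = 500, seed = 1L) {
  if (!length(subtypes)) {
    stop_irritmap("At least one subtype is required.",
                  "irritmap_config_error")
  }
  for (st in subtypes) {
    if (!inherits(st$template, "irritmap_ied_template")) {
      stop_irritmap("Each subtype needs an `irritmap_ied_template`.",
                    "irritmap_config_error")
    }
    if (is.null(st$source) || is.null(st$n_events)) {
      stop_irritmap("Each subtype needs `source` and `n_events`.",
                    "irritmap_config_error")
    }
  }
  if (!is.null(noise_sd) && noise_sd < 0) {
    stop_irritmap("`noise_sd` must be >= 0.", "irritmap_config_error")
  }
  if (is.null(noise_sd)) assert_scalar_number(snr, "snr", positive = TRUE)
  structure(list(subtypes = subtypes, sampling_rate = sampling_rate,
                 duration_s = duration_s, snr = snr, noise_sd = noise_sd,
                 pink_fraction = pink_fraction, ar_coef = ar_coef,
                 min_gap_ms = min_gap_ms, seed = as.integer(seed)),
            class = "irritmap_sim_config")
}

# Schedule event peak times subtype by subtype; each subtype's draw stream is
# seeded independently so its times do not depend on later subtypes, while the
# global minimum gap is still enforced against already-placed events.
schedule_events <- function(cfg, margin_s) {
  fs <- cfg$sampling_rate
  gap <- cfg$min_gap_ms / 1000
  placed <- numeric(0)
  out <- vector("list", length(cfg$subtypes))
  for (k in seq_along(cfg$subtypes)) {
    n <- cfg$subtypes[[k]]$n_events
    if (n == 0L) {
      out[[k]] <- numeric(0)
      next
    }
    times <- with_seed(derive_seed(cfg$seed, k), {
      got <- numeric(0)
      tries <- 0L
      while (length(got) < n && tries < 20000L) {
        cand <- runif(1, margin_s, cfg$duration_s - margin_s)
        if (!length(placed) || min(abs(placed - cand)) >= gap) {
          if (!length(got) || min(abs(got - cand)) >= gap) {
            got <- c(got, cand)
          }
        }
        tries <- tries + 1L
      }
      if (length(got) < n) {
        stop_irritmap(
          "Could not place all events with the requested minimum gap.",
          "irritmap_config_error")
      }
      got
    })
    placed <- c(placed, times)
    out[[k]] <- round(times * fs) + 1L  # peak samples
  }
  out
}

#' Simulate a scalp EEG recording with known IED subtypes
#'
#' Each event adds `amplitude x lead-field column x template waveform` to the
#' clean projection; background noise (white + AR(1) mixture, scaled so the
#' mean event peak over background SD matches the configured SNR) is added on
#' top. All randomness derives from `cfg$seed`, so repeated calls are
#' identical.
#'
#' @param cfg an [sim_config()].
#' @param lf an [new_leadfield()] covering every configured source.
#' @param sources optional [source_space()]; if given, true parcel ids are
#'   recorded in the ground truth.
#' @return A list with elements `recording` (an `irritmap_recording`) and
#'   `truth` (list of `events` and `subtypes` tibbles).
#' @export
simulate_recording <- function(cfg, lf, sources = NULL) {
  stopifnot(inherits(cfg, "irritmap_sim_config"),
            inherits(lf, "irritmap_leadfield"))
  fs <- cfg$sampling_rate
  nt <- round(cfg$duration_s * fs)
  nch <- nrow(lf$gain)
  for (st in cfg$subtypes) {
    if (st$source < 1L || st$source > lf$n_sources) {
      stop_irritmap("Subtype source index outside the lead field.",
                    "irritmap_config_error")
    }
  }
  margin_s <- max(vapply(cfg$subtypes, function(st) {
    length(st$template$waveform) / fs
  }, numeric(1))) / 2 + cfg$min_gap_ms / 2000

  peaks <- schedule_events(cfg, margin_s)
  clean <- matrix(0, nch, nt)
  topo <- matrix(0, nch, length(cfg$subtypes))
  for (k in seq_along(cfg$subtypes)) {
    st <- cfg$subtypes[[k]]
    amp <- st$amplitude %||% 1
    if (lf$orientation == "free") {
      ori <- st$orientation
      if (is.null(ori)) {
        stop_irritmap(
          "Free-orientation lead fields need a subtype `orientation`.",
          "irritmap_config_error")
      }
      g <- lf$gain[, (3 * st$source - 2):(3 * st$source)] %*% ori
    } else {
      g <- lf$gain[, st$source]
    }
    topo[, k] <- amp * as.vector(g)
    wv <- st$template$waveform
    off <- seq_along(wv) - st$template$peak_index
    for (p in peaks[[k]]) {
      idx <- p + off
      keep <- idx >= 1L & idx <= nt
      clean[, idx[keep]] <- clean[, idx[keep]] +
        topo[, k] %o% wv[keep]
    }
  }

  noise_sd <- cfg$noise_sd
  if (is.null(noise_sd)) {
    mean_peak <- mean(vapply(seq_along(cfg$subtypes), function(k) {
      max(abs(topo[, k]))
    }, numeric(1))[lengths(peaks) > 0])
    noise_sd <- mean_peak / cfg$snr
  }
  noise <- matrix(0, nch, nt)
  if (noise_sd > 0) {
    rho <- cfg$pink_fraction
    norm <- sqrt((1 - rho)^2 + rho^2)
    noise <- with_seed(derive_seed(cfg$seed, 0L), {
      white <- matrix(rnorm(nch * nt), nch, nt)
      if (rho > 0) {
        innov <- matrix(rnorm(nch * nt), nch, nt)
        ar <- t(apply(innov, 1L, function(e) {
          stats::filter(e * sqrt(1 - cfg$ar_coef^2), cfg$ar_coef,
                        method = "recursive")
        }))
        ((1 - rho) * white + rho * ar) / norm
      } else white
    })
    noise <- noise * noise_sd
  }

  rec <- new_recording(clean + noise, fs)
  events <- tibble::tibble(
    peak_sample = unlist(peaks),
    subtype = rep(seq_along(peaks), lengths(peaks)),
    source = rep(vapply(cfg$subtypes, function(s) as.integer(s$source),
                        integer(1)), lengths(peaks)))
  events <- dplyr::arrange(events, .data$peak_sample)
  subtypes <- tibble::tibble(
    subtype = seq_along(cfg$subtypes),
    kind = vapply(cfg$subtypes, function(s) s$template$kind, character(1)),
    source = vapply(cfg$subtypes, function(s) as.integer(s$source),
                    integer(1)),
    n_events = lengths(peaks),
    parcel_id = if (is.null(sources)) NA_integer_ else
      sources$parcel_ids[vapply(cfg$subtypes, function(s)
        as.integer(s$source), integer(1))])
  list(recording = rec,
       truth = list(events = events, subtypes = subtypes,
                    noise_sd = noise_sd))
}

# Marker panel emulated by the histology generator; `count` markers are
# rounded to integers, `area` markers are stained-area fractions, lengths are
# mm.
histology_marker_panel <- function() {
  tibble::tibble(
    marker = c("soma_count", "process_count", "GFAP_area", "IL1b_area",
               "TNFa_area", "HMGB1_area", "NR2B_area", "mGluR5_area",
               "GABAAa6_area", "cuffing_density", "cortical_thickness_mm"),
    type = c("count", "count", "area", "area", "area", "area", "area",
             "area", "area", "count", "length"),
    baseline = c(40, 60, 0.06, 0.05, 0.05, 0.05, 0.06, 0.05, 0.05, 3,
                 1.7))
}

#' Simulate paired target/control histology measurement tables
#'
#' Emulates the quantification of replicate microscope fields from the
#' irritative-zone target region and its contralateral control: each zone
#' contributes `n_replicates` measurements per marker and region, with a
#' zone-level random effect shared between the paired regions and
#' independent replicate noise. Target means are `control mean * (1 +
#' effect)`.
#'
#' @param n_zones number of paired zones (the study analog is 8).
#' @param markers character vector of marker names; defaults to the full
#'   panel (anatomical, inflammatory, functional markers, cuffing density and
#'   cortical thickness).
#' @param effect_sizes named numeric vector of relative target effects per
#'   marker (0 = null); unnamed scalar recycles to all markers.
#' @param noise_sd replicate noise SD as a fraction of the marker baseline.
#' @param zone_sd SD of the zone-level multiplicative random effect.
#' @param n_replicates measurements per zone, region and marker.
#' @param seed integer seed.
#' @return A list with `table` (long tibble: `zone`, `marker`, `region`,
#'   `replicate`, `value`) and `truth` (configured effects and means).
#' @export
simulate_histology_tables <- function(n_zones = 8, markers = NULL,
                                      effect_sizes = 0, noise_sd = 0.35,
                                      zone_sd = 0.15, n_replicates = 6,
                                      seed = 1L) {
  if (n_zones < 2L) {
    stop_irritmap("`n_zones` must be >= 2.", "irritmap_config_error")
  }
  if (noise_sd < 0) {
    stop_irritmap("`noise_sd` must be >= 0.", "irritmap_config_error")
  }
  panel <- histology_marker_panel()
  if (is.null(markers)) markers <- panel$marker
  panel <- panel[match(markers, panel$marker), ]
  panel$baseline[is.na(panel$baseline)] <- 1
  panel$type[is.na(panel$type)] <- "area"
  panel$marker <- markers
  if (is.null(names(effect_sizes))) {
    effect_sizes <- setNames(rep_len(effect_sizes, length(markers)), markers)
  } else {
    full <- setNames(rep(0, length(markers)), markers)
    full[intersect(names(effect_sizes), markers)] <-
      effect_sizes[intersect(names(effect_sizes), markers)]
    effect_sizes <- full
  }
  tab <- with_seed(seed, {
    grid <- tidyr::expand_grid(zone = seq_len(n_zones),
                               marker = markers,
                               replicate = seq_len(n_replicates))
    zone_eff <- matrix(rnorm(n_zones * length(markers), 0, zone_sd),
                       n_zones, length(markers),
                       dimnames = list(NULL, markers))
    rows <- lapply(c("control", "target"), function(region) {
      g <- grid
      g$region <- region
      mu <- panel$baseline[match(g$marker, panel$marker)]
      eff <- if (region == "target") effect_sizes[g$marker] else 0
      mean_val <- mu * (1 + eff) *
        (1 + zone_eff[cbind(g$zone, match(g$marker, markers))])
      g$value <- mean_val + rnorm(nrow(g), 0, noise_sd * mu)
      g
    })
    dplyr::bind_rows(rows)
  })
  tab$value <- pmax(tab$value, 0)
  is_count <- panel$type[match(tab$marker, panel$marker)] == "count"
  tab$value[is_count] <- round(tab$value[is_count])
  tab <- dplyr::select(tab, "zone", "marker", "region", "replicate", "value")
  list(table = tab,
       truth = list(effects = effect_sizes,
                    baselines = setNames(panel$baseline, markers),
                    noise_sd = noise_sd, zone_sd = zone_sd,
                    n_replicates = n_replicates))
}

#' Average replicates to one value per zone, region and marker
#'
#' The unit of analysis for the paired statistics is the zone: the
#' `n_replicates` microscope fields per region are averaged first.
#'
#' @param table long measurement tibble from [simulate_histology_tables()]
#'   (columns `zone`, `marker`, `region`, `value`).
#' @return A tibble with one row per zone x marker and columns `target`,
#'   `control`.
#' @export
histology_zone_means <- function(table) {
  table |>
    dplyr::group_by(.data$zone, .data$marker, .data$region) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "value")
}
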