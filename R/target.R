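# Cortical-structure naming convention (Paxinos-Watson identifiers): right
# hemisphere ids 1-48, left partners = right id + 48.
parcel_table <- function() {
  region <- c("AID", "AIP", "AIV", "Apir", "Au1", "AuD", "AuV", "Cg1",
              "Cg2", "DI", "DIEnt", "DLEnt", "DLO", "Ect", "Fr3", "GI",
              "GIDI", "LPtA", "M1", "M2", "MEnt", "MPtA", "PRh", "PtPC",
              "PtPD", "PtPR", "RSD", "RSGb", "RSGc", "S1", "S1BF", "S1DZ",
              "S1DZ0", "S1FL", "S1HL", "S1J", "S1Sh", "S1Tr", "S1ULp",
              "S2", "TeA", "V1", "V1B", "V1M", "V2L", "V2ML", "V2MM",
              "VIEnt")
  tibble::tibble(region = region, right = seq_along(region),
                 left = seq_along(region) + 48L)
}

#' Cortical parcellation lookup
#'
#' Region-id convention for the rat cortical atlas: each named structure has
#' a right-hemisphere id (1-48) and a left partner (id + 48). The
#' parcellation carries the id-to-name/hemisphere lookup and the
#' contralateral pairing used to pick control regions.
#'
#' @param used_ids optional integer vector of *right* ids to restrict the
#'   table to (both hemispheres of each pair are kept).
#' @return An `irritmap_parcellation`: tibble with columns `id`, `region`,
#'   `hemisphere`, `partner`.
#' @export
parcellation <- function(used_ids = NULL) {
  tab <- parcel_table()
  if (!is.null(used_ids)) {
    if (!all(used_ids %in% tab$right)) {
      stop_irritmap("`used_ids` must be right-hemisphere ids (1-48).",
                    "irritmap_lookup_error")
    }
    tab <- tab[tab$right %in% used_ids, ]
  }
  out <- dplyr::bind_rows(
    tibble::tibble(id = tab$right, region = tab$region,
                   hemisphere = "right", partner = tab$left),
    tibble::tibble(id = tab$left, region = tab$region,
                   hemisphere = "left", partner = tab$right))
  structure(dplyr::arrange(out, .data$id), class = c("irritmap_parcellation",
                                                     class(out)))
}

#' Look up a parcel id
#'
#' @param id integer parcel id (right: 1-48, left: 49-96).
#' @param parc a [parcellation()].
#' @return A list with `region` and `hemisphere`.
#' @export
parcel_label <- function(id, parc = parcellation()) {
  row <- parc[parc$id == id, ]
  if (!nrow(row)) {
    stop_irritmap(sprintf("Unknown parcel id %s.", format(id)),
                  "irritmap_lookup_error")
  }
  list(region = row$region[[1]], hemisphere = row$hemisphere[[1]])
}

#' Contralateral partner of a parcel
#'
#' @inheritParams parcel_label
#' @return Integer id of the mirrored parcel in the other hemisphere.
#' @export
contralateral_id <- function(id, parc = parcellation()) {
  row <- parc[parc$id == id, ]
  if (!nrow(row)) {
    stop_irritmap(sprintf("Parcel id %s has no contralateral partner.",
                          format(id)), "irritmap_selection_error")
  }
  as.integer(row$partner[[1]])
}

#' Select the target (irritative) and control parcels
#'
#' Applies the two selection criteria: the target is the parcel where the
#' source distribution of the *most frequent* IED subtype is maximal (ties
#' broken by larger peak power), and its contralateral partner is the
#' control, which must be silent — for *every* subtype the control-parcel
#' power may not exceed `silence_ratio` times that subtype's target-parcel
#' power.
#'
#' @param localized list from [localize_subtypes()].
#' @param parc a [parcellation()].
#' @param silence_ratio maximum tolerated contralateral/target power ratio.
#' @return An `irritmap_iz_report`: list with `target_parcel`,
#'   `control_parcel`, `silent` (verdict), `subtypes` (per-subtype tibble),
#'   `n_spikes`, `n_sharp_waves`, `silence_ratio`.
#' @export
select_target <- function(localized, parc = parcellation(),
                          silence_ratio = 0.2) {
  if (!length(localized)) {
    stop_irritmap("At least one localized subtype is required.",
                  "irritmap_selection_error")
  }
  counts <- vapply(localized, function(l) l$n_events, numeric(1))
  peak_power <- vapply(localized, function(l) {
    l$parcel_power$power[1]
  }, numeric(1))
  most <- which(counts == max(counts))
  lead <- most[which.max(peak_power[most])]
  target <- localized[[lead]]$peak_parcel
  control <- contralateral_id(target, parc)

  parcel_power_at <- function(l, id) {
    p <- l$parcel_power$power[l$parcel_power$parcel_id == id]
    if (length(p)) p[[1]] else 0
  }
  per <- lapply(seq_along(localized), function(k) {
    l <- localized[[k]]
    tp <- parcel_power_at(l, target)
    cp <- parcel_power_at(l, control)
    pk <- l$parcel_power$power[1]
    lab <- parcel_label(l$peak_parcel, parc)
    tibble::tibble(
      subtype = k, kind = l$kind %||% NA_character_, n_events = l$n_events,
      peak_parcel = l$peak_parcel, peak_region = lab$region,
      peak_hemisphere = lab$hemisphere,
      latency_ms = l$map$latency_ms,
      peak_power = pk, target_power = tp, control_power = cp,
      # "silent": the control parcel carries a negligible fraction of the
      # subtype's own peak activation
      contra_ratio = ifelse(pk > 0, cp / pk, Inf))
  })
  per <- dplyr::bind_rows(per)
  silent <- all(per$contra_ratio <= silence_ratio)
  kinds <- per$kind
  structure(list(
    target_parcel = target, control_parcel = control, silent = silent,
    lead_subtype = lead, subtypes = per,
    n_spikes = sum(per$n_events[kinds == "spike"], na.rm = TRUE),
    n_sharp_waves = sum(per$n_events[kinds == "sharp_wave"], na.rm = TRUE),
    silence_ratio = silence_ratio, parcellation = parc),
    class = "irritmap_iz_report")
}

#' @export
print.irritmap_iz_report <- function(x, ...) {
  tl <- parcel_label(x$target_parcel, x$parcellation)
  cl <- parcel_label(x$control_parcel, x$parcellation)
  cat(sprintf(
    paste0("<irritmap_iz_report> target %s-%s (%d), control %s-%s (%d), ",
           "contralateral silence: %s\n  %d spikes, %d sharp-waves over %d subtypes\n"),
    tl$region, tl$hemisphere, x$target_parcel, cl$region, cl$hemisphere,
    x$control_parcel, ifelse(x$silent, "yes", "NO"), x$n_spikes,
    x$n_sharp_waves, nrow(x$subtypes)))
  invisible(x)
}

#' @export
tidy.irritmap_iz_report <- function(x, ...) {
  x$subtypes
}

#' @export
glance.irritmap_iz_report <- function(x, ...) {
  tl <- parcel_label(x$target_parcel, x$parcellation)
  tibble::tibble(
    target_parcel = x$target_parcel, target_region = tl$region,
    target_hemisphere = tl$hemisphere, control_parcel = x$control_parcel,
    silent = x$silent, n_subtypes = nrow(x$subtypes),
    n_spikes = x$n_spikes, n_sharp_waves = x$n_sharp_waves)
}

#' Write an irritative-zone report as JSON
#'
#' @param report an `irritmap_iz_report`.
#' @param path output path.
#' @export
write_iz_report <- function(report, path) {
  tl <- parcel_label(report$target_parcel, report$parcellation)
  cl <- parcel_label(report$control_parcel, report$parcellation)
  out <- list(
    n_spikes = report$n_spikes, n_sharp_waves = report$n_sharp_waves,
    localized_structures = report$subtypes$peak_parcel,
    target = list(parcel = report$target_parcel, region = tl$region,
                  hemisphere = tl$hemisphere),
    control = list(parcel = report$control_parcel, region = cl$region,
                   hemisphere = cl$hemisphere),
    contralateral_silent = report$silent,
    subtypes = report$subtypes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
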