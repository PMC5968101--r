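test_that("IED templates have exact FWHM and respect duration bands", {
  tpl <- make_ied_template("spike", 45, 1000, asymmetry = 8)
  expect_equal(max(abs(tpl$waveform)), 1)
  fwhm_samples <- sum(abs(tpl$waveform) >= 0.5)
  expect_lte(abs(fwhm_samples - 45), 1)
  sw <- make_ied_template("sharp_wave", 120, 1000)
  expect_lte(abs(sum(abs(sw$waveform) >= 0.5) - 120), 1)
  expect_error(make_ied_template("spike", 120, 1000),
               class = "irritmap_template_error")
  expect_error(make_ied_template("sharp_wave", 45, 1000),
               class = "irritmap_template_error")
})

test_that("simulated recordings are deterministic and correctly booked", {
  geom <- fix_geom()
  cfg <- study_config(seed = 9, geom = geom, n_events = 5, duration_s = 40)
  sim1 <- simulate_recording(cfg, geom$leadfield, geom$sources)
  sim2 <- simulate_recording(cfg, geom$leadfield, geom$sources)
  expect_identical(sim1$recording$data, sim2$recording$data)
  expect_equal(nrow(sim1$truth$events), 15)
  expect_equal(sort(unique(sim1$truth$events$subtype)), 1:3)
  expect_equal(sim1$truth$subtypes$n_events, rep(5L, 3))
  expect_equal(sim1$truth$subtypes$parcel_id, c(49L, 55L, 52L))
  # global minimum gap
  gaps <- diff(sort(sim1$truth$events$peak_sample))
  expect_true(all(gaps >= 0.5 * cfg$sampling_rate))
})

test_that("event insertion is additive in the clean projection", {
  geom <- fix_geom()
  base <- study_config(seed = 4, geom = geom, n_events = 4, duration_s = 30)
  mute <- function(cfg, keep) {
    cfg$subtypes <- lapply(seq_along(cfg$subtypes), function(k) {
      st <- cfg$subtypes[[k]]
      if (!(k %in% keep)) st$amplitude <- 0
      st
    })
    cfg$noise_sd <- 0
    cfg
  }
  full <- simulate_recording(mute(base, 1:3), geom$leadfield)
  a <- simulate_recording(mute(base, 1), geom$leadfield)
  b <- simulate_recording(mute(base, 2:3), geom$leadfield)
  expect_equal(full$recording$data, a$recording$data + b$recording$data,
               tolerance = 1e-12)
})

test_that("empirical SNR lands within 20% of the configured target", {
  geom <- fix_geom()
  cfg <- study_config(seed = 2, geom = geom, n_events = 8, duration_s = 60,
                      snr = 5)
  sim <- simulate_recording(cfg, geom$leadfield, geom$sources)
  clean_cfg <- cfg
  clean_cfg$noise_sd <- 0
  clean <- simulate_recording(clean_cfg, geom$leadfield)$recording$data
  noise <- sim$recording$data - clean
  peaks <- vapply(seq_len(nrow(sim$truth$events)), function(i) {
    p <- sim$truth$events$peak_sample[i]
    max(abs(clean[, p]))
  }, numeric(1))
  snr_emp <- mean(peaks) / sd(noise[which.max(rowSums(clean^2)), ])
  expect_gt(snr_emp, 4)
  expect_lt(snr_emp, 6)
})

test_that("background noise has a decaying (reddened) spectrum", {
  geom <- fix_geom()
  slopes <- vapply(1:5, function(s) {
    cfg <- sim_config(list(list(template = make_ied_template("spike", 40,
                                                             500),
                                source = 1, n_events = 0)),
                      sampling_rate = 500, duration_s = 20, noise_sd = 1,
                      seed = s)
    sim <- simulate_recording(cfg, geom$leadfield)
    sp <- stats::spec.pgram(sim$recording$data[1, ], plot = FALSE,
                            spans = 15)
    coef(lm(log(sp$spec) ~ log(sp$freq)))[2]
  }, numeric(1))
  expect_lt(mean(slopes), 0)
})

test_that("histology tables honour configured effects and pairing", {
  out0 <- simulate_histology_tables(n_zones = 8, effect_sizes = 0,
                                    noise_sd = 0, zone_sd = 0.1, seed = 1)
  zm <- histology_zone_means(out0$table)
  expect_true(all(abs(zm$target - zm$control) < 1e-12))
  expect_equal(dplyr::n_distinct(out0$table$zone), 8L)
  expect_equal(dplyr::n_distinct(out0$table$replicate), 6L)

  out <- simulate_histology_tables(n_zones = 8,
                                   effect_sizes = c(GFAP_area = 0.5),
                                   noise_sd = 0, zone_sd = 0, seed = 2)
  zm <- histology_zone_means(out$table)
  gf <- dplyr::filter(zm, .data$marker == "GFAP_area")
  expect_equal(mean(gf$target) / mean(gf$control), 1.5, tolerance = 1e-9)
  counts <- dplyr::filter(out$table, .data$marker == "soma_count")
  expect_true(all(counts$value == round(counts$value)))
  expect_error(simulate_histology_tables(noise_sd = -1),
               class = "irritmap_config_error")
  expect_error(simulate_histology_tables(n_zones = 1),
               class = "irritmap_config_error")
})

test_that("null histology tables reject near the nominal level", {
  hits <- vapply(1:300, function(s) {
    tab <- simulate_histology_tables(n_zones = 8, markers = "GFAP_area",
                                     effect_sizes = 0, seed = s)$table
    zm <- histology_zone_means(tab)
    paired_compare(zm$target, zm$control)$p_value < 0.05
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_gt(mean(hits), ci[1] - 0.01)
  expect_lt(mean(hits), ci[2] + 0.01)
})
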