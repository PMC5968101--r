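test_that("band-pass keeps the passband and rejects the stopband", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  rec <- new_recording(rbind(sin(2 * pi * 30 * t), sin(2 * pi * 30 * t)), fs)
  out <- bandpass(rec, 15, 50)
  mid <- 1000:4000
  expect_gt(max(abs(out$data[1, mid])), 0.95)
  rec2 <- new_recording(rbind(sin(2 * pi * 2 * t), sin(2 * pi * 2 * t)), fs)
  out2 <- bandpass(rec2, 15, 50)
  atten_db <- 20 * log10(max(abs(out2$data[1, mid])))
  expect_lt(atten_db, -20)
  # designed transfer function predicts the measured attenuation
  bf <- signal::butter(4, c(15, 50) / (fs / 2), type = "pass")
  h <- signal::freqz(bf$b, bf$a, Fs = fs, n = 2048)
  h2 <- abs(h$h[which.min(abs(h$f - 2))])^2  # squared: forward-backward
  expect_equal(max(abs(out2$data[1, mid])), h2, tolerance = 0.5 * h2 + 1e-4)
  expect_error(bandpass(rec, 50, 15), class = "irritmap_filter_error")
  expect_error(bandpass(rec, 15, 400), class = "irritmap_filter_error")
})

test_that("zero input yields no events", {
  rec <- new_recording(matrix(0, 4, 2000), 500)
  expect_equal(nrow(detect_events(rec)), 0)
})

test_that("noiseless simulated IEDs are all recovered at the right times", {
  geom <- fix_geom()
  cfg <- study_config(seed = 6, geom = geom, n_events = 6, duration_s = 40)
  cfg$noise_sd <- 0
  sim <- simulate_recording(cfg, geom$leadfield, geom$sources)
  rec <- apply_average_reference(sim$recording)
  ev <- detect_ieds(rec)
  tr <- sim$truth$events
  expect_equal(nrow(ev), nrow(tr))
  matched <- vapply(tr$peak_sample, function(p) {
    min(abs(ev$peak_sample - p))
  }, numeric(1))
  expect_true(all(matched <= 1))
  # durations fall in the right bands and kinds follow the truth
  kinds <- vapply(tr$peak_sample, function(p) {
    ev$kind[which.min(abs(ev$peak_sample - p))]
  }, character(1))
  expect_equal(kinds, c("spike", "spike", "sharp_wave")[tr$subtype])
})

test_that("raising the threshold never yields more events", {
  geom <- fix_geom()
  cfg <- study_config(seed = 12, geom = geom, n_events = 6, duration_s = 40)
  sim <- simulate_recording(cfg, geom$leadfield, geom$sources)
  rec <- apply_average_reference(sim$recording)
  counts <- vapply(c(3, 4, 5, 6), function(k) {
    nrow(detect_events(bandpass(rec, 15, 50), k_sd = k, duration_rec = rec))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split_by_kind partitions on the 70 ms boundary and conserves", {
  ev <- empty_events()[0, ]
  ev <- tibble::tibble(peak_sample = 1:4, peak_s = 1:4 / 500,
                       channel = "a", amp_uV = 1,
                       duration_ms = c(30, 90, 150, 60),
                       kind = "")
  sp <- split_by_kind(ev)
  expect_equal(sort(sp$spikes$duration_ms), c(30, 60))
  expect_equal(sort(sp$sharp_waves$duration_ms), c(90, 150))
  expect_equal(nrow(sp$spikes) + nrow(sp$sharp_waves), nrow(ev))
  # boundary: exactly 70 ms is a sharp-wave
  ev70 <- dplyr::mutate(ev[1, ], duration_ms = 70)
  expect_equal(nrow(split_by_kind(ev70)$sharp_waves), 1L)
  empty <- split_by_kind(empty_events())
  expect_equal(nrow(empty$spikes), 0L)
  expect_equal(nrow(empty$sharp_waves), 0L)
})

test_that("epoch extraction is shape-stable, centers peaks and baselines", {
  fs <- 1000
  rec <- new_recording(matrix(rnorm(32 * 5000), 32), fs)
  ev <- tibble::tibble(peak_sample = c(10L, 1000L, 2000L, 4996L))
  expect_message(tens <- extract_epochs(rec, ev, window_ms = 300),
                 "close to the recording edge")
  d <- dim(tens)
  expect_equal(d[1], 32)
  expect_equal(d[2], 301)  # 300 ms at 1000 Hz, centered window
  expect_equal(d[3], 2)    # edge events dropped
  # constant channel is zero after baseline subtraction
  rec2 <- new_recording(rbind(rep(5, 3000), rnorm(3000)), fs)
  t2 <- extract_epochs(rec2, tibble::tibble(peak_sample = 1500L), 300)
  expect_equal(max(abs(t2[1, , 1])), 0)
  expect_error(extract_epochs(rec2, tibble::tibble(peak_sample = 100L),
                              window_ms = 10000),
               class = "irritmap_epoch_error")
})

test_that("event tables round-trip through CSV", {
  ev <- tibble::tibble(peak_sample = c(101L, 402L), peak_s = c(0.2, 0.802),
                       channel = c("E01", "E07"), amp_uV = c(12.5, -8.1),
                       duration_ms = c(44.2, 120.8),
                       kind = c("spike", "sharp_wave"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  ev2 <- read_events(path, sampling_rate = 500)
  expect_equal(ev2$peak_sample, ev$peak_sample)
  expect_equal(ev2$duration_ms, ev$duration_ms)
  expect_equal(ev2$kind, ev$kind)
})
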