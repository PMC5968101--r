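test_that("sLORETA localizes every toy source exactly (noiseless)", {
  lf <- fix_geom()$leadfield
  hits <- vapply(seq_len(lf$n_sources), function(s) {
    map <- sloreta(lf, lf$gain[, s], lambda_rel = 1e-6)
    which.max(map$power) == s
  }, logical(1))
  expect_true(all(hits))
})

test_that("sLORETA matches a dense linear-algebra oracle to 1e-10", {
  g <- matrix(c(1, 2, 0.5, -1, 0.3, 2, 0.2, -1, 1, 0.5, 0.5, -2), 4, 3,
              byrow = TRUE)
  g <- sweep(g, 2, colMeans(g))
  lf <- new_leadfield(g, 3, "fixed", referenced = TRUE)
  y <- as.vector(g %*% c(1, -0.5, 0.2))
  y <- y - mean(y)
  map <- sloreta(lf, y, lambda_rel = 1e-3)
  n <- 4
  h <- diag(n) - 1 / n
  lam <- 1e-3 * sum(diag(g %*% t(g))) / n
  minv <- MASS::ginv(g %*% t(g) + lam * h)
  tm <- t(g) %*% minv
  jj <- as.vector(tm %*% y)
  s <- tm %*% g
  oracle <- jj^2 / diag(s)
  expect_lt(max(abs(map$power - oracle)), 1e-10)
  # zero topography -> zero power
  expect_equal(max(sloreta(lf, rep(0, 4))$power), 0)
})

test_that("sLORETA enforces its referencing contract", {
  g <- matrix(rnorm(12), 4, 3)
  lf_raw <- new_leadfield(g, 3, "fixed", referenced = FALSE)
  expect_error(sloreta(lf_raw, rnorm(4)), class = "irritmap_contract_error")
  lf <- apply_average_reference(lf_raw)
  expect_error(sloreta(lf, c(1, 1, 1, 2)),
               class = "irritmap_contract_error")
  expect_error(sloreta(lf, c(1, -1, 0, 0), lambda_rel = -1),
               class = "irritmap_contract_error")
})

test_that("rescaling the topography does not move the power maximum", {
  lf <- fix_geom()$leadfield
  topo <- lf$gain[, 17]
  m1 <- sloreta(lf, topo, lambda_rel = 1e-4)
  m2 <- sloreta(lf, 3.7 * topo, lambda_rel = 1e-4)
  expect_equal(which.max(m1$power), which.max(m2$power))
  expect_equal(m2$power / max(m2$power), m1$power / max(m1$power),
               tolerance = 1e-9)
})

test_that("two-thirds latency follows the triangle geometry exactly", {
  # triangular GFP peaking at 150 ms with value 3: rising edge from 100 ms,
  # crossing GFP = 2 at 100 + 50 * 2/3 ms
  fs <- 1000
  nt <- 301
  gfp_target <- rep(0, nt)
  ramp <- 101:151
  gfp_target[ramp] <- seq(0, 3, length.out = length(ramp))
  gfp_target[152:201] <- seq(3, 0, length.out = 51)[-1]
  # build a 2-channel epoch whose across-channel sd equals gfp_target
  tc <- rbind(gfp_target / sqrt(2), -gfp_target / sqrt(2))
  mi <- structure(list(time_course = tc, sampling_rate = fs,
                       kind = "spike", n_events = 1, cluster = 1),
                  class = "irritmap_mean_ied")
  lat <- twothirds_latency(mi)
  expect_equal(lat, round(100 + 50 * 2 / 3))
  # falling phase option crosses after the peak
  expect_gt(twothirds_latency(mi, phase = "falling"), 150)
  # monotone GFP to the edge: warns, stays before the edge
  tc2 <- rbind(seq(0.8, 1, length.out = 200),
               -seq(0.8, 1, length.out = 200))
  mi2 <- structure(list(time_course = tc2, sampling_rate = fs,
                        kind = "spike", n_events = 1, cluster = 1),
                   class = "irritmap_mean_ied")
  expect_warning(lat2 <- twothirds_latency(mi2), "2/3")
  expect_lt(lat2, 199 / fs * 1000)
  # a rising ramp that does cross 2/3 before the edge needs no warning
  tc3 <- rbind(seq(0, 1, length.out = 200), -seq(0, 1, length.out = 200))
  mi3 <- mi2
  mi3$time_course <- tc3
  expect_lt(twothirds_latency(mi3), 199 / fs * 1000)
  flat <- structure(list(time_course = matrix(1, 3, 50),
                         sampling_rate = fs),
                    class = "irritmap_mean_ied")
  expect_error(twothirds_latency(flat), class = "irritmap_latency_error")
})

test_that("single simulated subtypes localize to their true parcels", {
  geom <- fix_geom()
  lf <- geom$leadfield
  # clean epoch built directly from the lead-field projection
  src <- which(geom$sources$parcel_ids == 51L)[5]
  tpl <- make_ied_template("spike", 40, 500)
  nt <- 151
  wv <- c(rep(0, 40), tpl$waveform, rep(0, nt))
  tc <- outer(lf$gain[, src], wv[seq_len(nt)])
  mi <- structure(list(time_course = tc, sampling_rate = 500,
                       kind = "spike", n_events = 10, cluster = 1),
                  class = "irritmap_mean_ied")
  loc <- localize_subtypes(lf, list(mi), geom$sources, geom$parcellation,
                           lambda_rel = 1e-4)
  expect_equal(loc[[1]]$peak_parcel, 51L)
  # mirrored source yields the mirrored peak parcel
  src_r <- which(geom$sources$parcel_ids == 3L)[5]
  mi_r <- mi
  mi_r$time_course <- outer(lf$gain[, src_r], wv[seq_len(nt)])
  loc2 <- localize_subtypes(lf, list(mi, mi_r), geom$sources,
                            geom$parcellation, lambda_rel = 1e-4)
  expect_equal(loc2[[2]]$peak_parcel, 3L)
  expect_equal(length(localize_subtypes(lf, list(), geom$sources,
                                        geom$parcellation)), 0L)
})

test_that("target selection applies the frequency and silence criteria", {
  parc <- parcellation()
  fake <- function(peak, n_events, powers, kind = "spike") {
    pp <- tibble::tibble(parcel_id = as.integer(names(powers)),
                         power = as.numeric(powers)) |>
      dplyr::arrange(dplyr::desc(power))
    list(map = structure(list(power = pp$power, latency_ms = 10,
                              subtype = 1),
                         class = "irritmap_source_map"),
         peak_parcel = peak, parcel_power = pp, kind = kind,
         n_events = n_events)
  }
  # one active parcel only -> that parcel is the target, verdict true
  one <- fake(67L, 10, c(`67` = 1, `19` = 0.01))
  rep1 <- select_target(list(one), parc)
  expect_equal(rep1$target_parcel, 67L)
  expect_equal(rep1$control_parcel, 19L)
  expect_true(rep1$silent)
  # contralateral co-activation at 50% with ratio 0.2 -> verdict false
  co <- fake(67L, 10, c(`67` = 1, `19` = 0.5))
  expect_false(select_target(list(co), parc, silence_ratio = 0.2)$silent)
  # loosening the ratio never flips true -> false
  verdicts <- vapply(c(0.1, 0.2, 0.5, 0.6, 1), function(r) {
    select_target(list(co), parc, silence_ratio = r)$silent
  }, logical(1))
  expect_true(all(diff(as.integer(verdicts)) >= 0))
  # most frequent subtype wins; ties break by peak power
  a <- fake(67L, 10, c(`67` = 1, `19` = 0.01))
  b <- fake(79L, 20, c(`79` = 0.5, `31` = 0.01))
  expect_equal(select_target(list(a, b), parc)$target_parcel, 79L)
  b2 <- fake(79L, 10, c(`79` = 0.5, `31` = 0.01))
  expect_equal(select_target(list(a, b2), parc)$target_parcel, 67L)
  expect_error(select_target(list(), parc),
               class = "irritmap_selection_error")
})

test_that("parcel ids follow the atlas naming convention", {
  parc <- parcellation()
  expect_equal(parcel_label(1, parc),
               list(region = "AID", hemisphere = "right"))
  expect_equal(parcel_label(49, parc),
               list(region = "AID", hemisphere = "left"))
  expect_equal(parcel_label(79, parc),
               list(region = "S1BF", hemisphere = "left"))
  m1 <- parcel_label(67, parc)
  expect_equal(m1$region, "M1")
  expect_equal(m1$hemisphere, "left")
  expect_equal(contralateral_id(67, parc), 19L)
  expect_equal(contralateral_id(19, parc), 67L)
  expect_error(parcel_label(200, parc), class = "irritmap_lookup_error")
  restricted <- parcellation(used_ids = c(1, 19))
  expect_error(parcel_label(31, restricted),
               class = "irritmap_lookup_error")
})

test_that("sectioning arithmetic is exact", {
  expect_equal(shrink_factor(10, 5.6, -4.4), 1)
  expect_equal(shrink_factor(5, 5.6, -4.4), 0.5)
  a <- shrink_factor(7.41, 5.6, -4.4)
  expect_equal(a * (5.6 - -4.4), 7.41, tolerance = 1e-15)
  expect_error(shrink_factor(5, -4.4, 5.6), class = "irritmap_geometry_error")
  # printed-coordinate scaling: Bregma -0.63 mm at alpha 0.741
  expect_equal(atlas_to_specimen(-0.63, 0.741), -0.46683)
  expect_equal(atlas_to_specimen(0, 0.741), 0)
  expect_equal(atlas_to_specimen(2.5, 1), 2.5)
  x <- 3.7
  expect_equal(atlas_to_specimen(atlas_to_specimen(x, 0.741), 1 / 0.741), x,
               tolerance = 1e-12)
  plan <- sectioning_plan(7.41, 5.6, -4.4, block_center_mm = -0.63)
  expect_equal(plan$alpha, 0.741)
  expect_equal(plan$l_mm, -0.46683)
  expect_equal(plan$B2_mm, 0.741 * 5.6)
  td <- tidy(plan)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$block_to_mm - td$block_from_mm, 0.741 * 4)
})
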