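test_that("stained-area fraction recovers a known blob mask", {
  img <- synthetic_stain_image(600, 600, centers = matrix(c(300, 300), 1),
                               radii = 11.3, noise_sd = 0)
  expect_equal(stained_area_fraction(img$image, 0.95, 5),
               sum(img$mask) / 360000, tolerance = 1e-12)
  expect_equal(count_objects(img$image, 0.95, 5), 1L)
  expect_equal(stained_area_fraction(matrix(0, 50, 50)), 0)
  expect_warning(stained_area_fraction(matrix(2, 30, 30)), "Constant")
})

test_that("small objects are filtered, bridges merge, blanks are empty", {
  # 3-pixel speck beside a real blob: only the blob survives min_object_px
  img <- matrix(0, 200, 200)
  img[60 + (-5:5), 60 + (-5:5)] <- 1
  img[150, 150:152] <- 1
  expect_equal(count_objects(img, 0.9, min_object_px = 5,
                             background_radius = 10), 1L)
  # diagonal single-pixel bridge joins two squares under 8-connectivity
  m <- matrix(0, 50, 50)
  m[10:20, 10:20] <- 1
  m[21, 21] <- 1
  m[22:32, 22:32] <- 1
  expect_equal(count_objects(m, 0.5, 5, background_radius = 20), 1L)
  expect_equal(count_objects(matrix(0, 40, 40)), 0L)
})

test_that("seven clean synthetic blobs are counted as seven", {
  centers <- cbind(rep(c(60, 150, 240), length.out = 7),
                   rep(c(60, 150, 240), each = 3)[1:7])
  im <- synthetic_stain_image(300, 300, centers = centers, radii = 6,
                              noise_sd = 0.05, seed = 3)
  expect_equal(count_objects(im$image, 0.95, min_object_px = 20), 7L)
})

test_that("area fraction is monotone non-increasing in the threshold", {
  im <- synthetic_stain_image(200, 200, n_blobs = 4, radii = 7,
                              noise_sd = 0.1, seed = 5)
  fr <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(q) {
    stained_area_fraction(im$image, q, 5)
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("the exact signed-rank distribution matches brute enumeration", {
  set.seed(10)
  checked <- 0
  for (i in 1:60) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(0:2, 1))
    d <- d[d != 0]
    if (length(d) < 3) next
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p_value, wilcoxon_brute(d), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 40)
})

test_that("signed-rank edge behaviour is correct", {
  d <- c(0.4, 1.2, 2.2, 0.7, 3.0)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$statistic, 0)  # all positive: no negative ranks
  expect_equal(wilcoxon_signed_rank(-d)$p_value, res$p_value)
  # tie-free data agrees with the reference implementation
  d2 <- c(1.3, -0.4, 2.2, 0.8, -1.9, 0.6, 3.1, -2.5)
  expect_equal(wilcoxon_signed_rank(d2)$p_value,
               stats::wilcox.test(d2)$p.value, tolerance = 1e-12)
  deg <- wilcoxon_signed_rank(rep(0, 6))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # large n switches to the corrected normal approximation
  set.seed(3)
  d3 <- rnorm(40, 0.4)
  res3 <- wilcoxon_signed_rank(d3)
  expect_equal(res3$method, "normal")
  expect_equal(res3$p_value, stats::wilcox.test(d3, correct = TRUE,
                                                exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("paired comparison gates on normality and stars correctly", {
  expect_equal(p_stars(c(0.04, 0.004, 0.0004, 0.2)),
               c("*", "**", "***", ""))
  t0 <- rep(1.5, 6)
  deg <- paired_compare(t0, t0)
  expect_equal(deg$test, "degenerate")
  expect_equal(deg$p_value, 1)
  # clearly normal differences at large n -> paired t
  set.seed(4)
  ctrl <- rnorm(30)
  res_t <- paired_compare(ctrl + rnorm(30, 1), ctrl)
  expect_equal(res_t$test, "paired_t")
  # heavily skewed differences -> Wilcoxon
  skew <- ctrl + rexp(30)^3
  res_w <- paired_compare(skew, ctrl)
  expect_equal(res_w$test, "wilcoxon")
  expect_error(paired_compare(1:2, 1:2), class = "irritmap_stats_error")
})

test_that("the paired t path equals the closed-form statistic", {
  set.seed(8)
  target <- rnorm(12, 1)
  control <- rnorm(12)
  d <- target - control
  res <- paired_compare(target, control)
  expect_equal(res$test, "paired_t")
  expect_equal(res$statistic, mean(d) * sqrt(12) / sd(d),
               tolerance = 1e-12)
})

test_that("marker summaries report means, SDs, N and stars per marker", {
  out <- simulate_histology_tables(
    n_zones = 8, effect_sizes = c(GFAP_area = 0.5, IL1b_area = 0.5),
    noise_sd = 0.2, zone_sd = 0.05, seed = 3)
  summ <- summarize_markers(out$table)
  expect_equal(unique(summ$n_pairs), 8L)
  expect_true(all(c("target_mean", "control_sd", "stars") %in% names(summ)))
  gf <- summ[summ$marker == "GFAP_area", ]
  expect_equal(gf$direction, "increase")
  expect_true(gf$p_value < 0.05)
  # constant columns give zero SD
  const <- tidyr::expand_grid(zone = 1:4, marker = "m",
                              region = c("target", "control"),
                              replicate = 1:2)
  const$value <- ifelse(const$region == "target", 2, 1)
  sc <- summarize_markers(const)
  expect_equal(sc$target_sd, 0)
  # Holm option is available but off by default
  s2 <- summarize_markers(out$table, p_adjust = "holm")
  expect_true(all(s2$p_value >= summ$p_value - 1e-12))
})

test_that("null tables rarely star any given marker", {
  stars <- vapply(1:120, function(s) {
    tab <- simulate_histology_tables(n_zones = 8, markers = "NR2B_area",
                                     effect_sizes = 0, seed = 1000 + s)$table
    summarize_markers(tab)$stars != ""
  }, logical(1))
  expect_lt(mean(stars), 0.12)
})

test_that("configured effects near d = 1.5 are detected at n = 8", {
  hits <- vapply(1:120, function(s) {
    tab <- simulate_histology_tables(n_zones = 8, markers = "TNFa_area",
                                     effect_sizes = c(TNFa_area = 0.31),
                                     seed = 2000 + s)$table
    zm <- histology_zone_means(tab)
    paired_compare(zm$target, zm$control)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
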