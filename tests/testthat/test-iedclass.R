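test_that("an exact rank-1 tensor is recovered essentially perfectly", {
  mk <- make_rank_tensor(c(12, 40, 15), 1, seed = 7)
  m <- parafac(mk$tensor, 1, seed = 1, restarts = 3)
  expect_gte(m$fit, 0.9999)
  cong <- factor_congruence(m, mk$factors)
  expect_true(all(cong >= 0.999))
})

test_that("a noiseless rank-3 tensor is recovered with high congruence", {
  mk <- make_rank_tensor(c(16, 60, 30), 3, seed = 2)
  m <- parafac(mk$tensor, 3, seed = 1, restarts = 5)
  cong <- factor_congruence(m, mk$factors)
  expect_true(all(cong >= 0.99))
  expect_true(all(diff(m$fit_history) >= -1e-9))
})

test_that("constraints are honoured exactly", {
  mk <- make_rank_tensor(c(10, 30, 12), 2, seed = 3)
  m <- parafac(mk$tensor, 2, seed = 1, restarts = 3)
  gram <- crossprod(m$spatial)
  expect_equal(gram, diag(2), tolerance = 1e-8)
  expect_gte(min(m$sample), 0)
})

test_that("permuting tensor samples permutes the sample atoms alike", {
  mk <- make_rank_tensor(c(8, 20, 10), 2, seed = 4)
  perm <- c(3, 1, 7, 10, 2, 8, 5, 9, 4, 6)
  m1 <- parafac(mk$tensor, 2, seed = 1, restarts = 2)
  m2 <- parafac(mk$tensor[, , perm], 2, seed = 1, restarts = 2)
  expect_equal(m1$fit, m2$fit, tolerance = 1e-6)
  # align factor order/sign, then compare rows
  cong <- abs(crossprod(
    sweep(m1$sample, 2, sqrt(colSums(m1$sample^2)), "/"),
    sweep(m2$sample[order(perm), , drop = FALSE], 2,
          sqrt(colSums(m2$sample^2)), "/")))
  expect_true(all(apply(cong, 1, max) > 0.999))
})

test_that("channel reordering leaves the fit unchanged", {
  mk <- make_rank_tensor(c(9, 25, 11), 2, seed = 5)
  set.seed(5)
  ord <- sample(9)
  m1 <- parafac(mk$tensor, 2, seed = 1, restarts = 2)
  m2 <- parafac(mk$tensor[ord, , ], 2, seed = 1, restarts = 2)
  expect_equal(m1$fit, m2$fit, tolerance = 1e-6)
})

test_that("core consistency flags over-factoring and honours edge cases", {
  mk <- make_rank_tensor(c(14, 30, 20), 2, seed = 6)
  m2 <- parafac(mk$tensor, 2, seed = 1, restarts = 3)
  expect_gte(core_consistency(m2, mk$tensor), 99)
  unconstr <- c(electrode = "none", time = "none", sample = "none")
  m4 <- parafac(mk$tensor, 4, seed = 1, restarts = 3,
                constraints = unconstr)
  expect_lt(core_consistency(m4, mk$tensor), 50)
  m1 <- parafac(mk$tensor, 1, seed = 1, restarts = 2)
  expect_equal(core_consistency(m1, mk$tensor), 100)
})

test_that("rank selection finds the true rank of a clean tensor", {
  mk <- make_rank_tensor(c(14, 30, 24), 2, seed = 8)
  sel <- select_rank(mk$tensor, max_rank = 4, seed = 1, restarts = 3)
  expect_equal(sel$n_factors, 2L)
})

test_that("clustering separates blobs, collapses degenerate input", {
  set.seed(99)
  blob <- abs(rbind(cbind(rnorm(20, 8), rnorm(20, 0.5)),
                    cbind(rnorm(20, 0.5), rnorm(20, 8))))
  model <- structure(list(sample = blob, n_factors = 2L),
                     class = "irritmap_factor_model")
  asg <- cluster_samples(model, k_range = 1:4, seed = 1)
  expect_equal(asg$k, 2L)
  truth <- rep(1:2, each = 20)
  purity <- max(mean(asg$labels == truth), mean(asg$labels == 3 - truth))
  expect_equal(purity, 1)

  same <- structure(list(sample = matrix(1, 15, 2), n_factors = 2L),
                    class = "irritmap_factor_model")
  expect_equal(cluster_samples(same, 1:4, seed = 1)$k, 1L)
  expect_error(cluster_samples(model, k_range = 1:100),
               class = "irritmap_config_error")
})

test_that("cluster means conserve events and average faithfully", {
  epoch <- matrix(rnorm(8 * 50), 8, 50)
  tens <- array(rep(epoch, 6), c(8, 50, 6))
  attr(tens, "sampling_rate") <- 500
  class(tens) <- c("irritmap_ied_tensor", "array")
  asg <- irritmap:::new_assignment(rep(1L, 6), 1L, NA_real_, NULL, NULL)
  cm <- cluster_means(tens, asg)
  expect_equal(cm[[1]]$time_course, epoch)
  expect_equal(cm[[1]]$n_events, 6L)

  asg2 <- irritmap:::new_assignment(rep(c(1L, 2L), c(3, 5)), 2L, NA_real_,
                                    NULL, NULL)
  tens2 <- array(rnorm(8 * 50 * 8), c(8, 50, 8))
  attr(tens2, "sampling_rate") <- 500
  class(tens2) <- c("irritmap_ied_tensor", "array")
  cm2 <- cluster_means(tens2, asg2)
  expect_equal(vapply(cm2, function(x) x$n_events, integer(1)), c(3L, 5L))
  expect_equal(sum(vapply(cm2, function(x) x$n_events, integer(1))), 8L)
  bad <- irritmap:::new_assignment(rep(1L, 8), 2L, NA_real_, NULL, NULL)
  expect_error(cluster_means(tens2, bad),
               class = "irritmap_assignment_error")
})

test_that("classified subtype counts mirror the per-recording structure", {
  # a recording with two spike generators and one sharp-wave generator
  # yields 2 spike subtypes and 1 sharp-wave subtype with conserved counts
  geom <- fix_geom()
  cfg <- study_config(seed = 21, geom = geom, n_events = 8,
                      duration_s = 60)
  cfg$noise_sd <- 0
  sim <- simulate_recording(cfg, geom$leadfield, geom$sources)
  res <- map_irritative_zones(sim$recording, geom$leadfield, geom$sources,
                              geom$parcellation, seed = 21)
  kinds <- vapply(res$means, function(m) m$kind, character(1))
  expect_equal(sum(kinds == "spike"), 2L)
  expect_equal(sum(kinds == "sharp_wave"), 1L)
  expect_equal(sum(vapply(res$means, function(m) m$n_events, integer(1))),
               24L)
})
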