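test_that("gray histograms are smoothed, normalized probability vectors", {
  h <- gray_histogram(matrix(100L, 8, 8))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_true(all(h > 0))
  expect_gt(h[101], 0.999)
  u <- gray_histogram(matrix(0:255, 16, 16))
  expect_equal(max(u) / min(u), 1, tolerance = 1e-3)
  withr::with_seed(51, {
    for (i in 1:100) {
      px <- matrix(sample.int(256L, 64L, replace = TRUE) - 1L, 8, 8)
      expect_equal(sum(gray_histogram(px)), 1, tolerance = 1e-9)
    }
  })
  expect_error(gray_histogram(integer(0)), "empty")
})

test_that("KL divergence: identity, forced value, asymmetry, domain error", {
  p <- gray_histogram(matrix(sample.int(256L, 64L, replace = TRUE) - 1L, 8, 8))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)   # log2(2)
  a <- c(0.5, 0.5); b <- c(0.9, 0.1)
  expect_false(isTRUE(all.equal(kl_divergence(a, b), kl_divergence(b, a))))
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "zero bin")
})

test_that("JS divergence: bounds, symmetry, identity, analytic cases", {
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)        # disjoint supports
  # half/point case: M = (0.75, 0.25), JS = H(M) - 1/2
  expect_equal(js_divergence(c(0.5, 0.5), c(1, 0)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)) - 0.5,
               tolerance = 1e-12)
  expect_equal(js_divergence(c(0.5, 0.5), c(1, 0)), 0.311278, tolerance = 1e-6)
  withr::with_seed(61, {
    for (i in 1:50) {
      p <- gray_histogram(matrix(sample.int(256L, 64L, TRUE) - 1L, 8, 8))
      q <- gray_histogram(matrix(sample.int(256L, 64L, TRUE) - 1L, 8, 8))
      js <- js_divergence(p, q)
      expect_gte(js, 0); expect_lte(js, 1)
      expect_equal(js, js_divergence(q, p), tolerance = 1e-12)
      expect_equal(js_divergence(p, p), 0, tolerance = 1e-12)
    }
  })
})

test_that("intra pair counts follow (F - shift) * R and identical frames give 0", {
  seq <- const_sequence(rep(100, 10), h = 16L, w = 16L)
  rois <- roi_set(data.frame(frame_index = NA, roi_id = 0:4,
                             x = 0:4 * 3L, y = 0L, w = 3L, h = 6L), seq)
  s1 <- intra_pairs(seq, rois, 1L)
  expect_equal(nrow(s1), 45L)                    # (10 - 1) * 5
  expect_true(all(s1$js == 0))
  s9 <- intra_pairs(seq, rois, 9L)
  expect_equal(nrow(s9), 5L)                     # boundary shift
  expect_error(intra_pairs(seq, rois, 10L), "shift")
  all_s <- intra_pairs_all_shifts(seq, rois)
  expect_equal(nrow(all_s), sum((10 - 1:9) * 5))
  expect_true(all(all_s$frame_b - all_s$frame_a == all_s$shift))
})

test_that("inter pairs are capped, seeded, and never pair a case with itself", {
  withr::with_seed(71, {
    seqs <- list(const_sequence(rep(40, 4), 16L, 16L, "a"),
                 image_sequence(random_frames(4L, 16L, 16L), "b", "normal"),
                 image_sequence(random_frames(4L, 16L, 16L), "c", "normal"))
  })
  rois <- lapply(seqs, full_roi)
  s <- inter_pairs(seqs, rois, seed = 5L, max_pairs = 100L)
  expect_equal(nrow(s), 100L)
  expect_true(all(s$case_a != s$case_b))
  s2 <- inter_pairs(seqs, rois, seed = 5L, max_pairs = 100L)
  expect_identical(s, s2)                        # reproducible from seed
  expect_error(inter_pairs(seqs[1], rois[1], seed = 1L), "2 cases")
  # identical constant content in two cases -> inter JS exactly 0
  twin <- list(const_sequence(rep(40, 3), 16L, 16L, "a"),
               const_sequence(rep(40, 3), 16L, 16L, "b"))
  s0 <- inter_pairs(twin, lapply(twin, full_roi), seed = 1L, max_pairs = 50L)
  expect_true(all(s0$js == 0))
})

test_that("shift curves expose constructed temporal structure", {
  # frames alternating between two textures: zero JS at even shifts,
  # a positive constant at odd shifts
  withr::with_seed(81, {
    a <- matrix(sample.int(256L, 256L, TRUE) - 1L, 16, 16)
    b <- matrix(sample.int(256L, 256L, TRUE) - 1L, 16, 16)
  })
  seq <- image_sequence(rep(list(a, b), 5), "alt", "g")
  curve <- shift_curve(seq, full_roi(seq))
  even <- curve$mean_js[curve$shift %% 2 == 0]
  odd <- curve$mean_js[curve$shift %% 2 == 1]
  expect_true(all(even == 0))
  expect_true(all(odd > 0.2))
  expect_equal(length(unique(round(odd, 12))), 1L)
  expect_equal(curve$n, (10 - 1:9) * 1L)

  flat <- shift_curve(const_sequence(rep(10, 10), 16L, 16L),
                      full_roi(const_sequence(rep(10, 10), 16L, 16L)))
  expect_true(all(flat$mean_js == 0))
})

test_that("period estimation finds constructed periods and rejects flat curves", {
  mk <- function(y) structure(data.frame(shift = seq_along(y), mean_js = y,
                                         sd_js = 0, n = 1L),
                              class = c("shift_curve", "data.frame"))
  expect_equal(estimate_period(mk(0.05 + 0.01 * sin(2 * pi * (1:119) / 35))), 35L)
  expect_equal(estimate_period(mk(0.05 + 0.01 * sin(2 * pi * (1:60) / 12))), 12L)
  expect_true(is.na(estimate_period(mk(rep(0.05, 60)))))
  # linear drift alone must not masquerade as a period
  expect_true(is.na(estimate_period(mk(seq(0.01, 0.1, length.out = 60)))))
  expect_error(estimate_period(mk(rep(0.05, 5))), "short")
})

test_that("intra/inter divergence ratio tracks within-case correlation", {
  # with fresh speckle every frame (rho = 0) intra and inter pairs are
  # exchangeable draws, so their means agree; as rho grows the shared
  # persistent field pulls intra divergence below inter
  ratio <- vapply(c(0, 0.8, 0.95), function(rho) {
    cfg <- phantom_config(groups = phantom_presets()["normal"],
                          cases_per_group = 3L, frames_per_case = 12L,
                          rho = rho, breath_amplitude = 0,
                          drift_per_frame = 0, seed = 91L)
    coh <- generate_cohort(cfg)
    intra <- unlist(lapply(names(coh$sequences), function(id)
      intra_pairs_all_shifts(coh$sequences[[id]], coh$rois[[id]])$js))
    inter <- inter_pairs(coh$sequences, coh$rois, seed = 91L,
                         max_pairs = 500L)$js
    mean(intra) / mean(inter)
  }, numeric(1))
  expect_gt(ratio[1], 0.95)
  expect_lt(ratio[1], 1.05)
  expect_true(ratio[1] > ratio[2] && ratio[2] > ratio[3])
})
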