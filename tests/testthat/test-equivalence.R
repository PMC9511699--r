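test_that("noninferiority test matches the t.test oracle on random configs", {
  withr::with_seed(101, {
    for (i in 1:20) {
      n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
      inter <- rnorm(n1, mean = runif(1, 0.02, 0.2), sd = runif(1, 0.005, 0.08))
      intra <- rnorm(n2, mean = runif(1, 0.02, 0.2), sd = runif(1, 0.005, 0.08))
      df <- sample(c(0, 0.05, 0.2), 1)           # includes delta = 0 reduction
      r <- equivalence_t_test(inter, intra, delta_frac = df)
      o <- oracle_equiv(inter, intra, df)
      expect_equal(r$t, o$t, tolerance = 1e-6)
      expect_equal(r$df, o$df, tolerance = 1e-12)
      expect_equal(r$p, o$p, tolerance = 1e-6)
      expect_equal(r$delta, df * mean(inter))
      expect_identical(r$independent, r$p < r$alpha)
    }
  })
})

test_that("identical samples are declared independent at the 5% margin", {
  # moderate spread relative to the mean: the 5% margin must be resolvable
  # at n = 200, which needs mean/sd above ~3.3 (delta/SE > t_crit)
  withr::with_seed(111, {
    x <- rnorm(200, 0.06, 0.012)
  })
  r <- equivalence_t_test(x, x, delta_frac = 0.05)
  expect_equal(r$m1, r$m2)
  expect_lt(r$t, 0)
  expect_lt(r$p, 0.05)
  expect_true(r$independent)
  # delta = 0 with identical samples: exactly the symmetric null
  r0 <- equivalence_t_test(x, x, delta_frac = 0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  expect_false(r0$independent)
})

test_that("the worked fibrosis-scale example reproduces the formula", {
  # inter 0.07 +/- 0.08, intra 0.05 +/- 0.05, n = 50 each: the margin
  # (0.0035) is smaller than the observed deficit, so equivalence fails
  withr::with_seed(121, {
    scale_to <- function(x, m, s) m + (x - mean(x)) / sd(x) * s
    inter <- scale_to(rnorm(50), 0.07, 0.08)
    intra <- scale_to(rnorm(50), 0.05, 0.05)
  })
  r <- equivalence_t_test(inter, intra)
  sp <- sqrt((49 * 0.08^2 + 49 * 0.05^2) / 98)
  t_hand <- (0.07 - 0.05 - 0.0035) / (sp * sqrt(2 / 50))
  expect_equal(r$t, t_hand, tolerance = 1e-9)
  expect_equal(r$t, 1.2367, tolerance = 1e-4)
  expect_equal(r$p, stats::pt(t_hand, 98), tolerance = 1e-12)
  expect_equal(r$p, 0.8905, tolerance = 1e-4)
  expect_false(r$independent)
})

test_that("p rises with the intra-vs-inter deficit and ignores sample order", {
  withr::with_seed(131, {
    base <- rnorm(100, 0.06, 0.02)
    intra <- rnorm(100, 0.06, 0.02)
  })
  deficits <- c(0, 0.005, 0.01, 0.02)
  ps <- vapply(deficits, function(d)
    equivalence_t_test(base + d, intra, delta_frac = 0.05)$p, numeric(1))
  expect_true(all(diff(ps) > 0))
  r1 <- equivalence_t_test(base, intra)
  r2 <- equivalence_t_test(rev(base), sample(intra))
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("degenerate variance is flagged and decided by sign", {
  r <- equivalence_t_test(rep(0.1, 5), rep(0.2, 5), delta_frac = 0.05)
  expect_true(r$degenerate)
  expect_equal(r$p, 0)                           # intra above inter: pass
  r2 <- equivalence_t_test(rep(0.2, 5), rep(0.1, 5), delta_frac = 0.05)
  expect_equal(r2$p, 1)
  expect_error(equivalence_t_test(0.1, c(0.1, 0.2)), "at least 2")
})

test_that("group reports carry one decision per group", {
  withr::with_seed(141, {
    x <- rnorm(300, 0.06, 0.02)
    groups <- list(
      g1 = list(inter = x, intra = x),
      g2 = list(inter = x, intra = x / 2),      # halved intra: clear failure
      g3 = list(inter = x, intra = x + rnorm(300, 0, 0.001))
    )
  })
  rep <- group_independence_report(groups)
  expect_equal(nrow(rep), 3L)
  expect_true(rep$independent[rep$group == "g1"])
  expect_false(rep$independent[rep$group == "g2"])
  expect_true(rep$independent[rep$group == "g3"])
  # the data-frame entry path used by the pipeline gives the same answers
  df <- do.call(rbind, lapply(names(groups), function(g)
    rbind(data.frame(kind = "inter", js = groups[[g]]$inter, group = g),
          data.frame(kind = "intra", js = groups[[g]]$intra, group = g))))
  rep2 <- group_independence_report(df)
  expect_equal(rep2[order(rep2$group), ]$p, rep[order(rep$group), ]$p)
})
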