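test_that("group statistics match stats-package oracles", {
  withr::with_seed(201, {
    x <- data.frame(f1 = rnorm(30), f2 = rnorm(30, 2))
    g <- rep(c("a", "b", "c"), each = 10)
  })
  st <- group_feature_stats(x, g)
  expect_equal(unname(st$means["f1", "a"]), mean(x$f1[g == "a"]))
  p_ab <- st$pairwise_p$p[st$pairwise_p$feature == "f1" &
                            st$pairwise_p$group_a == "a" &
                            st$pairwise_p$group_b == "b"]
  expect_equal(p_ab,
               t.test(x$f1[g == "a"], x$f1[g == "b"], var.equal = TRUE)$p.value,
               tolerance = 1e-9)
  expect_equal(unname(st$anova_p["f1"]),
               summary(aov(x$f1 ~ factor(g)))[[1]]$`Pr(>F)`[1],
               tolerance = 1e-9)
  # near-identical replicates with separated means: tiny p
  y <- data.frame(f = c(10, 10, 10, 12, 20, 20, 20, 22))
  st2 <- group_feature_stats(y, rep(c("lo", "hi"), each = 4))
  expect_lt(st2$pairwise_p$p[1], 1e-5)
  expect_error(group_feature_stats(x, rep("a", 30)), "2 groups")
})

test_that("roc_auc equals exhaustive pair counting, including ties", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), factor(c("n", "n", "d", "d"), c("n", "d")))
  expect_equal(r$auc, 0.75)
  withr::with_seed(211, {
    for (i in 1:40) {
      n <- sample(4:12, 1)
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # force ties
      labs <- factor(sample(c("a", "b"), n, replace = TRUE))
      if (nlevels(droplevels(labs)) < 2) next
      r <- roc_auc(scores, labs)
      expect_equal(r$auc, oracle_auc(scores, labs == levels(labs)[2]))
    }
  })
  # monotone transform invariance
  withr::with_seed(212, {
    s <- rnorm(30); l <- factor(rep(c("a", "b"), 15))
  })
  expect_equal(roc_auc(s, l)$auc, roc_auc(exp(2 * s), l)$auc)
  # perfect separation
  rp <- roc_auc(c(1, 2, 3, 10, 11, 12), factor(rep(c("a", "b"), each = 3)))
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 100)
  expect_equal(rp$specificity, 100)
  expect_error(roc_auc(1:3, factor(rep("a", 3))), "2 classes")
})

test_that("LOO harness produces one out-of-fold score per sample, no leakage", {
  withr::with_seed(221, {
    X <- matrix(rnorm(40), 20, 2)
    y <- rep(0:1, 10)
  })
  sc <- loo_cv(X, y,
               fit_fun = function(Xt, yt, i) list(X = Xt, y = yt),
               predict_fun = function(m, x) mean(m$y))
  expect_length(sc, 20L)
  # a memorizing 1-NN stub must score at chance on shuffled labels: the
  # harness may never show the model its own held-out row
  withr::with_seed(222, {
    aucs <- replicate(30, {
      ys <- sample(y)
      sc <- loo_cv(X, ys,
                   fit_fun = function(Xt, yt, i) list(X = Xt, y = yt),
                   predict_fun = function(m, x) {
                     d <- rowSums((m$X - matrix(x, nrow(m$X), ncol(m$X),
                                                byrow = TRUE))^2)
                     m$y[which.min(d)]
                   })
      roc_auc(sc, factor(ys))$auc
    })
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("logistic LOO separates a separable 1-D feature and is deterministic", {
  x <- matrix(c(1:10, 21:30), ncol = 1)
  y <- factor(rep(c("lo", "hi"), each = 10), levels = c("lo", "hi"))
  sc <- loo_cv_scores(x, y, "logistic")
  expect_length(sc, 20L)
  expect_equal(roc_auc(sc, y)$auc, 1)
  expect_identical(sc, loo_cv_scores(x, y, "logistic"))
  expect_error(loo_cv_scores(x, factor(rep(c("a", "b", "c"), length.out = 20)),
                             "logistic"), "2 classes")
})

test_that("random-forest LOO is seed-reproducible and finds clear structure", {
  withr::with_seed(231, {
    X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
    y <- factor(rep(c("a", "b"), each = 20))
  })
  s1 <- loo_cv_scores(X, y, "random_forest", seed = 9L, n_trees = 50L)
  s2 <- loo_cv_scores(X, y, "random_forest", seed = 9L, n_trees = 50L)
  expect_identical(s1, s2)
  expect_gt(roc_auc(s1, y)$auc, 0.95)
  s3 <- loo_cv_scores(X, y, "random_forest", seed = 10L, n_trees = 50L)
  expect_false(identical(s1, s3))
})

test_that("multicategory one-vs-rest reports cover every class", {
  withr::with_seed(241, {
    X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2),
               matrix(rnorm(40, 6), 20, 2))
    y <- factor(rep(c("a", "b", "c"), each = 20))
  })
  reports <- multicategory_eval(X, y, seed = 3L, n_trees = 50L)
  expect_named(reports, c("a", "b", "c"))
  for (r in reports) expect_gt(r$auc, 0.9)
  expect_error(multicategory_eval(X, factor(rep(c("a", "b"), 30))), "3 classes")
})
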