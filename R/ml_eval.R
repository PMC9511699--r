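#' Per-feature group statistics
#'
#' For every feature column: group means and standard errors, all pairwise
#' two-sample two-sided pooled-variance t-tests, and a one-way ANOVA across
#' all groups. Groups of different animals are independent, so the tests are
#' unpaired.
#'
#' @param features data frame of numeric feature columns.
#' @param groups character/factor vector of group labels, one per row.
#' @return a `group_stats` list with elements `means` (feature x group),
#'   `se` (feature x group), `pairwise_p` (data frame: feature, group_a,
#'   group_b, p) and `anova_p` (named vector per feature).
#' @export
group_feature_stats <- function(features, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  gl <- levels(groups)
  means <- sapply(features, function(v) tapply(v, groups, mean))
  se <- sapply(features, function(v)
    tapply(v, groups, function(x) stats::sd(x) / sqrt(length(x))))
  pairs <- utils::combn(gl, 2)
  pw <- do.call(rbind, lapply(names(features), function(f) {
    data.frame(feature = f, group_a = pairs[1, ], group_b = pairs[2, ],
               p = apply(pairs, 2, function(pr) {
                 stats::t.test(features[[f]][groups == pr[1]],
                               features[[f]][groups == pr[2]],
                               var.equal = TRUE)$p.value
               }))
  }))
  rownames(pw) <- NULL
  anova_p <- vapply(features, function(v)
    stats::anova(stats::lm(v ~ groups))$`Pr(>F)`[1], numeric(1))
  structure(list(means = t(means), se = t(se), pairwise_p = pw,
                 anova_p = anova_p),
            class = "group_stats")
}

# ridge-stabilized logistic regression by IRLS. A tiny ridge (lambda) keeps
# the fit finite on separable folds, where plain ML estimates diverge; with
# lambda -> 0 this is ordinary logistic regression. Deterministic.
logistic_fit <- function(X, y, lambda = 1e-6, max_iter = 50L, tol = 1e-10) {
  X <- cbind(1, as.matrix(X))
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(lambda, p); pen[1, 1] <- 0       # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

logistic_predict <- function(beta, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% beta))
}

#' Leave-one-out cross-validation harness
#'
#' Generic round-robin CV: each sample is scored by a model fitted on all the
#' other samples. The harness itself never looks at the held-out row, so a
#' memorizing learner plugged in here still scores at chance on shuffled
#' labels — a property the test suite checks.
#'
#' @param X numeric feature matrix (n x p).
#' @param y response vector of length n.
#' @param fit_fun `function(Xtrain, ytrain, fold)` returning a fitted model.
#' @param predict_fun `function(model, xrow)` returning the held-out score.
#' @return numeric (or matrix) scores, one entry per sample.
#' @export
loo_cv <- function(X, y, fit_fun, predict_fun) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    model <- fit_fun(X[-i, , drop = FALSE], y[-i], i)
    out[[i]] <- predict_fun(model, X[i, , drop = FALSE])
  }
  if (all(lengths(out) == 1L)) unlist(out) else do.call(rbind, out)
}

#' Leave-one-out scores for the built-in classifiers
#'
#' Runs [loo_cv()] with either ridge-stabilized logistic regression (binary
#' labels; deterministic) or the compiled random forest (any number of
#' classes; reproducible from `seed`). Scores are probabilities: a vector of
#' P(class = positive) for logistic / binary forest, or an n x K probability
#' matrix for a multiclass forest.
#'
#' @param features numeric feature matrix or data frame (n x p).
#' @param labels vector of class labels; for `"logistic"` exactly 2 classes.
#' @param model `"logistic"` or `"random_forest"`.
#' @param seed integer seed (required for the forest).
#' @param n_trees,mtry forest size and features per split (defaults 100 and
#'   `floor(sqrt(p))`).
#' @return per-sample out-of-fold scores; the positive class for binary tasks
#'   is the second factor level, and matrix columns are named by class.
#' @export
loo_cv_scores <- function(features, labels, model = c("logistic", "random_forest"),
                          seed = 1L, n_trees = 100L, mtry = NULL) {
  model <- match.arg(model)
  X <- as.matrix(as.data.frame(features)[vapply(as.data.frame(features),
                                                is.numeric, logical(1))])
  f <- as.factor(labels)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  if (model == "logistic") {
    if (nlevels(f) != 2L) stop("logistic regression needs exactly 2 classes")
    y <- as.integer(f) - 1L
    loo_cv(X, y,
           fit_fun = function(Xt, yt, i) {
             if (length(unique(yt)) < 2L) stop("degenerate fold: single class in training set")
             logistic_fit(Xt, yt)
           },
           predict_fun = logistic_predict)
  } else {
    y <- as.integer(f) - 1L
    K <- nlevels(f)
    scores <- loo_cv(X, y,
                     fit_fun = function(Xt, yt, i) {
                       if (length(unique(yt)) < 2L) stop("degenerate fold: single class in training set")
                       list(X = Xt, y = yt, seed = as.integer(seed) + i)
                     },
                     predict_fun = function(m, x) {
                       drop(rf_fit_predict(m$X, m$y, x, K, as.integer(n_trees),
                                           as.integer(mtry), m$seed))
                     })
    if (K == 2L) scores[, 2L] else { colnames(scores) <- levels(f); scores }
  }
}

#' ROC analysis by Mann-Whitney pair counting
#'
#' AUC is the probability that a random positive outscores a random negative,
#' ties counting one half — computed exactly via midranks, identical to
#' exhaustive pair counting. Sensitivity and specificity (percent) are
#' reported at the Youden-optimal threshold (maximizing Sn + Sp - 1 over all
#' observed score cutpoints; ties broken toward higher sensitivity).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels; the positive class is the second factor
#'   level (or `positive`).
#' @param positive optional explicit positive-class label.
#' @return a `classification_report` list: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `n`, `n_pos`, `n_neg`, `predictions`
#'   (data frame of score + truth) and `roc` (data frame of curve points).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("need exactly 2 classes, got ", nlevels(f))
  if (is.null(positive)) positive <- levels(f)[2]
  pos <- f == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                           # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cut <- sort(unique(scores), decreasing = TRUE)
  sn <- vapply(cut, function(c) sum(scores[pos] >= c) / n1, numeric(1))
  sp <- vapply(cut, function(c) sum(scores[!pos] < c) / n0, numeric(1))
  best <- which.max(sn + sp - 1)
  structure(
    list(auc = auc, sensitivity = 100 * sn[best], specificity = 100 * sp[best],
         threshold = cut[best], n = n1 + n0, n_pos = n1, n_neg = n0,
         predictions = data.frame(score = scores, label = f),
         roc = data.frame(threshold = cut, sensitivity = 100 * sn,
                          specificity = 100 * sp)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> AUC = %.3f, Sn = %.1f%%, Sp = %.1f%% (n = %d: %d pos / %d neg)\n",
              x$auc, x$sensitivity, x$specificity, x$n, x$n_pos, x$n_neg))
  invisible(x)
}

#' One-vs-rest multicategory evaluation by random forest
#'
#' Leave-one-out random-forest class probabilities, then one ROC/AUC per
#' class against the rest — the multicategory companion to the two-class
#' logistic analysis.
#'
#' @param features numeric feature matrix or data frame.
#' @param labels vector with >= 3 classes.
#' @param seed forest seed.
#' @param n_trees,mtry forest parameters (see [loo_cv_scores()]).
#' @return named list of [roc_auc()] reports, one per class.
#' @export
multicategory_eval <- function(features, labels, seed = 1L, n_trees = 100L,
                               mtry = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) < 3L) stop("multicategory evaluation needs >= 3 classes")
  P <- loo_cv_scores(features, f, "random_forest", seed = seed,
                     n_trees = n_trees, mtry = mtry)
  reports <- lapply(levels(f), function(cl)
    roc_auc(P[, cl], factor(f == cl, levels = c(FALSE, TRUE),
                            labels = c("rest", cl)), positive = cl))
  names(reports) <- levels(f)
  reports
}
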