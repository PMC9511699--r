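#' One-sided equivalence (noninferiority) t-test for divergence samples
#'
#' Tests whether intra-case divergence is *not meaningfully lower* than
#' inter-case divergence. With `M1 = mean(inter)`, `M2 = mean(intra)` and
#' margin `delta = delta_frac * M1` (default 5% of the inter mean), the
#' statistic is
#' \deqn{t = \frac{M_1 - M_2 - \delta}{s_p\sqrt{1/n_1 + 1/n_2}}, \qquad
#'       s_p^2 = \frac{(n_1-1)\sigma_1^2 + (n_2-1)\sigma_2^2}{n_1+n_2-2}}
#' with `df = n1 + n2 - 2` and one-sided `p = P(T_df <= t)`. Small `p`
#' rejects H0 ("intra divergence is lower than inter by at least delta") in
#' favor of the intra samples being no more self-similar than inter samples —
#' i.e. the frames behave like independent draws. With `delta_frac = 0` this
#' reduces to the standard one-sided pooled two-sample t-test.
#'
#' A Welch (unpooled) standard error and Satterthwaite df are available with
#' `pooled = FALSE`; the pooled form is the default.
#'
#' If the pooled variance is exactly zero the statistic is degenerate; the
#' result is flagged (`degenerate = TRUE`) and `p` is set to 0, 0.5 or 1 by
#' the sign of `M1 - M2 - delta` (negative, zero, positive).
#'
#' @param inter numeric vector of inter-case JS divergences (n1 >= 2).
#' @param intra numeric vector of intra-case JS divergences (n2 >= 2).
#' @param delta_frac noninferiority margin as a fraction of `M1`
#'   (default 0.05: at most a 5% reduction in divergence is tolerated).
#' @param alpha significance level for the independence decision.
#' @param pooled use the pooled-variance standard error (default) or Welch.
#' @return an `equivalence_result` list: `m1, m2, sd1, sd2, n1, n2, delta,
#'   t, df, p, p_upper, alpha, independent, degenerate`.
#' @export
equivalence_t_test <- function(inter, intra, delta_frac = 0.05, alpha = 0.05,
                               pooled = TRUE) {
  inter <- as.numeric(inter); intra <- as.numeric(intra)
  n1 <- length(inter); n2 <- length(intra)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 observations in each sample (n1=", n1, ", n2=", n2, ")")
  stopifnot(delta_frac >= 0)
  m1 <- mean(inter); m2 <- mean(intra)
  s1 <- stats::sd(inter); s2 <- stats::sd(intra)
  delta <- delta_frac * m1
  num <- m1 - m2 - delta
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  degenerate <- se == 0
  if (degenerate) {
    t <- if (num == 0) 0 else sign(num) * Inf
    p <- if (num < 0) 0 else if (num == 0) 0.5 else 1
  } else {
    t <- num / se
    p <- stats::pt(t, df)
  }
  structure(
    list(m1 = m1, m2 = m2, sd1 = s1, sd2 = s2, n1 = n1, n2 = n2,
         delta = delta, t = t, df = df, p = p, p_upper = 1 - p,
         alpha = alpha, independent = p < alpha, degenerate = degenerate),
    class = "equivalence_result"
  )
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(paste0(
    "One-sided equivalence (noninferiority) t-test\n",
    "  inter: M1 = %.4g (sd %.4g, n = %d)\n",
    "  intra: M2 = %.4g (sd %.4g, n = %d)\n",
    "  margin delta = %.4g, t(%.4g) = %.4g, one-sided p = %.4g\n",
    "  decision (alpha = %g): frames %s\n"),
    x$m1, x$sd1, x$n1, x$m2, x$sd2, x$n2,
    x$delta, x$df, x$t, x$p, x$alpha,
    if (x$independent) "behave as INDEPENDENT samples"
    else "are NOT demonstrably independent"))
  invisible(x)
}

#' Per-group independence report
#'
#' Runs [equivalence_t_test()] for every group and assembles the intra/inter
#' summary table: one row per group with sample counts, both distributions'
#' mean +/- sd, the margin, the test statistic and the independence
#' decision.
#'
#' @param groups named list; each element is a list (or data frame split)
#'   with numeric elements `inter` and `intra` holding the group's JS
#'   samples. A `divergence_samples` data frame with a `group` column is also
#'   accepted and split by `kind` internally.
#' @param delta_frac,alpha,pooled passed to [equivalence_t_test()].
#' @return data frame with one row per group: `group, n_intra, n_inter,
#'   mean_intra, sd_intra, mean_inter, sd_inter, delta, t, df, p,
#'   independent`.
#' @export
group_independence_report <- function(groups, delta_frac = 0.05, alpha = 0.05,
                                      pooled = TRUE) {
  if (is.data.frame(groups)) {
    if (is.null(groups$group)) stop("data frame input needs a 'group' column")
    groups <- lapply(split(groups, groups$group), function(d)
      list(inter = d$js[d$kind == "inter"], intra = d$js[d$kind == "intra"]))
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  rows <- lapply(names(groups), function(g) {
    r <- equivalence_t_test(groups[[g]]$inter, groups[[g]]$intra,
                            delta_frac = delta_frac, alpha = alpha,
                            pooled = pooled)
    data.frame(group = g, n_intra = r$n2, n_inter = r$n1,
               mean_intra = r$m2, sd_intra = r$sd2,
               mean_inter = r$m1, sd_inter = r$sd1,
               delta = r$delta, t = r$t, df = r$df, p = r$p,
               independent = r$independent)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
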