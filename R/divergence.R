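#' Smoothed 256-bin grayscale histogram of an ROI
#'
#' Tabulates the ROI's 8-bit gray levels into 256 bins, adds a small
#' pseudocount to every bin and renormalizes. The pseudocount keeps every bin
#' strictly positive so Kullback-Leibler terms are always defined; at the
#' default `1e-6` it is negligible against any populated bin.
#'
#' @param pixels integer matrix (or vector) of gray levels 0..255.
#' @param pseudocount positive smoothing mass added to each bin before
#'   normalization (in units of relative frequency).
#' @return numeric vector of 256 probabilities summing to 1.
#' @export
gray_histogram <- function(pixels, pseudocount = 1e-6) {
  if (length(pixels) == 0L) stop("empty ROI")
  stopifnot(pseudocount > 0)
  p <- tabulate(as.integer(pixels) + 1L, nbins = 256L) / length(pixels) + pseudocount
  p / sum(p)
}

#' Kullback-Leibler divergence (bits)
#'
#' `KL(P || Q) = sum_i p_i log2(p_i / q_i)`, with `0 log 0 = 0`. Asymmetric
#' and unbounded; requires `q_i > 0` wherever `p_i > 0` (which smoothing
#' guarantees).
#'
#' @param p,q probability vectors of equal length.
#' @return divergence in bits, >= 0, 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  if (any(q[nz] == 0)) stop("KL undefined: q has a zero bin where p > 0 (smooth first)")
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence (bits)
#'
#' The bounded symmetrization of KL via the mixture midpoint:
#' `JS(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`. In log
#' base 2, `JS` lies in `[0, 1]`: 0 iff the distributions are identical, 1
#' iff their supports are disjoint.
#'
#' @param p,q probability vectors of equal length.
#' @return divergence in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  (kl_divergence(p, m) + kl_divergence(q, m)) / 2
}

# Column-wise JS between two probability matrices (256 x n each), used by the
# pair samplers. Equivalent to mapply(js_divergence, ...) but ~50x faster via
# the entropy identity JS = H(M) - H(P)/2 - H(Q)/2. `hP`/`hQ` allow reusing
# per-column entropies across many pair sets.
col_entropy <- function(M) {
  X <- M * log2(M)
  X[M == 0] <- 0
  -colSums(X)
}

js_divergence_cols <- function(P, Q, hP = col_entropy(P), hQ = col_entropy(Q)) {
  col_entropy((P + Q) / 2) - (hP + hQ) / 2
}

# All ROI histograms of a sequence as a 256 x (F*R) matrix, with index
# bookkeeping; computed once per case so pair sampling is cheap.
case_histograms <- function(sequence, rois, pseudocount = 1e-6) {
  rois <- as.data.frame(rois)
  H <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    gray_histogram(roi_pixels(sequence, r$frame_index, r), pseudocount)
  }, numeric(256))
  list(H = H, entropy = col_entropy(H),
       frame_index = rois$frame_index, roi_id = rois$roi_id)
}

#' Intra-case divergence samples at one time shift
#'
#' Pairs ROI `k` on frame `t` with the same `roi_id` `k` on frame `t + shift`
#' for every admissible `t`, and records the JS divergence of their grayscale
#' histograms. Pairing identical `roi_id`s isolates temporal from spatial
#' divergence; cross-ROI pairing is available via `cross_roi = TRUE`.
#'
#' @param sequence an [image_sequence()].
#' @param rois an [roi_set()].
#' @param shift frame difference, `1 <= shift <= F - 1`.
#' @param pseudocount histogram smoothing (see [gray_histogram()]).
#' @param cross_roi if `TRUE`, also pair different `roi_id`s across the two
#'   frames (off by default).
#' @param .hists precomputed [case_histograms] (internal fast path).
#' @return a `divergence_samples` data frame with columns
#'   `kind, case_a, case_b, frame_a, frame_b, roi_id, shift, js`
#'   (`(F - shift) * R` rows for the default same-ROI pairing).
#' @export
intra_pairs <- function(sequence, rois, shift, pseudocount = 1e-6,
                        cross_roi = FALSE, .hists = NULL) {
  nf <- n_frames(sequence)
  if (shift < 1L || shift > nf - 1L)
    stop("shift must be in 1..", nf - 1L, " (got ", shift, ")")
  ch <- if (is.null(.hists)) case_histograms(sequence, rois, pseudocount) else .hists
  ta <- ch$frame_index
  keep_a <- which(ta + shift <= nf - 1L)
  if (cross_roi) {
    key <- ch$frame_index
    ia <- integer(0); ib <- integer(0)
    for (a in keep_a) {
      b <- which(key == ta[a] + shift)
      ia <- c(ia, rep(a, length(b))); ib <- c(ib, b)
    }
  } else {
    ia <- keep_a
    ib <- match(paste(ta[keep_a] + shift, ch$roi_id[keep_a]),
                paste(ch$frame_index, ch$roi_id))
  }
  js <- js_divergence_cols(ch$H[, ia, drop = FALSE], ch$H[, ib, drop = FALSE],
                           ch$entropy[ia], ch$entropy[ib])
  out <- data.frame(kind = "intra",
                    case_a = sequence$case_id, case_b = sequence$case_id,
                    frame_a = ch$frame_index[ia], frame_b = ch$frame_index[ib],
                    roi_id = if (cross_roi) NA_integer_ else ch$roi_id[ia],
                    shift = shift, js = js)
  class(out) <- c("divergence_samples", "data.frame")
  out
}

#' Intra-case samples pooled over time shifts
#'
#' Convenience wrapper running [intra_pairs()] at every `shift` in
#' `1..F-1` (or a chosen subset) — the sampling scheme behind the intra
#' divergence distribution of the independence test.
#'
#' @inheritParams intra_pairs
#' @param shifts integer vector of shifts to include; `NULL` (default) means
#'   every possible shift.
#' @return a `divergence_samples` data frame.
#' @export
intra_pairs_all_shifts <- function(sequence, rois, pseudocount = 1e-6,
                                   shifts = NULL) {
  ch <- case_histograms(sequence, rois, pseudocount)
  if (is.null(shifts)) shifts <- seq_len(n_frames(sequence) - 1L)
  out <- do.call(rbind, lapply(shifts, function(d)
    intra_pairs(sequence, rois, d, .hists = ch)))
  class(out) <- c("divergence_samples", "data.frame")
  out
}

#' Inter-case divergence samples
#'
#' Draws ROI-region pairs from two *different* cases uniformly at random over
#' all (case, frame, ROI) combinations, capped at `max_pairs`, and records
#' their JS divergences. Sampling is reproducible from `seed`. Cases are
#' expected to belong to one group; pooling across groups is the caller's
#' choice.
#'
#' @param sequences list of [image_sequence()] (>= 2 cases).
#' @param rois_list list of [roi_set()], parallel to `sequences`.
#' @param seed integer RNG seed for the pair draw.
#' @param max_pairs number of pairs to draw (default 2000).
#' @param pseudocount histogram smoothing.
#' @return a `divergence_samples` data frame with `shift = NA`.
#' @export
inter_pairs <- function(sequences, rois_list, seed, max_pairs = 2000L,
                        pseudocount = 1e-6) {
  if (length(sequences) < 2L)
    stop("inter-case sampling needs at least 2 cases")
  chs <- Map(case_histograms, sequences, rois_list,
             MoreArgs = list(pseudocount = pseudocount))
  H <- do.call(cbind, lapply(chs, `[[`, "H"))
  case_of <- rep(seq_along(chs), vapply(chs, function(c) length(c$frame_index), integer(1)))
  frame_of <- unlist(lapply(chs, `[[`, "frame_index"), use.names = FALSE)
  roi_of <- unlist(lapply(chs, `[[`, "roi_id"), use.names = FALSE)
  n <- length(case_of)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  ia <- sample.int(n, max_pairs, replace = TRUE)
  ib <- sample.int(n, max_pairs, replace = TRUE)
  clash <- which(case_of[ia] == case_of[ib])
  while (length(clash)) {                     # resample until cases differ
    ib[clash] <- sample.int(n, length(clash), replace = TRUE)
    clash <- clash[case_of[ia[clash]] == case_of[ib[clash]]]
  }
  ids <- vapply(sequences, function(s) s$case_id, character(1))
  hh <- unlist(lapply(chs, `[[`, "entropy"), use.names = FALSE)
  out <- data.frame(kind = "inter",
                    case_a = ids[case_of[ia]], case_b = ids[case_of[ib]],
                    frame_a = frame_of[ia], frame_b = frame_of[ib],
                    roi_id = NA_integer_, shift = NA_integer_,
                    js = js_divergence_cols(H[, ia, drop = FALSE], H[, ib, drop = FALSE],
                                            hh[ia], hh[ib]))
  class(out) <- c("divergence_samples", "data.frame")
  out
}

# save/restore .Random.seed so seeded sampling does not disturb the caller's
# RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Divergence-versus-time-shift curve
#'
#' Mean and standard deviation of intra-case JS divergence at every time
#' shift `1..F-1`. Periodic structure in this curve (respiratory motion)
#' is what [estimate_period()] quantifies.
#'
#' @inheritParams intra_pairs
#' @return a `shift_curve` data frame with columns
#'   `shift, mean_js, sd_js, n`.
#' @export
shift_curve <- function(sequence, rois, pseudocount = 1e-6) {
  if (n_frames(sequence) < 3L) stop("need at least 3 frames for a shift curve")
  shift_curve_from_samples(intra_pairs_all_shifts(sequence, rois, pseudocount))
}

# aggregate intra samples (possibly precomputed) into a shift curve
shift_curve_from_samples <- function(samples) {
  s <- samples[samples$kind == "intra", ]
  agg <- lapply(split(s$js, s$shift), function(v)
    c(mean(v), stats::sd(v), length(v)))
  out <- data.frame(shift = as.integer(names(agg)),
                    mean_js = vapply(agg, `[`, numeric(1), 1L),
                    sd_js = vapply(agg, `[`, numeric(1), 2L),
                    n = as.integer(vapply(agg, `[`, numeric(1), 3L)))
  out <- out[order(out$shift), ]
  rownames(out) <- NULL
  class(out) <- c("shift_curve", "data.frame")
  out
}

#' Average shift curves across the cases of a cohort
#'
#' Case curves are aligned on `shift` and their `mean_js` averaged with
#' pair-count weights; only shifts present in every curve are kept.
#'
#' @param curves list of [shift_curve()]s.
#' @return a `shift_curve` data frame (`sd_js` is the between-case sd of the
#'   per-case means).
#' @export
pool_shift_curves <- function(curves) {
  shifts <- Reduce(intersect, lapply(curves, `[[`, "shift"))
  rows <- lapply(sort(shifts), function(d) {
    m <- vapply(curves, function(c) c$mean_js[c$shift == d], numeric(1))
    n <- vapply(curves, function(c) c$n[c$shift == d], integer(1))
    data.frame(shift = d, mean_js = sum(m * n) / sum(n),
               sd_js = stats::sd(m), n = sum(n))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("shift_curve", "data.frame")
  out
}

#' Estimate the dominant period of a shift curve
#'
#' Linearly detrends the `mean_js` sequence, computes its autocorrelation,
#' and returns the lag of the first local autocorrelation maximum at lag >= 2
#' exceeding the white-noise band `2 / sqrt(L)` (`L` = curve length). In the
#' respiratory setting this is the breathing period in frames. Returns `NA`
#' when no significant peak exists (flat or aperiodic curves).
#'
#' @param curve a [shift_curve()] (length >= 8).
#' @return integer period in frames, or `NA`.
#' @export
estimate_period <- function(curve) {
  y <- curve$mean_js
  L <- length(y)
  if (L < 8L) stop("shift curve too short for period estimation (need >= 8 points)")
  t <- seq_len(L)
  resid <- stats::residuals(stats::lm(y ~ t))   # remove drift before acf
  # flat or purely linear curves leave only rounding noise: no periodicity
  if (stats::sd(resid) <= 1e-9 * (stats::sd(y) + abs(mean(y))))
    return(NA_integer_)
  y <- resid
  a <- stats::acf(y, lag.max = L - 2L, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # undo the biased estimator's (L - lag)/L taper, which otherwise tilts
  # broad peaks toward lower lags
  a <- a * L / (L - seq_along(a) + 1)
  thr <- 2 / sqrt(L)
  for (lag in 2L:(length(a) - 2L)) {
    v <- a[lag + 1L]                            # a[1] is lag 0
    if (v > thr && v >= a[lag] && v >= a[lag + 2L]) {
      # apex of the whole contiguous super-threshold region around this
      # local max, so small wiggles on a broad peak don't bias the estimate
      lo <- lag; hi <- lag
      while (lo > 2L && a[lo] > thr) lo <- lo - 1L
      while (hi < length(a) - 1L && a[hi + 2L] > thr) hi <- hi + 1L
      region <- lo:hi
      m <- region[which.max(a[region + 1L])]
      # parabolic interpolation through the apex and its neighbors gives a
      # fractional period; the discrete acf otherwise floors the estimate
      y0 <- a[m]; y1 <- a[m + 1L]; y2 <- a[m + 2L]
      denom <- y0 - 2 * y1 + y2
      frac <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
      return(as.integer(round(m + max(-0.5, min(0.5, frac)))))
    }
  }
  NA_integer_
}

#' Write divergence samples or a shift curve to CSV
#' @param x a `divergence_samples` or `shift_curve` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_divergence_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
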