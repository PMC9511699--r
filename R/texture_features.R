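#' First-order ROI features
#'
#' `echo_intensity` is the arithmetic mean gray level of an ROI;
#' `internal_heterogeneity` is the standard deviation of gray level within
#' the ROI ("local variance"). The population convention (divisor n) is used
#' for every standard deviation in this package.
#'
#' @param pixels numeric matrix (or vector) of ROI gray levels.
#' @return scalar.
#' @export
echo_intensity <- function(pixels) {
  if (length(pixels) == 0L) stop("empty ROI")
  mean(as.numeric(pixels))
}

#' @rdname echo_intensity
#' @export
internal_heterogeneity <- function(pixels) {
  if (length(pixels) < 2L) stop("ROI must contain at least 2 pixels")
  v <- as.numeric(pixels)
  sqrt(mean((v - mean(v))^2))
}

#' Between-ROI heterogeneity of a case
#'
#' The standard deviation (population convention) of the ROI mean intensities
#' across all ROIs and frames of one case — how much echo intensity varies
#' across the sampled regions of the organ.
#'
#' @param roi_means numeric vector of per-ROI mean intensities.
#' @return scalar standard deviation.
#' @export
heterogeneity <- function(roi_means) {
  if (length(roi_means) < 2L) stop("need at least 2 ROI means")
  v <- as.numeric(roi_means)
  sqrt(mean((v - mean(v))^2))
}

#' Gray-level run-length matrix
#'
#' Quantizes the 8-bit ROI onto `levels` equal-width bins
#' (`level = floor(value * levels / 256)`) and counts maximal runs of equal
#' level along rows (`"horizontal"`) or columns (`"vertical"`). Entry
#' `(i, j)` of the result is the number of runs of level `i` with length `j`.
#'
#' @param pixels integer matrix of ROI gray levels in 0..255.
#' @param levels number of quantized gray levels G (>= 2).
#' @param direction `"horizontal"` or `"vertical"`.
#' @return integer matrix `G x Lmax` of class `run_length_matrix`, with
#'   attributes `levels`, `direction` and `n_runs`.
#' @export
run_length_matrix <- function(pixels, levels = 16L,
                              direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (length(pixels) == 0L) stop("empty ROI")
  stopifnot(levels >= 2L)
  q <- matrix(pmin(as.integer(floor(as.numeric(pixels) * levels / 256)), levels - 1L),
              nrow = nrow(pixels))
  if (direction == "vertical") q <- t(q)
  lmax <- ncol(q)
  counts <- matrix(0L, nrow = levels, ncol = lmax)
  for (r in seq_len(nrow(q))) {
    row <- q[r, ]
    # maximal runs: breakpoints where the level changes
    brk <- c(which(row[-1] != row[-length(row)]), length(row))
    len <- diff(c(0L, brk))
    lev <- row[brk]
    for (k in seq_along(len))
      counts[lev[k] + 1L, len[k]] <- counts[lev[k] + 1L, len[k]] + 1L
  }
  structure(counts, class = "run_length_matrix", levels = levels,
            direction = direction, n_runs = sum(counts))
}

#' Gray-level and run-length nonuniformity
#'
#' Galloway nonuniformity statistics normalized by the squared run count so
#' both scores live in (0, 1]:
#' \deqn{GLNU = \sum_i \left(\sum_j R(i,j)\right)^2 / N^2, \qquad
#'       RLNU = \sum_j \left(\sum_i R(i,j)\right)^2 / N^2}
#' where `R(i,j)` counts runs of level `i` and length `j` and `N` is the
#' total run count. GLNU is 1 iff a single gray level produces every run;
#' RLNU is 1 iff all runs share one length; both fall toward `1/G` (resp.
#' `1/Lmax`) as runs spread evenly.
#'
#' @param rlm a [run_length_matrix()].
#' @return dimensionless score in (0, 1].
#' @export
glnu <- function(rlm) {
  n <- attr(rlm, "n_runs")
  if (is.null(n) || n < 1L) stop("run-length matrix has no runs")
  sum(rowSums(rlm)^2) / n^2
}

#' @rdname glnu
#' @export
rlnu <- function(rlm) {
  n <- attr(rlm, "n_runs")
  if (is.null(n) || n < 1L) stop("run-length matrix has no runs")
  sum(colSums(rlm)^2) / n^2
}

#' First-order gray-level entropy
#'
#' Shannon entropy (log base 2, bits) of the ROI's gray-level
#' relative-frequency histogram over the raw 0..255 levels, with the
#' convention `0 * log 0 = 0`.
#'
#' @param pixels integer matrix of ROI gray levels.
#' @return entropy in bits, >= 0.
#' @export
gl_entropy <- function(pixels) {
  if (length(pixels) == 0L) stop("empty ROI")
  p <- tabulate(as.integer(pixels) + 1L, nbins = 256L) / length(pixels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the six texture features for every ROI of a case
#'
#' Computes, for every (frame, ROI) of the sequence: echo intensity, internal
#' heterogeneity, GLNU, RLNU (each averaged over the configured run-length
#' scan directions) and entropy, plus the single case-level heterogeneity
#' (standard deviation of all ROI mean intensities of the case), repeated on
#' every row so each row is a complete ML instance.
#'
#' @param sequence an [image_sequence()].
#' @param rois an [roi_set()] for that sequence.
#' @param rl_levels run-length quantization levels G (default 16).
#' @param rl_directions character vector of scan directions to average over
#'   (default horizontal and vertical).
#' @return data frame, one row per (frame, ROI), in the
#'   [write_feature_table()] column order.
#' @export
extract_features <- function(sequence, rois, rl_levels = 16L,
                             rl_directions = c("horizontal", "vertical")) {
  rois <- as.data.frame(rois)
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    px <- roi_pixels(sequence, r$frame_index, r)
    gl <- vapply(rl_directions, function(d) {
      m <- run_length_matrix(px, rl_levels, d)
      c(glnu(m), rlnu(m))
    }, numeric(2))
    data.frame(case_id = sequence$case_id, group = sequence$group,
               frame_index = r$frame_index, roi_id = r$roi_id,
               echo_intensity = echo_intensity(px),
               internal_heterogeneity = internal_heterogeneity(px),
               heterogeneity = NA_real_,
               glnu = mean(gl[1, ]), rlnu = mean(gl[2, ]),
               entropy = gl_entropy(px))
  })
  out <- do.call(rbind, rows)
  out$heterogeneity <- if (nrow(out) >= 2L) heterogeneity(out$echo_intensity) else 0
  rownames(out) <- NULL
  out
}
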