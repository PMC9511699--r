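# shared fixtures and independent oracles, built in code at test time

# a sequence of constant-valued frames
const_sequence <- function(values, h = 8L, w = 8L, case_id = "c1",
                           group = "normal") {
  image_sequence(lapply(values, function(v) matrix(as.integer(v), h, w)),
                 case_id, group)
}

# one full-frame ROI on every frame
full_roi <- function(sequence) {
  d <- frame_dim(sequence)
  roi_set(data.frame(frame_index = NA, roi_id = 0L, x = 0L, y = 0L,
                     w = d[2], h = d[1]), sequence)
}

random_frames <- function(f, h = 8L, w = 8L) {
  lapply(seq_len(f), function(i)
    matrix(sample.int(256L, h * w, replace = TRUE) - 1L, h, w))
}

# --- independent oracles ------------------------------------------------

# run enumeration with base::rle, row by row (the implementation walks
# breakpoints manually, so this is an independent route)
oracle_rlm <- function(pixels, levels, direction) {
  q <- matrix(pmin(floor(as.numeric(pixels) * levels / 256), levels - 1),
              nrow = nrow(pixels))
  if (direction == "vertical") q <- t(q)
  counts <- matrix(0L, levels, ncol(q))
  for (r in seq_len(nrow(q))) {
    runs <- rle(q[r, ])
    for (k in seq_along(runs$lengths))
      counts[runs$values[k] + 1L, runs$lengths[k]] <-
        counts[runs$values[k] + 1L, runs$lengths[k]] + 1L
  }
  counts
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  total <- 0
  for (a in s1) for (b in s0)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(s1) * length(s0))
}

# noninferiority t-test via stats::t.test on margin-shifted data: subtracting
# the constant delta from every inter value turns the noninferiority test
# into a plain one-sided pooled two-sample test with identical t and p
oracle_equiv <- function(inter, intra, delta_frac) {
  delta <- delta_frac * mean(inter)
  tt <- stats::t.test(inter - delta, intra, var.equal = TRUE,
                      alternative = "less")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
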