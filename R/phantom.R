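#' Phantom cohort configuration
#'
#' Describes a synthetic B-mode-like speckle-video cohort: per-group
#' intensity statistics, cohort shape, within-case frame correlation,
#' periodic respiratory intensity modulation with growing amplitude, and a
#' slow drift. The generator targets the *statistical* structure the
#' independence analysis assumes — group mean/spread scales, within-case
#' texture persistence, breathing periodicity — not acoustic realism.
#'
#' Pixel model for frame `t` (0-based) of a case with base level `mu_c`
#' (drawn per case from `N(mu, sigma_between)`):
#' \deqn{I_t = clip_{0..255}\big(\mu_c\,[1 + \rho\,c_v S_p +
#'   \sqrt{1-\rho^2}(g_t - 1)] + A(t)\sin(2\pi t/T + \phi_c) + d\,t\big)}
#' with `c_v = sigma_within / mu`. `S_p` is one persistent zero-mean,
#' unit-sd *tissue structure* field per case, spatially correlated over
#' `tissue_scale_px` pixels (smoothed Gaussian noise): the anatomy that
#' stays put from frame to frame. `g_t` is a fresh unit-mean gamma speckle
#' field per frame (shape `k = c_v^{-2}`, the fast-changing coherent
#' interference pattern), `A(t) = breath_amplitude * amp_growth^(t/T)`, and
#' `phi_c` a random per-case respiratory phase. Either way the within-ROI
#' pixel spread is `sigma_within`. `rho = 1` with zero breathing/drift gives
#' literally identical frames; `rho = 0` regenerates the texture
#' independently every frame. The persistent field must be spatially
#' structured: a featureless iid field shared between frames leaves the
#' 256-bin histograms nearly uncorrelated (fresh jitter is far wider than
#' one gray level), which would make within-case dependence invisible to
#' the divergence test regardless of `rho`.
#'
#' Default group presets carry the mean +/- spread scale of rat-liver
#' B-mode texture (echo intensity and internal heterogeneity per pathology);
#' `sigma_between`, the breathing parameters and the drift are phantom
#' parameters (see the methods vignette for how they were fixed).
#'
#' @param groups named list of per-group parameter lists with elements
#'   `mu`, `sigma_within`, `sigma_between`.
#' @param cases_per_group cases simulated per group.
#' @param frames_per_case frames per case (F).
#' @param frame_size `c(height, width)` in pixels.
#' @param rois_per_frame number of ROIs placed on a fixed grid (R).
#' @param roi_size ROI side length in pixels (square ROIs).
#' @param rho within-case frame correlation dial in [0, 1].
#' @param tissue_scale_px spatial correlation length of the persistent
#'   tissue-structure field, in pixels.
#' @param breath_period_frames respiratory period T in frames.
#' @param breath_amplitude peak respiratory intensity modulation (gray
#'   levels) in the first cycle.
#' @param amp_growth multiplicative amplitude growth per breathing cycle
#'   (>= 1).
#' @param drift_per_frame slow additive intensity drift (gray levels per
#'   frame).
#' @param frame_rate_hz nominal frame rate (35 frames per 4.5 s breathing
#'   cycle by default).
#' @param seed integer master seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(groups = phantom_presets(),
                           cases_per_group = 4L,
                           frames_per_case = 60L,
                           frame_size = c(64L, 64L),
                           rois_per_frame = 5L,
                           roi_size = 16L,
                           rho = 0.5,
                           tissue_scale_px = 4L,
                           breath_period_frames = 35L,
                           breath_amplitude = 4,
                           amp_growth = 1.1,
                           drift_per_frame = 0.02,
                           frame_rate_hz = 35 / 4.5,
                           seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, breath_period_frames >= 2L,
            amp_growth >= 1, cases_per_group >= 1L, frames_per_case >= 1L,
            rois_per_frame >= 1L, roi_size * roi_size >= 16L)
  for (g in names(groups)) {
    p <- groups[[g]]
    stopifnot(is.numeric(p$mu), is.numeric(p$sigma_within),
              is.numeric(p$sigma_between), p$mu > 0, p$sigma_within > 0,
              p$sigma_between >= 0)
    if (p$mu + 3 * p$sigma_within > 255 * 1.05)
      stop("group '", g, "': intensity parameters push pixels far beyond 255")
  }
  structure(list(groups = groups, cases_per_group = as.integer(cases_per_group),
                 frames_per_case = as.integer(frames_per_case),
                 frame_size = as.integer(frame_size),
                 rois_per_frame = as.integer(rois_per_frame),
                 roi_size = as.integer(roi_size), rho = rho,
                 tissue_scale_px = as.integer(tissue_scale_px),
                 breath_period_frames = as.integer(breath_period_frames),
                 breath_amplitude = breath_amplitude, amp_growth = amp_growth,
                 drift_per_frame = drift_per_frame,
                 frame_rate_hz = frame_rate_hz, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Built-in group presets
#'
#' Echo-intensity mean and within-ROI spread per pathology group at the
#' scale reported for rat liver B-mode texture (normal, steatosis with
#' fatty change, fibrosis); `sigma_between` is the between-case spread of
#' the group mean under standardized imaging presets.
#'
#' @return named list of group parameter lists.
#' @export
phantom_presets <- function() {
  list(
    normal    = list(mu = 25.4, sigma_within = 13.2, sigma_between = 0.25),
    steatosis = list(mu = 34.7, sigma_within = 12.0, sigma_between = 0.25),
    fibrosis  = list(mu = 55.9, sigma_within = 16.3, sigma_between = 0.25)
  )
}

# zero-mean, unit-sd field with spatial correlation length `scale` px:
# iid Gaussian noise box-blurred (circularly, separably) then standardized.
smooth_field <- function(h, w, scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (scale > 1L) {
    blur1 <- function(m, k) {           # circular running mean along rows
      n <- nrow(m)
      idx <- outer(seq_len(n), -(k %/% 2):((k - 1L) %/% 2), `+`)
      idx <- (idx - 1L) %% n + 1L
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_len(ncol(idx))) out <- out + m[idx[, j], , drop = FALSE]
      out / k
    }
    z <- blur1(z, scale)
    z <- t(blur1(t(z), scale))
  }
  (z - mean(z)) / stats::sd(c(z))
}

# fixed, non-overlapping ROI grid: as many ROIs as fit row-major on a grid of
# roi_size squares with a margin, identical for every case so inter-case
# divergence reflects content, never geometry.
phantom_roi_grid <- function(frame_size, rois_per_frame, roi_size) {
  h <- frame_size[1]; w <- frame_size[2]; s <- roi_size
  per_row <- w %/% s
  per_col <- h %/% s
  if (per_row * per_col < rois_per_frame)
    stop("ROI grid does not fit: ", rois_per_frame, " ROIs of ", s, "x", s,
         " on a ", h, "x", w, " frame")
  k <- seq_len(rois_per_frame) - 1L
  data.frame(frame_index = NA_integer_, roi_id = k,
             x = (k %% per_row) * s, y = (k %/% per_row) * s,
             w = s, h = s)
}

#' Generate one phantom case
#'
#' Draws one case from a group of a [phantom_config()]: a per-case base
#' level, a persistent tissue-structure field weighted by `rho`, fresh
#' per-frame gamma speckle mixed in at weight `sqrt(1 - rho^2)`, plus
#' breathing modulation and drift (see [phantom_config()] for the pixel
#' model). Deterministic given `seed`.
#'
#' @param config a [phantom_config()].
#' @param group group name in `config$groups`.
#' @param case_id case identifier.
#' @param seed integer seed for this case.
#' @return list with elements `sequence` ([image_sequence()]) and `rois`
#'   ([roi_set()]).
#' @export
generate_case <- function(config, group, case_id, seed) {
  p <- config$groups[[group]]
  if (is.null(p)) stop("unknown group '", group, "'")
  h <- config$frame_size[1]; w <- config$frame_size[2]
  f <- config$frames_per_case
  rho <- config$rho
  k <- (p$mu / p$sigma_within)^2              # gamma shape for the speckle
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  cv <- p$sigma_within / p$mu
  mu_c <- stats::rnorm(1, p$mu, p$sigma_between)
  phi_c <- stats::runif(1, 0, 2 * pi)
  s_p <- smooth_field(h, w, config$tissue_scale_px)   # persistent anatomy
  t_idx <- seq_len(f) - 1L
  amp <- config$breath_amplitude * config$amp_growth^(t_idx / config$breath_period_frames)
  breath <- amp * sin(2 * pi * t_idx / config$breath_period_frames + phi_c)
  drift <- config$drift_per_frame * t_idx
  frames <- lapply(seq_len(f), function(i) {
    g_t <- matrix(stats::rgamma(h * w, shape = k, scale = 1 / k), h, w)
    v <- mu_c * pmax(1 + rho * cv * s_p + sqrt(1 - rho^2) * (g_t - 1), 0) +
      breath[i] + drift[i]
    m <- matrix(as.integer(pmin(pmax(round(v), 0), 255)), h, w)
    m
  })
  seq <- image_sequence(frames, case_id, group, config$frame_rate_hz)
  rois <- roi_set(phantom_roi_grid(config$frame_size, config$rois_per_frame,
                                   config$roi_size), seq)
  list(sequence = seq, rois = rois)
}

#' Generate a full phantom cohort
#'
#' Generates `cases_per_group` cases for every group of the configuration.
#' Case seeds are derived deterministically from the master seed, so the
#' whole cohort is reproducible bit-for-bit.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_cohort` list: `sequences` (named list of
#'   [image_sequence()]), `rois` (parallel named list of [roi_set()]) and
#'   `config` (the generating truth).
#' @export
generate_cohort <- function(config) {
  sequences <- list(); rois <- list()
  gi <- 0L
  for (g in names(config$groups)) {
    gi <- gi + 1L
    for (ci in seq_len(config$cases_per_group)) {
      id <- sprintf("%s_%02d", g, ci)
      case_seed <- (config$seed + 7919L * gi + 104729L * ci) %% .Machine$integer.max
      case <- generate_case(config, g, id, case_seed)
      sequences[[id]] <- case$sequence
      rois[[id]] <- case$rois
    }
  }
  structure(list(sequences = sequences, rois = rois, config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases (%s), %d frames of %dx%d px, %d ROIs, rho = %g\n",
              length(x$sequences),
              paste(names(x$config$groups), collapse = "/"),
              x$config$frames_per_case, x$config$frame_size[1],
              x$config$frame_size[2], x$config$rois_per_frame, x$config$rho))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Layout consumable by the readers: one directory per case containing
#' `frames/frame_%04d.png` (or `.pgm`) and `rois.csv`, plus a cohort-level
#' `truth.json` holding the generating configuration.
#'
#' @param cohort a `phantom_cohort`.
#' @param path output directory.
#' @param format frame format, `"png"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$sequences)) {
    cd <- file.path(path, id)
    dir.create(cd, showWarnings = FALSE)
    write_sequence(cohort$sequences[[id]], file.path(cd, "frames"), format)
    # store the broadcastable single-frame layout
    r <- as.data.frame(cohort$rois[[id]])
    r <- r[r$frame_index == 0L, ]
    r$frame_index <- NA_integer_
    utils::write.csv(r, file.path(cd, "rois.csv"), row.names = FALSE, na = "")
  }
  truth <- unclass(cohort$config)
  truth$group_labels <-
    as.list(vapply(cohort$sequences, function(s) s$group, character(1)))
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path cohort directory containing case subdirectories and
#'   `truth.json`.
#' @return a `phantom_cohort`-shaped list (`config` is the deserialized
#'   truth, re-classed when complete).
#' @export
read_cohort <- function(path) {
  tf <- file.path(path, "truth.json")
  if (!file.exists(tf)) stop("not a cohort directory (no truth.json): ", path)
  truth <- jsonlite::fromJSON(tf)
  labels <- unlist(truth$group_labels)
  sequences <- list(); rois <- list()
  for (id in names(labels)) {
    cd <- file.path(path, id)
    s <- read_sequence(file.path(cd, "frames"), id, labels[[id]],
                       frame_rate_hz = truth$frame_rate_hz)
    sequences[[id]] <- s
    rois[[id]] <- read_rois(file.path(cd, "rois.csv"), s)
  }
  config <- truth[setdiff(names(truth), "group_labels")]
  structure(list(sequences = sequences, rois = rois, config = config),
            class = "phantom_cohort")
}
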