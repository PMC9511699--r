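#' Construct an image sequence
#'
#' An `image_sequence` holds the ordered 8-bit grayscale frames of one case
#' (one video clip of one subject) together with its group label and frame
#' rate. Frame order is acquisition order; the time index of frame `i` is
#' `i - 1`.
#'
#' @param frames list of integer matrices, all the same dimension, values in
#'   0..255. Matrices are stored as `[row, col]`, i.e. `y` indexes rows and
#'   `x` indexes columns.
#' @param case_id character scalar identifying the case.
#' @param group character scalar group label (e.g. "normal", "fibrosis").
#' @param frame_rate_hz optional positive frame rate, frames per second.
#' @return an object of class `image_sequence`.
#' @export
image_sequence <- function(frames, case_id, group, frame_rate_hz = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch: all frames must share the same height and width")
  frames <- lapply(frames, function(f) {
    if (!is.numeric(f)) stop("frames must be numeric matrices")
    if (any(f != floor(f)) || any(f < 0) || any(f > 255))
      stop("pixel values must be integers in [0, 255]")
    storage.mode(f) <- "integer"
    f
  })
  if (!is.null(frame_rate_hz)) {
    stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1L, frame_rate_hz > 0)
  }
  structure(
    list(case_id = as.character(case_id), group = as.character(group),
         frames = frames, frame_rate_hz = frame_rate_hz),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> case '%s' (group '%s'): %d frames of %dx%d px%s\n",
              x$case_id, x$group, length(x$frames), d[1], d[2],
              if (is.null(x$frame_rate_hz)) "" else
                sprintf(" @ %.3g Hz", x$frame_rate_hz)))
  invisible(x)
}

#' Number of frames in a sequence
#' @param sequence an `image_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(sequence) length(sequence$frames)

#' Frame height and width
#' @param sequence an `image_sequence`.
#' @return integer vector `c(height, width)`.
#' @export
frame_dim <- function(sequence) dim(sequence$frames[[1]])

# ---------------------------------------------------------------------------
# frame files: 8-bit grayscale PNG (via the png package) or plain-text PGM
# (ASCII "P2"). The study's display data are 8-bit, and the 256-bin histogram
# convention downstream assumes it, so anything else is rejected.

read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L && {
      r <- a[, , 1]; !isTRUE(all.equal(r, a[, , 2])) || !isTRUE(all.equal(r, a[, , 3]))
    })
      stop("non-grayscale PNG rejected: ", path)
    a <- a[, , 1]
  }
  # 8-bit PNG samples are v/255 exactly; 16-bit files land off-grid and fail
  v <- a * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop("non-8-bit PNG rejected (16-bit or non-integer samples): ", path)
  m <- round(v)
  storage.mode(m) <- "integer"
  m
}

write_frame_png <- function(frame, path) {
  png::writePNG(frame / 255, path)
  invisible(path)
}

read_frame_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(), quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII (P2) PGM supported: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (maxval != 255L) stop("non-8-bit PGM rejected (maxval ", maxval, "): ", path)
  v <- as.integer(tok[-(1:4)])
  if (length(v) != w * h) stop("truncated PGM: ", path)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

write_frame_pgm <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), "255"), con)
  apply(frame, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read an image sequence from disk
#'
#' Reads a directory of single-frame image files, one per frame. Frames are
#' taken in lexicographic filename order (enforced; filesystem listing order
#' is never trusted), so zero-padded frame numbers sort correctly. Supported
#' formats: 8-bit grayscale PNG and plain-text PGM (`P2`). All frames must
#' share one shape; non-8-bit input is rejected.
#'
#' @param path directory containing the frame files.
#' @param case_id case identifier to attach.
#' @param group group label to attach.
#' @param frame_rate_hz optional frame rate.
#' @return an [image_sequence()].
#' @export
read_sequence <- function(path, case_id, group, frame_rate_hz = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, pattern = "\\.(png|pgm)$", ignore.case = TRUE)
  if (length(files) == 0L) stop("no .png or .pgm frames found in ", path)
  files <- sort(files, method = "radix")   # locale-independent lexicographic
  frames <- lapply(file.path(path, files), function(f) {
    ext <- tolower(tools::file_ext(f))
    if (ext == "png") read_frame_png(f) else read_frame_pgm(f)
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch among frames in ", path, ": ",
         paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = " vs "))
  image_sequence(frames, case_id, group, frame_rate_hz)
}

#' Write an image sequence to disk
#'
#' Writes one file per frame, named `frame_0000.png`, `frame_0001.png`, ...
#' so that lexicographic order reproduces acquisition order on re-read.
#'
#' @param sequence an [image_sequence()].
#' @param path output directory (created if absent).
#' @param format `"png"` (default) or `"pgm"` (plain text).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequence, path, format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sequence$frames)) {
    f <- file.path(path, sprintf("frame_%04d.%s", i - 1L, format))
    if (format == "png") write_frame_png(sequence$frames[[i]], f)
    else write_frame_pgm(sequence$frames[[i]], f)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# ROIs

#' Construct a per-frame ROI table
#'
#' An `roi_set` is a data frame with columns `frame_index`, `roi_id`, `x`,
#' `y`, `w`, `h`. Coordinates are 0-based with half-open extent
#' `[x, x + w) x [y, y + h)`; `x` indexes columns, `y` rows. Every frame of a
#' case carries the same ROIs (same `roi_id`s, same count); `roi_id` k names
#' the spatially corresponding region on every frame.
#'
#' @param df data frame with the columns above; `frame_index` may be `NA` to
#'   broadcast a single per-frame layout to all frames.
#' @param sequence the [image_sequence()] the ROIs belong to (for bounds and
#'   broadcast).
#' @return an `roi_set` data frame (one row per frame x ROI).
#' @export
roi_set <- function(df, sequence) {
  need <- c("frame_index", "roi_id", "x", "y", "w", "h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ROI table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  nf <- n_frames(sequence)
  if (all(is.na(df$frame_index))) {          # broadcast one layout to all frames
    df <- do.call(rbind, lapply(seq_len(nf) - 1L, function(t) {
      d <- df; d$frame_index <- t; d
    }))
  } else if (anyNA(df$frame_index)) {
    stop("frame_index must be all present or all empty (broadcast)")
  }
  for (col in need) df[[col]] <- as.integer(df[[col]])
  if (any(df$frame_index < 0L | df$frame_index >= nf))
    stop("frame_index out of range 0..", nf - 1L)
  if (any(df$w <= 0L | df$h <= 0L)) stop("ROI width and height must be positive")
  if (any(df$w * df$h < 16L)) stop("ROI smaller than 16 pixels is too small for a histogram")
  d <- frame_dim(sequence)
  bad <- df$x < 0L | df$y < 0L | df$x + df$w > d[2] | df$y + df$h > d[1]
  if (any(bad)) {
    b <- df[bad, ][1, ]
    stop(sprintf("ROI out of bounds: frame %d, roi_id %d (%d+%d x %d+%d on %dx%d frame)",
                 b$frame_index, b$roi_id, b$x, b$w, b$y, b$h, d[2], d[1]))
  }
  counts <- table(df$frame_index)
  if (length(unique(as.integer(counts))) != 1L || length(counts) != nf)
    stop("every frame must carry the same number of ROIs")
  ids <- split(df$roi_id, df$frame_index)
  ref <- sort(ids[[1]])
  if (anyDuplicated(ref) || !all(vapply(ids, function(v) identical(sort(v), ref), logical(1))))
    stop("roi_ids must be unique within a frame and consistent across frames")
  df <- df[order(df$frame_index, df$roi_id), ]
  rownames(df) <- NULL
  class(df) <- c("roi_set", "data.frame")
  df
}

#' Read ROI definitions from CSV or JSON
#'
#' The CSV schema is `frame_index, roi_id, x, y, w, h` (0-based, half-open;
#' see [roi_set()]). Rows with an empty `frame_index` define a single layout
#' that is broadcast to every frame of the sequence. A JSON file holding an
#' array of objects with the same fields is accepted too.
#'
#' @param path CSV or JSON file.
#' @param sequence the [image_sequence()] the ROIs apply to.
#' @return an [roi_set()].
#' @export
read_rois <- function(path, sequence) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    df <- as.data.frame(jsonlite::fromJSON(path))
    if (is.null(df$frame_index)) df$frame_index <- NA_integer_
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  roi_set(df, sequence)
}

#' Write an ROI table to CSV
#' @param rois an [roi_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

#' Extract the pixels of one ROI from one frame
#' @param sequence an [image_sequence()].
#' @param frame_index 0-based frame index.
#' @param roi one row of an [roi_set()] (or any list with `x, y, w, h`).
#' @return integer matrix of ROI pixels.
#' @export
roi_pixels <- function(sequence, frame_index, roi) {
  f <- sequence$frames[[frame_index + 1L]]
  f[(roi$y + 1L):(roi$y + roi$h), (roi$x + 1L):(roi$x + roi$w), drop = FALSE]
}

# ---------------------------------------------------------------------------
# feature tables

feature_table_columns <- c("case_id", "group", "frame_index", "roi_id",
                           "echo_intensity", "internal_heterogeneity",
                           "heterogeneity", "glnu", "rlnu", "entropy")

#' Write a per-ROI feature table to CSV
#'
#' Fixed column order: `case_id, group, frame_index, roi_id, echo_intensity,
#' internal_heterogeneity, heterogeneity, glnu, rlnu, entropy`. Floats keep
#' enough digits (15 significant) that a re-read reproduces them.
#'
#' @param rows data frame carrying at least the columns above.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (nrow(as.data.frame(rows)) == 0L && length(names(rows)) == 0L)
    rows <- stats::setNames(
      as.data.frame(matrix(nrow = 0L, ncol = length(feature_table_columns))),
      feature_table_columns)
  miss <- setdiff(feature_table_columns, names(rows))
  if (length(miss))
    stop("feature table missing field(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(rows)[feature_table_columns]
  num <- vapply(df, is.numeric, logical(1)) &
    !(names(df) %in% c("frame_index", "roi_id"))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = which(names(df) %in% c("case_id", "group")))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data frame in the canonical column order.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character", group = "character"))
  miss <- setdiff(feature_table_columns, names(df))
  if (length(miss)) stop("not a feature table, missing: ", paste(miss, collapse = ", "))
  df[feature_table_columns]
}
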