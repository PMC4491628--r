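#' Motion sequence container
#'
#' A `motion_sequence` holds a fixed-rate time series of labelled 3D landmark
#' positions, the raw material from which relative visual features and joint
#' angles are extracted. Positions are stored as a numeric array of dimension
#' `T x K x 3` (frames x landmarks x coordinates). The coordinate convention
#' used throughout the package is right-handed with the y axis vertical, so
#' that view rotations "about the vertical axis" are rotations about y; the
#' convention is carried in the object, not hard-coded into the maths.
#'
#' @param frames numeric array `T x K x 3`, or a `T x 3K` matrix with
#'   coordinates in landmark-major triples (x1 y1 z1 x2 y2 z2 ...).
#' @param landmark_names character vector of length K; defaults to
#'   `M1..MK`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param up_axis which coordinate axis is vertical (default `"y"`).
#' @return an object of class `motion_sequence`.
#' @export
motion_sequence <- function(frames, landmark_names = NULL, sample_rate = 120,
                            up_axis = "y") {
  if (is.matrix(frames)) {
    if (ncol(frames) %% 3L != 0L)
      stop("matrix input must have 3 columns per landmark")
    K <- ncol(frames) %/% 3L
    frames <- array(frames, dim = c(nrow(frames), 3L, K))
    frames <- aperm(frames, c(1L, 3L, 2L))
    # columns were x1 y1 z1 x2 ...: array() above filled coordinate-major,
    # so rebuild explicitly
  }
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stop("frames must be a T x K x 3 array or a T x 3K matrix")
  K <- dim(frames)[2]
  if (is.null(landmark_names)) landmark_names <- paste0("M", seq_len(K))
  if (length(landmark_names) != K)
    stop("landmark_names length does not match landmark count")
  if (anyDuplicated(landmark_names))
    stop("landmark names must be unique")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (any(!is.finite(frames)))
    stop("non-finite coordinates in motion data")
  dimnames(frames) <- list(NULL, landmark_names, c("x", "y", "z"))
  structure(
    list(frames = frames, landmark_names = landmark_names,
         sample_rate = sample_rate, up_axis = match.arg(up_axis, c("x", "y", "z"))),
    class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<motion_sequence> %d frames, %d landmarks @ %g Hz (%.2f s)\n",
              d[1], d[2], x$sample_rate, d[1] / x$sample_rate))
  cat("  landmarks:", paste(utils::head(x$landmark_names, 8), collapse = " "),
      if (d[2] > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.motion_sequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[1]
n_landmarks <- function(seq) dim(seq$frames)[2]

#' Flatten landmark positions of one frame to a K x 3 matrix
#' @param seq a `motion_sequence`
#' @param t frame index
#' @return K x 3 numeric matrix with landmark row names
#' @export
frame_positions <- function(seq, t) {
  stopifnot(inherits(seq, "motion_sequence"))
  if (t < 1 || t > n_frames(seq)) stop("frame index out of range")
  m <- seq$frames[t, , , drop = FALSE]
  dim(m) <- dim(seq$frames)[2:3]
  rownames(m) <- seq$landmark_names
  colnames(m) <- c("x", "y", "z")
  m
}

## ------------------------------------------------------------------ I/O ----

#' Read a motion-capture file
#'
#' Supports three dialects: TRC (tab-delimited mocap text), C3D (the common
#' Intel-processor floating-point variant) and the package's plain tabular
#' text format. The tabular dialect is the canonical fixture format: a
#' `# markers:` header line, a `# rate:` header line, then one whitespace
#' separated row per frame with 3 columns (x y z) per marker.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"trc"`, `"c3d"` or `"tab"`.
#' @return a [motion_sequence()].
#' @export
read_motion <- function(path, format = c("auto", "trc", "c3d", "tab")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, trc = "trc", c3d = "c3d", "tab")
  }
  switch(format,
         trc = read_trc(path),
         c3d = read_c3d(path),
         tab = read_motion_tab(path))
}

#' Write a motion sequence
#' @param seq a [motion_sequence()]
#' @param path output path
#' @param format `"trc"`, `"c3d"` or `"tab"`
#' @return `path`, invisibly.
#' @export
write_motion <- function(seq, path, format = c("tab", "trc", "c3d")) {
  stopifnot(inherits(seq, "motion_sequence"))
  format <- match.arg(format)
  switch(format,
         tab = write_motion_tab(seq, path),
         trc = write_trc(seq, path),
         c3d = write_c3d(seq, path))
  invisible(path)
}

read_motion_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  mk <- grep("^#\\s*markers:", hdr, value = TRUE)
  if (length(mk) != 1L)
    stop("tabular motion file lacks a single '# markers:' header line: ", path)
  names <- strsplit(sub("^#\\s*markers:\\s*", "", mk), "\\s+")[[1]]
  rt <- grep("^#\\s*rate:", hdr, value = TRUE)
  rate <- if (length(rt) == 1L) as.numeric(sub("^#\\s*rate:\\s*", "", rt)) else 120
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("tabular motion file has no data rows: ", path)
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (anyNA(v))
      stop(sprintf("unparseable or NaN value in data row %d of %s", i, path))
    v
  })
  ncols <- lengths(vals)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in tabular motion file: ", path)
  if (ncols[1] != 3L * length(names))
    stop(sprintf("row width %d does not match 3 x %d markers in %s",
                 ncols[1], length(names), path))
  m <- do.call(rbind, vals)
  motion_sequence(m, landmark_names = names, sample_rate = rate)
}

write_motion_tab <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# markers:", paste(seq$landmark_names, collapse = " ")),
               paste("# rate:", format(seq$sample_rate, digits = 15))), con)
  m <- flatten_frames(seq)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# T x 3K matrix, landmark-major triples
flatten_frames <- function(seq) {
  a <- aperm(seq$frames, c(1L, 3L, 2L))   # T x 3 x K
  dim(a) <- c(dim(seq$frames)[1], 3L * dim(seq$frames)[2])
  a
}

unflatten_frames <- function(m, K) {
  a <- array(m, dim = c(nrow(m), 3L, K))
  aperm(a, c(1L, 3L, 2L))
}

read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("TRC file too short: ", path)
  meta_keys <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(meta_vals), meta_keys)
  rate <- as.numeric(meta[["DataRate"]])
  if (!length(rate) || is.na(rate))
    stop("TRC header line 3 lacks a numeric DataRate: ", path)
  nmark <- as.numeric(meta[["NumMarkers"]])
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[nzchar(trimws(labels))]
  labels <- labels[!labels %in% c("Frame#", "Time")]
  if (!is.na(nmark) && length(labels) != nmark)
    stop(sprintf("TRC marker label count (%d) disagrees with NumMarkers (%d) in %s",
                 length(labels), nmark, path))
  body <- lines[-seq_len(5L)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t")[[1]]))
    if (length(v) < 2L + 3L * length(labels) || anyNA(v[seq_len(2L + 3L * length(labels))]))
      stop(sprintf("unparseable TRC data row %d in %s", i + 5L, path))
    v[2L + seq_len(3L * length(labels))]
  })
  m <- do.call(rbind, rows)
  motion_sequence(m, landmark_names = labels, sample_rate = rate)
}

write_trc <- function(seq, path) {
  K <- n_landmarks(seq); T <- n_frames(seq); r <- seq$sample_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(r, r, T, K, "m", r, 1, T), collapse = "\t"), con)
  lab <- c("Frame#", "Time", as.vector(rbind(seq$landmark_names, "", "")))
  writeLines(paste(lab, collapse = "\t"), con)
  xyz <- paste0(rep(c("X", "Y", "Z"), K), rep(seq_len(K), each = 3))
  writeLines(paste(c("", "", xyz), collapse = "\t"), con)
  m <- flatten_frames(seq)
  tm <- (seq_len(T) - 1) / r
  body <- cbind(seq_len(T), format(tm, digits = 10),
                format(m, digits = 17, scientific = FALSE, trim = TRUE))
  utils::write.table(body, con, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
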