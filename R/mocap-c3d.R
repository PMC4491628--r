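## Minimal C3D support: the common modern variant only (Intel/IEEE processor
## type 84, floating-point 3D samples, no analog channels). Files written by
## write_c3d() round-trip through read_c3d() at single precision. The C3D
## layout: 512-byte blocks; block 1 is the header, the parameter section
## holds group/parameter records (POINT:LABELS, POINT:RATE, ...), then frame
## data as (x, y, z, residual) float quadruples per marker.

C3D_BLOCK <- 512L

read_c3d <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", C3D_BLOCK)
  if (length(hdr) < C3D_BLOCK || as.integer(hdr[2]) != 0x50L)
    stop("not a C3D file (bad header magic): ", path)
  param_block <- as.integer(hdr[1])
  u16 <- function(raw, i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  npoints <- u16(hdr, 3L)
  nanalog <- u16(hdr, 5L)
  first_frame <- u16(hdr, 7L)
  last_frame <- u16(hdr, 9L)
  scale <- readBin(hdr[13:16], "double", size = 4, endian = "little")
  data_block <- u16(hdr, 17L)
  rate <- readBin(hdr[21:24], "double", size = 4, endian = "little")
  if (scale >= 0)
    stop("integer-scaled C3D data not supported (only float variant): ", path)

  # parameter section: only needed for labels and the processor type
  seek(con, (param_block - 1L) * C3D_BLOCK)
  praw <- readBin(con, "raw", 4L)
  if (as.integer(praw[4]) != 84L)
    stop("unsupported C3D processor type (only Intel/84): ", path)
  labels <- c3d_read_labels(con, param_block, npoints)

  nframes <- last_frame - first_frame + 1L
  seek(con, (data_block - 1L) * C3D_BLOCK)
  per_frame <- 4L * npoints + nanalog
  vals <- readBin(con, "double", n = nframes * per_frame, size = 4,
                  endian = "little")
  if (length(vals) < nframes * per_frame)
    stop("truncated C3D data section: ", path)
  m <- matrix(vals, ncol = per_frame, byrow = TRUE)
  xyz_cols <- as.vector(vapply(seq_len(npoints) - 1L,
                               function(k) 4L * k + 1:3, integer(3)))
  motion_sequence(m[, xyz_cols, drop = FALSE],
                  landmark_names = labels, sample_rate = rate)
}

c3d_read_labels <- function(con, param_block, npoints) {
  seek(con, (param_block - 1L) * C3D_BLOCK + 4L)
  groups <- list()
  labels <- NULL
  rate_group_id <- NA_integer_
  repeat {
    nname <- readBin(con, "integer", size = 1, signed = TRUE)
    if (length(nname) == 0L) break
    id <- readBin(con, "integer", size = 1, signed = TRUE)
    if (length(id) == 0L || nname == 0L) break
    name <- rawToChar(readBin(con, "raw", abs(nname)))
    offset_pos <- seek(con)
    offset <- readBin(con, "integer", size = 2, signed = TRUE,
                      endian = "little")
    if (id < 0L) {            # group record
      groups[[name]] <- -id
      dlen <- readBin(con, "integer", size = 1, signed = TRUE)
      if (dlen > 0) readBin(con, "raw", dlen)
    } else {                  # parameter record
      type <- readBin(con, "integer", size = 1, signed = TRUE)
      ndim <- readBin(con, "integer", size = 1, signed = TRUE)
      dims <- if (ndim > 0)
        readBin(con, "integer", n = ndim, size = 1, signed = FALSE) else integer()
      nel <- if (length(dims)) prod(dims) else 1L
      if (identical(name, "LABELS") && identical(groups[["POINT"]], id) &&
          type == -1L && ndim == 2L) {
        raw <- readBin(con, "raw", nel)
        labels <- apply(matrix(raw, nrow = dims[1]), 2,
                        function(r) trimws(rawToChar(r)))
      }
    }
    if (offset == 0L) break
    seek(con, offset_pos + offset)
  }
  if (is.null(labels)) labels <- paste0("M", seq_len(npoints))
  if (length(labels) != npoints)
    stop("C3D POINT:LABELS count does not match header point count")
  labels
}

write_c3d <- function(seq, path) {
  K <- n_landmarks(seq); T <- n_frames(seq)
  if (T > 65535L) stop("C3D writer supports at most 65535 frames")
  labels <- formatC(substr(seq$landmark_names, 1, 16), width = 16,
                    flag = "-")
  # parameter section: POINT group with LABELS, RATE, USED
  pbuf <- raw()
  put <- function(...) pbuf <<- c(pbuf, ...)
  i8 <- function(x) as.raw(bitwAnd(as.integer(x), 0xFFL))
  i16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                              endian = "little")
  rec <- function(name, id, payload) {
    nm <- charToRaw(name)
    off <- length(payload) + 2L
    c(i8(length(nm)), i8(id), nm, i16(off), payload)
  }
  put(rec("POINT", -1L, i8(0L)))                       # group, no description
  put(rec("LABELS", 1L, c(i8(-1L), i8(2L), i8(16L), i8(K),
                          charToRaw(paste(labels, collapse = "")),
                          i8(0L))))
  put(rec("RATE", 1L, c(i8(4L), i8(0L), f32(seq$sample_rate), i8(0L))))
  put(rec("USED", 1L, c(i8(2L), i8(0L), i16(K), i8(0L))))
  put(c(i8(0L), i8(0L)))                               # terminator
  nparam_blocks <- as.integer(ceiling((length(pbuf) + 4L) / C3D_BLOCK))
  param_head <- c(as.raw(c(0x01, 0x50)), i8(nparam_blocks), i8(84L))
  psec <- c(param_head, pbuf)
  psec <- c(psec, raw(nparam_blocks * C3D_BLOCK - length(psec)))

  data_block <- 2L + nparam_blocks
  hdr <- c(i8(2L), as.raw(0x50), i16(K), i16(0L), i16(1L), i16(T),
           i16(10L),                     # max interpolation gap
           f32(-1),                      # negative scale => float data
           i16(data_block), i16(1L), f32(seq$sample_rate))
  hdr <- c(hdr, raw(C3D_BLOCK - length(hdr)))

  m <- flatten_frames(seq)
  data <- matrix(0, nrow = T, ncol = 4L * K)
  for (k in seq_len(K)) data[, 4L * (k - 1L) + 1:3] <- m[, 3L * (k - 1L) + 1:3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(psec, con)
  writeBin(as.numeric(t(data)), con, size = 4, endian = "little")
  invisible(path)
}
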