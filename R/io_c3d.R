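## Minimal C3D reader/writer (Intel processor type, floating-point data).
## Covers the subset produced by common motion-capture exports: one point
## group with labels/rate/scale and optional analog channels. The writer
## exists chiefly so the reader can be exercised against files built in
## code (fixtures are never shipped as binaries).

#' Read a C3D motion-capture file
#'
#' Parses the header and parameter section (Intel/float dialect), returning
#' marker trajectories in metres and analog channels with their rate.
#' Unsupported parameter blocks are skipped with a warning.
#'
#' @param path file path.
#' @return list with `markers` (a `cd_markers`), `analog` (data.frame, one
#'   column per channel, or NULL), `analog_rate` (Hz), `point_rate` (Hz).
#' @export
read_c3d <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = file.size(path))
  if (length(raw) < 512L) stop("corrupt C3D (short file): ", path,
                               call. = FALSE)
  u8 <- function(i) as.integer(raw[i])
  i16 <- function(i) {
    v <- u8(i) + 256L * u8(i + 1L)
    if (v >= 32768L) v - 65536L else v
  }
  f32 <- function(i) readBin(raw[i:(i + 3L)], "double", size = 4L,
                             endian = "little")
  if (u8(2L) != 0x50) stop("corrupt C3D (magic byte): ", path, call. = FALSE)
  param_block <- u8(1L)
  n_points <- i16(3L)
  analog_per_frame <- i16(5L)          # channels * subframes
  first_frame <- i16(7L)
  last_frame <- i16(9L)
  point_scale <- f32(13L)
  data_block <- i16(17L)
  analog_subframes <- i16(19L)
  point_rate <- f32(21L)
  n_frames <- last_frame - first_frame + 1L

  ## ---- parameter section ----
  p0 <- (param_block - 1L) * 512L + 1L
  proc <- u8(p0 + 3L)
  if (proc != 84L) {
    stop("unsupported C3D processor type ", proc,
         " (only Intel/84 is handled)", call. = FALSE)
  }
  params <- list()
  pos <- p0 + 4L
  repeat {
    nchar_name <- u8(pos)
    if (nchar_name > 127L) nchar_name <- nchar_name - 256L  # locked flag
    nl <- abs(nchar_name)
    gid <- u8(pos + 1L); if (gid > 127L) gid <- gid - 256L
    if (nl == 0L) break
    nm <- rawToChar(raw[(pos + 2L):(pos + 1L + nl)])
    off_at <- pos + 2L + nl
    nxt <- i16(off_at)
    if (gid < 0L) {
      ## group record
      params[[as.character(-gid)]] <- params[[as.character(-gid)]] %||%
        list(name = nm, params = list())
      params[[as.character(-gid)]]$name <- nm
    } else if (gid > 0L) {
      dt <- u8(off_at + 2L); if (dt > 127L) dt <- dt - 256L
      nd <- u8(off_at + 3L)
      dims <- if (nd > 0L) vapply(seq_len(nd), function(k)
        u8(off_at + 3L + k), 1L) else integer(0)
      dstart <- off_at + 4L + nd
      count <- if (length(dims)) prod(dims) else 1L
      val <- tryCatch({
        if (dt == -1L) {
          ch <- rawToChar(raw[dstart:(dstart + count - 1L)])
          if (length(dims) >= 2L) {
            ## char matrix: first dim is string length
            substring(ch, seq(1L, count, by = dims[1L]),
                      seq(dims[1L], count, by = dims[1L]))
          } else ch
        } else if (dt == 1L) {
          vapply(seq_len(count), function(k) u8(dstart + k - 1L), 1L)
        } else if (dt == 2L) {
          vapply(seq_len(count), function(k) i16(dstart + 2L * (k - 1L)),
                 1L)
        } else if (dt == 4L) {
          vapply(seq_len(count), function(k) f32(dstart + 4L * (k - 1L)),
                 1)
        } else {
          warning("skipping C3D parameter '", nm, "' with unknown type ",
                  dt, call. = FALSE)
          NULL
        }
      }, error = function(e) NULL)
      g <- as.character(gid)
      params[[g]] <- params[[g]] %||% list(name = paste0("G", gid),
                                           params = list())
      params[[g]]$params[[nm]] <- val
    }
    if (nxt == 0L) break
    pos <- off_at + nxt
    if (pos > length(raw)) break
  }
  by_group <- function(gname) {
    for (g in params) if (identical(g$name, gname)) return(g$params)
    list()
  }
  point_par <- by_group("POINT")
  analog_par <- by_group("ANALOG")
  labels <- trimws(point_par$LABELS %||% paste0("M", seq_len(n_points)))
  labels <- labels[seq_len(min(n_points, length(labels)))]
  units <- tolower(trimws((point_par$UNITS %||% "mm")[1L]))
  scale_to_m <- if (units == "mm") 1e-3 else 1
  analog_labels <- trimws(analog_par$LABELS %||% character(0))
  n_analog <- if (analog_subframes > 0L) {
    analog_per_frame %/% max(analog_subframes, 1L)
  } else 0L
  analog_rate <- as.numeric((analog_par$RATE %||%
                               (point_rate * max(analog_subframes, 1L)))[1L])

  ## ---- data section (float only) ----
  if (point_scale >= 0) {
    stop("integer-format C3D point data not supported (POINT:SCALE >= 0)",
         call. = FALSE)
  }
  d0 <- (data_block - 1L) * 512L + 1L
  words_per_frame <- 4L * n_points + analog_per_frame
  need <- d0 + 4L * words_per_frame * n_frames - 1L
  if (need > length(raw)) stop("corrupt C3D (truncated data section): ",
                               path, call. = FALSE)
  all_f <- readBin(raw[d0:need], "double", size = 4L,
                   n = words_per_frame * n_frames, endian = "little")
  frame_mat <- matrix(all_f, nrow = words_per_frame)
  mk <- list()
  for (i in seq_len(n_points)) {
    rows <- (4L * (i - 1L) + 1L):(4L * (i - 1L) + 3L)
    m <- t(frame_mat[rows, , drop = FALSE]) * scale_to_m
    resid <- frame_mat[4L * i, ]
    m[resid < 0, ] <- NA_real_         # negative residual = invalid sample
    mk[[labels[i]]] <- m
  }
  time <- (seq_len(n_frames) - 1L) / point_rate
  analog <- NULL
  if (n_analog > 0L) {
    arow0 <- 4L * n_points
    avals <- frame_mat[(arow0 + 1L):words_per_frame, , drop = FALSE]
    ## subframe-major within each frame: channels vary fastest
    amat <- matrix(as.numeric(avals), ncol = n_analog, byrow = TRUE)
    if (length(analog_labels) >= n_analog) {
      colnames(amat) <- analog_labels[seq_len(n_analog)]
    } else {
      colnames(amat) <- paste0("A", seq_len(n_analog))
    }
    analog <- as.data.frame(amat)
  }
  list(markers = marker_set(time, mk, rate = point_rate),
       analog = analog, analog_rate = analog_rate,
       point_rate = point_rate)
}

#' Write a minimal C3D file
#'
#' Floating-point Intel dialect with a POINT group (and an ANALOG group when
#' channels are supplied). Mainly used to build test fixtures in code.
#'
#' @param markers a `cd_markers` (positions in metres; written as mm).
#' @param path output path.
#' @param analog optional data.frame of analog channels sampled at
#'   `analog_subframes` times the point rate.
#' @param analog_subframes analog samples per 3D frame.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(markers, path, analog = NULL, analog_subframes = 1L) {
  stopifnot(inherits(markers, "cd_markers"))
  nmk <- length(markers$markers)
  n <- length(markers$time)
  rate <- markers$rate
  n_analog <- if (is.null(analog)) 0L else ncol(analog)
  if (n_analog > 0L && nrow(analog) != n * analog_subframes) {
    stop("analog rows must equal frames * analog_subframes", call. = FALSE)
  }
  analog_per_frame <- n_analog * analog_subframes

  i16r <- function(v) writeBin(as.integer(v), con2, size = 2L,
                               endian = "little")
  u8r <- function(v) writeBin(as.integer(v), con2, size = 1L)
  f32r <- function(v) writeBin(as.numeric(v), con2, size = 4L,
                               endian = "little")

  ## ---- parameter section in memory first (to know its block count) ----
  par_con <- rawConnection(raw(0), "wb")
  wpar <- function(con2, expr) expr
  con2 <- par_con
  u8r(c(1L, 80L, 0L, 84L))             # part1, magic, nblocks (patched), Intel
  put_group <- function(id, name, desc = "") {
    u8r(nchar(name)); u8r(256L - id)   # negative id as unsigned byte
    writeBin(charToRaw(name), con2)
    i16r(3L + nchar(desc))             # offset to next record
    u8r(nchar(desc))
    if (nchar(desc)) writeBin(charToRaw(desc), con2)
  }
  put_param <- function(gid, name, value, type, dims) {
    u8r(nchar(name)); u8r(gid)
    writeBin(charToRaw(name), con2)
    sz <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[[as.character(type)]]
    count <- if (length(dims)) prod(dims) else 1L
    i16r(2L + 1L + 1L + length(dims) + sz * count + 1L)
    u8r(if (type < 0) 256L + type else type)
    u8r(length(dims))
    for (d in dims) u8r(d)
    if (type == -1L) {
      writeBin(charToRaw(paste(value, collapse = "")), con2)
    } else if (type == 2L) {
      i16r(value)
    } else if (type == 4L) {
      f32r(value)
    } else {
      u8r(value)
    }
    u8r(0L)                            # empty description
  }
  labels <- names(markers$markers)
  lab_w <- max(4L, max(nchar(labels)))
  lab_pad <- formatC(labels, width = lab_w, flag = "-")
  put_group(1L, "POINT")
  put_param(1L, "USED", nmk, 2L, integer(0))
  put_param(1L, "FRAMES", n, 2L, integer(0))
  put_param(1L, "SCALE", -1.0, 4L, integer(0))
  put_param(1L, "RATE", rate, 4L, integer(0))
  put_param(1L, "UNITS", "mm", -1L, 2L)
  put_param(1L, "LABELS", lab_pad, -1L, c(lab_w, nmk))
  put_group(2L, "ANALOG")
  put_param(2L, "USED", n_analog, 2L, integer(0))
  put_param(2L, "RATE", rate * analog_subframes, 4L, integer(0))
  if (n_analog > 0L) {
    alab <- colnames(analog)
    aw <- max(4L, max(nchar(alab)))
    put_param(2L, "LABELS", formatC(alab, width = aw, flag = "-"), -1L,
              c(aw, n_analog))
  }
  ## terminator record: nchar=0 via final param's next offset 0 is implied;
  ## write an explicit zero-length record
  u8r(c(0L, 0L))
  par_raw <- rawConnectionValue(par_con)
  close(par_con)
  n_par_blocks <- ceiling(length(par_raw) / 512)
  par_raw[3L] <- as.raw(n_par_blocks)
  length(par_raw) <- 512L * n_par_blocks
  data_block <- 2L + n_par_blocks

  con2 <- file(path, "wb")
  on.exit(close(con2))
  ## ---- header block ----
  u8r(c(2L, 80L))                      # parameter section at block 2
  i16r(nmk)
  i16r(analog_per_frame)
  i16r(1L); i16r(n)                    # first/last frame
  i16r(0L)                             # max gap
  f32r(-1.0)                           # POINT:SCALE (float data)
  i16r(data_block)
  i16r(analog_subframes)
  f32r(rate)
  writeBin(raw(512L - 24L), con2)      # pad header block
  writeBin(par_raw, con2)
  ## ---- data ----
  for (r in seq_len(n)) {
    for (i in seq_len(nmk)) {
      p <- markers$markers[[i]][r, ] * 1e3
      if (anyNA(p)) {
        f32r(c(0, 0, 0, -1))
      } else {
        f32r(c(p, 0))
      }
    }
    if (n_analog > 0L) {
      rows <- ((r - 1L) * analog_subframes + 1L):(r * analog_subframes)
      f32r(as.numeric(t(as.matrix(analog[rows, , drop = FALSE]))))
    }
  }
  invisible(path)
}
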