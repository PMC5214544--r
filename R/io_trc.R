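## TRC marker trajectory files: tab-delimited, coordinates in millimetres
## on disk (the de-facto dialect), metres in memory. Occlusions are empty
## fields or NaN on disk, NA in memory.

#' Read a TRC marker file
#'
#' @param path file path.
#' @return a `cd_markers` (see [marker_set()]); positions in metres.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L) {
    stop("malformed TRC file (fewer than 5 lines): ", path, call. = FALSE)
  }
  if (!grepl("^PathFileType", lines[1L])) {
    stop("malformed TRC header at line 1 (expected PathFileType): ", path,
         call. = FALSE)
  }
  keys <- strsplit(lines[2L], "\t")[[1L]]
  vals <- strsplit(lines[3L], "\t")[[1L]]
  meta <- stats::setNames(as.list(vals), keys)
  rate <- as.numeric(meta$DataRate %||% NA)
  n_frames <- as.integer(meta$NumFrames %||% NA)
  n_markers <- as.integer(meta$NumMarkers %||% NA)
  units <- as.character(meta$Units %||% "mm")
  if (is.na(rate) || is.na(n_markers)) {
    stop("malformed TRC header at line 2/3 (DataRate/NumMarkers): ", path,
         call. = FALSE)
  }
  head4 <- strsplit(lines[4L], "\t")[[1L]]
  marker_names <- head4[-(1:2)]
  marker_names <- marker_names[nzchar(marker_names)]
  if (length(marker_names) != n_markers) {
    stop("TRC NumMarkers (", n_markers, ") does not match marker columns (",
         length(marker_names), ") at line 4: ", path, call. = FALSE)
  }
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  ncol_expect <- 2L + 3L * n_markers
  cells <- lapply(strsplit(body, "\t"), function(x) {
    length(x) <- ncol_expect
    suppressWarnings(as.numeric(x))
  })
  dat <- do.call(rbind, cells)
  if (!is.na(n_frames) && nrow(dat) != n_frames) {
    stop("TRC NumFrames (", n_frames, ") does not match data rows (",
         nrow(dat), "): ", path, call. = FALSE)
  }
  scale <- if (tolower(units) == "mm") 1e-3 else 1
  time <- dat[, 2L]
  mk <- list()
  for (i in seq_len(n_markers)) {
    mk[[marker_names[i]]] <- dat[, 2L + (3L * (i - 1L) + 1L):(3L * i),
                                 drop = FALSE] * scale
  }
  marker_set(time, mk, rate = rate)
}

#' Write a TRC marker file
#'
#' Positions are written in millimetres; NA samples become empty fields.
#' Round trip with [read_trc()] is lossless to well below 1e-9 mm.
#'
#' @param markers a `cd_markers`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path) {
  stopifnot(inherits(markers, "cd_markers"))
  nmk <- length(markers$markers)
  n <- length(markers$time)
  rate <- markers$rate
  nm <- names(markers$markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PathFileType", "4", "(X/Y/Z)", basename(path),
                   sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(fmt_num(rate), fmt_num(rate), n, nmk, "mm",
                   fmt_num(rate), 1L, n, sep = "\t"), con)
  lab <- c("Frame#", "Time",
           unlist(lapply(nm, function(x) c(x, "", ""))))
  writeLines(paste(lab, collapse = "\t"), con)
  sub <- c("", "", unlist(lapply(seq_len(nmk), function(i)
    paste0(c("X", "Y", "Z"), i))))
  writeLines(paste(sub, collapse = "\t"), con)
  for (r in seq_len(n)) {
    vals <- unlist(lapply(markers$markers, function(m) m[r, ] * 1e3))
    cells <- ifelse(is.na(vals), "", fmt_num(vals))
    writeLines(paste(c(r, fmt_num(markers$time[r]), cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

fmt_num <- function(x) {
  formatC(x, format = "g", digits = 15)
}
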