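## STO / MOT time-series tables: header through `endheader`, tab-delimited
## numeric block, first column time. Angles may be stored in degrees
## (`inDegrees=yes`); in memory everything is SI radians.

#' Read an STO/MOT time-series table
#'
#' Honours `nRows`/`nColumns` (and the `datarows`/`datacolumns` dialect) and
#' the `inDegrees` flag: when the file is in degrees all non-time columns
#' are converted to radians in memory and the flag is remembered for
#' write-back.
#'
#' @param path file path.
#' @param columns optional character vector: return (and order) only these
#'   columns (plus time).
#' @return data.frame of class `cd_timeseries` with a `time` column;
#'   attributes `in_degrees`, `name`.
#' @export
read_sto_mot <- function(path, columns = NULL) {
  lines <- readLines(path, warn = FALSE)
  endh <- grep("^\\s*endheader\\s*$", lines)
  if (!length(endh)) {
    stop("malformed STO/MOT header: no 'endheader' line in ", path,
         call. = FALSE)
  }
  endh <- endh[1L]
  header <- lines[seq_len(endh - 1L)]
  getval <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*="), header, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1L]))
  }
  n_rows <- as.integer(getval("nRows") %||% getval("datarows") %||% NA)
  n_cols <- as.integer(getval("nColumns") %||% getval("datacolumns") %||% NA)
  in_deg <- tolower(getval("inDegrees") %||% "no") %in% c("yes", "true")
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  cn <- strsplit(trimws(body[1L]), "[\t ]+")[[1L]]
  dat <- utils::read.table(text = paste(body[-1L], collapse = "\n"),
                           col.names = cn, check.names = FALSE)
  if (!is.na(n_rows) && nrow(dat) != n_rows) {
    stop("STO/MOT nRows (", n_rows, ") does not match data rows (",
         nrow(dat), ") in ", path, call. = FALSE)
  }
  if (!is.na(n_cols) && ncol(dat) != n_cols) {
    stop("STO/MOT nColumns (", n_cols, ") does not match data columns (",
         ncol(dat), ") in ", path, call. = FALSE)
  }
  names(dat)[1L] <- "time"
  if (in_deg) {
    for (k in 2:ncol(dat)) dat[[k]] <- deg2rad(dat[[k]])
  }
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(dat))
    if (length(missing)) {
      stop("requested column(s) absent: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    dat <- dat[, c("time", setdiff(columns, "time")), drop = FALSE]
  }
  attr(dat, "in_degrees") <- in_deg
  attr(dat, "name") <- sub("\\.[^.]*$", "", basename(path))
  class(dat) <- c("cd_timeseries", class(dat))
  dat
}

#' Write an STO/MOT time-series table
#'
#' @param table data.frame with a `time` first column (radians internally).
#' @param path output path.
#' @param in_degrees write angle columns in degrees (default: the table's
#'   `in_degrees` attribute, else FALSE).
#' @param name header name line (default from the table or the file name).
#' @return `path`, invisibly.
#' @export
write_sto_mot <- function(table, path, in_degrees = NULL, name = NULL) {
  stopifnot(names(table)[1L] == "time")
  if (is.null(in_degrees)) {
    in_degrees <- isTRUE(attr(table, "in_degrees"))
  }
  if (is.null(name)) {
    name <- attr(table, "name", exact = TRUE) %||%
      sub("\\.[^.]*$", "", basename(path))
  }
  out <- as.data.frame(table)
  if (in_degrees) {
    for (k in 2:ncol(out)) out[[k]] <- rad2deg(out[[k]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               paste0("nRows=", nrow(out)),
               paste0("nColumns=", ncol(out)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(out), collapse = "\t")), con)
  utils::write.table(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export a coordinate trajectory as an STO table
#'
#' Column names follow the `<joint>/<coordinate>` convention.
#'
#' @param am a `cd_assembled`.
#' @param traj data.frame `time` + coordinate columns (radians).
#' @param path output path.
#' @param in_degrees write in degrees. The `inDegrees` flag applies to every
#'   data column, so the default (FALSE, SI units) is recommended for
#'   mixed rotational/translational coordinate sets.
#' @return `path`, invisibly.
#' @export
write_coordinates_sto <- function(am, traj, path, in_degrees = FALSE) {
  cols <- intersect(colnames(traj), am$coords$name)
  out <- data.frame(time = traj$time)
  for (nm in cols) {
    ji <- am$coords$joint[am$coord_index[[nm]]]
    out[[paste0(ji, "/", nm)]] <- traj[[nm]]
  }
  attr(out, "in_degrees") <- in_degrees
  write_sto_mot(out, path, in_degrees = in_degrees, name = am$name)
}
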