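# Minimal FCS 3.0 list-mode support: single dataset, float data, little- or
# big-endian. Covers the interchange need of this package (synthetic events
# in/out); instrument files with analysis segments or integer data should be
# exported to CSV upstream.

fcs_pad <- function(x, width) formatC(x, width = width, flag = " ")

#' Write events to an FCS 3.0 file
#'
#' Float (single-precision) list-mode data, little-endian, one dataset.
#' Only numeric marker columns are written; metadata columns are dropped.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @param markers Columns to write; autodetected numeric markers by default.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, markers = NULL) {
  markers <- markers %||% event_marker_cols(events)
  m <- as.matrix(events[markers])
  storage.mode(m) <- "double"
  n <- nrow(m); p <- ncol(m)
  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p))
  for (j in seq_len(p)) {
    kw[sprintf("$P%dN", j)] <- markers[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- format(ceiling(max(abs(m[, j]), 1)) * 2,
                                      scientific = FALSE)
  }
  # fixed-width data offsets so the TEXT length is independent of the values
  build_text <- function(b, e) {
    paste0("/", paste0(c(rbind(c("$BEGINDATA", "$ENDDATA", names(kw)),
                               c(sprintf("%010d", b), sprintf("%010d", e), kw))),
                       collapse = "/"), "/")
  }
  text_start <- 58L
  text <- build_text(0, 0)
  data_start <- text_start + nchar(text)
  data_end <- data_start + 4L * n * p - 1L
  text <- build_text(data_start, data_end)
  header <- paste0("FCS3.0    ",
                   fcs_pad(text_start, 8), fcs_pad(text_start + nchar(text) - 1L, 8),
                   fcs_pad(data_start, 8), fcs_pad(data_end, 8),
                   fcs_pad(0, 8), fcs_pad(0, 8))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0 file
#'
#' Supports float/double list-mode data in the first dataset.
#'
#' @param path FCS file path.
#' @return Event tibble with one column per parameter (`$PnN` names).
#' @export
read_fcs <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 58) {
    stop("not a parseable FCS file (too short): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!startsWith(header, "FCS")) {
    stop("missing FCS magic in header of ", path, call. = FALSE)
  }
  off <- suppressWarnings(as.integer(trimws(substring(
    header, seq(11, 51, by = 8), seq(18, 58, by = 8)))))
  if (anyNA(off[1:2])) stop("malformed FCS header offsets in ", path, call. = FALSE)
  seek(con, off[1])
  text <- readChar(con, off[2] - off[1] + 1L, useBytes = TRUE)
  delim <- substring(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("malformed FCS TEXT segment in ", path, call. = FALSE)
  kw <- setNames(parts[seq(2, length(parts), by = 2)],
                 toupper(parts[seq(1, length(parts), by = 2)]))
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  dtype <- toupper(kw[["$DATATYPE"]] %||% "F")
  if (!dtype %in% c("F", "D")) {
    stop("unsupported FCS $DATATYPE `", dtype, "`", call. = FALSE)
  }
  endian <- if (startsWith(kw[["$BYTEORD"]] %||% "1,2,3,4", "1")) "little" else "big"
  data_start <- off[3]
  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
  }
  seek(con, data_start)
  size <- if (dtype == "F") 4L else 8L
  vals <- readBin(con, "double", n = n * p, size = size, endian = endian)
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(m) <- vapply(seq_len(p), function(j) {
    kw[[sprintf("$P%dN", j)]] %||% sprintf("P%d", j)
  }, character(1))
  tibble::as_tibble(m)
}

#' Read an event matrix from CSV or FCS
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @param channel_map Optional named character vector renaming file channels
#'   to panel markers (`c(file_channel = "Marker")`); unmapped channels are
#'   retained as-is.
#' @return Event tibble.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        channel_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (file.info(path)$size == 0) stop("empty file: ", path, call. = FALSE)
  out <- if (format == "fcs") {
    read_fcs(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!nrow(out) || !ncol(out)) stop("no events parsed from ", path, call. = FALSE)
  if (!is.null(channel_map)) {
    hit <- names(out) %in% names(channel_map)
    names(out)[hit] <- channel_map[names(out)[hit]]
  }
  out
}

#' Write an event matrix to CSV or FCS
#' @param events Event tibble.
#' @param path Output path (`.fcs` triggers FCS 3.0 output).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    write_fcs(events, path)
  } else {
    readr::write_csv(events, path, progress = FALSE)
  }
  invisible(path)
}
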