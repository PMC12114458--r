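# FCS 3.0/3.1 list-mode and CSV event-table I/O.
#
# The FCS writer emits FCS 3.1 with a single dataset: float32 list-mode data
# ($DATATYPE=F, $MODE=L, $BYTEORD=1,2,3,4). The reader accepts FCS 3.0 and
# 3.1, float or double data, either byte order, and widens integer data
# ($DATATYPE=I, 16/32-bit) to double. $VOL is interpreted as nanolitres, the
# common volumetric-counter convention. No multi-dataset files, no
# $SPILLOVER parsing and no $PnE log-amplifier decoding: compensation is an
# explicit step downstream and modern small-particle data are acquired
# linearly.

FCS_DELIM <- "/"

#' Read flow-cytometry events from an FCS or CSV file
#'
#' @param path path to an existing file.
#' @param dialect `"fcs"` or `"csv"`; by default inferred from the file
#'   extension (`.fcs` vs anything else).
#' @param acquisition fallback [acquisition_meta()] used for fields absent
#'   from the file and its sidecar.
#' @return an [event_table()].
#' @details For CSV, the header row carries channel names and an optional
#'   JSON sidecar at `<path>.meta.json` supplies
#'   `flow_rate_ul_per_min`, `volume_ul`, `duration_s` and `sample_id`.
#' @export
read_events <- function(path, dialect = NULL, acquisition = acquisition_meta()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  dialect <- match.arg(dialect, c("fcs", "csv"))
  if (dialect == "fcs") read_fcs(path, acquisition) else read_csv_events(path, acquisition)
}

#' Write flow-cytometry events to an FCS or CSV file
#'
#' @param table an [event_table()].
#' @param path output path.
#' @param dialect `"fcs"` or `"csv"`; inferred from the extension by default.
#' @return the path, invisibly.
#' @export
write_events <- function(table, path, dialect = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  dialect <- match.arg(dialect, c("fcs", "csv"))
  if (dialect == "fcs") write_fcs(table, path) else write_csv_events(table, path)
  invisible(path)
}

# ---- CSV dialect -----------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta.json")

read_csv_events <- function(path, acquisition) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  acq <- acquisition_meta(
    flow_rate_ul_per_min = meta$flow_rate_ul_per_min %||% acquisition$flow_rate_ul_per_min,
    volume_ul = meta$volume_ul %||% acquisition$volume_ul,
    duration_s = meta$duration_s %||% NULL)
  event_table(as.matrix(df), channel_names = names(df), acquisition = acq,
              sample_id = meta$sample_id %||% "")
}

write_csv_events <- function(table, path) {
  utils::write.csv(as.data.frame(table$events), path, row.names = FALSE)
  meta <- list(flow_rate_ul_per_min = table$acquisition$flow_rate_ul_per_min,
               volume_ul = table$acquisition$volume_ul,
               duration_s = table$acquisition$duration_s,
               sample_id = table$sample_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- FCS dialect -----------------------------------------------------------

write_fcs <- function(table, path) {
  ev <- table$events
  n <- nrow(ev); p <- ncol(ev)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$NEXTDATA" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$TOT" = as.character(n), "$PAR" = as.character(p),
          "$FIL" = if (nzchar(table$sample_id)) table$sample_id else basename(path),
          "$VOL" = format(table$acquisition$volume_ul * 1000),  # nL
          "FLOWRATE" = format(table$acquisition$flow_rate_ul_per_min),
          "DURATION" = format(table$acquisition$duration_s))
  for (i in seq_len(p)) {
    kw[[sprintf("$P%dN", i)]] <- table$channel_names[i]
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- format(max(262144, 2^ceiling(log2(max(ev[, i], 1) + 1))))
  }
  # offsets: header is 58 bytes; BEGINDATA/ENDDATA written fixed-width so the
  # text length does not depend on their values
  pack <- function(keys) {
    paste0(FCS_DELIM,
           paste0(names(keys), FCS_DELIM, unname(keys), FCS_DELIM, collapse = ""))
  }
  base_text <- pack(c(kw, "$BEGINDATA" = sprintf("%010d", 0),
                      "$ENDDATA" = sprintf("%010d", 0)))
  text_start <- 58L
  text_end <- text_start + nchar(base_text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_len <- 4L * n * p
  data_end <- if (data_len > 0) data_start + data_len - 1L else 0L
  text <- pack(c(kw, "$BEGINDATA" = sprintf("%010d", data_start),
                 "$ENDDATA" = sprintf("%010d", data_end)))
  stopifnot(nchar(text, type = "bytes") == nchar(base_text, type = "bytes"))
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 text_start, text_end,
                 if (data_len > 0) data_start else 0L, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (data_len > 0) {
    writeBin(as.vector(t(ev)), con, size = 4, endian = "little")
  }
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

read_fcs <- function(path, acquisition) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 58, useBytes = TRUE)
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' (FCS 3.0/3.1 supported)",
         call. = FALSE)
  }
  off <- suppressWarnings(as.integer(substring(hdr,
                                               seq(11, by = 8, length.out = 6),
                                               seq(18, by = 8, length.out = 6))))
  if (any(is.na(off[1:2]))) stop("malformed FCS header offsets", call. = FALSE)
  seek(con, off[1])
  kw <- parse_fcs_text(readBin(con, "raw", off[2] - off[1] + 1))
  need <- function(name) {
    v <- kw[[name]]
    if (is.null(v)) stop("FCS file missing required keyword ", name, call. = FALSE)
    v
  }
  n <- as.integer(need("$TOT"))
  p <- as.integer(need("$PAR"))
  chans <- vapply(seq_len(p), function(i) need(sprintf("$P%dN", i)), character(1))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  data_start <- off[3]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.integer(need("$BEGINDATA"))
  }
  ev <- matrix(numeric(0), nrow = 0, ncol = p)
  if (n > 0) {
    seek(con, data_start)
    vals <- switch(dtype,
      F = readBin(con, "numeric", n = n * p, size = 4, endian = endian),
      D = readBin(con, "numeric", n = n * p, size = 8, endian = endian),
      I = {
        bits <- as.integer(kw[["$P1B"]] %||% "32")
        readBin(con, "integer", n = n * p, size = bits / 8,
                endian = endian, signed = bits > 16)
      },
      stop("unsupported $DATATYPE ", dtype, call. = FALSE))
    if (length(vals) != n * p) stop("truncated FCS data segment", call. = FALSE)
    ev <- matrix(as.double(vals), nrow = n, ncol = p, byrow = TRUE)
  }
  vol_ul <- if (!is.null(kw[["$VOL"]])) as.numeric(kw[["$VOL"]]) / 1000 else acquisition$volume_ul
  flow <- if (!is.null(kw[["FLOWRATE"]])) as.numeric(kw[["FLOWRATE"]]) else acquisition$flow_rate_ul_per_min
  dur <- if (!is.null(kw[["DURATION"]])) as.numeric(kw[["DURATION"]]) else NULL
  event_table(ev, channel_names = chans,
              acquisition = acquisition_meta(flow, vol_ul, dur),
              sample_id = kw[["$FIL"]] %||% "")
}
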