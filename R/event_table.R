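# Event-table container: an n_events x n_channels matrix of non-negative
# pulse intensities plus acquisition metadata. Channel naming follows the
# blue-laser small-particle convention: FSC/SSC scatter and FL1 (533/30,
# SYTO9) / FL3 (>670, PI) fluorescence, each as pulse height (-H) and
# area (-A).

CANONICAL_CHANNELS <- c("FSC-H", "FSC-A", "SSC-H", "SSC-A",
                        "FL1-H", "FL1-A", "FL3-H", "FL3-A", "TIME")

# alias -> canonical; covers the usual exports (dots/underscores, long forms)
.channel_alias <- function(x) {
  key <- toupper(gsub("[._]", "-", trimws(x)))
  key <- sub("-HEIGHT$", "-H", key)
  key <- sub("-AREA$", "-A", key)
  key
}

#' Canonicalize flow-cytometry channel names
#'
#' Maps common channel-name spellings (dots or underscores for dashes,
#' `-Height`/`-Area` long forms, any case) onto the canonical
#' `FSC-H`, `FSC-A`, `SSC-H`, `SSC-A`, `FL1-H`, `FL1-A`, `FL3-H`, `FL3-A`
#' set used throughout the package.
#'
#' @param x character vector of channel names.
#' @return character vector of canonical names.
#' @export
canonical_channel <- function(x) {
  out <- .channel_alias(x)
  bad <- !(out %in% CANONICAL_CHANNELS)
  if (any(bad)) {
    stop("unknown channel name(s): ", paste(unique(x[bad]), collapse = ", "),
         "; accepted names/aliases map onto: ",
         paste(CANONICAL_CHANNELS, collapse = ", "), call. = FALSE)
  }
  out
}

#' Acquisition metadata
#'
#' Flow rate, acquired volume and acquisition duration for one sample.
#' When `duration_s` is missing it is derived as
#' `60 * volume_ul / flow_rate_ul_per_min`. When all three are supplied they
#' must be mutually consistent within 1%. Defaults mirror a typical
#' small-particle protocol on a volumetric bench cytometer: 35 uL/min,
#' 25 uL acquired.
#'
#' @param flow_rate_ul_per_min flow rate in microlitres per minute (> 0).
#' @param volume_ul acquired volume in microlitres (> 0).
#' @param duration_s acquisition duration in seconds, or `NULL` to derive it.
#' @return an object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(flow_rate_ul_per_min = 35, volume_ul = 25,
                             duration_s = NULL) {
  stopifnot(is.numeric(flow_rate_ul_per_min), flow_rate_ul_per_min > 0,
            is.numeric(volume_ul), volume_ul > 0)
  derived <- 60 * volume_ul / flow_rate_ul_per_min
  if (is.null(duration_s)) {
    duration_s <- derived
  } else {
    stopifnot(is.numeric(duration_s), duration_s > 0)
    if (abs(duration_s - derived) > 0.01 * derived) {
      stop(sprintf(
        "duration_s (%.3f) inconsistent with volume/flow rate (%.3f s) beyond 1%%",
        duration_s, derived), call. = FALSE)
    }
  }
  structure(list(flow_rate_ul_per_min = flow_rate_ul_per_min,
                 volume_ul = volume_ul,
                 duration_s = duration_s),
            class = "acquisition_meta")
}

#' Construct an event table
#'
#' @param events numeric matrix, events in rows, channels in columns. All
#'   intensities must be finite and non-negative.
#' @param channel_names channel names (canonicalized); defaults to the
#'   matrix column names.
#' @param acquisition an [acquisition_meta()] object.
#' @param sample_id sample identifier string.
#' @return an object of class `event_table`.
#' @export
event_table <- function(events, channel_names = colnames(events),
                        acquisition = acquisition_meta(), sample_id = "") {
  if (is.data.frame(events)) events <- as.matrix(events)
  if (is.null(dim(events))) events <- matrix(events, nrow = 0,
                                             ncol = length(channel_names))
  storage.mode(events) <- "double"
  if (is.null(channel_names)) {
    stop("channel names are required", call. = FALSE)
  }
  channel_names <- canonical_channel(channel_names)
  if (anyDuplicated(channel_names)) {
    stop("duplicate channel names", call. = FALSE)
  }
  if (length(channel_names) != ncol(events)) {
    stop("channel_names length must equal the number of event columns",
         call. = FALSE)
  }
  if (nrow(events) > 0 && (any(!is.finite(events)) || any(events < 0))) {
    stop("event intensities must be finite and non-negative", call. = FALSE)
  }
  colnames(events) <- channel_names
  rownames(events) <- NULL
  stopifnot(inherits(acquisition, "acquisition_meta"))
  structure(list(events = events,
                 channel_names = channel_names,
                 acquisition = acquisition,
                 sample_id = as.character(sample_id)),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s: %d events x %d channels (%s)\n",
              if (nzchar(x$sample_id)) x$sample_id else "<unnamed>",
              nrow(x$events), ncol(x$events),
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  acquisition: %.1f uL at %.1f uL/min (%.1f s)\n",
              x$acquisition$volume_ul, x$acquisition$flow_rate_ul_per_min,
              x$acquisition$duration_s))
  invisible(x)
}

#' Number of events in an event table
#' @param table an `event_table`.
#' @return integer event count.
#' @export
n_events <- function(table) nrow(table$events)

# internal: fetch one channel column, with a clear error
channel_values <- function(table, channel) {
  channel <- canonical_channel(channel)
  if (!channel %in% table$channel_names) {
    stop("channel ", channel, " not present (have: ",
         paste(table$channel_names, collapse = ", "), ")", call. = FALSE)
  }
  table$events[, channel]
}

#' Subset an event table by row
#'
#' Keeps the selected events, preserving acquisition metadata and any
#' per-event `truth` annotations carried by synthetic tables.
#'
#' @param table an `event_table`.
#' @param keep logical or integer row index.
#' @return the subset `event_table`.
#' @export
subset_events <- function(table, keep) {
  truth <- attr(table, "truth")
  out <- table
  out$events <- table$events[keep, , drop = FALSE]
  if (!is.null(truth)) {
    attr(out, "truth") <- lapply(truth, function(v) {
      if (length(v) == nrow(table$events)) v[keep] else v
    })
  }
  out
}
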