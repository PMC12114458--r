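# Gating: log-scale transform, hardware-style FSC-H thresholding, pulse
# area/height doublet exclusion, SYTO9 back-gated density gate construction,
# and gate application. The pipeline order is threshold -> doublet
# exclusion -> bacteria gate; each step only removes events.

#' Gating configuration
#'
#' @param fsc_h_threshold hardware-style FSC-H threshold (events with lower
#'   FSC-H are dropped; the comparison keeps events at exactly the
#'   threshold). Default 1000, the control-data-derived setting that retains
#'   all bacterial events while suppressing background.
#' @param doublet_channels area/height channel pair for doublet
#'   discrimination (default `SSC-A` vs `SSC-H`).
#' @param doublet_ratio_k robust-outlier multiplier: events with
#'   area/height ratio above `median + k * MAD` are doublets.
#' @param syto9_channel channel carrying SYTO9 fluorescence.
#' @param syto9_cut_quantile quantile of the unstained control defining the
#'   SYTO9-positive cut.
#' @param syto9_abs_cut absolute fallback intensity cut when no unstained
#'   control is available.
#' @param density_mass fraction of SYTO9-positive events the density gate
#'   must cover, in (0, 1\].
#' @param transform_floor floor applied before log10 (intensities below it
#'   map to `log10(floor)`).
#' @param grid_bins histogram resolution per axis for density-gate
#'   construction.
#' @return object of class `gating_config`.
#' @export
gating_config <- function(fsc_h_threshold = 1000,
                          doublet_channels = c("SSC-A", "SSC-H"),
                          doublet_ratio_k = 3.0,
                          syto9_channel = "FL1-H",
                          syto9_cut_quantile = 0.995,
                          syto9_abs_cut = 1000,
                          density_mass = 0.98,
                          transform_floor = 1,
                          grid_bins = 64) {
  stopifnot(fsc_h_threshold >= 0, length(doublet_channels) == 2,
            doublet_ratio_k > 0, syto9_cut_quantile > 0, syto9_cut_quantile < 1,
            density_mass > 0, density_mass <= 1, transform_floor > 0,
            grid_bins >= 8)
  structure(list(fsc_h_threshold = fsc_h_threshold,
                 doublet_channels = canonical_channel(doublet_channels),
                 doublet_ratio_k = doublet_ratio_k,
                 syto9_channel = canonical_channel(syto9_channel),
                 syto9_cut_quantile = syto9_cut_quantile,
                 syto9_abs_cut = syto9_abs_cut,
                 density_mass = density_mass,
                 transform_floor = transform_floor,
                 grid_bins = as.integer(grid_bins)),
            class = "gating_config")
}

#' Floored log10 transform of selected channels
#'
#' Replaces each named channel by `log10(max(value, floor))`; other
#' channels are untouched. This is the plain log display scale; no
#' logicle/biexponential parameters are introduced.
#'
#' @param table an [event_table()].
#' @param channels channels to transform.
#' @param floor positive floor.
#' @return transformed [event_table()].
#' @export
transform_log <- function(table, channels, floor = 1) {
  stopifnot(inherits(table, "event_table"), floor > 0)
  channels <- canonical_channel(channels)
  missing <- setdiff(channels, table$channel_names)
  if (length(missing)) stop("missing channel(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  out <- table
  for (ch in channels) {
    out$events[, ch] <- log10(pmax(table$events[, ch], floor))
  }
  truth <- attr(table, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth
  attr(out, "log_channels") <- union(attr(table, "log_channels"), channels)
  out
}

#' Apply the hardware-style FSC-H event threshold
#'
#' Removes events with untransformed FSC-H strictly below the configured
#' threshold (events at exactly the threshold are kept, matching the
#' inclusive behaviour of instrument trigger thresholds).
#'
#' @param table an [event_table()] on the linear intensity scale.
#' @param cfg a [gating_config()].
#' @return filtered [event_table()] with attribute `n_removed`.
#' @export
apply_event_threshold <- function(table, cfg = gating_config()) {
  stopifnot(inherits(table, "event_table"))
  fsc <- channel_values(table, "FSC-H")
  keep <- fsc >= cfg$fsc_h_threshold
  out <- subset_events(table, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Exclude doublets by pulse area/height linearity
#'
#' Singlets have pulse area proportional to pulse height; coincident
#' particles inflate area without a matching height increase. The per-event
#' area/height ratio is screened with a robust outlier rule: events with
#' ratio above `median + k * MAD` (MAD scaled for SD consistency) are
#' excluded as doublets. Zero-height events cannot be screened and are
#' excluded as noise, counted separately. A degenerate all-identical ratio
#' distribution (MAD = 0) excludes nothing.
#'
#' @param table an [event_table()] on the linear scale.
#' @param cfg a [gating_config()].
#' @return list with `table` (singlets), `n_excluded` (doublets) and
#'   `n_noise` (zero-height events).
#' @export
exclude_doublets <- function(table, cfg = gating_config()) {
  stopifnot(inherits(table, "event_table"))
  area <- channel_values(table, cfg$doublet_channels[1])
  height <- channel_values(table, cfg$doublet_channels[2])
  noise <- height <= 0
  ratio <- area[!noise] / height[!noise]
  is_doublet <- rep(FALSE, length(ratio))
  if (length(ratio) > 1) {
    med <- stats::median(ratio)
    madr <- stats::mad(ratio)  # constant 1.4826: SD-consistent
    if (madr > 0) is_doublet <- ratio > med + cfg$doublet_ratio_k * madr
  }
  keep <- rep(FALSE, n_events(table))
  keep[!noise][!is_doublet] <- TRUE
  list(table = subset_events(table, keep),
       n_excluded = sum(is_doublet),
       n_noise = sum(noise))
}

#' Polygon gate constructor
#'
#' @param vertices two-column matrix of vertex coordinates (in transformed
#'   space when `transform_tag = "log10-floored"`); must describe a simple
#'   polygon with at least 3 vertices.
#' @param channels ordered pair of channel names.
#' @param transform_tag `"log10-floored"` or `"linear"`.
#' @param transform_floor floor used by the log transform.
#' @return object of class `cyto_gate`.
#' @export
polygon_gate <- function(vertices, channels,
                         transform_tag = c("log10-floored", "linear"),
                         transform_floor = 1) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3, all(is.finite(vertices)))
  transform_tag <- match.arg(transform_tag)
  structure(list(kind = "polygon", channels = canonical_channel(channels),
                 vertices = unname(vertices), transform_tag = transform_tag,
                 transform_floor = transform_floor),
            class = "cyto_gate")
}

#' Rectangle gate constructor
#'
#' @param xlim,ylim ordered numeric bounds (inclusive).
#' @inheritParams polygon_gate
#' @return object of class `cyto_gate`.
#' @export
rectangle_gate <- function(xlim, ylim, channels,
                           transform_tag = c("log10-floored", "linear"),
                           transform_floor = 1) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            xlim[1] <= xlim[2], ylim[1] <= ylim[2])
  transform_tag <- match.arg(transform_tag)
  structure(list(kind = "rectangle", channels = canonical_channel(channels),
                 xlim = xlim, ylim = ylim, transform_tag = transform_tag,
                 transform_floor = transform_floor),
            class = "cyto_gate")
}

#' @export
print.cyto_gate <- function(x, ...) {
  cat(sprintf("<cyto_gate> %s on (%s, %s), %s scale\n", x$kind,
              x$channels[1], x$channels[2], x$transform_tag))
  if (x$kind == "polygon") cat(sprintf("  %d vertices\n", nrow(x$vertices)))
  invisible(x)
}

#' Point-in-polygon membership (boundary inclusive)
#'
#' Even-odd ray-casting with an explicit on-edge test; points on an edge or
#' vertex count as inside.
#'
#' @param px,py point coordinates (vectors).
#' @param vx,vy polygon vertex coordinates.
#' @param eps tolerance for the on-edge test.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n, length(px) == length(py))
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # collinear within eps and inside the segment bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on_seg <- abs(cross) <= eps * max(seg_len, 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Build the bacteria gate by SYTO9 back-gating
#'
#' SYTO9-positive events of a stained growth control (those above the
#' `syto9_cut_quantile` quantile of the unstained control, or above the
#' configured absolute cut when no unstained control exists) are projected
#' onto (log10 FSC-H, log10 SSC-H). The gate is the convex hull of the
#' smallest set of 2-D histogram bins (a `grid_bins` x `grid_bins` grid over
#' the data range) whose occupancy covers `density_mass` of those events.
#'
#' @param control stained growth-control [event_table()] after thresholding
#'   and doublet exclusion, on the linear scale.
#' @param unstained optional unstained-control [event_table()].
#' @param cfg a [gating_config()].
#' @return a polygon `cyto_gate` tagged `log10-floored`.
#' @export
build_bacteria_gate <- function(control, unstained = NULL,
                                cfg = gating_config()) {
  stopifnot(inherits(control, "event_table"))
  fl1 <- channel_values(control, cfg$syto9_channel)
  cut <- if (!is.null(unstained)) {
    stats::quantile(channel_values(unstained, cfg$syto9_channel),
                    cfg$syto9_cut_quantile, names = FALSE, type = 7)
  } else cfg$syto9_abs_cut
  pos <- fl1 > cut
  if (sum(pos) < 100) {
    stop("only ", sum(pos), " SYTO9-positive control events; ",
         "acquire a larger stained control (>= 100 required)", call. = FALSE)
  }
  x <- log10(pmax(channel_values(control, "FSC-H")[pos], cfg$transform_floor))
  y <- log10(pmax(channel_values(control, "SSC-H")[pos], cfg$transform_floor))
  nb <- cfg$grid_bins
  xr <- range(x); yr <- range(y)
  # widen degenerate ranges so cut() is well defined
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  xb <- seq(xr[1], xr[2], length.out = nb + 1)
  yb <- seq(yr[1], yr[2], length.out = nb + 1)
  ix <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1L), nb)
  iy <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1L), nb)
  counts <- table(factor(ix, levels = 1:nb), factor(iy, levels = 1:nb))
  ord <- order(counts, decreasing = TRUE)
  cum <- cumsum(counts[ord])
  n_need <- which(cum >= cfg$density_mass * length(x))[1]
  sel <- ord[seq_len(n_need)]
  bi <- ((sel - 1) %% nb) + 1      # row = x bin
  bj <- ((sel - 1) %/% nb) + 1     # col = y bin
  # all four corners of every selected bin
  cx <- c(xb[bi], xb[bi + 1], xb[bi], xb[bi + 1])
  cy <- c(yb[bj], yb[bj], yb[bj + 1], yb[bj + 1])
  hull <- grDevices::chull(cx, cy)
  polygon_gate(cbind(cx[hull], cy[hull]), channels = c("FSC-H", "SSC-H"),
               transform_tag = "log10-floored",
               transform_floor = cfg$transform_floor)
}

#' Apply a gate to an event table
#'
#' Events whose (transformed) coordinates lie inside the gate region are
#' returned; boundary points count as inside. Tables already carrying
#' log-transformed gate channels must match the gate's `transform_tag`.
#'
#' @param table an [event_table()]; on the linear scale for
#'   `log10-floored` gates (the transform is applied internally), or
#'   pre-transformed with [transform_log()] on exactly the gate channels.
#' @param gate a `cyto_gate`.
#' @return list with `inside` (the gated [event_table()], on the gate's
#'   scale), `n_inside` and `keep` (per-event membership, usable to subset
#'   the original table).
#' @export
apply_gate <- function(table, gate) {
  stopifnot(inherits(table, "event_table"), inherits(gate, "cyto_gate"))
  logged <- attr(table, "log_channels")
  if (gate$transform_tag == "log10-floored") {
    if (!all(gate$channels %in% (logged %||% character(0)))) {
      if (any(gate$channels %in% (logged %||% character(0)))) {
        stop("transform mismatch: gate channels partially log-transformed",
             call. = FALSE)
      }
      table <- transform_log(table, gate$channels, gate$transform_floor)
    }
  } else if (any(gate$channels %in% (logged %||% character(0)))) {
    stop("transform mismatch: linear gate applied to log-transformed channels",
         call. = FALSE)
  }
  px <- channel_values(table, gate$channels[1])
  py <- channel_values(table, gate$channels[2])
  keep <- switch(gate$kind,
    polygon = point_in_polygon(px, py, gate$vertices[, 1], gate$vertices[, 2]),
    rectangle = px >= gate$xlim[1] & px <= gate$xlim[2] &
                py >= gate$ylim[1] & py <= gate$ylim[2],
    stop("unsupported gate kind ", gate$kind, call. = FALSE))
  list(inside = subset_events(table, keep), n_inside = sum(keep),
       keep = keep)
}

#' Serialize a gate to JSON
#' @param gate a `cyto_gate`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gate <- function(gate, path) {
  stopifnot(inherits(gate, "cyto_gate"))
  obj <- unclass(gate)
  # a plain matrix serializes row-wise as an array of [x, y] pairs
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gate from JSON
#' @param path path written by [write_gate()].
#' @return a `cyto_gate`.
#' @export
read_gate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "polygon") {
    polygon_gate(obj$vertices,
                 channels = obj$channels, transform_tag = obj$transform_tag,
                 transform_floor = obj$transform_floor)
  } else {
    rectangle_gate(obj$xlim, obj$ylim, channels = obj$channels,
                   transform_tag = obj$transform_tag,
                   transform_floor = obj$transform_floor)
  }
}
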