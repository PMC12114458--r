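# SYTO9/PI dual-stain viability analysis: control-anchored quadrant gating
# with optional spillover compensation. SYTO9 (all cells with accessible
# nucleic acid) reads on FL1, PI (membrane-compromised cells) on FL3;
# double-positive events are membrane-compromised / VBNC-candidate cells.

#' Compensate FL1/FL3 spillover
#'
#' Observed detector signals are modelled as `observed = true %*% S` for a
#' 2x2 spillover matrix `S` (row i = detector split of dye i); compensation
#' right-multiplies by `solve(S)` and floors negatives at zero. Applied to
#' both height and (when present) area channels.
#'
#' @param table an [event_table()] with FL1/FL3 channels on the linear
#'   scale.
#' @param spillover invertible 2x2 matrix.
#' @return compensated [event_table()] with attribute
#'   `compensation_applied = TRUE`.
#' @export
compensate <- function(table, spillover) {
  stopifnot(inherits(table, "event_table"), is.matrix(spillover),
            all(dim(spillover) == c(2, 2)))
  inv <- tryCatch(solve(spillover),
                  error = function(e) stop("singular spillover matrix",
                                           call. = FALSE))
  out <- table
  for (suffix in c("-H", "-A")) {
    ch <- paste0(c("FL1", "FL3"), suffix)
    if (all(ch %in% table$channel_names)) {
      out$events[, ch] <- pmax(table$events[, ch] %*% inv, 0)
    }
  }
  truth <- attr(table, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth
  attr(out, "compensation_applied") <- TRUE
  out
}

#' Estimate the FL1/FL3 spillover matrix from single-stain controls
#'
#' Off-diagonals are the median background-subtracted secondary/primary
#' intensity ratios among stain-positive events (positivity defined against
#' the unstained control's 99.5th percentile); diagonals are fixed at 1.
#'
#' @param single_stain_fl1,single_stain_fl3 single-stain control
#'   [event_table()]s.
#' @param unstained unstained-control [event_table()] supplying background
#'   medians and positivity cuts.
#' @param cut_quantile positivity quantile of the unstained control.
#' @return 2x2 spillover matrix.
#' @export
estimate_spillover <- function(single_stain_fl1, single_stain_fl3, unstained,
                               cut_quantile = 0.995) {
  u1 <- channel_values(unstained, "FL1-H")
  u3 <- channel_values(unstained, "FL3-H")
  bg1 <- stats::median(u1); bg3 <- stats::median(u3)
  cut1 <- stats::quantile(u1, cut_quantile, names = FALSE)
  cut3 <- stats::quantile(u3, cut_quantile, names = FALSE)
  ratio_of <- function(tbl, primary, secondary, cut, bg_p, bg_s) {
    p <- channel_values(tbl, primary)
    s <- channel_values(tbl, secondary)
    pos <- p > cut
    if (!any(pos)) {
      stop("no stain-positive events in the ", primary,
           " single-stain control", call. = FALSE)
    }
    max(0, stats::median((s[pos] - bg_s) / (p[pos] - bg_p)))
  }
  s12 <- ratio_of(single_stain_fl1, "FL1-H", "FL3-H", cut1, bg1, bg3)
  s21 <- ratio_of(single_stain_fl3, "FL3-H", "FL1-H", cut3, bg3, bg1)
  matrix(c(1, s12, s21, 1), nrow = 2, byrow = TRUE)
}

#' Stain-control bundle for quadrant analysis
#'
#' @param unstained mandatory unstained [event_table()].
#' @param heat_killed optional heat-inactivated (dead) control.
#' @param single_stain_fl1,single_stain_fl3 optional single-stain controls.
#' @return object of class `stain_controls`.
#' @export
stain_controls <- function(unstained, heat_killed = NULL,
                           single_stain_fl1 = NULL, single_stain_fl3 = NULL) {
  stopifnot(inherits(unstained, "event_table"))
  structure(list(unstained = unstained, heat_killed = heat_killed,
                 single_stain_fl1 = single_stain_fl1,
                 single_stain_fl3 = single_stain_fl3),
            class = "stain_controls")
}

#' Live/dead/double-positive quadrant fractions
#'
#' Quadrant cuts are the `cut_quantile` quantiles of the log10-transformed
#' unstained control, per channel; events at a cut count as positive. At
#' most `cap` events are analyzed (uniform seeded subsample beyond that,
#' reflecting capped acquisition). Quadrants: live = FL1+FL3-, dead =
#' FL3+FL1-, double-positive (membrane-compromised / VBNC-candidate) =
#' FL1+FL3+, unstained = FL1-FL3-.
#'
#' @param sample gated [event_table()] on the linear scale.
#' @param controls a [stain_controls()] (or an unstained [event_table()]).
#' @param cap maximum number of events analyzed.
#' @param cut_quantile per-channel positivity quantile of the unstained
#'   control.
#' @param spillover optional 2x2 matrix; when supplied, sample and controls
#'   are compensated before gating.
#' @param subsample_seed seed for the over-cap subsample.
#' @param transform_floor floor for the log10 transform.
#' @return object of class `quadrant_result`: `n_analyzed`, `fractions`
#'   (live, dead, double_positive, unstained), `cuts` (log10 units),
#'   `compensation_applied`.
#' @export
quadrant_fractions <- function(sample, controls, cap = 5000,
                               cut_quantile = 0.995, spillover = NULL,
                               subsample_seed = 1, transform_floor = 1) {
  if (inherits(controls, "event_table")) controls <- stain_controls(controls)
  stopifnot(inherits(controls, "stain_controls"), cap >= 1)
  if (is.null(controls$unstained)) stop("unstained control is required",
                                        call. = FALSE)
  unst <- controls$unstained
  if (!is.null(spillover)) {
    sample <- compensate(sample, spillover)
    unst <- compensate(unst, spillover)
  }
  lg <- function(v) log10(pmax(v, transform_floor))
  cut1 <- stats::quantile(lg(channel_values(unst, "FL1-H")), cut_quantile,
                          names = FALSE)
  cut3 <- stats::quantile(lg(channel_values(unst, "FL3-H")), cut_quantile,
                          names = FALSE)
  fl1 <- lg(channel_values(sample, "FL1-H"))
  fl3 <- lg(channel_values(sample, "FL3-H"))
  n <- length(fl1)
  if (n > cap) {
    idx <- with_substream(substream_seed(subsample_seed, "quadrant-cap"),
                          sample.int(n, cap))
    fl1 <- fl1[idx]; fl3 <- fl3[idx]
    n <- cap
  }
  p1 <- fl1 >= cut1  # boundary counts as positive
  p3 <- fl3 >= cut3
  fractions <- c(live = mean(p1 & !p3),
                 dead = mean(p3 & !p1),
                 double_positive = mean(p1 & p3),
                 unstained = mean(!p1 & !p3))
  structure(list(n_analyzed = n, fractions = fractions,
                 cuts = c(fl1_cut = cut1, fl3_cut = cut3),
                 compensation_applied = !is.null(spillover)),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat(sprintf("<quadrant_result> n=%d%s\n", x$n_analyzed,
              if (x$compensation_applied) " (compensated)" else ""))
  print(round(x$fractions, 4))
  invisible(x)
}
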