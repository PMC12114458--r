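# Count-rate computation and control normalization. The assay's readout is
# the gated event rate (events/s), rescaled between the no-bacteria
# negative control (0) and the untreated growth control (1).

#' Gated event rate
#'
#' @param n_gated gated event count (>= 0).
#' @param acq an [acquisition_meta()]; its `duration_s` (possibly derived
#'   from volume and flow rate) is the denominator.
#' @return events per second.
#' @export
count_rate <- function(n_gated, acq) {
  stopifnot(inherits(acq, "acquisition_meta"), n_gated >= 0)
  if (!is.finite(acq$duration_s) || acq$duration_s <= 0) {
    stop("non-positive acquisition duration", call. = FALSE)
  }
  n_gated / acq$duration_s
}

#' Control-normalized count rate
#'
#' `(rate_sample - rate_nc) / (rate_pc - rate_nc)`, clamped below at 0.
#' The negative (no-bacteria) control maps to 0 and the growth control to 1
#' by construction; values above 1 are kept, as super-control rates reflect
#' real growth variation, while sub-background rates are noise. Invariant to
#' adding a common background rate to all three inputs.
#'
#' @param rate_sample,rate_nc,rate_pc sample, negative-control and
#'   growth-control rates (events/s); `rate_sample` may be a vector.
#' @return normalized count(s), dimensionless and >= 0.
#' @export
normalize_rate <- function(rate_sample, rate_nc, rate_pc) {
  stopifnot(all(rate_sample >= 0), rate_nc >= 0, rate_pc >= 0)
  if (rate_pc <= rate_nc) {
    stop("growth control failed: positive-control rate (", rate_pc,
         ") must exceed negative-control rate (", rate_nc, ")", call. = FALSE)
  }
  pmax(0, (rate_sample - rate_nc) / (rate_pc - rate_nc))
}

#' Detect outgrowth between time zero and 4 h
#'
#' One-sided Welch test of replicate count rates: growth is flagged when
#' the 4 h rates exceed the time-zero rates at `alpha`. With fewer than two
#' replicate pairs only a descriptive summary is returned and the flag is
#' `NA`.
#'
#' @param rates_t0,rates_t4 replicate event rates at 0 h and 4 h.
#' @param alpha significance level.
#' @return list with `growth`, `t`, `df`, `p`, and the rate means.
#' @export
detect_growth <- function(rates_t0, rates_t4, alpha = 0.05) {
  stopifnot(all(rates_t0 >= 0), all(rates_t4 >= 0),
            length(rates_t0) == length(rates_t4))
  m0 <- mean(rates_t0); m4 <- mean(rates_t4)
  if (length(rates_t0) < 2) {
    return(list(growth = NA, t = NA_real_, df = NA_real_, p = NA_real_,
                mean_t0 = m0, mean_t4 = m4))
  }
  wt <- welch_t(rates_t4, rates_t0, sides = "one")
  list(growth = is.finite(wt$p) && wt$p < alpha,
       t = wt$t, df = wt$df, p = wt$p, mean_t0 = m0, mean_t4 = m4)
}
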