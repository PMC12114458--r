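# MBC calling on two-fold dilution ladders and EN 13727-style log
# reductions. A concentration is "above or MBC" when its normalized count
# falls strictly below the cut-off (default 0.1 on the normalized scale);
# the MBC is the lowest concentration of the contiguous killing run that
# starts at the top of the ladder.

#' Classify a normalized count against the bactericidal cut-off
#'
#' @param normalized non-negative normalized count(s).
#' @param threshold cut-off (default 0.1); the comparison is strict
#'   (`normalized < threshold`), so a value exactly at the cut-off is
#'   `not_MBC`.
#' @return character vector of `"above_or_MBC"` / `"not_MBC"`.
#' @export
classify_concentration <- function(normalized, threshold = 0.1) {
  stopifnot(all(normalized >= 0), threshold > 0)
  ifelse(normalized < threshold, "above_or_MBC", "not_MBC")
}

#' Call the MBC from a two-fold dilution ladder
#'
#' Under the default `strict` policy the ladder is scanned from the highest
#' concentration down and the MBC is the lowest concentration of the
#' contiguous `above_or_MBC` run starting at the top; an isolated passing
#' well below a failing one does not move the call. If the top
#' concentration fails, the call is censored above the tested range. If
#' every concentration passes, the call is the lowest tested concentration
#' with `below_range = TRUE`, keeping downstream log2 comparisons
#' well defined. The `lowest_passing` policy instead returns the minimum
#' passing concentration regardless of contiguity.
#'
#' @param concentrations strictly decreasing two-fold ladder.
#' @param normalized normalized counts aligned with `concentrations`.
#' @param threshold classification cut-off.
#' @param policy `"strict"` or `"lowest_passing"`.
#' @return object of class `mbc_call`: `status` (`"called"` or
#'   `"censored_above_range"`), `mbc`, `labels`, `threshold_used`,
#'   `policy`, `below_range`.
#' @export
call_mbc <- function(concentrations, normalized, threshold = 0.1,
                     policy = c("strict", "lowest_passing")) {
  policy <- match.arg(policy)
  stopifnot(length(concentrations) >= 2,
            length(normalized) == length(concentrations),
            all(diff(concentrations) < 0))
  ratio <- concentrations[-length(concentrations)] / concentrations[-1]
  if (any(abs(ratio - 2) > 1e-9)) {
    stop("concentrations must form a two-fold descending ladder", call. = FALSE)
  }
  if (any(is.na(normalized))) {
    stop("missing normalized count at concentration ",
         paste(concentrations[is.na(normalized)], collapse = ", "),
         call. = FALSE)
  }
  labels <- classify_concentration(normalized, threshold)
  names(labels) <- as.character(concentrations)
  kill <- labels == "above_or_MBC"
  res <- list(labels = labels, threshold_used = threshold, policy = policy,
              below_range = FALSE)
  if (policy == "strict") {
    if (!kill[1]) {
      res$status <- "censored_above_range"
      res$mbc <- NA_real_
    } else {
      run_end <- if (all(kill)) length(kill) else min(which(!kill)) - 1L
      res$status <- "called"
      res$mbc <- concentrations[run_end]
      res$below_range <- all(kill)
    }
  } else {
    if (!any(kill)) {
      res$status <- "censored_above_range"
      res$mbc <- NA_real_
    } else {
      res$status <- "called"
      res$mbc <- min(concentrations[kill])
      res$below_range <- all(kill)
    }
  }
  structure(res, class = "mbc_call")
}

#' @export
print.mbc_call <- function(x, ...) {
  cat(sprintf("<mbc_call> status=%s mbc=%s (threshold %.3g, %s policy%s)\n",
              x$status, format(x$mbc), x$threshold_used, x$policy,
              if (x$below_range) ", below tested range" else ""))
  invisible(x)
}

#' Log10 reduction in viable count
#'
#' `lr = log10(n0 / max(nd, limit))`, with a censoring flag when the
#' surviving count falls below the detection limit (the reported value is
#' then a lower bound). Bactericidal efficacy corresponds to a reduction of
#' at least 5 log10, the suspension-test criterion for the medical area.
#'
#' @param n0 initial viable count (> 0).
#' @param nd surviving viable count (>= 0).
#' @param limit detection limit used to censor `nd`.
#' @return list with `lr`, `bactericidal`, `censored`, `detection_limit`.
#' @export
log_reduction <- function(n0, nd, limit = 1) {
  if (!is.numeric(n0) || n0 <= 0) stop("n0 must be positive", call. = FALSE)
  stopifnot(nd >= 0, limit > 0)
  censored <- nd < limit
  lr <- log10(n0 / max(nd, limit))
  list(lr = lr, bactericidal = lr >= 5, censored = censored,
       detection_limit = limit)
}
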