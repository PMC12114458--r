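# Synthetic cytometer: a seeded generator of scatter/fluorescence event
# clouds emulating a disinfectant-efficacy assay. Four populations are
# modelled -- intact bacteria, disinfectant-damaged bacteria, sub-micron
# debris and electronic noise -- with a Hill-type kill curve linking
# disinfectant concentration to the surviving intact fraction after the
# outgrowth step. The generator exists so that every downstream step
# (thresholding, doublet exclusion, back-gated density gating, count-rate
# normalization, MBC calling, quadrant viability analysis) can be tested
# against known truth; it does not claim instrument-level realism.

#' Scatter/fluorescence population model
#'
#' Bacteria-like populations (`intact`, `damaged`) are drawn log-normally
#' per channel with a configurable FSC/SSC correlation. `debris` and
#' `noise` are drawn from linear-space exponentials concentrated below the
#' bacteria cluster, emulating sub-cellular particles and electronic
#' background.
#'
#' @param name one of `"intact"`, `"damaged"`, `"debris"`, `"noise"`.
#' @param log10_mean named per-channel location (log10 intensity) for
#'   `FSC-H`, `SSC-H`, `FL1-H`, `FL3-H`; for exponential populations this is
#'   the log10 of the channel mean.
#' @param log10_sd per-channel scale (ignored for exponential populations).
#' @param corr_fsc_ssc FSC/SSC correlation in (-1, 1).
#' @param weight non-negative relative weight.
#' @return an object of class `population_model`.
#' @export
population_model <- function(name, log10_mean, log10_sd,
                             corr_fsc_ssc = 0.6, weight = 1) {
  name <- match.arg(name, c("intact", "damaged", "debris", "noise"))
  stopifnot(all(c("FSC-H", "SSC-H", "FL1-H", "FL3-H") %in% names(log10_mean)),
            all(log10_sd > 0), corr_fsc_ssc > -1, corr_fsc_ssc < 1, weight >= 0)
  structure(list(name = name, log10_mean = log10_mean, log10_sd = log10_sd,
                 corr_fsc_ssc = corr_fsc_ssc, weight = weight),
            class = "population_model")
}

#' Default population set
#'
#' Locations put the intact-bacteria cluster well above a 1000-intensity
#' FSC-H hardware threshold (log10 mean 4.0), as expected for 0.5--1 um
#' particles on a small-particle-capable instrument, with debris and noise
#' concentrated one to two decades below. Damaged cells sit 0.3 log10 lower
#' in FSC with 1.5x the SSC spread, realizing the altered scatter profile of
#' membrane-compromised cells; the magnitude of that shift is a modelling
#' choice, not a measured value.
#'
#' @param syto9_log10 stained intact-cell FL1-H location (log10).
#' @return named list of [population_model()] objects.
#' @export
default_populations <- function(syto9_log10 = 3.5) {
  list(
    intact = population_model("intact",
      log10_mean = c("FSC-H" = 4.0, "SSC-H" = 3.7, "FL1-H" = syto9_log10,
                     "FL3-H" = 1.5),
      log10_sd = c("FSC-H" = 0.12, "SSC-H" = 0.12, "FL1-H" = 0.18,
                   "FL3-H" = 0.20)),
    damaged = population_model("damaged",
      log10_mean = c("FSC-H" = 3.7, "SSC-H" = 3.7, "FL1-H" = 2.6,
                     "FL3-H" = 2.2),
      log10_sd = c("FSC-H" = 0.16, "SSC-H" = 0.18, "FL1-H" = 0.25,
                   "FL3-H" = 0.25)),
    debris = population_model("debris",
      log10_mean = c("FSC-H" = log10(300), "SSC-H" = log10(250),
                     "FL1-H" = log10(60), "FL3-H" = log10(40)),
      log10_sd = c("FSC-H" = 0.3, "SSC-H" = 0.3, "FL1-H" = 0.3, "FL3-H" = 0.3)),
    noise = population_model("noise",
      log10_mean = c("FSC-H" = log10(120), "SSC-H" = log10(100),
                     "FL1-H" = log10(30), "FL3-H" = log10(25)),
      log10_sd = c("FSC-H" = 0.3, "SSC-H" = 0.3, "FL1-H" = 0.3, "FL3-H" = 0.3))
  )
}

#' Hill-type kill curve
#'
#' Surviving fraction `floor + (1 - floor) / (1 + (c / c50)^hill)`:
#' monotone non-increasing in concentration, equal to 1 at zero dose.
#'
#' @param c50 concentration of half-maximal kill (ladder units, e.g. % v/v).
#' @param hill Hill slope (> 0); steeper values give sharper ladders.
#' @param floor surviving fraction as concentration grows without bound.
#' @return object of class `kill_curve`.
#' @export
kill_curve <- function(c50, hill = 4, floor = 0) {
  stopifnot(c50 > 0, hill > 0, floor >= 0, floor <= 1)
  structure(list(c50 = c50, hill = hill, floor = floor), class = "kill_curve")
}

#' Surviving fraction under a kill curve
#' @param kill a [kill_curve()].
#' @param concentration non-negative concentration(s).
#' @return surviving fraction(s) in \[0, 1\].
#' @export
hill_survival <- function(kill, concentration) {
  stopifnot(inherits(kill, "kill_curve"), all(concentration >= 0))
  kill$floor + (1 - kill$floor) / (1 + (concentration / kill$c50)^kill$hill)
}

#' Synthetic-experiment configuration
#'
#' Defaults describe one assay of the study design the package targets: a
#' two-fold descending disinfectant ladder, a growth (positive) control
#' whose bacteria-like events reflect ~4 h outgrowth (`growth_factor` over
#' the time-zero inoculum `n0_events`), a no-bacteria negative control
#' emitting only debris/noise at `nc_event_rate` events/s, and volumetric
#' acquisition at 35 uL/min for 25 uL.
#'
#' @param seed integer master seed; per-sample sub-streams are derived from
#'   it by stable hashing so samples are independent yet reproducible.
#' @param populations list of [population_model()]s (named intact, damaged,
#'   debris, noise).
#' @param kill a [kill_curve()].
#' @param ladder strictly decreasing concentrations with neighbour ratio 2.
#' @param n0_events expected bacteria-like events in the inoculum before
#'   outgrowth.
#' @param growth_factor multiplicative outgrowth of surviving cells (>= 1).
#' @param doublet_fraction fraction of bacteria-like events emitted as
#'   doublets, in \[0, 0.2\].
#' @param doublet_area_gain,doublet_height_gain pulse-area and pulse-height
#'   gains of a doublet relative to a singlet.
#' @param spillover 2x2 mixing matrix for (FL1, FL3); row i gives the
#'   detector split of dye i.
#' @param nc_event_rate debris/noise events per second in the negative
#'   control (and as background in every sample).
#' @param acquisition an [acquisition_meta()].
#' @param unstained_fl1_log10 FL1-H location used for unstained bacteria.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             populations = default_populations(),
                             kill = kill_curve(c50 = 2, hill = 4),
                             ladder = c(10, 5, 2.5, 1.25, 0.625),
                             n0_events = 500,
                             growth_factor = 20,
                             doublet_fraction = 0.05,
                             doublet_area_gain = 2.0,
                             doublet_height_gain = 1.3,
                             spillover = diag(2),
                             nc_event_rate = 2,
                             acquisition = acquisition_meta(),
                             unstained_fl1_log10 = 1.7) {
  stopifnot(length(ladder) >= 2, all(diff(ladder) < 0))
  if (any(abs(ladder[-length(ladder)] / ladder[-1] - 2) > 1e-9)) {
    stop("ladder must be two-fold descending (neighbour ratio 2)", call. = FALSE)
  }
  stopifnot(n0_events > 0, growth_factor >= 1,
            doublet_fraction >= 0, doublet_fraction <= 0.2,
            is.matrix(spillover), all(dim(spillover) == c(2, 2)),
            nc_event_rate >= 0)
  structure(list(seed = as.integer(seed), populations = populations,
                 kill = kill, ladder = ladder, n0_events = n0_events,
                 growth_factor = growth_factor,
                 doublet_fraction = doublet_fraction,
                 doublet_area_gain = doublet_area_gain,
                 doublet_height_gain = doublet_height_gain,
                 spillover = spillover, nc_event_rate = nc_event_rate,
                 acquisition = acquisition,
                 unstained_fl1_log10 = unstained_fl1_log10),
            class = "synthetic_config")
}

# stable sub-stream seed: polynomial string hash mod (2^31 - 1)
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = ":")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed_int, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed_int)
  force(expr)
}

SINGLET_AREA_GAIN <- 1.5  # pulse area of a singlet relative to its height

# draw one population's heights (4 channels, log-normal or exponential)
draw_population <- function(pop, n, stained = TRUE, unstained_fl1_log10 = 1.7) {
  chans <- c("FSC-H", "SSC-H", "FL1-H", "FL3-H")
  if (n == 0) {
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, chans)))
  }
  mu <- pop$log10_mean[chans]
  if (!stained && pop$name %in% c("intact", "damaged")) {
    mu["FL1-H"] <- unstained_fl1_log10
  }
  if (pop$name %in% c("intact", "damaged")) {
    sd <- pop$log10_sd[chans]
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    rho <- pop$corr_fsc_ssc
    fsc <- mu["FSC-H"] + sd["FSC-H"] * z1
    ssc <- mu["SSC-H"] + sd["SSC-H"] * (rho * z1 + sqrt(1 - rho^2) * z2)
    fl1 <- stats::rnorm(n, mu["FL1-H"], sd["FL1-H"])
    fl3 <- stats::rnorm(n, mu["FL3-H"], sd["FL3-H"])
    out <- cbind(10^fsc, 10^ssc, 10^fl1, 10^fl3)
  } else {
    # linear-space exponentials below the bacteria cluster
    out <- vapply(chans, function(ch) stats::rexp(n, rate = 1 / 10^mu[ch]),
                  numeric(n))
    out <- matrix(out, nrow = n)
  }
  colnames(out) <- chans
  out
}

# expand 4 height channels into height+area pairs, plant doublets, permute
assemble_events <- function(heights, pop_labels, cfg, doublet_eligible) {
  n <- nrow(heights)
  is_doublet <- rep(FALSE, n)
  if (n > 0 && cfg$doublet_fraction > 0 && any(doublet_eligible)) {
    idx <- which(doublet_eligible)
    pick <- idx[stats::runif(length(idx)) < cfg$doublet_fraction]
    is_doublet[pick] <- TRUE
  }
  area_noise <- function(n) exp(stats::rnorm(n, 0, 0.04))
  ev <- matrix(0, n, 8,
               dimnames = list(NULL, c("FSC-H", "FSC-A", "SSC-H", "SSC-A",
                                       "FL1-H", "FL1-A", "FL3-H", "FL3-A")))
  for (ch in c("FSC", "SSC", "FL1", "FL3")) {
    h <- heights[, paste0(ch, "-H")]
    a <- h * SINGLET_AREA_GAIN * area_noise(n)
    h[is_doublet] <- h[is_doublet] * cfg$doublet_height_gain
    a[is_doublet] <- a[is_doublet] * cfg$doublet_area_gain
    ev[, paste0(ch, "-H")] <- h
    ev[, paste0(ch, "-A")] <- a
  }
  ord <- sample.int(n)  # uniform arrival times => exchangeable event order
  list(events = ev[ord, , drop = FALSE],
       population = pop_labels[ord],
       is_doublet = is_doublet[ord])
}

#' Simulate one acquired sample
#'
#' @param cfg a [synthetic_config()].
#' @param concentration disinfectant concentration; required (and must be a
#'   ladder member or 0) when `role = "treated"`, otherwise `NULL`.
#' @param role `"treated"`, `"growth_control"` or `"negative_control"`.
#' @param stained whether bacteria carry SYTO9 fluorescence (growth controls
#'   are measured stained to allow back-gating; treated samples are
#'   label-free).
#' @return an [event_table()] carrying a `truth` attribute with per-event
#'   population labels and doublet flags.
#' @details Expected composition: the growth control draws
#'   `Poisson(n0_events * growth_factor)` intact events; a treated sample at
#'   concentration c draws `Poisson(n0_events * growth_factor * survival(c))`
#'   intact events plus `Poisson(n0_events * (1 - survival(c)))`
#'   damaged-population events (killed cells do not grow out); every sample
#'   adds debris/noise background at `nc_event_rate` events/s. Doublets are
#'   planted among bacteria-like events with the configured area/height
#'   gains. No hardware threshold is applied: thresholding belongs to the
#'   analysis pipeline.
#' @export
simulate_sample <- function(cfg, concentration = NULL,
                            role = c("treated", "growth_control",
                                     "negative_control"),
                            stained = (role[1] != "treated")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  role <- match.arg(role)
  if (role == "treated") {
    if (is.null(concentration)) stop("treated samples need a concentration",
                                     call. = FALSE)
    if (concentration != 0 &&
        !any(abs(cfg$ladder - concentration) < 1e-12 * max(cfg$ladder))) {
      stop("concentration ", concentration, " is not in the ladder",
           call. = FALSE)
    }
  } else if (!is.null(concentration)) {
    stop("concentration applies only to treated samples", call. = FALSE)
  }
  conc_key <- if (is.null(concentration)) "NA" else format(concentration)
  seed_i <- substream_seed(cfg$seed, role, conc_key)
  dur <- cfg$acquisition$duration_s
  with_substream(seed_i, {
    n_bg <- stats::rpois(1, cfg$nc_event_rate * dur)
    n_debris <- stats::rbinom(1, n_bg, 0.8)
    n_noise <- n_bg - n_debris
    n_intact <- 0L; n_damaged <- 0L
    if (role == "growth_control") {
      n_intact <- stats::rpois(1, cfg$n0_events * cfg$growth_factor)
    } else if (role == "treated") {
      surv <- hill_survival(cfg$kill, concentration)
      n_intact <- stats::rpois(1, cfg$n0_events * cfg$growth_factor * surv)
      n_damaged <- stats::rpois(1, cfg$n0_events * (1 - surv))
    }
    counts <- c(intact = n_intact, damaged = n_damaged,
                debris = n_debris, noise = n_noise)
    heights <- do.call(rbind, lapply(names(counts), function(nm) {
      draw_population(cfg$populations[[nm]], counts[[nm]], stained,
                      cfg$unstained_fl1_log10)
    }))
    labels <- rep(names(counts), counts)
    parts <- assemble_events(heights, labels, cfg,
                             doublet_eligible = labels %in% c("intact", "damaged"))
    tbl <- event_table(parts$events, acquisition = cfg$acquisition,
                       sample_id = paste0(role,
                                          if (role == "treated")
                                            paste0("_c", conc_key) else ""))
    attr(tbl, "truth") <- list(population = parts$population,
                               is_doublet = parts$is_doublet,
                               concentration = concentration,
                               survival = if (role == "treated")
                                 hill_survival(cfg$kill, concentration) else 1)
    tbl
  })
}

#' Simulate a complete dilution-ladder experiment
#'
#' @param cfg a [synthetic_config()].
#' @return list with `growth_control`, `negative_control`, `treated` (a list
#'   of event tables named by concentration) and `truth` (per-concentration
#'   surviving fractions, the true MBC and its ladder index).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  treated <- lapply(cfg$ladder, function(cc) simulate_sample(cfg, cc, "treated"))
  names(treated) <- vapply(cfg$ladder, format, character(1))
  list(growth_control = simulate_sample(cfg, role = "growth_control"),
       negative_control = simulate_sample(cfg, role = "negative_control"),
       treated = treated,
       truth = list(survival = hill_survival(cfg$kill, cfg$ladder),
                    true_mbc = true_mbc(cfg),
                    true_mbc_index = true_mbc(cfg, index = TRUE)))
}

#' True MBC of a synthetic configuration
#'
#' The lowest ladder concentration whose expected surviving bacteria-like
#' events fall below 10% of the growth control, i.e. `survival(c) < 0.1`.
#'
#' @param cfg a [synthetic_config()].
#' @param index return the ladder index instead of the concentration.
#' @param threshold survival threshold (on the normalized scale).
#' @return concentration (or index), or `NA` if no ladder member kills.
#' @export
true_mbc <- function(cfg, index = FALSE, threshold = 0.1) {
  surv <- hill_survival(cfg$kill, cfg$ladder)
  below <- which(surv < threshold)
  if (length(below) == 0) return(NA_real_)
  # ladder is descending, survival non-decreasing down the ladder: take the
  # lowest concentration still below threshold
  i <- max(below)
  if (index) i else cfg$ladder[i]
}

#' Simulate the quantitative suspension-test arm
#'
#' Emulates the culture-based reference method: viable counts before and
#' after disinfectant exposure as Poisson colony-count draws, with killed
#' cells invisible by construction (they do not form colonies). This is the
#' input side for [log_reduction()]; it involves no scatter measurement.
#'
#' @param cfg a [synthetic_config()] (supplies the kill curve and seed).
#' @param concentration disinfectant concentration (>= 0).
#' @param inoculum expected initial viable count, in CFU/mL-equivalent
#'   units (default 1e6, the standard suspension-test working density).
#' @return list with `n0` and `nd` viable counts.
#' @export
simulate_suspension_test <- function(cfg, concentration, inoculum = 1e6) {
  stopifnot(inherits(cfg, "synthetic_config"), concentration >= 0,
            inoculum > 0)
  surv <- hill_survival(cfg$kill, concentration)
  with_substream(substream_seed(cfg$seed, "suspension", format(concentration)), {
    list(n0 = stats::rpois(1, inoculum),
         nd = stats::rpois(1, inoculum * surv))
  })
}

#' Simulate a SYTO9/PI dual-stained sample
#'
#' Live cells are FL1-bright/FL3-dim, dead cells FL3-bright/FL1-dim,
#' injured (membrane-compromised, VBNC-candidate) cells bright in both, and
#' debris dim in both. The configured 2x2 spillover matrix mixes the true
#' (FL1, FL3) dye signals into the detectors. A heat-killed control
#' corresponds to `fractions = c(0, 1 - debris, 0, debris)`.
#'
#' @param cfg a [synthetic_config()].
#' @param fractions numeric length-4 vector `(live, dead, injured, debris)`
#'   summing to 1.
#' @param n_events number of events to draw.
#' @param label sample id suffix (also salts the sub-stream).
#' @return an [event_table()] with a `truth` attribute holding the class of
#'   each event.
#' @export
simulate_stained_sample <- function(cfg, fractions, n_events = 5000,
                                    label = "stained") {
  stopifnot(inherits(cfg, "synthetic_config"), length(fractions) == 4,
            all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  classes <- c("live", "dead", "injured", "debris")
  loc <- list(live = c(3.5, 1.3), dead = c(1.3, 3.5),
              injured = c(3.2, 3.2), debris = c(1.2, 1.2))
  sdl <- c(live = 0.15, dead = 0.15, injured = 0.15, debris = 0.25)
  seed_i <- substream_seed(cfg$seed, "stained", label,
                           paste(format(fractions), collapse = ","))
  with_substream(seed_i, {
    counts <- stats::rmultinom(1, n_events, fractions)[, 1]
    names(counts) <- classes
    heights <- do.call(rbind, lapply(classes, function(cl) {
      n <- counts[[cl]]
      if (n == 0) return(matrix(numeric(0), 0, 4,
                                dimnames = list(NULL, c("FSC-H", "SSC-H",
                                                        "FL1-H", "FL3-H"))))
      scat_pop <- if (cl == "debris") cfg$populations$debris else cfg$populations$intact
      scat <- draw_population(scat_pop, n)
      fl_true <- cbind(10^stats::rnorm(n, loc[[cl]][1], sdl[[cl]]),
                       10^stats::rnorm(n, loc[[cl]][2], sdl[[cl]]))
      fl_obs <- fl_true %*% cfg$spillover
      cbind("FSC-H" = scat[, "FSC-H"], "SSC-H" = scat[, "SSC-H"],
            "FL1-H" = fl_obs[, 1], "FL3-H" = fl_obs[, 2])
    }))
    labels <- rep(classes, counts)
    parts <- assemble_events(heights, labels, cfg,
                             doublet_eligible = rep(FALSE, nrow(heights)))
    tbl <- event_table(parts$events, acquisition = cfg$acquisition,
                       sample_id = label)
    attr(tbl, "truth") <- list(class = parts$population,
                               fractions = stats::setNames(fractions, classes))
    tbl
  })
}
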