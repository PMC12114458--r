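test_that("Hill survival matches its closed form and boundary behaviour", {
  k <- kill_curve(c50 = 1, hill = 4, floor = 0)
  expect_equal(hill_survival(k, 0), 1)
  expect_equal(hill_survival(k, 8), 1 / (1 + 8^4))
  # monotone non-increasing, floor respected
  k2 <- kill_curve(c50 = 2, hill = 3, floor = 0.05)
  cs <- seq(0, 50, by = 0.5)
  s <- hill_survival(k2, cs)
  expect_true(all(diff(s) <= 0))
  expect_gte(min(s), 0.05)
  expect_equal(hill_survival(k2, 1e9), 0.05, tolerance = 1e-6)
})

test_that("config validation rejects broken ladders and fractions", {
  expect_error(synthetic_config(ladder = c(10, 5, 3)), "two-fold")
  expect_error(synthetic_config(ladder = c(5, 10, 20)))
  expect_error(synthetic_config(doublet_fraction = 0.5))
  expect_no_error(synthetic_config(ladder = c(0.4, 0.2, 0.1, 0.05)))
})

test_that("negative controls draw background at the configured Poisson rate", {
  cfg <- small_cfg(nc_event_rate = 2)
  dur <- cfg$acquisition$duration_s
  counts <- vapply(1:200, function(s) {
    tbl <- simulate_sample(small_cfg(seed = s, nc_event_rate = 2),
                           role = "negative_control")
    truth <- attr(tbl, "truth")
    expect_false(any(truth$population %in% c("intact", "damaged")))
    n_events(tbl)
  }, numeric(1))
  mu <- 2 * dur
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("zero-dose treated samples are distributed like growth controls", {
  # same marginal law; reject at most rarely across seeds
  pvals <- vapply(1:30, function(s) {
    cfg <- small_cfg(seed = s)
    tr <- simulate_sample(cfg, 0, "treated", stained = TRUE)
    gc <- simulate_sample(cfg, role = "growth_control")
    fsc_tr <- tr$events[attr(tr, "truth")$population == "intact", "FSC-H"]
    fsc_gc <- gc$events[attr(gc, "truth")$population == "intact", "FSC-H"]
    suppressWarnings(stats::ks.test(fsc_tr, fsc_gc)$p.value)
  }, numeric(1))
  expect_lte(mean(pvals < 0.01), 0.1)
})

test_that("experiments are seed-deterministic and complete", {
  cfg <- small_cfg(seed = 42)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1$growth_control$events, ex2$growth_control$events)
  expect_identical(lapply(ex1$treated, `[[`, "events"),
                   lapply(ex2$treated, `[[`, "events"))
  expect_length(ex1$treated, 5)   # one table per ladder member
  expect_named(ex1, c("growth_control", "negative_control", "treated", "truth"))
  # different seeds decorrelate
  ex3 <- simulate_experiment(small_cfg(seed = 43))
  expect_false(identical(ex1$growth_control$events, ex3$growth_control$events))
})

test_that("the generator's true MBC matches a brute-force Hill scan", {
  for (c50 in c(0.5, 1, 2, 4, 20)) {
    cfg <- small_cfg(kill = kill_curve(c50 = c50, hill = 4))
    surv <- hill_survival(cfg$kill, cfg$ladder)
    killing <- cfg$ladder[surv < 0.1]
    expected <- if (length(killing)) min(killing) else NA_real_
    expect_equal(true_mbc(cfg), expected, info = paste("c50 =", c50))
  }
})

test_that("mean surviving events decrease with concentration", {
  sums <- matrix(0, nrow = 100, ncol = 5)
  for (s in 1:100) {
    cfg <- small_cfg(seed = s, n0_events = 80, growth_factor = 5)
    sums[s, ] <- vapply(cfg$ladder, function(cc) {
      tbl <- simulate_sample(cfg, cc, "treated")
      sum(attr(tbl, "truth")$population == "intact")
    }, numeric(1))
  }
  m <- colMeans(sums)  # ladder is descending, so means must increase
  expect_true(all(diff(m) >= 0))
})

test_that("expected totals scale with acquisition duration", {
  mean_n <- function(vol) {
    mean(vapply(1:40, function(s) {
      cfg <- synthetic_config(seed = s, n0_events = 30, growth_factor = 2,
                              nc_event_rate = 4,
                              acquisition = acquisition_meta(35, vol))
      n_events(simulate_sample(cfg, role = "negative_control"))
    }, numeric(1)))
  }
  n1 <- mean_n(25); n2 <- mean_n(50)
  expect_equal(n2 / n1, 2, tolerance = 0.25)
})

test_that("without planted doublets the area/height ratio is unimodal", {
  cfg <- small_cfg(seed = 9, doublet_fraction = 0)
  tbl <- simulate_sample(cfg, role = "growth_control")
  truth <- attr(tbl, "truth")
  bact <- truth$population %in% c("intact", "damaged")
  ratio <- tbl$events[bact, "SSC-A"] / tbl$events[bact, "SSC-H"]
  expect_false(any(truth$is_doublet))
  # tight spread around the singlet gain; no secondary mode at ~2x
  expect_lt(stats::mad(ratio) / stats::median(ratio), 0.1)
  expect_lt(max(ratio) / stats::median(ratio), 1.5)
})

test_that("stained samples realize the requested class structure", {
  cfg <- small_cfg(seed = 5)
  # pure live: no event should reach the dead-population FL3 location
  live <- simulate_stained_sample(cfg, c(1, 0, 0, 0), n_events = 2000)
  expect_lt(max(live$events[, "FL3-H"]), 10^3.0)
  expect_error(simulate_stained_sample(cfg, c(0.5, 0.5, 0.5, 0)), "sum to 1")
  # spillover then exact inverse recovers intensities
  S <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE)
  cfgS <- small_cfg(seed = 5, spillover = S)
  mixed <- simulate_stained_sample(cfgS, c(0.4, 0.4, 0.1, 0.1), n_events = 1000)
  unmixed <- compensate(mixed, S)
  remixed <- unmixed
  remixed$events[, c("FL1-H", "FL3-H")] <-
    unmixed$events[, c("FL1-H", "FL3-H")] %*% S
  expect_equal(remixed$events[, "FL1-H"], mixed$events[, "FL1-H"],
               tolerance = 1e-10)
})

test_that("the suspension-test emulator reflects the kill curve", {
  cfg <- synthetic_config(seed = 2, kill = kill_curve(c50 = 1, hill = 4))
  st0 <- simulate_suspension_test(cfg, 0, inoculum = 1e5)
  expect_equal(st0$nd / st0$n0, 1, tolerance = 0.05)
  st <- simulate_suspension_test(cfg, 10, inoculum = 1e5)
  expect_lt(st$nd, 30)  # survival 1e-4 of 1e5
})
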