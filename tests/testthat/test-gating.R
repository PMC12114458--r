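make_table <- function(...) {
  cols <- list(...)
  event_table(do.call(cbind, cols))
}

test_that("log transform is exact on powers of ten and floors at zero", {
  tbl <- make_table("FSC-H" = c(1, 10, 100, 1000, 0),
                    "SSC-H" = c(5, 5, 5, 5, 5))
  out <- transform_log(tbl, "FSC-H")
  expect_equal(out$events[, "FSC-H"], c(0, 1, 2, 3, 0))
  expect_equal(out$events[, "SSC-H"], tbl$events[, "SSC-H"])  # untouched
  expect_error(transform_log(tbl, "FL1-H"), "missing channel")
})

test_that("the FSC-H threshold keeps events at exactly the cut", {
  tbl <- make_table("FSC-H" = c(500, 1000, 1500), "SSC-H" = c(1, 1, 1))
  out <- apply_event_threshold(tbl, gating_config(fsc_h_threshold = 1000))
  expect_equal(n_events(out), 2)
  expect_equal(attr(out, "n_removed"), 1)
  expect_equal(out$events[, "FSC-H"], c(1000, 1500))
  # degenerate cases
  empty <- make_table("FSC-H" = numeric(0), "SSC-H" = numeric(0))
  expect_equal(n_events(apply_event_threshold(empty, gating_config())), 0)
  all_kept <- apply_event_threshold(tbl, gating_config(fsc_h_threshold = 0))
  expect_equal(n_events(all_kept), 3)
})

test_that("doublet exclusion recovers planted doublets with little collateral", {
  cfg <- synthetic_config(seed = 21, n0_events = 300, growth_factor = 10,
                          doublet_fraction = 0.10)
  tbl <- simulate_sample(cfg, role = "growth_control")
  tbl <- apply_event_threshold(tbl, gating_config())
  truth <- attr(tbl, "truth")
  res <- exclude_doublets(tbl, gating_config())
  kept_truth <- attr(res$table, "truth")
  n_doublets <- sum(truth$is_doublet)
  n_missed <- sum(kept_truth$is_doublet)
  singlets <- !truth$is_doublet
  n_singlets_lost <- sum(singlets) - sum(!kept_truth$is_doublet)
  expect_gte((n_doublets - n_missed) / n_doublets, 0.90)
  expect_lte(n_singlets_lost / sum(singlets), 0.02)
})

test_that("doublet exclusion degenerates safely", {
  # all-identical ratios: MAD = 0 => nothing excluded
  tbl <- make_table("SSC-H" = rep(100, 5), "SSC-A" = rep(150, 5),
                    "FSC-H" = rep(100, 5))
  res <- exclude_doublets(tbl, gating_config())
  expect_equal(res$n_excluded, 0)
  expect_equal(n_events(res$table), 5)
  # single event
  one <- make_table("SSC-H" = 100, "SSC-A" = 150, "FSC-H" = 100)
  expect_equal(exclude_doublets(one, gating_config())$n_excluded, 0)
  # zero heights are noise, counted separately
  noisy <- make_table("SSC-H" = c(0, 100, 110), "SSC-A" = c(10, 150, 160),
                      "FSC-H" = c(1, 1, 1))
  resn <- exclude_doublets(noisy, gating_config())
  expect_equal(resn$n_noise, 1)
  expect_equal(n_events(resn$table), 2)
})

test_that("point-in-polygon is boundary-inclusive and matches the oracle", {
  sq <- polygon_gate(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                     channels = c("FSC-H", "SSC-H"),
                     transform_tag = "linear")
  vx <- sq$vertices[, 1]; vy <- sq$vertices[, 2]
  expect_true(point_in_polygon(0.5, 0.5, vx, vy))
  expect_true(point_in_polygon(0, 0, vx, vy))     # vertex
  expect_true(point_in_polygon(0.5, 0, vx, vy))   # edge
  expect_false(point_in_polygon(1.5, 0.5, vx, vy))
  # random non-convex polygon vs winding-angle oracle
  set.seed(14)
  theta <- sort(stats::runif(7, 0, 2 * pi))
  r <- stats::runif(7, 0.3, 1)
  vx2 <- r * cos(theta); vy2 <- r * sin(theta)
  px <- stats::runif(2000, -1.2, 1.2); py <- stats::runif(2000, -1.2, 1.2)
  expect_equal(point_in_polygon(px, py, vx2, vy2),
               oracle_in_polygon(px, py, vx2, vy2))
})

test_that("the back-gated bacteria gate captures the intact population", {
  cfg <- synthetic_config(seed = 31, n0_events = 400, growth_factor = 10)
  gc <- simulate_sample(cfg, role = "growth_control")
  gc <- exclude_doublets(apply_event_threshold(gc, gating_config()),
                         gating_config())$table
  unst <- simulate_sample(synthetic_config(seed = 32, n0_events = 400,
                                           growth_factor = 10),
                          role = "growth_control", stained = FALSE)
  gate <- build_bacteria_gate(gc, unstained = unst, cfg = gating_config())
  expect_s3_class(gate, "cyto_gate")
  expect_equal(gate$transform_tag, "log10-floored")
  intact <- subset_events(gc, attr(gc, "truth")$population == "intact")
  inside <- apply_gate(intact, gate)
  expect_gte(inside$n_inside / n_events(intact), 0.98 * 0.98)
  # negative control events stay out of the gate
  nc <- simulate_sample(cfg, role = "negative_control")
  expect_equal(apply_gate(nc, gate)$n_inside, 0)
})

test_that("gate construction is deterministic and honors density_mass", {
  cfg <- synthetic_config(seed = 33, n0_events = 400, growth_factor = 10)
  gc <- simulate_sample(cfg, role = "growth_control")
  gc <- apply_event_threshold(gc, gating_config())
  g1 <- build_bacteria_gate(gc, cfg = gating_config())
  g2 <- build_bacteria_gate(gc, cfg = gating_config())
  expect_identical(g1$vertices, g2$vertices)
  # full mass: hull contains every SYTO9-positive event
  gfull <- build_bacteria_gate(gc, cfg = gating_config(density_mass = 1))
  pos <- subset_events(gc, gc$events[, "FL1-H"] > 1000)
  expect_equal(apply_gate(pos, gfull)$n_inside, n_events(pos))
  # increasing density_mass never shrinks the gate
  areas <- vapply(c(0.6, 0.8, 0.95, 1.0), function(m) {
    polygon_area(build_bacteria_gate(gc, cfg = gating_config(density_mass = m))$vertices)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  # too few positives is an explicit error
  tiny <- subset_events(gc, seq_len(50))
  expect_error(build_bacteria_gate(tiny, cfg = gating_config()), "100")
})

test_that("gate application enforces transform consistency", {
  gate <- polygon_gate(rbind(c(3, 3), c(5, 3), c(5, 5), c(3, 5)),
                       channels = c("FSC-H", "SSC-H"))
  tbl <- make_table("FSC-H" = c(10000, 10), "SSC-H" = c(10000, 10))
  res <- apply_gate(tbl, gate)   # transform applied internally
  expect_equal(res$n_inside, 1)
  pre <- transform_log(tbl, c("FSC-H", "SSC-H"))
  expect_equal(apply_gate(pre, gate)$n_inside, 1)
  half <- transform_log(tbl, "FSC-H")
  expect_error(apply_gate(half, gate), "transform mismatch")
  lin <- rectangle_gate(c(0, 100), c(0, 100), channels = c("FSC-H", "SSC-H"),
                        transform_tag = "linear")
  expect_error(apply_gate(pre, lin), "transform mismatch")
})

test_that("gates serialize to JSON and back", {
  gate <- polygon_gate(rbind(c(3.1, 3.2), c(4.9, 3.3), c(4.5, 4.8)),
                       channels = c("FSC-H", "SSC-H"))
  f <- withr::local_tempfile(fileext = ".json")
  write_gate(gate, f)
  back <- read_gate(f)
  expect_equal(back$vertices, gate$vertices)
  expect_equal(back$channels, gate$channels)
  expect_equal(back$transform_tag, gate$transform_tag)
})
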