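# Event regions, the three-level scoring rule, and detection efficiency.

# Single-year VHI cube with n_drought of n_total pixels at VHI 20 and the
# rest at 60, on a 10 x 10 unit grid.
vhi_fraction_cube <- function(n_drought, n_total = 100L, year = 2000L) {
  v <- rep(60, n_total)
  v[seq_len(n_drought)] <- 20
  layers_cube(list(matrix(v, 10, 10)), years = year)
}

whole_grid_event <- function(year = 2000L, id = "e1", continent = NA_character_) {
  drought_event(id, year, bbox = c(0, 0, 10, 10), continent = continent)
}

test_that("region masks follow pixel centers, half-open on the max edges", {
  g <- grid_spec(4, 4)                        # origin (0, 4), unit pixels
  ev <- drought_event("box", 2000L, bbox = c(0, 2, 2, 4))  # top-left 2x2
  m <- region_mask(ev, g)
  expect_equal(sum(m), 4L)
  expect_true(all(m[1:2, 1:2]))
  # max edge excluded: a box ending at a center keeps the half-open rule
  ev2 <- drought_event("edge", 2000L, bbox = c(0, 0, 1.5, 4))
  expect_equal(sum(region_mask(ev2, g)), 4L)  # only column 1 centers (0.5)
  # mask regions are returned unchanged
  mm <- matrix(FALSE, 4, 4); mm[2, 3] <- TRUE
  expect_identical(region_mask(drought_event("m", 2000L, mask = mm), g), mm)
  expect_error(region_mask(drought_event("out", 2000L, bbox = c(50, 50, 60, 60)), g),
               "out")
  expect_error(drought_event("both", 2000L), "exactly one")
})

test_that("score_event reproduces the 1 / 0.5 / 0 rule with strict boundaries", {
  ev <- whole_grid_event()
  expect_equal(score_event(vhi_fraction_cube(85L), ev)$score, 1)
  expect_equal(score_event(vhi_fraction_cube(50L), ev)$score, 0.5)
  expect_equal(score_event(vhi_fraction_cube(10L), ev)$score, 0)
  # boundaries: exactly 80% scores 0.5; exactly 40% scores 0
  expect_equal(score_event(vhi_fraction_cube(80L), ev)$score, 0.5)
  expect_equal(score_event(vhi_fraction_cube(40L), ev)$score, 0)
  expect_equal(score_event(vhi_fraction_cube(41L), ev)$score, 0.5)
  expect_equal(score_event(vhi_fraction_cube(81L), ev)$score, 1)
  s <- score_event(vhi_fraction_cube(85L), ev)
  expect_equal(s$n_region_pixels, 100L)
  expect_equal(s$fraction, 0.85)
})

test_that("scoring counts only valid pixels and validates the year", {
  cube <- vhi_fraction_cube(50L)
  cube$valid[1, , 6:10] <- FALSE            # half the grid missing
  s <- score_event(cube, whole_grid_event())
  expect_equal(s$n_region_pixels, 50L)
  expect_equal(s$fraction, 1)               # all 50 remaining are at VHI 20
  expect_equal(s$score, 1)
  expect_error(score_event(cube, whole_grid_event(year = 1999L)), "1999")
  cube$valid[] <- FALSE
  expect_error(score_event(cube, whole_grid_event()), "no valid pixels")
})

test_that("score_event is monotone: lowering VHI never lowers the score", {
  set.seed(70)
  for (i in 1:10) {
    v <- matrix(runif(100, 0, 100), 10, 10)
    cube <- layers_cube(list(v), years = 2000L)
    lower <- layers_cube(list(pmax(v - runif(100, 0, 30), 0)), years = 2000L)
    expect_gte(score_event(lower, whole_grid_event())$score,
               score_event(cube, whole_grid_event())$score)
  }
})

test_that("DTE is 100 * S / TDE, order-invariant, and stratifiable", {
  ev <- whole_grid_event()
  scores <- list(
    score_event(vhi_fraction_cube(85L), whole_grid_event(id = "a", continent = "africa")),
    score_event(vhi_fraction_cube(50L), whole_grid_event(id = "b", continent = "africa")),
    score_event(vhi_fraction_cube(10L), whole_grid_event(id = "c", continent = "asia")))
  rep1 <- detection_efficiency(scores)
  expect_equal(rep1$dte, 50)
  expect_equal(rep1$total_score, 1.5)
  expect_equal(detection_efficiency(rev(scores))$dte, rep1$dte)
  expect_equal(detection_efficiency(scores[c(1, 1, 1)])$dte, 100)
  strat <- detection_efficiency(scores, by = "continent")
  expect_equal(strat$groups$dte[strat$groups$group == "africa"], 75)
  expect_equal(strat$groups$dte[strat$groups$group == "asia"], 0)
  expect_error(detection_efficiency(list()), "no events")
})

test_that("pooled DTE lies between the DTEs of the pooled groups", {
  set.seed(71)
  for (i in 1:20) {
    s1 <- sample(c(0, 0.5, 1), sample(1:8, 1), replace = TRUE)
    s2 <- sample(c(0, 0.5, 1), sample(1:8, 1), replace = TRUE)
    d1 <- 100 * sum(s1) / length(s1); d2 <- 100 * sum(s2) / length(s2)
    pooled <- 100 * sum(c(s1, s2)) / (length(s1) + length(s2))
    expect_gte(pooled, min(d1, d2) - 1e-12)
    expect_lte(pooled, max(d1, d2) + 1e-12)
  }
})

test_that("compare_indices scores both cubes on identical events", {
  cube <- vhi_fraction_cube(85L)
  ev <- list(whole_grid_event())
  same <- compare_indices(cube, cube, ev)
  expect_equal(same$report_a$dte, same$report_b$dte)
  # a uniformly healthier cube never detects more
  healthier <- cube; healthier$values <- pmin(cube$values + 10, 100)
  cmp <- compare_indices(cube, healthier, ev)
  expect_lte(cmp$report_b$dte, cmp$report_a$dte)
  expect_equal(cmp$per_year$n_observed, 1L)
  expect_equal(cmp$per_year$n_detected_a, 1L)
})

test_that("event catalogs round-trip through CSV", {
  td <- withr::local_tempdir()
  df <- data.frame(event_id = c("e1", "e2"), year = c(1999L, 2000L),
                   min_lon = c(0, 2), min_lat = c(0, 2),
                   max_lon = c(5, 8), max_lat = c(5, 8),
                   continent = c("africa", "asia"))
  path <- file.path(td, "events.csv")
  write.csv(df, path, row.names = FALSE)
  events <- read_events_csv(path)
  expect_length(events, 2L)
  expect_equal(events[[2]]$bbox, c(2, 2, 8, 8))
  expect_equal(events[[1]]$continent, "africa")
  expect_error(read_events_csv({
    p2 <- file.path(td, "bad.csv")
    write.csv(df[, 1:3], p2, row.names = FALSE); p2
  }), "missing columns")
})
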