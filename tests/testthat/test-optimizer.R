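# Grid search for the optimal VCI contribution weight.

# Independent brute-force oracle: recomputes the weighted blend and the
# product-moment correlation from the defining sums for every candidate,
# sharing no code with the package implementation.
oracle_best_a <- function(v, t_, y, candidates) {
  r <- vapply(candidates, function(a) {
    x <- a * v + (1 - a) * t_
    xm <- sum(x) / length(x); ym <- sum(y) / length(y)
    num <- sum((x - xm) * (y - ym))
    den <- sqrt(sum((x - xm)^2)) * sqrt(sum((y - ym)^2))
    num / den
  }, 0)
  i <- which(r == max(r))[1L]
  list(a = candidates[i], r = r[i])
}

test_that("the default candidate grid is 0.02..0.98 in steps of 0.02", {
  a <- candidate_grid()
  expect_length(a, 49L)
  expect_equal(a, seq(2, 98, by = 2) / 100, tolerance = 1e-12)
  expect_equal(min(a), 0.02)
  expect_equal(max(a), 0.98)
  expect_true(all(diff(a) > 0))
  expect_equal(a[25], 0.5)    # the equal-weight blend is itself a candidate
  expect_error(candidate_grid(0), "0, 0.5")
})

test_that("pearson_r matches hand-computed values and flags degeneracy", {
  x <- c(1, 5, 2, 8)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.981981, tolerance = 1e-5)
  expect_true(is.na(pearson_r(c(1, 2), c(3, 4))))          # too short
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))    # constant
  expect_true(is.na(pearson_r(c(1, NA, 2, 3), c(1, 2, NA, 3), min_n = 3L)))
})

test_that("correlation profiles peak at the matching endpoint", {
  set.seed(10)
  v <- runif(41, 0, 100); t_ <- runif(41, 0, 100)
  pr_v <- correlation_profile(v, t_, ref = v)
  expect_length(pr_v, 49L)
  expect_equal(select_a_opt(pr_v)$a_opt, 0.98)
  pr_t <- correlation_profile(v, t_, ref = t_)
  expect_equal(select_a_opt(pr_t)$a_opt, 0.02)
  # vci == tci -> blend independent of a -> constant profile
  pr_c <- correlation_profile(v, v, ref = t_)
  expect_true(all(abs(pr_c - pr_c[1]) < 1e-12))
  # too little overlap -> all undefined
  expect_true(all(is.na(correlation_profile(v[1:5], t_[1:5], v[1:5],
                                            min_overlap = 10L))))
})

test_that("select_a_opt takes the argmax and breaks ties toward smaller a", {
  cand <- candidate_grid()
  prof <- rep(0.1, 49); prof[15] <- 0.9       # unique max at a = 0.30
  expect_equal(select_a_opt(prof, cand), list(a_opt = 0.30, r_max = 0.9))
  expect_equal(select_a_opt(rep(0.3, 49), cand)$a_opt, 0.02)
  prof2 <- rep(0, 49); prof2[c(24, 25)] <- 0.8  # exact tie at 0.48 and 0.50
  expect_equal(select_a_opt(prof2, cand)$a_opt, 0.48)
  expect_true(is.na(select_a_opt(rep(NA_real_, 49), cand)$a_opt))
})

test_that("optimize_contribution matches the brute-force oracle pixel by pixel", {
  set.seed(20)
  nt <- 41L; nr <- 5L; nc <- 8L
  vci <- rand_cube(nt, nr, nc, seed = 21)
  tci <- rand_cube(nt, nr, nc, seed = 22)
  ref_vals <- array(rnorm(nt * nr * nc), c(nt, nr, nc))
  # mix in signal so maxima are non-trivial
  ref_vals <- ref_vals + 0.03 * vci$values - 0.02 * tci$values
  ref <- raster_cube(ref_vals, vci$times, vci$grid)
  cmap <- optimize_contribution(vci, tci, ref)
  cand <- candidate_grid()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    o <- oracle_best_a(vci$values[, r, cc], tci$values[, r, cc],
                       ref$values[, r, cc], cand)
    expect_identical(cmap$a_opt[r, cc], o$a)
    expect_equal(cmap$r_max[r, cc], o$r, tolerance = 1e-12)
  }
  expect_true(all(cmap$n_used == nt))
})

test_that("a 2x2 scene tracking vci/tci recovers the endpoint weights", {
  set.seed(30)
  nt <- 41L
  vci <- rand_cube(nt, 2, 2, seed = 31)
  tci <- rand_cube(nt, 2, 2, seed = 32)
  ref_vals <- array(NA_real_, c(nt, 2, 2))
  ref_vals[, 1, ] <- vci$values[, 1, ]   # top row follows vegetation
  ref_vals[, 2, ] <- tci$values[, 2, ]   # bottom row follows temperature
  ref <- raster_cube(ref_vals, vci$times, vci$grid)
  cmap <- optimize_contribution(vci, tci, ref)
  expect_equal(cmap$a_opt, matrix(c(0.98, 0.02, 0.98, 0.02), 2, 2))
  expect_equal(dominance_summary(cmap),
               list(frac_tci_dominated = 0.5, frac_vci_dominated = 0.5))

  # all-invalid reference -> all-invalid map
  ref$valid[] <- FALSE
  cm2 <- optimize_contribution(vci, tci, ref)
  expect_false(any(cm2$valid))
  expect_error(dominance_summary(cm2), "no valid pixels")
})

test_that("the estimate is invariant under positive affine transforms of the reference", {
  vci <- rand_cube(20, 3, 3, seed = 41)
  tci <- rand_cube(20, 3, 3, seed = 42)
  ref <- rand_cube(20, 3, 3, seed = 43, lo = -4, hi = 4)
  c1 <- optimize_contribution(vci, tci, ref)
  ref2 <- ref; ref2$values <- 7 + 0.031 * ref$values
  c2 <- optimize_contribution(vci, tci, ref2)
  expect_identical(c1$a_opt, c2$a_opt)
  expect_equal(c1$r_max, c2$r_max, tolerance = 1e-9)
})

test_that("pixels below the joint-overlap floor are invalid, not guessed", {
  vci <- rand_cube(12, 1, 2, seed = 51)
  tci <- rand_cube(12, 1, 2, seed = 52)
  ref <- rand_cube(12, 1, 2, seed = 53)
  ref$valid[1:5, 1, 2] <- FALSE                 # 7 joint steps < 10
  cmap <- optimize_contribution(vci, tci, ref, min_overlap = 10L)
  expect_true(cmap$valid[1, 1])
  expect_false(cmap$valid[1, 2])
  expect_equal(cmap$n_used[1, 2], 7L)
})

test_that("compute_vhi_opt applies the per-pixel weights", {
  vci <- series_cube(70); tci <- series_cube(30)
  ref <- series_cube(1)
  cmap <- structure(list(grid = vci$grid, a_opt = matrix(0.2, 1, 1),
                         r_max = matrix(1, 1, 1), n_used = matrix(1L, 1, 1),
                         valid = matrix(TRUE, 1, 1),
                         candidates = candidate_grid()),
                    class = "contribution_map")
  expect_equal(compute_vhi_opt(vci, tci, cmap)$values[1, 1, 1], 38)

  # a map holding 0.5 everywhere reproduces the equal-weight VHI
  vci2 <- rand_cube(6, 2, 2, seed = 61); tci2 <- rand_cube(6, 2, 2, seed = 62)
  cmap2 <- cmap
  cmap2$grid <- vci2$grid
  cmap2$a_opt <- matrix(0.5, 2, 2); cmap2$valid <- matrix(TRUE, 2, 2)
  expect_equal(compute_vhi_opt(vci2, tci2, cmap2)$values,
               compute_vhi(vci2, tci2, 0.5)$values)
  expect_error(compute_vhi_opt(vci, tci, cmap2), "grid")
})
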