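shifted_cubes <- function() {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- TRUE
  list(a = binary_mask(a), b = binary_mask(b))
}

test_that("dice coefficient follows the formula and the undefined rule", {
  m <- shifted_cubes()
  expect_equal(dice_coefficient(m$a, m$a), 1)
  expect_equal(dice_coefficient(m$a, m$b), 2 * 4 / (8 + 8))
  disj <- binary_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)))
  disj2 <- binary_mask(array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2)))
  expect_equal(dice_coefficient(disj, disj2), 0)
  empty <- binary_mask(array(FALSE, c(2, 2, 2)))
  expect_equal(dice_coefficient(empty, empty), 0) # 0/0 -> 0
  # geometry mismatches are errors, never silent zeros
  expect_error(dice_coefficient(m$a, empty), class = "segrank_geometry_error")
  sp <- binary_mask(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 2))
  expect_error(dice_coefficient(m$a, sp), class = "segrank_geometry_error")
})

test_that("boundary voxels match an exhaustive neighbour scan", {
  single <- binary_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)))
  expect_identical(nrow(boundary_voxels(single)), 1L)
  cube <- array(FALSE, c(6, 6, 6)); cube[2:5, 2:5, 2:5] <- TRUE
  bv <- boundary_voxels(binary_mask(cube))
  expect_identical(nrow(bv), 56L) # 4^3 - 2^3 shell voxels
  expect_identical(nrow(boundary_voxels(binary_mask(array(FALSE, c(3, 3, 3))))), 0L)
  set.seed(11)
  for (i in 1:5) {
    m <- random_mask(c(9, 8, 7))
    got <- boundary_voxels(binary_mask(m))
    want <- which(oracle_boundary(m), arr.ind = TRUE)
    expect_equal(unname(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]),
                 unname(want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE]))
  }
})

test_that("surface dice reproduces the worked shifted-cube example", {
  m <- shifted_cubes()
  expect_equal(surface_dice(m$a, m$a, 0), 1)
  expect_equal(surface_dice(m$a, m$b, 1), 1)
  expect_equal(surface_dice(m$a, m$b, 0.5), 0.5)
  empty <- binary_mask(array(FALSE, c(4, 4, 4)))
  expect_equal(surface_dice(empty, empty, 1), 0)   # undefined -> 0
  expect_equal(surface_dice(m$a, empty, 1), 0)     # one empty -> 0
  expect_error(surface_dice(m$a, m$b, -1), class = "segrank_config_error")
})

test_that("metrics are symmetric, bounded and tolerance-monotone", {
  set.seed(21)
  for (i in 1:12) {
    sp <- if (i %% 2 == 0) c(1, 1, 2) else c(1, 1, 1)
    p <- binary_mask(random_mask(), sp)
    g <- binary_mask(random_mask(), sp)
    expect_equal(dice_coefficient(p, g), dice_coefficient(g, p))
    d <- dice_coefficient(p, g)
    expect_true(d >= 0 && d <= 1)
    prev <- -1
    for (tol in c(0, 0.5, 1, 2, 5)) {
      s <- surface_dice(p, g, tol)
      expect_equal(s, surface_dice(g, p, tol))
      expect_true(s >= 0 && s <= 1)
      expect_gte(s, prev)
      prev <- s
    }
    if (any(p$voxels) && any(g$voxels)) {
      diag_mm <- sqrt(sum((dim(p$voxels) * sp)^2))
      expect_equal(surface_dice(p, g, diag_mm), 1)
    }
  }
})

test_that("DSC and NSD match the brute-force oracles, incl. anisotropic", {
  set.seed(31)
  for (i in 1:15) {
    sp <- if (i %% 2 == 0) c(1, 1, 2) else c(1, 1, 1)
    p <- random_mask(c(10, 9, 8))
    g <- random_mask(c(10, 9, 8))
    expect_identical(dice_coefficient(binary_mask(p, sp), binary_mask(g, sp)),
                     oracle_dice(p, g))
    for (tol in c(0, 0.5, 1, 2))
      expect_equal(surface_dice(binary_mask(p, sp), binary_mask(g, sp), tol),
                   oracle_nsd(p, g, sp, tol), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under shared translation and permutation", {
  set.seed(41)
  p <- random_mask(c(10, 10, 10), noise = 0)
  g <- random_mask(c(10, 10, 10), noise = 0)
  shift1 <- function(m) {
    out <- array(FALSE, dim(m) + 2L)
    out[2:11, 2:11, 2:11] <- m
    out
  }
  p0 <- binary_mask(p); g0 <- binary_mask(g)
  p1 <- binary_mask(shift1(p)); g1 <- binary_mask(shift1(g))
  expect_equal(dice_coefficient(p1, g1), dice_coefficient(p0, g0))
  expect_equal(surface_dice(p1, g1, 1.5), surface_dice(p0, g0, 1.5))
  pp <- binary_mask(aperm(p, c(3, 1, 2))); gp <- binary_mask(aperm(g, c(3, 1, 2)))
  expect_equal(dice_coefficient(pp, gp), dice_coefficient(p0, g0))
  expect_equal(surface_dice(pp, gp, 1.5), surface_dice(p0, g0, 1.5))
})

test_that("evaluate_case yields 2 records per ROI and applies the 0 rule", {
  spec <- task_spec("Prostate-like", "development", c(pz = 1, tz = 2), 4)
  vox <- array(0L, c(8, 8, 8)); vox[2:4, 2:4, 2:4] <- 1L # label 2 absent
  gt <- label_volume(vox); pred <- label_volume(vox)
  rec <- evaluate_case(pred, gt, spec, team = "A", case = "c1")
  expect_identical(nrow(rec), 4L)
  expect_setequal(rec$metric, c("DSC", "NSD"))
  # present ROI identical -> both metrics 1; ROI absent from both -> 0
  expect_equal(rec$value[rec$roi == "pz"], c(1, 1))
  expect_equal(rec$value[rec$roi == "tz"], c(0, 0))
  single <- task_spec("Spleen-like", "mystery", c(spleen = 1), 3)
  rec1 <- evaluate_case(pred, gt, single, "A", "c1")
  expect_identical(nrow(rec1), 2L)
  expect_equal(rec1$value, c(1, 1))
  bad <- label_volume(array(0L, c(4, 4, 4)))
  expect_error(evaluate_case(bad, gt, spec, "A", "c1"),
               class = "segrank_geometry_error")
})

test_that("metric tables enforce the complete block and round-trip via CSV", {
  tb <- dominance_table(n_teams = 3, n_cases = 4)
  expect_s3_class(tb, "metric_table")
  broken <- tb[-1, ]
  expect_error(metric_table(broken), "incomplete block",
               class = "segrank_data_error")
  expect_error(metric_table(rbind(tb, tb[1, ])), "duplicate",
               class = "segrank_format_error")
  expect_error(metric_table(transform(tb, value = value + 2)),
               class = "segrank_format_error")
  f <- tempfile(fileext = ".csv")
  write_metric_table(tb, f)
  expect_equal(as.data.frame(read_metric_table(f)), as.data.frame(tb),
               tolerance = 1e-12)
  # deterministic row order: team -> task -> case -> roi -> metric
  expect_identical(order(tb$team, tb$task, tb$case, tb$roi, tb$metric),
                   seq_len(nrow(tb)))
})
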