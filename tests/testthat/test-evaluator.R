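test_that("Pearson correlation follows the product-moment formula", {
  a <- array(c(1, 2, 3, 4), c(4, 1, 1))
  b <- array(c(1, 2, 4, 3), c(4, 1, 1))
  expect_equal(pearson_cc(a, b), 0.8)     # hand-computed
  expect_equal(pearson_cc(a, a), 1)
  expect_equal(pearson_cc(2.5 * a + 3, a), 1)   # affine invariance
  expect_equal(pearson_cc(-a, a), -1)
  expect_error(pearson_cc(array(1, c(4, 1, 1)), a), "constant")
  expect_error(pearson_cc(a, array(0, c(2, 2, 1))), "shape")
})

test_that("the central-region correlation selects the right cube", {
  grid <- map_grid(unit_cell(10), 20)    # 0.5 A spacing
  set.seed(61)
  truth <- array(stats::rnorm(8000), c(20, 20, 20))
  pred <- array(stats::rnorm(8000), c(20, 20, 20))
  # make prediction perfect inside the central 6 A (12-voxel) cube only
  pred[5:16, 5:16, 5:16] <- truth[5:16, 5:16, 5:16]
  tm <- voxel_map(grid, truth)
  pm <- voxel_map(grid, pred)
  expect_equal(pearson_cc(pm, tm, region = 6), 1)
  expect_lt(pearson_cc(pm, tm), 1)
  expect_error(pearson_cc(pm, tm, region = 100), "range")
})

test_that("truth-vs-truth gives zero phase error in every shell", {
  set.seed(62)
  cell <- unit_cell(10)
  grid <- map_grid(cell, 16)
  den <- density_from_reflections(
    structure_factors(random_atoms(4), cell, 1.5), grid)
  pe <- phase_error_by_shell(den, den, 1.5)
  present <- !is.na(pe$by_shell$mean_error_deg)
  expect_true(any(present))
  expect_lt(max(pe$by_shell$mean_error_deg[present]), 1e-8)
  expect_lt(pe$overall, 1e-8)
  expect_equal(pearson_cc(den, den), 1)
})

test_that("uniformly random phases average 90 degrees of error", {
  set.seed(63)
  cell <- unit_cell(12)
  grid <- map_grid(cell, 26)
  rset <- enumerate_hkl(cell, 1.0)
  n_refl <- nrow(rset$refl)
  expect_gte(n_refl, 2000)
  df <- rset$refl
  df$amp <- stats::rexp(n_refl) + 0.1
  df$phase_deg <- stats::runif(n_refl, -180, 180)
  truth <- density_from_reflections(
    patternet:::.new_reflection_set(df, cell, 1.0), grid)
  df2 <- df
  df2$phase_deg <- stats::runif(n_refl, -180, 180)
  pred <- density_from_reflections(
    patternet:::.new_reflection_set(df2, cell, 1.0), grid)
  pe <- phase_error_by_shell(pred, truth, 1.0)
  expect_gt(pe$overall, 88)
  expect_lt(pe$overall, 92)
  # unweighted mode agrees at this sample size
  pe_u <- phase_error_by_shell(pred, truth, 1.0, weighted = FALSE)
  expect_gt(pe_u$overall, 88)
  expect_lt(pe_u$overall, 92)
})

test_that("the centrosymmetric twin shows the analytic -2*phi error", {
  set.seed(64)
  cell <- unit_cell(8)
  grid <- map_grid(cell, 16)
  atoms <- random_atoms(4)
  sf <- structure_factors(atoms, cell, 1.5)
  den <- density_from_reflections(sf, grid)
  den_inv <- density_from_reflections(
    structure_factors(invert_atoms(atoms), cell, 1.5), grid)
  pe <- phase_error_by_shell(den_inv, den, 1.5)
  truth <- reflections_from_density(den, 1.5)
  expected <- abs(patternet:::.wrap_phase(-2 * truth$refl$phase_deg))
  strong <- truth$refl$amp > 1e-6 * max(truth$refl$amp)
  expect_equal(pe$reflections$dphi_deg[strong], expected[strong],
               tolerance = 1e-6)
})

test_that("phase error ignores a positive rescale of the prediction", {
  set.seed(65)
  cell <- unit_cell(8)
  grid <- map_grid(cell, 16)
  den <- density_from_reflections(
    structure_factors(random_atoms(3), cell, 1.5), grid)
  scaled <- voxel_map(grid, 3.7 * den$values)
  pe <- phase_error_by_shell(scaled, den, 1.5)
  expect_lt(pe$overall, 1e-8)
})

test_that("fraction-below counts shell errors against the threshold", {
  errs <- rbind(c(10, 80, NA), c(70, 40, NA), c(20, 90, NA),
                c(50, 61, NA))
  fb <- fraction_below(errs, 60)
  expect_equal(fb[1], 0.75)
  expect_equal(fb[2], 0.25)
  expect_true(is.na(fb[3]))
  expect_equal(unname(fraction_below(matrix(0, 3, 2), 60)), c(1, 1))
  expect_error(fraction_below(matrix(numeric(0), 0, 2), 60), "empty")
  expect_error(fraction_below(errs, 190), "threshold")
})

test_that("evaluation reports aggregate medians across examples", {
  set.seed(66)
  cell <- unit_cell(8)
  grid <- map_grid(cell, 16)
  truth <- density_from_reflections(
    structure_factors(random_atoms(5), cell, 1.5), grid)
  # single perfect example: medians equal that example's values
  rep1 <- evaluate_predictions(list(truth), list(truth), 1.5)
  expect_equal(rep1$median_cc, 1)
  expect_lt(rep1$median_phase_error, 1e-8)
  expect_true(all(rep1$shell_fraction_below == 1, na.rm = TRUE))
  # odd count: the median is the middle order statistic
  noisy <- function(sd) {
    voxel_map(grid, truth$values + array(stats::rnorm(16^3, 0, sd),
                                         c(16, 16, 16)))
  }
  preds <- list(truth, noisy(0.3 * stats::sd(truth$values)),
                noisy(3 * stats::sd(truth$values)))
  rep3 <- evaluate_predictions(preds, list(truth, truth, truth), 1.5)
  expect_equal(rep3$median_cc, sort(rep3$per_example$cc)[2])
  expect_equal(rep3$median_phase_error,
               sort(rep3$per_example$phase_error_deg)[2])
  dir <- withr::local_tempdir()
  write_report(rep3, dir)
  expect_true(file.exists(file.path(dir, "per_example.csv")))
  expect_true(file.exists(file.path(dir, "shells.csv")))
  summ <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(summ$median_cc, rep3$median_cc)
})
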