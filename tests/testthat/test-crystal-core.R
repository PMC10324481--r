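test_that("reflection enumeration matches the resolution cutoff geometry", {
  cell <- unit_cell(10)
  expect_equal(nrow(enumerate_hkl(cell, 20)$refl), 0)
  rs <- enumerate_hkl(cell, 5)
  # h^2 + k^2 + l^2 <= (a/d_min)^2 = 4: full-sphere counts {6,12,8,6} for
  # norms {1,2,3,4}, halved for Friedel-unique storage
  expect_equal(nrow(rs$refl), 16)
  expect_false(any(rs$refl$h == 2 & rs$refl$k == 1 & rs$refl$l == 0))
  expect_true(all(rs$refl$d >= 5))
  # boundary inclusive: (2,0,0) has d exactly 5
  expect_true(any(rs$refl$h == 2 & rs$refl$k == 0 & rs$refl$l == 0 |
                  rs$refl$h == -2 & rs$refl$k == 0 & rs$refl$l == 0))
  # Friedel-unique: no key stored together with its negation
  key <- paste(rs$refl$h, rs$refl$k, rs$refl$l)
  neg <- paste(-rs$refl$h, -rs$refl$k, -rs$refl$l)
  expect_length(intersect(key, neg), 0)
  expect_error(enumerate_hkl(cell, -1), "positive")
  expect_error(enumerate_hkl(cell, 0), "positive")
})

test_that("structure factors reproduce closed-form cases", {
  cell <- unit_cell(10)
  # single atom at the origin: every exponent is zero
  sf <- structure_factors(atom_list("C", matrix(0, 1, 3), b_iso = 0),
                          cell, 5)
  expect_equal(sf$refl$amp, rep(6, 16))
  expect_equal(sf$refl$phase_deg, rep(0, 16))
  # atom at x = 1/4: F(1,0,0) = exp(2 pi i / 4) = i
  sf <- structure_factors(atom_list("C", matrix(c(0.25, 0, 0), 1, 3),
                                    b_iso = 0, f = 1), cell, 5)
  r <- sf$refl[sf$refl$h == 1 & sf$refl$k == 0 & sf$refl$l == 0, ]
  expect_equal(r$amp, 1)
  expect_equal(r$phase_deg, 90)
  # two equal atoms half a cell apart: odd h extinct, even h doubled
  sf <- structure_factors(
    atom_list(c("C", "C"), rbind(c(0, 0, 0), c(0.5, 0, 0)), b_iso = 0,
              f = 1), cell, 5)
  g <- function(h) sf$refl$amp[sf$refl$h == h & sf$refl$k == 0 &
                               sf$refl$l == 0]
  expect_equal(g(1), 0, tolerance = 1e-12)
  expect_equal(g(2), 2)
  expect_error(structure_factors(list(), cell, 5), "non-empty")
})

test_that("structure factors agree with scalar direct summation", {
  set.seed(101)
  cell <- unit_cell(9)
  for (rep in 1:3) {
    atoms <- random_atoms(5)
    sf <- structure_factors(atoms, cell, 3)
    bf <- bf_structure_factors(atoms, cell, 3)
    expect_lt(max(abs(sf$refl$amp - bf$amp)) / max(bf$amp), 1e-10)
    dphi <- abs(patternet:::.wrap_phase(sf$refl$phase_deg - bf$phase_deg))
    expect_lt(max(dphi[bf$amp > 1e-9 * max(bf$amp)]), 1e-8)
  }
})

test_that("F(0,0,0) equals the total scattering power", {
  set.seed(7)
  cell <- unit_cell(8)
  atoms <- random_atoms(6, b_iso = 20)
  sf <- structure_factors(atoms, cell, 2, include_f000 = TRUE)
  r0 <- sf$refl[sf$refl$h == 0 & sf$refl$k == 0 & sf$refl$l == 0, ]
  expect_equal(r0$amp, sum(atoms$f))
  expect_equal(r0$phase_deg, 0)
})

test_that("density synthesis reproduces closed forms and the voxel oracle", {
  cell <- unit_cell(10)
  grid <- map_grid(cell, 8)
  # F(0,0,0) = V alone gives the constant map 1
  df <- data.frame(h = 0, k = 0, l = 0, d = Inf, amp = cell$volume,
                   phase_deg = 0)
  rset <- patternet:::.new_reflection_set(df, cell, 5,
                                          includes_f000 = TRUE)
  den <- density_from_reflections(rset, grid, on_alias = "allow")
  expect_equal(den$values, array(1, c(8, 8, 8)))
  # F(1,0,0) = V/2, phase 0 (with its Friedel mate) gives cos(2 pi x)
  df <- data.frame(h = 1, k = 0, l = 0, d = 10, amp = cell$volume / 2,
                   phase_deg = 0)
  rset <- patternet:::.new_reflection_set(df, cell, 5)
  den <- density_from_reflections(rset, grid, on_alias = "allow")
  expect_equal(den$values[, 1, 1], cos(2 * pi * (0:7) / 8))
  expect_equal(max(abs(sweep(den$values, 1, den$values[, 1, 1]))), 0)
  # random 3-atom structure against the per-voxel complex-sum oracle
  set.seed(11)
  atoms <- random_atoms(3)
  sf <- structure_factors(atoms, cell, 2.5)
  g16 <- map_grid(cell, 16)
  den <- density_from_reflections(sf, g16)
  expect_lt(max(abs(den$values - bf_density(sf, g16))), 1e-8)
})

test_that("undersampled synthesis is refused (aliasing guard)", {
  cell <- unit_cell(10)
  atoms <- atom_list("C", matrix(0.3, 1, 3))
  sf <- structure_factors(atoms, cell, 2)
  coarse <- map_grid(cell, 8)   # spacing 1.25 A > d_min/2 = 1 A
  expect_error(density_from_reflections(sf, coarse), "alias")
  expect_warning(density_from_reflections(sf, coarse, on_alias = "warn"),
                 "alias")
})

test_that("Patterson synthesis peaks at interatomic vectors", {
  cell <- unit_cell(10)
  grid <- map_grid(cell, 20)
  # single atom: only the origin self-vector
  sf <- structure_factors(atom_list("C", matrix(c(0.37, 0.81, 0.24), 1, 3),
                                    b_iso = 8), cell, 1.5)
  pat <- patterson_from_reflections(sf, grid)
  expect_equal(which.max(pat$values), 1L)  # origin voxel
  expect_equal(pat$values, flip_map(pat$values), tolerance = 1e-12)
  # two equal atoms 0.2 fractional apart along x: cross-peaks at +/-0.2,
  # equal height, origin peak about twice as high (band-limited)
  sf <- structure_factors(
    atom_list(c("C", "C"), rbind(c(0.4, 0.5, 0.5), c(0.6, 0.5, 0.5)),
              b_iso = 8), cell, 1.5)
  pat <- patterson_from_reflections(sf, grid)
  v <- pat$values
  expect_equal(which.max(v), 1L)
  # voxel (0.2, 0, 0) is index (5, 1, 1) on the 20-grid (0-based 4)
  expect_equal(v[5, 1, 1], v[17, 1, 1])   # centrosymmetric mate at 0.8
  peak_ratio <- v[1, 1, 1] / v[5, 1, 1]
  expect_gt(peak_ratio, 1.8)
  expect_lt(peak_ratio, 2.2)
  # cross-peaks are local maxima along x
  expect_gt(v[5, 1, 1], v[7, 1, 1])
  expect_gt(v[5, 1, 1], v[3, 1, 1])
})

test_that("map-to-reflections inverts density synthesis", {
  cell <- unit_cell(10)
  grid <- map_grid(cell, 16)
  # constant map: only F(0,0,0) = V
  const <- voxel_map(grid, array(1, c(16, 16, 16)))
  rs <- reflections_from_density(const, 2.5, include_f000 = TRUE)
  r0 <- rs$refl$h == 0 & rs$refl$k == 0 & rs$refl$l == 0
  expect_equal(rs$refl$amp[r0], cell$volume)
  expect_lt(max(rs$refl$amp[!r0]), 1e-8)
  # cos(2 pi x): only (+-1, 0, 0), amplitude V/2, phase 0
  cosx <- voxel_map(grid, array(rep(cos(2 * pi * (0:15) / 16), 256),
                                c(16, 16, 16)))
  rs <- reflections_from_density(cosx, 2.5)
  r100 <- rs$refl$h == 1 & rs$refl$k == 0 & rs$refl$l == 0
  expect_equal(rs$refl$amp[r100], cell$volume / 2)
  expect_equal(rs$refl$phase_deg[r100], 0)
  expect_lt(max(rs$refl$amp[!r100]), 1e-8)
  # round trip on a random structure-factor set
  set.seed(21)
  sf <- structure_factors(random_atoms(4), cell, 2.5)
  den <- density_from_reflections(sf, grid)
  rt <- reflections_from_density(den, 2.5)
  expect_equal(rt$refl[, c("h", "k", "l")], sf$refl[, c("h", "k", "l")])
  expect_lt(max(abs(rt$refl$amp - sf$refl$amp)), 1e-8)
  dphi <- abs(patternet:::.wrap_phase(rt$refl$phase_deg -
                                      sf$refl$phase_deg))
  expect_lt(max(dphi[sf$refl$amp > 1e-8]), 1e-8)
})

test_that("min-max normalization maps onto [-1, 1] and is idempotent", {
  grid <- map_grid(unit_cell(3), 2)
  vals <- array(c(0, 2, 4, 2, 0, 4, 2, 2), c(2, 2, 2))
  m <- normalize_map(voxel_map(grid, vals))
  expect_equal(sort(unique(as.vector(m$values))), c(-1, 0, 1))
  expect_equal(normalize_map(m)$values, m$values)
  # constant map degenerates to zeros rather than erroring
  const <- voxel_map(grid, array(7, c(2, 2, 2)))
  expect_equal(normalize_map(const)$values, array(0, c(2, 2, 2)))
  # symmetric alternative keeps zero fixed
  m2 <- normalize_map(voxel_map(grid, vals - 1), mode = "maxabs")
  expect_equal(max(abs(m2$values)), 1)
  expect_equal(m2$values[1, 1, 1], -1 / 3)
  bad <- voxel_map(grid, array(c(NA, 1:7), c(2, 2, 2)))
  expect_error(normalize_map(bad), "non-finite")
})

test_that("reflection sets survive the tab-separated round trip", {
  set.seed(31)
  cell <- unit_cell(7, 8, 9)
  sf <- structure_factors(random_atoms(4), cell, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reflections(sf, path)
  back <- read_reflections(path)
  expect_equal(back$cell$a, 7)
  expect_equal(back$cell$c, 9)
  expect_equal(back$d_min, 3)
  expect_equal(back$refl$amp, sf$refl$amp, tolerance = 1e-9)
  expect_equal(back$refl$phase_deg, sf$refl$phase_deg, tolerance = 1e-9)
})
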