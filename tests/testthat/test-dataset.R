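test_that("the conformer generator is deterministic and complete", {
  a <- synth_dipeptide("ALA", "ALA", seed = 7)
  b <- synth_dipeptide("ALA", "ALA", seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$frac,
                         synth_dipeptide("ALA", "ALA", seed = 8)$frac))
  expect_equal(n_atoms(a), 10)          # 5 heavy atoms per alanine
  expect_equal(n_atoms(synth_dipeptide("GLY", "ALA", seed = 1)), 9)
  expect_equal(n_atoms(synth_dipeptide("TRP", "ARG", seed = 1,
                                       cell = unit_cell(14))), 25)
  expect_equal(unname(residue_heavy_atoms(c("G", "A", "K", "S", "W"))),
               c(4, 5, 9, 6, 14))
  expect_error(synth_dipeptide("XXX", "ALA", seed = 1), "unknown residue")
})

test_that("generated alpha carbons always carry the L configuration", {
  set.seed(1001)
  all_res <- c("ALA", "SER", "CYS", "THR", "VAL", "LEU", "ILE", "MET",
               "PRO", "PHE", "TYR", "TRP", "ASP", "ASN", "GLU", "GLN",
               "LYS", "ARG", "HIS")
  n_draws <- 0L
  for (rep in 1:500) {
    rs <- sample(all_res, 2, replace = TRUE)
    at <- synth_dipeptide(rs[1], rs[2], seed = sample.int(2^30, 1),
                          cell = unit_cell(14))
    cart <- sweep(at$frac, 2, 14, "*")
    for (r in 1:2) {
      g <- function(nm) cart[which(at$meta$resno == r &
                                   at$meta$atom == nm), ]
      vol <- chiral_volume(g("N"), g("CA"), g("C"), g("CB"))
      expect_gt(vol, 0)
      n_draws <- n_draws + 1L
    }
  }
  expect_gte(n_draws, 1000)
})

test_that("truncation to dialanine keeps exactly the N, CA, C, O, CB set", {
  aa <- synth_dipeptide("ALA", "ALA", seed = 3)
  expect_equal(truncate_to_dialanine(aa)$frac, aa$frac)
  ks <- truncate_to_dialanine(synth_dipeptide("LYS", "SER", seed = 3,
                                              cell = unit_cell(12)))
  expect_equal(n_atoms(ks), 10)
  expect_equal(unique(ks$meta$resname), "ALA")
  expect_true(all(ks$meta$atom %in% c("N", "CA", "C", "O", "CB")))
  # glycine keeps its 4 backbone atoms: truncation never invents a CB
  gk <- truncate_to_dialanine(synth_dipeptide("GLY", "LYS", seed = 3))
  expect_equal(n_atoms(gk), 9)
  expect_equal(sum(gk$meta$resno == 1), 4)
  # missing backbone atom is a data error
  broken <- synth_dipeptide("ALA", "ALA", seed = 3)
  keep <- broken$meta$atom != "O" | broken$meta$resno != 1
  broken <- atom_list(broken$element[keep],
                      broken$frac[keep, , drop = FALSE],
                      meta = broken$meta[keep, , drop = FALSE])
  expect_error(truncate_to_dialanine(broken), "missing backbone")
})

test_that("center of mass lands exactly on the cell center", {
  cell <- unit_cell(10)
  one <- atom_list("C", matrix(c(0.1, 0.9, 0.3), 1, 3))
  expect_equal(as.vector(center_by_mass(one, cell)$frac),
               c(0.5, 0.5, 0.5))
  # two equal-mass atoms 2 A apart along x end symmetric about the center
  two <- atom_list(c("C", "C"), rbind(c(0.10, 0.2, 0.2),
                                      c(0.30, 0.2, 0.2)))
  cen <- center_by_mass(two, cell)
  expect_equal(cen$frac * 10,
               rbind(c(4, 5, 5), c(6, 5, 5)), ignore_attr = TRUE)
  set.seed(9)
  for (rep in 1:5) {
    atoms <- center_by_mass(random_atoms(6), cell)
    com <- colSums(atoms$frac * atoms$mass / sum(atoms$mass))
    expect_lt(max(abs(com - 0.5)), 1e-10)
  }
})

test_that("clash check flags close periodic images but not bonds", {
  cell <- unit_cell(10)
  expect_true(clash_check(atom_list("C", matrix(0.5, 1, 3)), cell, 2))
  pair <- atom_list(c("C", "C"), rbind(c(0.05, 0.5, 0.5),
                                       c(0.95, 0.5, 0.5)))
  expect_false(clash_check(pair, cell, 2))   # image distance 1 A
  expect_true(clash_check(pair, cell, 0.5))
  # a 1.5 A bonded pair inside the molecule is legitimate
  bonded <- atom_list(c("C", "C"), rbind(c(0.50, 0.5, 0.5),
                                         c(0.65, 0.5, 0.5)))
  expect_true(clash_check(bonded, cell, 2))
  # a 1.95 A non-bonded contact is below a 2 A threshold
  close_nb <- atom_list(c("C", "C"), rbind(c(0.500, 0.5, 0.5),
                                           c(0.695, 0.5, 0.5)))
  expect_false(clash_check(close_nb, cell, 2))
})

test_that("examples are normalized pairs with the ambiguity structure", {
  cfg <- dataset_config(10, 0.5, seed = 5)
  # a single carbon: density blob at the center, Patterson origin peak
  carbon <- atom_list("C", matrix(0.3, 1, 3))
  ex <- make_example(carbon, cfg)
  expect_equal(dim(ex$density$values), c(20, 20, 20))
  expect_equal(which.max(ex$patterson$values), 1L)
  expect_equal(which.max(ex$density$values),
               which(array(seq_len(8000), c(20, 20, 20)) ==
                     (10 + 20 * 10 + 400 * 10 + 1)))
  expect_gte(min(ex$density$values), -1)
  expect_lte(max(ex$density$values), 1)
  expect_gte(min(ex$patterson$values), -1)
  expect_lte(max(ex$patterson$values), 1)
  # the centrosymmetric twin shares the Patterson but not the density
  atoms <- synth_dipeptide("ALA", "ALA", seed = 6)
  ex0 <- make_example(atoms, cfg)
  ex1 <- make_example(invert_atoms(atoms), cfg)
  expect_equal(ex1$patterson$values, ex0$patterson$values,
               tolerance = 1e-8)
  expect_gt(max(abs(ex1$density$values - ex0$density$values)), 0.1)
})

test_that("stored pairs are internally consistent through the transform", {
  cfg <- dataset_config(10, 0.5, seed = 12)
  atoms <- center_by_mass(synth_dipeptide("ALA", "ALA", seed = 12),
                          cfg$cell)
  rset <- structure_factors(atoms, cfg$cell, cfg$d_min)
  den <- density_from_reflections(rset, cfg$grid)
  # Patterson from the density's own recovered amplitudes matches the
  # Patterson from the original structure factors
  ramp <- reflections_from_density(den, cfg$d_min)
  p1 <- patterson_from_reflections(ramp, cfg$grid)
  p0 <- patterson_from_reflections(rset, cfg$grid)
  expect_lt(max(abs(p1$values - p0$values)) / max(abs(p0$values)), 1e-6)
})

test_that("dataset generation is reproducible with disjoint splits", {
  cfg <- dataset_config(10, 0.5, split = c(train = 0.9, validation = 0.1),
                        seed = 77)
  ds1 <- build_dataset(cfg, 10)
  ds2 <- build_dataset(cfg, 10)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$examples[[3]]$density$values,
                   ds2$examples[[3]]$density$values)
  expect_equal(length(ds1$examples), 10)
  expect_equal(sum(ds1$manifest$split == "train"), 9)
  expect_equal(sum(ds1$manifest$split == "validation"), 1)
  expect_length(intersect(ds1$manifest$source[ds1$manifest$split == "train"],
                          ds1$manifest$source[ds1$manifest$split ==
                                              "validation"]), 0)
  # Table-style geometry: 10 A cell at 0.5 A spacing is a 20^3 grid
  expect_equal(dim(ds1$examples[[1]]$patterson$values), c(20, 20, 20))
})

test_that("datasets survive the save/load round trip", {
  cfg <- dataset_config(10, 0.5, seed = 3)
  ds <- build_dataset(cfg, 4)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "maps.rds")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_dataset(dir)
  expect_equal(length(back$examples), 4)
  expect_equal(back$examples[[2]]$patterson$values,
               ds$examples[[2]]$patterson$values)
  expect_equal(back$config$grid$nx, 20)
  expect_equal(back$manifest$split, ds$manifest$split)
})

test_that("enlarged-cell examples leave the border empty", {
  # the 20 A dialanine cell pads the molecule with empty space; density
  # (which is zero-mean) should be near its background level at the faces
  cfg <- dataset_config(20, 0.5, seed = 8)
  atoms <- synth_dipeptide("ALA", "ALA", seed = 8, cell = cfg$cell)
  atoms <- center_by_mass(atoms, cfg$cell)
  rset <- structure_factors(atoms, cfg$cell, cfg$d_min)
  den <- density_from_reflections(rset, cfg$grid)
  v <- den$values
  border <- c(v[1:4, , ], v[, 1:4, ], v[, , 1:4])
  expect_lt(max(abs(border)), 0.1 * max(abs(v)))
})
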