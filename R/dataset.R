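#' Center an atom list at the cell center by mass
#'
#' Rigidly translates the atoms so that the mass-weighted centroid sits at
#' fractional (0.5, 0.5, 0.5). Coordinates are not wrapped afterwards (the
#' Fourier synthesis is periodic, and wrapping would shift the centroid of
#' the stored coordinates), so the molecule should be contiguous on input.
#' Centering removes the translation degree of freedom that the Patterson
#' map cannot see, so the network's target densities always sit mid-cell.
#'
#' @param atoms An [atom_list()].
#' @param cell A [unit_cell()].
#' @return The centered [atom_list()].
#' @export
center_by_mass <- function(atoms, cell) {
  w <- atoms$mass / sum(atoms$mass)
  com <- colSums(atoms$frac * w)
  frac <- sweep(atoms$frac, 2, c(0.5, 0.5, 0.5) - com, "+")
  atom_list(atoms$element, frac, b_iso = atoms$b_iso, f = atoms$f,
            mass = atoms$mass, label = atoms$label, meta = atoms$meta)
}

#' Check a centered molecule for periodic-image clashes
#'
#' Fails when any atom pair, including pairs formed with periodic images in
#' neighboring unit cells, comes closer than \code{min_dist} by the
#' minimum-image convention. Bonded-range contacts within the molecule
#' itself (direct distance below 1.9 A) are legitimate chemistry and do not
#' fail the check; only image contacts and non-bonded direct contacts do.
#'
#' @param atoms A centered [atom_list()].
#' @param cell A [unit_cell()].
#' @param min_dist Rejection threshold in Angstrom (default 2.0).
#' @return \code{TRUE} (pass) or \code{FALSE} (fail).
#' @export
clash_check <- function(atoms, cell, min_dist = 2.0) {
  n <- n_atoms(atoms)
  if (n < 2L) return(TRUE)
  edges <- c(cell$a, cell$b, cell$c)
  cart <- sweep(atoms$frac, 2, edges, "*")
  for (i in seq_len(n - 1L)) {
    di <- sweep(cart[(i + 1L):n, , drop = FALSE], 2, cart[i, ], "-")
    direct <- sqrt(rowSums(di^2))
    dmi <- sweep(di, 2, edges, function(x, e) x - e * round(x / e))
    mimg <- sqrt(rowSums(dmi^2))
    bonded <- direct < 1.9
    # a bonded pair only fails if some periodic image is closer than the
    # direct (chemical) contact and below threshold
    bad <- (mimg < min_dist) & (!bonded | mimg < direct - 1e-9)
    if (any(bad)) return(FALSE)
  }
  TRUE
}

#' Truncate a dipeptide to dialanine
#'
#' Keeps only the N, CA, C, O and CB atoms of each residue and renames both
#' residues ALA. Glycine has no CB and keeps its four backbone atoms;
#' truncation never invents atoms.
#'
#' @param atoms An [atom_list()] with per-atom metadata naming two standard
#'   residues.
#' @return The truncated [atom_list()].
#' @export
truncate_to_dialanine <- function(atoms) {
  meta <- atoms$meta
  if (is.null(meta) || is.null(meta$atom)) {
    stop("atom metadata with atom names is required for truncation",
         call. = FALSE)
  }
  keep_names <- c("N", "CA", "C", "O", "CB")
  keep <- meta$atom %in% keep_names
  for (rn in unique(meta$resno)) {
    have <- meta$atom[meta$resno == rn]
    missing <- setdiff(c("N", "CA", "C", "O"), have)
    if (length(missing)) {
      stop("residue ", rn, " is missing backbone atom(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  meta <- meta[keep, , drop = FALSE]
  meta$resname <- "ALA"
  atom_list(atoms$element[keep], atoms$frac[keep, , drop = FALSE],
            b_iso = atoms$b_iso[keep], f = atoms$f[keep],
            mass = atoms$mass[keep],
            label = paste0(atoms$label, ":trAA"), meta = meta)
}

#' Dataset recipe
#'
#' Bundles the geometric and sampling choices that define one dataset: cell
#' edge, grid spacing (must satisfy the Nyquist bound \code{spacing <=
#' d_min/2}), resolution cutoff, residue alphabet, dialanine truncation,
#' clash threshold, split fractions and the base seed.
#'
#' @param cell_edge Cubic cell edge in Angstrom.
#' @param spacing Grid spacing in Angstrom.
#' @param d_min Resolution cutoff in Angstrom (default 1.5).
#' @param alphabet \code{"ALA"} (dialanine datasets) or \code{"all20"}.
#' @param truncate Truncate extracted dipeptides to dialanine?
#' @param clash_distance Minimum allowed non-bonded/image contact (A).
#' @param split Named fractions for train/validation, summing to 1.
#' @param b_iso Global isotropic B in A^2 for the scattering model.
#' @param seed Base seed for example generation.
#' @return A \code{dataset_config} object.
#' @export
dataset_config <- function(cell_edge, spacing, d_min = 1.5,
                           alphabet = c("ALA", "all20"), truncate = TRUE,
                           clash_distance = 2.0,
                           split = c(train = 0.9, validation = 0.1),
                           b_iso = 15, seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(cell_edge > 0, spacing > 0, d_min > 0)
  if (spacing > d_min / 2 + 1e-9) {
    stop("spacing must be <= d_min/2 (Nyquist)", call. = FALSE)
  }
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1",
                                       call. = FALSE)
  cell <- unit_cell(cell_edge)
  structure(list(cell = cell, spacing = spacing, d_min = d_min,
                 alphabet = alphabet, truncate = truncate,
                 clash_distance = clash_distance, split = split,
                 b_iso = b_iso, seed = as.integer(seed),
                 grid = grid_from_spacing(cell, spacing)),
            class = "dataset_config")
}

#' @export
print.dataset_config <- function(x, ...) {
  cat(sprintf(
    "<dataset_config: %g A cell / %g A spacing -> %d^3 grid, d_min %g A, %s%s>\n",
    x$cell$a, x$spacing, x$grid$nx, x$d_min, x$alphabet,
    if (x$truncate) " (truncated to dialanine)" else ""))
  invisible(x)
}

#' Build one normalized (Patterson, density) training pair
#'
#' Runs the full example pipeline: center by mass, structure factors to
#' \code{d_min}, density and Patterson synthesis on the configured grid, and
#' per-map min-max normalization onto [-1, 1].
#'
#' @param atoms An [atom_list()] that passes [clash_check()].
#' @param config A [dataset_config()].
#' @return A list with \code{patterson} and \code{density} (both normalized
#'   [voxel_map()]s on one grid) and a \code{meta} record.
#' @export
make_example <- function(atoms, config) {
  atoms <- center_by_mass(atoms, config$cell)
  rset <- structure_factors(atoms, config$cell, config$d_min)
  den <- normalize_map(density_from_reflections(rset, config$grid))
  pat <- normalize_map(patterson_from_reflections(rset, config$grid))
  list(patterson = pat, density = den,
       meta = list(source = atoms$label,
                   residues = if (!is.null(atoms$meta))
                     unique(atoms$meta$resname) else NA,
                   n_atoms = n_atoms(atoms)))
}

# sample a residue pair from the configured alphabet
.sample_pair <- function(config) {
  if (config$alphabet == "ALA") c("ALA", "ALA")
  else sample(residue_alphabet(), 2L, replace = TRUE)
}

#' Generate a dataset of paired Patterson/density examples
#'
#' Examples come either from the built-in synthetic conformer generator
#' (\code{sources = NULL}) or from dipeptides extracted at random positions
#' of the given PDB files. Examples failing the periodic clash check are
#' skipped and counted. Train/validation assignment is by source structure,
#' so no source contributes to both splits.
#'
#' @param config A [dataset_config()].
#' @param n_examples Number of stored examples requested (>= 1).
#' @param sources \code{NULL} for synthetic examples, or a character vector
#'   of PDB file paths.
#' @param max_attempts Cap on generation attempts (clash rejections retry
#'   with fresh geometry).
#' @return A \code{patterson_dataset}: list of examples, manifest
#'   data.frame (source id, residues, split), config, and the number of
#'   clash rejections.
#' @export
build_dataset <- function(config, n_examples, sources = NULL,
                          max_attempts = 20L * n_examples) {
  stopifnot(n_examples >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  pdb_pool <- NULL
  if (!is.null(sources)) {
    pdb_pool <- lapply(sources, read_pdb)
    names(pdb_pool) <- basename(sources)
  }
  examples <- list()
  man <- list()
  rejected <- 0L
  attempt <- 0L
  while (length(examples) < n_examples && attempt < max_attempts) {
    attempt <- attempt + 1L
    if (is.null(pdb_pool)) {
      pair <- .sample_pair(config)
      sub_seed <- sample.int(2^31 - 2L, 1L)
      atoms <- synth_dipeptide(pair[1], pair[2], seed = sub_seed,
                               cell = config$cell, b_iso = config$b_iso)
      source_id <- sprintf("synth-%s-%s-%d", pair[1], pair[2], sub_seed)
    } else {
      si <- sample.int(length(pdb_pool), 1L)
      pdb <- pdb_pool[[si]]
      pos <- .random_dipeptide_position(pdb)
      if (is.null(pos)) { rejected <- rejected + 1L; next }
      atoms <- tryCatch(
        extract_dipeptide(pdb, pos$resno, chain = pos$chain,
                          cell = config$cell, b_iso = config$b_iso),
        error = function(e) NULL)
      if (is.null(atoms)) { rejected <- rejected + 1L; next }
      source_id <- names(pdb_pool)[si]
    }
    if (config$truncate) {
      atoms <- tryCatch(truncate_to_dialanine(atoms),
                        error = function(e) NULL)
      if (is.null(atoms)) { rejected <- rejected + 1L; next }
    }
    atoms <- center_by_mass(atoms, config$cell)
    if (!clash_check(atoms, config$cell, config$clash_distance)) {
      rejected <- rejected + 1L
      next
    }
    ex <- make_example(atoms, config)
    examples[[length(examples) + 1L]] <- ex
    man[[length(man) + 1L]] <- data.frame(
      example = length(examples), source = source_id,
      residues = paste(ex$meta$residues, collapse = "-"),
      n_atoms = ex$meta$n_atoms, stringsAsFactors = FALSE)
  }
  if (length(examples) == 0L) {
    stop("no examples survived generation (all rejected)", call. = FALSE)
  }
  manifest <- do.call(rbind, man)
  manifest$split <- .assign_splits(manifest$source, config$split)
  structure(list(examples = examples, manifest = manifest, config = config,
                 rejected = rejected),
            class = "patterson_dataset")
}

# source-level split assignment: a source never straddles splits
.assign_splits <- function(source_ids, split) {
  uniq <- unique(source_ids)
  n <- length(uniq)
  n_train <- round(split[["train"]] * n)
  if (n_train == n && n > 1L) n_train <- n - 1L
  if (n_train == 0L && n > 1L) n_train <- 1L
  shuffled <- sample(uniq)
  assign <- ifelse(uniq %in% shuffled[seq_len(n_train)], "train",
                   "validation")
  names(assign) <- uniq
  unname(assign[source_ids])
}

#' @export
print.patterson_dataset <- function(x, ...) {
  cat(sprintf("<patterson_dataset: %d examples (%d train / %d validation), %d^3 grid, %d clash-rejected>\n",
              length(x$examples), sum(x$manifest$split == "train"),
              sum(x$manifest$split == "validation"),
              x$config$grid$nx, x$rejected))
  invisible(x)
}

#' Save a dataset as an array bundle plus JSON manifest
#'
#' Maps are stacked into two aligned arrays (one Patterson, one density)
#' saved as an RDS bundle; the manifest and config go to a JSON sidecar.
#'
#' @param ds A \code{patterson_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- ds$config$grid
  n <- length(ds$examples)
  pat <- array(0, c(g$nx, g$ny, g$nz, n))
  den <- array(0, c(g$nx, g$ny, g$nz, n))
  for (i in seq_len(n)) {
    pat[, , , i] <- ds$examples[[i]]$patterson$values
    den[, , , i] <- ds$examples[[i]]$density$values
  }
  saveRDS(list(patterson = pat, density = den), file.path(dir, "maps.rds"))
  cfg <- ds$config
  jsonlite::write_json(
    list(manifest = ds$manifest, rejected = ds$rejected,
         config = list(cell_edge = cfg$cell$a, spacing = cfg$spacing,
                       d_min = cfg$d_min, alphabet = cfg$alphabet,
                       truncate = cfg$truncate,
                       clash_distance = cfg$clash_distance,
                       split = as.list(cfg$split), b_iso = cfg$b_iso,
                       seed = cfg$seed)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset written by [save_dataset()]
#' @param dir Dataset directory.
#' @return A \code{patterson_dataset}.
#' @export
load_dataset <- function(dir) {
  maps <- readRDS(file.path(dir, "maps.rds"))
  js <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  cfgj <- js$config
  config <- dataset_config(cfgj$cell_edge, cfgj$spacing, cfgj$d_min,
                           alphabet = cfgj$alphabet,
                           truncate = cfgj$truncate,
                           clash_distance = cfgj$clash_distance,
                           split = unlist(cfgj$split), b_iso = cfgj$b_iso,
                           seed = cfgj$seed)
  n <- dim(maps$patterson)[4]
  examples <- lapply(seq_len(n), function(i) {
    list(patterson = voxel_map(config$grid, maps$patterson[, , , i],
                               "patterson"),
         density = voxel_map(config$grid, maps$density[, , , i], "density"),
         meta = list(source = js$manifest$source[i]))
  })
  structure(list(examples = examples, manifest = js$manifest,
                 config = config, rejected = js$rejected),
            class = "patterson_dataset")
}
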