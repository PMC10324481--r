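# Element tables: point-scatterer weights (atomic number, electrons) and
# atomic masses (u). Heavy atoms of the 20 proteinogenic residues only need
# C, N, O, S; H is excluded from the scattering model throughout.
.element_f <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34)
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

#' Collection of point scatterers in fractional coordinates
#'
#' An atom list holds element symbols, fractional coordinates, scattering
#' weights f (electrons; the atomic number in the point-scatterer model), an
#' isotropic displacement parameter B (A^2) and atomic masses. It is the
#' unit-cell contents that structure-factor summation runs over.
#'
#' @param element Character vector of element symbols (e.g. "C", "N").
#' @param frac Numeric matrix (n x 3) of fractional coordinates.
#' @param b_iso Isotropic B-factor(s) in A^2, recycled over atoms. The default
#'   15 A^2 damps series-termination ripple at the 1.5 A resolution used for
#'   map synthesis.
#' @param f Optional scattering weights; defaults to the atomic number.
#' @param mass Optional masses in u; defaults to standard atomic masses.
#' @param label Identifier string.
#' @param meta Optional data.frame of per-atom annotations (atom name,
#'   residue name/number, chain) carried through geometry operations.
#' @return An object of class \code{atom_list}.
#' @export
atom_list <- function(element, frac, b_iso = 15, f = NULL, mass = NULL,
                      label = "", meta = NULL) {
  element <- toupper(as.character(element))
  frac <- as.matrix(frac)
  if (ncol(frac) != 3L || nrow(frac) != length(element)) {
    stop("frac must be an n x 3 matrix matching element length", call. = FALSE)
  }
  if (nrow(frac) == 0L) stop("atom list must be non-empty", call. = FALSE)
  if (any(!is.finite(frac))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(f)) {
    unknown <- setdiff(element, names(.element_f))
    if (length(unknown)) {
      stop("unknown element(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    f <- unname(.element_f[element])
  }
  if (is.null(mass)) mass <- unname(.element_mass[element])
  f <- rep_len(as.numeric(f), length(element))
  mass <- rep_len(as.numeric(mass), length(element))
  b_iso <- rep_len(as.numeric(b_iso), length(element))
  if (any(f <= 0) || any(mass <= 0)) {
    stop("scattering weights and masses must be positive", call. = FALSE)
  }
  dimnames(frac) <- list(NULL, c("x", "y", "z"))
  structure(list(element = element, frac = frac, f = f, b_iso = b_iso,
                 mass = mass, label = label, meta = meta),
            class = "atom_list")
}

#' @export
print.atom_list <- function(x, ...) {
  cat(sprintf("<atom_list '%s': %d atoms (%s)>\n", x$label,
              length(x$element),
              paste(names(sort(table(x$element), decreasing = TRUE)),
                    collapse = ",")))
  invisible(x)
}

#' Number of atoms in an atom list
#' @param atoms An [atom_list()].
#' @return Integer count.
#' @export
n_atoms <- function(atoms) length(atoms$element)

#' Translate all atoms by a fixed fractional vector
#'
#' Coordinates are wrapped back into [0, 1). The Patterson map of the
#' translated contents is identical to the original's.
#'
#' @param atoms An [atom_list()].
#' @param shift Length-3 fractional translation.
#' @return The translated [atom_list()].
#' @export
translate_atoms <- function(atoms, shift) {
  frac <- sweep(atoms$frac, 2, as.numeric(shift), "+") %% 1
  atom_list(atoms$element, frac, b_iso = atoms$b_iso, f = atoms$f,
            mass = atoms$mass, label = atoms$label, meta = atoms$meta)
}

#' Point-invert an atom list through a center
#'
#' Produces the centrosymmetric twin: every fractional coordinate x is
#' replaced by 2 * center - x (mod 1). The twin shares the original's
#' Patterson map exactly, which is the core ambiguity that fixed amino-acid
#' chirality lets the network resolve.
#'
#' @param atoms An [atom_list()].
#' @param center Fractional inversion center (default cell center).
#' @return The inverted [atom_list()].
#' @export
invert_atoms <- function(atoms, center = c(0.5, 0.5, 0.5)) {
  frac <- sweep(-atoms$frac, 2, 2 * as.numeric(center), "+") %% 1
  atom_list(atoms$element, frac, b_iso = atoms$b_iso, f = atoms$f,
            mass = atoms$mass, label = atoms$label, meta = atoms$meta)
}
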