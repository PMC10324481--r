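#' Read protein atoms from a PDB file
#'
#' Parses ATOM records (HETATM records — waters, ligands, ions — are
#' dropped, i.e. non-protein atoms are removed). Element symbols come from
#' the element column when present, with a fallback heuristic on the atom
#' name (leading digits stripped, first alphabetic character; two-letter
#' elements SE/FE etc. recognised). Parsing is delegated to
#' \code{bio3d::read.pdb} after a light record sanity scan.
#'
#' @param path Path to a PDB file.
#' @return A data.frame of class \code{pdb_atoms} with columns
#'   \code{atom, altloc, resname, chain, resno, insert, x, y, z, element}.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec == "ATOM  ")
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed ATOM record at line %d: too short", i),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("malformed ATOM record at line %d: bad coordinates", i),
           call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  element <- toupper(trimws(at$elesy))
  element[is.na(element)] <- ""
  fallback <- !element %in% names(.element_f)
  if (any(fallback)) {
    nm <- toupper(gsub("^[0-9']+", "", trimws(at$elety[fallback])))
    two <- substr(nm, 1, 2)
    guess <- ifelse(two %in% c("SE", "FE", "ZN", "MG"), two,
                    substr(nm, 1, 1))
    element[fallback] <- guess
  }
  out <- data.frame(atom = trimws(at$elety),
                    altloc = trimws(at$alt),
                    resname = trimws(at$resid),
                    chain = trimws(at$chain),
                    resno = at$resno,
                    insert = ifelse(is.na(at$insert), "", trimws(at$insert)),
                    x = at$x, y = at$y, z = at$z,
                    element = element, stringsAsFactors = FALSE)
  class(out) <- c("pdb_atoms", "data.frame")
  out
}

#' Extract one dipeptide from a parsed structure
#'
#' Collects every heavy atom of two sequence-adjacent residues (same chain,
#' consecutive residue numbering). The first alternate conformer is kept
#' when altloc duplication is present; hydrogens are excluded. A numbering
#' gap at the requested position is treated as a chain break and raises an
#' error.
#'
#' @param structure A \code{pdb_atoms} data.frame from [read_pdb()].
#' @param start_resno Residue number of the first residue of the pair.
#' @param chain Chain identifier; defaults to the first chain present.
#' @param cell A [unit_cell()] the fractional coordinates refer to.
#' @param b_iso Isotropic B (A^2) assigned to every atom.
#' @return An [atom_list()] with residue metadata.
#' @export
extract_dipeptide <- function(structure, start_resno, chain = NULL,
                              cell = unit_cell(10), b_iso = 15) {
  stopifnot(inherits(structure, "pdb_atoms"))
  if (is.null(chain)) chain <- structure$chain[1]
  sel <- structure[structure$chain == chain &
                     structure$resno %in% c(start_resno, start_resno + 1L), ,
                   drop = FALSE]
  sel <- sel[sel$element != "H", , drop = FALSE]
  # first altloc only
  key <- paste(sel$resno, sel$atom)
  sel <- sel[!duplicated(key), , drop = FALSE]
  have <- sort(unique(as.integer(sel$resno)))
  start_resno <- as.integer(start_resno)
  if (!identical(have, c(start_resno, start_resno + 1L))) {
    stop("chain break or missing residue at position ", start_resno,
         " of chain ", chain, call. = FALSE)
  }
  meta <- data.frame(atom = sel$atom, resname = sel$resname,
                     resno = match(sel$resno, have), chain = chain,
                     stringsAsFactors = FALSE)
  frac <- sweep(as.matrix(sel[, c("x", "y", "z")]), 2,
                c(cell$a, cell$b, cell$c), "/")
  atom_list(sel$element, frac, b_iso = b_iso,
            label = sprintf("%s:%s%d", chain,
                            paste(unique(sel$resname), collapse = "-"),
                            start_resno),
            meta = meta)
}

# random (chain, resno) with an adjacent successor; NULL if none
.random_dipeptide_position <- function(structure) {
  keys <- unique(structure[, c("chain", "resno")])
  ok <- merge(keys, transform(keys, resno = resno - 1L))
  if (nrow(ok) == 0L) return(NULL)
  row <- ok[sample.int(nrow(ok), 1L), ]
  list(chain = row$chain, resno = row$resno)
}
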