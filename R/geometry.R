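# Internal-coordinate (Z-matrix) machinery for building idealized peptide
# geometry, and the heavy-atom topology of the 20 standard residues.

#' Dihedral angle of four points
#' @param a,b,c,d Length-3 Cartesian coordinates.
#' @return Signed torsion angle in degrees, in (-180, 180].
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  .wrap_phase(deg)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Natural extension of reference frame: place atom D bonded to C with bond
# length r, angle B-C-D theta (deg), torsion A-B-C-D tau (deg).
.nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Side-chain Z-matrix rows per residue: atom, (torsion-ref a1, angle-ref a2,
# bond-parent a3), bond length (A), bond angle (deg), torsion spec. Torsion
# "chiN" is sampled uniformly; "chiN+x" adds a fixed offset; a bare number is
# a fixed torsion. Geometry uses generic ideal bond lengths/angles; rings are
# closed approximately, which is sufficient for plausible scattering targets.
.sidechain_zmat <- local({
  z <- function(...) {
    if (length(c(...)) == 0L) {
      return(data.frame(atom = character(), a1 = character(),
                        a2 = character(), a3 = character(),
                        bond = numeric(), angle = numeric(),
                        tors = character(), stringsAsFactors = FALSE))
    }
    m <- matrix(c(...), ncol = 7, byrow = TRUE)
    data.frame(atom = m[, 1], a1 = m[, 2], a2 = m[, 3], a3 = m[, 4],
               bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
               tors = m[, 7], stringsAsFactors = FALSE)
  }
  cb <- c("CB", "N", "C", "CA", "1.530", "110.1", "CHIR")  # chirality-fixing
  list(
    GLY = z(),
    ALA = z(cb),
    SER = z(cb, "OG", "N", "CA", "CB", 1.417, 110.8, "chi1"),
    CYS = z(cb, "SG", "N", "CA", "CB", 1.808, 113.8, "chi1"),
    THR = z(cb, "OG1", "N", "CA", "CB", 1.433, 109.6, "chi1",
                "CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120"),
    VAL = z(cb, "CG1", "N", "CA", "CB", 1.527, 110.5, "chi1",
                "CG2", "N", "CA", "CB", 1.527, 110.5, "chi1+120"),
    LEU = z(cb, "CG", "N", "CA", "CB", 1.530, 116.3, "chi1",
                "CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2",
                "CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+120"),
    ILE = z(cb, "CG1", "N", "CA", "CB", 1.530, 110.4, "chi1",
                "CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120",
                "CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2"),
    MET = z(cb, "CG", "N", "CA", "CB", 1.520, 114.1, "chi1",
                "SD", "CA", "CB", "CG", 1.803, 112.7, "chi2",
                "CE", "CB", "CG", "SD", 1.791, 100.2, "chi3"),
    PRO = z("CB", "N", "C", "CA", 1.530, 103.0, "CHIR",
            "CG", "N", "CA", "CB", 1.492, 104.5, 30,
            "CD", "CA", "CB", "CG", 1.503, 106.1, -35),
    PHE = z(cb, "CG", "N", "CA", "CB", 1.502, 113.8, "chi1",
                "CD1", "CA", "CB", "CG", 1.384, 120.8, "chi2",
                "CD2", "CA", "CB", "CG", 1.384, 120.8, "chi2+180",
                "CE1", "CB", "CG", "CD1", 1.384, 120.8, 180,
                "CE2", "CB", "CG", "CD2", 1.384, 120.8, 180,
                "CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0),
    TYR = z(cb, "CG", "N", "CA", "CB", 1.512, 113.9, "chi1",
                "CD1", "CA", "CB", "CG", 1.389, 120.8, "chi2",
                "CD2", "CA", "CB", "CG", 1.389, 120.8, "chi2+180",
                "CE1", "CB", "CG", "CD1", 1.382, 121.1, 180,
                "CE2", "CB", "CG", "CD2", 1.382, 121.1, 180,
                "CZ", "CG", "CD1", "CE1", 1.378, 119.6, 0,
                "OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180),
    TRP = z(cb, "CG", "N", "CA", "CB", 1.498, 113.6, "chi1",
                "CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2",
                "CD2", "CA", "CB", "CG", 1.433, 126.8, "chi2+180",
                "NE1", "CD2", "CG", "CD1", 1.374, 110.2, 0,
                "CE2", "CD1", "CG", "CD2", 1.409, 107.2, 0,
                "CE3", "CD1", "CG", "CD2", 1.398, 133.9, 180,
                "CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180,
                "CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180,
                "CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0),
    ASP = z(cb, "CG", "N", "CA", "CB", 1.516, 112.6, "chi1",
                "OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2",
                "OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180"),
    ASN = z(cb, "CG", "N", "CA", "CB", 1.516, 112.6, "chi1",
                "OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2",
                "ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180"),
    GLU = z(cb, "CG", "N", "CA", "CB", 1.520, 114.1, "chi1",
                "CD", "CA", "CB", "CG", 1.516, 112.6, "chi2",
                "OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3",
                "OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180"),
    GLN = z(cb, "CG", "N", "CA", "CB", 1.520, 114.1, "chi1",
                "CD", "CA", "CB", "CG", 1.516, 112.6, "chi2",
                "OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3",
                "NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180"),
    LYS = z(cb, "CG", "N", "CA", "CB", 1.520, 114.1, "chi1",
                "CD", "CA", "CB", "CG", 1.520, 111.3, "chi2",
                "CE", "CB", "CG", "CD", 1.520, 111.3, "chi3",
                "NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4"),
    ARG = z(cb, "CG", "N", "CA", "CB", 1.520, 114.1, "chi1",
                "CD", "CA", "CB", "CG", 1.520, 111.3, "chi2",
                "NE", "CB", "CG", "CD", 1.461, 112.0, "chi3",
                "CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4",
                "NH1", "CD", "NE", "CZ", 1.326, 120.0, 0,
                "NH2", "CD", "NE", "CZ", 1.326, 120.0, 180),
    HIS = z(cb, "CG", "N", "CA", "CB", 1.492, 113.8, "chi1",
                "ND1", "CA", "CB", "CG", 1.380, 122.7, "chi2",
                "CD2", "CA", "CB", "CG", 1.354, 131.0, "chi2+180",
                "CE1", "CD2", "CG", "ND1", 1.321, 109.0, 0,
                "NE2", "ND1", "CG", "CD2", 1.374, 107.0, 0)
  )
})

# Residue three-letter codes recognised by the generator.
residue_alphabet <- function() names(.sidechain_zmat)

# one- to three-letter residue code, tolerant of either form
.res3 <- function(code) {
  code <- toupper(code)
  one <- c(G = "GLY", A = "ALA", S = "SER", C = "CYS", T = "THR", V = "VAL",
           L = "LEU", I = "ILE", M = "MET", P = "PRO", F = "PHE", Y = "TYR",
           W = "TRP", D = "ASP", N = "ASN", E = "GLU", Q = "GLN", K = "LYS",
           R = "ARG", H = "HIS")
  out <- ifelse(nchar(code) == 1L, unname(one[code]), code)
  bad <- is.na(out) | !(out %in% residue_alphabet())
  if (any(bad)) {
    stop("unknown residue code(s): ", paste(code[bad], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Heavy-atom count of a standard residue
#' @param res Residue code, one- or three-letter.
#' @return Integer number of non-hydrogen atoms (backbone N, CA, C, O plus
#'   side chain).
#' @export
residue_heavy_atoms <- function(res) {
  res <- .res3(res)
  vapply(res, function(r) 4L + nrow(.sidechain_zmat[[r]]), integer(1))
}

# Torsion value for a Z-matrix spec string given sampled chi values.
.tors_value <- function(spec, chis, chir) {
  if (spec == "CHIR") return(chir)
  if (grepl("^chi", spec)) {
    m <- regmatches(spec, regexec("^chi([0-9]+)([+-][0-9.]+)?$", spec))[[1]]
    base <- chis[as.integer(m[2])]
    off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
    return(base + off)
  }
  as.numeric(spec)
}

# Improper torsion N-C-CA-CB fixing the L configuration at CA. The sign was
# validated against the chiral-volume criterion det[N-CA, C-CA, CB-CA] > 0
# that holds for L-amino-acid reference coordinates.
.L_CHIR_TORSION <- 122.5

# Build one residue's side chain given backbone coordinates (named list of
# 3-vectors containing N, CA, C). Returns a named list of side-chain coords.
.build_sidechain <- function(res, bb, rng_chis) {
  zm <- .sidechain_zmat[[res]]
  coords <- bb
  if (nrow(zm) == 0L) return(list())
  out <- list()
  for (i in seq_len(nrow(zm))) {
    row <- zm[i, ]
    tau <- .tors_value(row$tors, rng_chis, .L_CHIR_TORSION)
    pos <- .nerf_place(coords[[row$a1]], coords[[row$a2]], coords[[row$a3]],
                       row$bond, row$angle, tau)
    coords[[row$atom]] <- pos
    out[[row$atom]] <- pos
  }
  out
}

#' Signed chiral volume at an alpha carbon
#'
#' \code{det[N - CA, C - CA, CB - CA]} in cubic Angstrom; positive for the
#' L configuration of a standard amino acid, negative for D.
#'
#' @param n,ca,c,cb Cartesian coordinates of the four atoms.
#' @return Signed volume (A^3).
#' @export
chiral_volume <- function(n, ca, c, cb) {
  M <- rbind(n - ca, c - ca, cb - ca)
  det(M)
}

#' Generate an idealized dipeptide conformer
#'
#' Builds the heavy atoms of two peptide-bonded residues from idealized
#' internal coordinates: standard bond lengths and angles, a trans peptide
#' bond (omega = 180 deg), backbone phi/psi drawn from broad alpha/beta
#' rectangles of the allowed region, side-chain torsions uniform on
#' (-180, 180], and the L configuration fixed at both alpha carbons. The
#' result is deterministic in \code{seed} and is centered by mass in the
#' given cell. It stands in for dipeptides excised from experimental PDB
#' entries when none are supplied.
#'
#' @param res1,res2 Residue codes (one- or three-letter).
#' @param seed Integer seed; same (pair, seed) gives bit-identical output.
#' @param cell A [unit_cell()] the fractional coordinates refer to
#'   (default 10 A cube).
#' @param b_iso Isotropic B (A^2) assigned to every atom.
#' @return An [atom_list()] with per-atom metadata (atom name, residue,
#'   residue number).
#' @export
synth_dipeptide <- function(res1, res2, seed = NULL, cell = unit_cell(10),
                            b_iso = 15) {
  res1 <- .res3(res1); res2 <- .res3(res2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  # backbone torsions: alpha-helical or extended rectangle, equal odds
  draw_phipsi <- function() {
    if (stats::runif(1) < 0.5) {
      c(phi = stats::runif(1, -100, -45), psi = stats::runif(1, -60, -10))
    } else {
      c(phi = stats::runif(1, -170, -90), psi = stats::runif(1, 100, 180))
    }
  }
  pp1 <- draw_phipsi(); pp2 <- draw_phipsi()
  chis1 <- stats::runif(5, -180, 180)
  chis2 <- stats::runif(5, -180, 180)

  co <- list()
  co$N1 <- c(0, 0, 0)
  co$CA1 <- c(1.458, 0, 0)
  co$C1 <- co$CA1 + 1.525 * c(-cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
  co$O1 <- .nerf_place(co$N1, co$CA1, co$C1, 1.231, 120.8, pp1["psi"] + 180)
  co$N2 <- .nerf_place(co$N1, co$CA1, co$C1, 1.329, 116.2, pp1["psi"])
  co$CA2 <- .nerf_place(co$CA1, co$C1, co$N2, 1.458, 121.7, 180)   # omega
  co$C2 <- .nerf_place(co$C1, co$N2, co$CA2, 1.525, 111.2, pp2["phi"])
  co$O2 <- .nerf_place(co$N2, co$CA2, co$C2, 1.231, 120.8, pp2["psi"] + 180)

  sc1 <- .build_sidechain(res1, list(N = co$N1, CA = co$CA1, C = co$C1),
                          chis1)
  sc2 <- .build_sidechain(res2, list(N = co$N2, CA = co$CA2, C = co$C2),
                          chis2)

  names1 <- c("N", "CA", "C", "O", names(sc1))
  names2 <- c("N", "CA", "C", "O", names(sc2))
  xyz <- rbind(do.call(rbind, c(list(co$N1, co$CA1, co$C1, co$O1), sc1)),
               do.call(rbind, c(list(co$N2, co$CA2, co$C2, co$O2), sc2)))
  meta <- data.frame(
    atom = c(names1, names2),
    resname = c(rep(res1, length(names1)), rep(res2, length(names2))),
    resno = c(rep(1L, length(names1)), rep(2L, length(names2))),
    chain = "A", stringsAsFactors = FALSE)
  elements <- substr(meta$atom, 1, 1)
  frac <- sweep(xyz, 2, c(cell$a, cell$b, cell$c), "/")
  atoms <- atom_list(elements, frac, b_iso = b_iso,
                     label = paste0(res1, "-", res2, if (!is.null(seed))
                       paste0("/s", seed) else ""),
                     meta = meta)
  center_by_mass(atoms, cell)
}
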