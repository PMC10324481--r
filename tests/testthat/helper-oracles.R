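# Independent brute-force oracles and shared fixtures. These deliberately
# avoid the package's vectorized/FFT code paths: structure factors by scalar
# direct summation, density by per-voxel complex sums over explicit Friedel
# pairs, Patterson by spatial circular autocorrelation.

random_atoms <- function(n, b_iso = 5) {
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  atom_list(elements, matrix(stats::runif(3 * n), n, 3), b_iso = b_iso,
            label = "random")
}

# scalar direct summation of Eq-(1)-style structure factors
bf_structure_factors <- function(atoms, cell, d_min) {
  rset <- enumerate_hkl(cell, d_min)
  df <- rset$refl
  amp <- numeric(nrow(df)); pha <- numeric(nrow(df))
  for (r in seq_len(nrow(df))) {
    Fc <- 0 + 0i
    for (j in seq_len(n_atoms(atoms))) {
      arg <- 2 * pi * (df$h[r] * atoms$frac[j, 1] +
                       df$k[r] * atoms$frac[j, 2] +
                       df$l[r] * atoms$frac[j, 3])
      g <- exp(-atoms$b_iso[j] / (4 * df$d[r]^2))
      Fc <- Fc + atoms$f[j] * g * complex(argument = arg)
    }
    amp[r] <- Mod(Fc)
    pha[r] <- Arg(Fc) * 180 / pi
  }
  list(refl = df, amp = amp, phase_deg = pha)
}

# per-voxel complex summation of the inverse transform, Friedel mates
# enumerated explicitly
bf_density <- function(rset, grid) {
  df <- rset$refl
  n <- c(grid$nx, grid$ny, grid$nz)
  Fc <- complex(modulus = df$amp, argument = df$phase_deg * pi / 180)
  H <- rbind(as.matrix(df[, c("h", "k", "l")]),
             -as.matrix(df[, c("h", "k", "l")]))
  Fall <- c(Fc, Conj(Fc))
  out <- array(0, n)
  for (iz in 0:(n[3] - 1)) for (iy in 0:(n[2] - 1)) for (ix in 0:(n[1] - 1)) {
    ph <- -2 * pi * (H[, 1] * ix / n[1] + H[, 2] * iy / n[2] +
                     H[, 3] * iz / n[3])
    out[ix + 1, iy + 1, iz + 1] <-
      Re(sum(Fall * complex(argument = ph))) / rset$cell$volume
  }
  out
}

# circular (periodic) spatial autocorrelation of a 3D array
bf_autocorrelation <- function(rho) {
  n <- dim(rho)
  idx1 <- 0:(n[1] - 1); idx2 <- 0:(n[2] - 1); idx3 <- 0:(n[3] - 1)
  ac <- array(0, n)
  for (w in idx3) for (v in idx2) for (u in idx1) {
    ac[u + 1, v + 1, w + 1] <- sum(
      rho * rho[((idx1 + u) %% n[1]) + 1,
                ((idx2 + v) %% n[2]) + 1,
                ((idx3 + w) %% n[3]) + 1])
  }
  ac
}

# centrosymmetric image of a periodic map about the origin voxel
flip_map <- function(values) {
  n <- dim(values)
  values[c(1, n[1]:2), c(1, n[2]:2), c(1, n[3]:2)]
}

# a small two-residue PDB fixture (GLY then ALA) with decorations the
# parser must handle: a hydrogen, an altloc duplicate, a HETATM water and
# one atom with a blank element column
write_fixture_pdb <- function(path) {
  fmt <- function(serial, name, alt, res, chain, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00 10.00          %2s",
            serial, name, alt, res, chain, resno, x, y, z, elem)
  }
  lines <- c(
    "HEADER    SYNTHETIC FIXTURE",
    fmt(1, " N", " ", "GLY", "A", 1, 0.000, 0.000, 0.000, " N"),
    fmt(2, " CA", " ", "GLY", "A", 1, 1.458, 0.000, 0.000, " C"),
    fmt(3, " C", " ", "GLY", "A", 1, 2.009, 1.421, 0.000, " C"),
    fmt(4, " O", " ", "GLY", "A", 1, 1.251, 2.390, 0.000, " O"),
    fmt(5, " N", " ", "ALA", "A", 2, 3.332, 1.536, 0.000, " N"),
    fmt(6, " CA", "A", "ALA", "A", 2, 4.025, 2.810, 0.000, " C"),
    fmt(7, " CA", "B", "ALA", "A", 2, 4.125, 2.910, 0.100, " C"),
    fmt(8, " C", " ", "ALA", "A", 2, 5.531, 2.605, 0.000, " C"),
    fmt(9, " O", " ", "ALA", "A", 2, 6.010, 1.475, 0.000, " O"),
    fmt(10, " CB", " ", "ALA", "A", 2, 3.609, 3.602, 1.240, "  "),
    fmt(11, " HA", " ", "ALA", "A", 2, 3.800, 3.320, -0.880, " H"),
    sub("^ATOM  ", "HETATM",
        fmt(12, " O", " ", "HOH", "A", 101, 8.0, 8.0, 8.0, " O")),
    "END")
  writeLines(lines, path)
  path
}
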