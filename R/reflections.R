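#' Interplanar spacing for Miller indices in an orthogonal cell
#'
#' \code{d = 1 / sqrt(h^2/a^2 + k^2/b^2 + l^2/c^2)}. The (0,0,0) index
#' returns \code{Inf}.
#'
#' @param h,k,l Integer Miller indices (vectorized).
#' @param cell A [unit_cell()].
#' @return d-spacings in Angstrom.
#' @export
d_spacing <- function(h, k, l, cell) {
  s2 <- (h / cell$a)^2 + (k / cell$b)^2 + (l / cell$c)^2
  ifelse(s2 == 0, Inf, 1 / sqrt(s2))
}

# lexicographic (h,k,l) > (-h,-k,-l)?
.friedel_keep <- function(h, k, l) {
  (h > -h) | (h == -h & (k > -k | (k == -k & l >= -l)))
}

.new_reflection_set <- function(df, cell, d_min, friedel_unique = TRUE,
                                includes_f000 = FALSE) {
  rownames(df) <- NULL
  structure(list(refl = df, cell = cell, d_min = d_min,
                 friedel_unique = friedel_unique,
                 includes_f000 = includes_f000),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set: %d %sreflections to d_min = %.3g A%s>\n",
              nrow(x$refl), if (x$friedel_unique) "Friedel-unique " else "",
              x$d_min, if (x$includes_f000) " (+F000)" else ""))
  invisible(x)
}

#' Enumerate Friedel-unique Miller indices to a resolution limit
#'
#' Lists every (h,k,l) whose interplanar spacing satisfies
#' \code{d(h,k,l) >= d_min} (inclusive boundary), i.e. the index set fixed by
#' the radial extent of an observed diffraction pattern. Of each Friedel pair
#' only the lexicographically larger member is stored; (0,0,0) is excluded
#' unless \code{include_f000}.
#'
#' @param cell A [unit_cell()].
#' @param d_min High-resolution cutoff in Angstrom; must be positive.
#' @param include_f000 Keep the (0,0,0) term? Default \code{FALSE}
#'   (experimental data lack it, and maps synthesized without it have zero
#'   mean).
#' @return A \code{reflection_set} skeleton whose amplitudes and phases are
#'   \code{NA} until filled by [structure_factors()].
#' @export
enumerate_hkl <- function(cell, d_min, include_f000 = FALSE) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.numeric(d_min) || length(d_min) != 1L || d_min <= 0) {
    stop("d_min must be a positive number", call. = FALSE)
  }
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  d <- d_spacing(g$h, g$k, g$l, cell)
  keep <- d >= d_min & .friedel_keep(g$h, g$k, g$l)
  if (!include_f000) keep <- keep & !(g$h == 0 & g$k == 0 & g$l == 0)
  g <- g[keep, , drop = FALSE]
  d <- d[keep]
  ord <- order(-d, g$h, g$k, g$l)
  df <- data.frame(h = g$h[ord], k = g$k[ord], l = g$l[ord], d = d[ord],
                   amp = rep(NA_real_, length(ord)),
                   phase_deg = rep(NA_real_, length(ord)))
  .new_reflection_set(df, cell, d_min, friedel_unique = TRUE,
                      includes_f000 = include_f000)
}

# wrap phase in degrees to (-180, 180]
.wrap_phase <- function(p) {
  w <- ((p + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Structure factors of an atom list by direct summation
#'
#' Computes \code{F(h,k,l) = sum_j f_j g_j exp(+2 pi i (h x_j + k y_j + l
#' z_j))} over every Friedel-unique reflection to \code{d_min}, where
#' \code{f_j} is the point-scatterer weight and \code{g_j = exp(-B_j /
#' (4 d^2))} the isotropic displacement attenuation (\code{g_j = 1} at
#' (0,0,0)). Amplitude and phase (degrees, wrapped to (-180, 180]) are stored
#' per reflection.
#'
#' @param atoms A non-empty [atom_list()].
#' @param cell A [unit_cell()].
#' @param d_min Resolution cutoff in Angstrom.
#' @param include_f000 Include the forward-scattering term (equal to
#'   \code{sum(f_j)})? Default \code{FALSE}.
#' @return A \code{reflection_set} with amplitudes and phases filled in.
#' @export
structure_factors <- function(atoms, cell, d_min, include_f000 = FALSE) {
  if (!inherits(atoms, "atom_list") || n_atoms(atoms) == 0L) {
    stop("atoms must be a non-empty atom_list", call. = FALSE)
  }
  rset <- enumerate_hkl(cell, d_min, include_f000 = include_f000)
  df <- rset$refl
  if (nrow(df) == 0L) return(rset)
  H <- as.matrix(df[, c("h", "k", "l")])          # nref x 3
  phase <- H %*% t(atoms$frac)                     # nref x natom, in cycles
  s2 <- ifelse(is.finite(df$d), 1 / df$d^2, 0)     # 1/d^2 per reflection
  atten <- exp(-outer(s2, atoms$b_iso) / 4)        # nref x natom
  Fc <- (exp(2i * pi * phase) * atten) %*% atoms$f # complex nref x 1
  df$amp <- Mod(Fc)[, 1]
  df$phase_deg <- .wrap_phase(Arg(Fc)[, 1] * 180 / pi)
  # phase of a numerically-zero amplitude is meaningless; pin it to 0
  df$phase_deg[df$amp < 1e-12 * max(df$amp, 1)] <- 0
  .new_reflection_set(df, cell, d_min, friedel_unique = TRUE,
                      includes_f000 = include_f000)
}

#' Write a reflection set as tab-separated text
#'
#' Columns \code{h k l amplitude phase_deg}, preceded by comment header lines
#' recording the cell and resolution limit.
#'
#' @param rset A \code{reflection_set}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_reflections <- function(rset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell %.6g %.6g %.6g 90 90 90", rset$cell$a, rset$cell$b,
            rset$cell$c),
    sprintf("# d_min %.6g", rset$d_min),
    sprintf("# friedel_unique %s includes_f000 %s",
            rset$friedel_unique, rset$includes_f000),
    "h\tk\tl\tamplitude\tphase_deg"), con)
  utils::write.table(rset$refl[, c("h", "k", "l", "amp", "phase_deg")],
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a reflection set written by [write_reflections()]
#' @param path Input file path.
#' @return A \code{reflection_set}.
#' @export
read_reflections <- function(path) {
  hdr <- readLines(path, n = 3L)
  cellv <- as.numeric(strsplit(sub("^# cell ", "", hdr[1]), " ")[[1]])
  d_min <- as.numeric(sub("^# d_min ", "", hdr[2]))
  flags <- strsplit(sub("^# ", "", hdr[3]), " ")[[1]]
  df <- utils::read.table(path, skip = 4L, sep = "\t",
                          col.names = c("h", "k", "l", "amp", "phase_deg"))
  cell <- unit_cell(cellv[1], cellv[2], cellv[3])
  df$d <- d_spacing(df$h, df$k, df$l, cell)
  .new_reflection_set(df[, c("h", "k", "l", "d", "amp", "phase_deg")],
                      cell, d_min,
                      friedel_unique = as.logical(flags[2]),
                      includes_f000 = as.logical(flags[4]))
}
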