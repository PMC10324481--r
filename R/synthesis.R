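# Place Friedel-unique reflections (complex values) onto a full FFT grid,
# adding the conjugate at (-h,-k,-l). Values are accumulated, so a reflection
# landing on its own Friedel mate at an exact Nyquist index contributes
# F + conj(F) = 2 Re(F), which is what a real-valued synthesis requires there.
.fill_fgrid <- function(h, k, l, Fc, grid) {
  A <- array(0i, dim = c(grid$nx, grid$ny, grid$nz))
  idx1 <- cbind(h %% grid$nx, k %% grid$ny, l %% grid$nz) + 1L
  idx2 <- cbind((-h) %% grid$nx, (-k) %% grid$ny, (-l) %% grid$nz) + 1L
  for (i in seq_along(Fc)) {
    A[idx1[i, 1], idx1[i, 2], idx1[i, 3]] <-
      A[idx1[i, 1], idx1[i, 2], idx1[i, 3]] + Fc[i]
    A[idx2[i, 1], idx2[i, 2], idx2[i, 3]] <-
      A[idx2[i, 1], idx2[i, 2], idx2[i, 3]] + Conj(Fc[i])
  }
  # the (0,0,0) slot, if present in the input, was counted twice above
  zero <- h == 0 & k == 0 & l == 0
  if (any(zero)) A[1, 1, 1] <- A[1, 1, 1] - Conj(Fc[zero][1])
  A
}

.check_nyquist <- function(rset, grid, on_alias) {
  sp_ok <- all(grid$spacing <= rset$d_min / 2 + 1e-9)
  if (!sp_ok) {
    msg <- sprintf(
      "grid spacing (%.3g A) exceeds d_min/2 = %.3g A: synthesis will alias",
      max(grid$spacing), rset$d_min / 2)
    switch(on_alias,
           error = stop(msg, call. = FALSE),
           warn = warning(msg, call. = FALSE),
           allow = invisible(NULL))
  }
}

.complex_refl <- function(rset) {
  complex(modulus = rset$refl$amp,
          argument = rset$refl$phase_deg * pi / 180)
}

#' Electron density synthesis from structure factors
#'
#' Evaluates \code{rho(x,y,z) = (1/V) sum F(h,k,l) exp(-2 pi i (hx+ky+lz))}
#' at every voxel center of the grid, completing each stored Friedel-unique
#' reflection with its conjugate mate so that the synthesis is real. The
#' small imaginary residue left by floating-point arithmetic is checked
#' against \code{1e-8} of the map amplitude and discarded.
#'
#' @param rset A \code{reflection_set} with amplitudes and phases.
#' @param grid A [map_grid()] satisfying the Nyquist condition
#'   \code{spacing <= d_min / 2}.
#' @param on_alias What to do when the grid is too coarse: \code{"error"}
#'   (default), \code{"warn"} or \code{"allow"}.
#' @return A [voxel_map()] with role \code{"density"}.
#' @export
density_from_reflections <- function(rset, grid,
                                     on_alias = c("error", "warn", "allow")) {
  on_alias <- match.arg(on_alias)
  stopifnot(inherits(rset, "reflection_set"), inherits(grid, "map_grid"))
  .check_nyquist(rset, grid, on_alias)
  A <- .fill_fgrid(rset$refl$h, rset$refl$k, rset$refl$l,
                   .complex_refl(rset), grid)
  # forward DFT: sum_h A[h] exp(-2 pi i h x) at x = index/count
  rho <- stats::fft(A) / rset$cell$volume
  scale <- max(Mod(rho), .Machine$double.eps)
  if (max(abs(Im(rho))) > 1e-8 * scale) {
    stop("density synthesis produced a non-real map", call. = FALSE)
  }
  voxel_map(grid, array(Re(rho), dim(rho)), "density")
}

#' Patterson synthesis from structure-factor amplitudes
#'
#' Evaluates \code{P(u,v,w) = (1/V) sum |F(h,k,l)|^2 cos(2 pi (hu+kv+lw))}:
#' amplitudes are squared, phases ignored. The result is exactly real and
#' centrosymmetric about the origin voxel, and equals the circular
#' autocorrelation of the band-limited density scaled by \code{V / n_voxels}.
#'
#' @inheritParams density_from_reflections
#' @return A [voxel_map()] with role \code{"patterson"}.
#' @export
patterson_from_reflections <- function(rset, grid,
                                       on_alias = c("error", "warn", "allow")) {
  on_alias <- match.arg(on_alias)
  stopifnot(inherits(rset, "reflection_set"), inherits(grid, "map_grid"))
  .check_nyquist(rset, grid, on_alias)
  A <- .fill_fgrid(rset$refl$h, rset$refl$k, rset$refl$l,
                   complex(real = rset$refl$amp^2), grid)
  P <- Re(stats::fft(A)) / rset$cell$volume
  voxel_map(grid, array(P, dim(A)), "patterson")
}

#' Recover structure factors from a density map
#'
#' Forward discrete transform of the voxel values, truncated to
#' \code{d >= d_min}: \code{F(h,k,l) = (V / n_voxels) * sum_x rho(x)
#' exp(+2 pi i h.x)}. Inverse of [density_from_reflections()] on the retained
#' reflection set; used by the evaluator to obtain the phases of predicted
#' densities.
#'
#' @param map A [voxel_map()] with role \code{"density"}.
#' @param d_min Resolution cutoff in Angstrom.
#' @param include_f000 Keep the (0,0,0) coefficient (the map sum)?
#' @return A \code{reflection_set}.
#' @export
reflections_from_density <- function(map, d_min, include_f000 = FALSE) {
  stopifnot(inherits(map, "voxel_map"))
  grid <- map$grid
  cell <- grid$cell
  nvox <- grid$nx * grid$ny * grid$nz
  Fgrid <- stats::fft(map$values, inverse = TRUE) * cell$volume / nvox
  rset <- enumerate_hkl(cell, d_min, include_f000 = include_f000)
  df <- rset$refl
  if (nrow(df)) {
    idx <- cbind(df$h %% grid$nx, df$k %% grid$ny, df$l %% grid$nz) + 1L
    Fc <- Fgrid[idx]
    df$amp <- Mod(Fc)
    df$phase_deg <- .wrap_phase(Arg(Fc) * 180 / pi)
    df$phase_deg[df$amp < 1e-12 * max(df$amp, 1)] <- 0
  }
  .new_reflection_set(df, cell, d_min, friedel_unique = TRUE,
                      includes_f000 = include_f000)
}
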