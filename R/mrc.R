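# Minimal CCP4/MRC (mode 2, float32) map reader/writer for orthogonal P1
# cells with the fixed axis order X (fastest), Y, Z (slowest) = columns,
# rows, sections, which matches R's column-major array layout directly.

#' Write a voxel map as a CCP4/MRC file
#'
#' Mode-2 (32-bit float) maps with MAPC/MAPR/MAPS = 1/2/3 and the full cell
#' sampled from the origin. Cell lengths and grid counts are preserved
#' exactly; values survive the float32 round trip to about 1e-7 relative.
#'
#' @param map A [voxel_map()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "voxel_map"))
  g <- map$grid
  v <- as.vector(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(c(g$nx, g$ny, g$nz))               # NX NY NZ
  wi(2)                                 # MODE 2: float32
  wi(c(0, 0, 0))                        # NXSTART NYSTART NZSTART
  wi(c(g$nx, g$ny, g$nz))               # MX MY MZ
  wf(c(g$cell$a, g$cell$b, g$cell$c))   # CELLA
  wf(c(90, 90, 90))                     # CELLB
  wi(c(1, 2, 3))                        # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))        # DMIN DMAX DMEAN
  wi(1)                                 # ISPG (P1)
  wi(0)                                 # NSYMBT
  wi(rep(0, 25))                        # EXTRA
  wf(c(0, 0, 0))                        # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))                      # RMS
  wi(0)                                 # NLABL
  writeBin(raw(800), con)               # labels
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC map written with the package's conventions
#'
#' Accepts mode-2 maps with orthogonal (90/90/90) cells and axis order
#' MAPC/MAPR/MAPS = 1/2/3; anything else raises an unsupported-format
#' error. The full-cell sampling (MX = NX etc.) is asserted.
#'
#' @param path Input file.
#' @param role Map role for the returned [voxel_map()].
#' @return A [voxel_map()].
#' @export
read_map <- function(path, role = c("density", "patterson")) {
  role <- match.arg(role)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode, call. = FALSE)
  ri(3)                                  # starts
  mxyz <- ri(3)
  cella <- rf(3)
  cellb <- rf(3)
  maps <- ri(3)
  if (any(abs(cellb - 90) > 1e-4)) {
    stop("unsupported format: non-orthogonal cell", call. = FALSE)
  }
  if (!identical(maps, c(1L, 2L, 3L))) {
    stop("unsupported format: axis order must be X,Y,Z (1,2,3)",
         call. = FALSE)
  }
  if (!identical(nxyz, mxyz)) {
    stop("unsupported format: map must sample the full cell",
         call. = FALSE)
  }
  seek(con, 1024)
  v <- rf(prod(nxyz))
  grid <- map_grid(unit_cell(cella[1], cella[2], cella[3]),
                   nxyz[1], nxyz[2], nxyz[3])
  voxel_map(grid, array(v, nxyz), role)
}
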