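## Minimal CCP4/MRC (MRC2014) map I/O, mode 2 (float32), orthogonal cells,
## treated as a full P1 cell. No R package in the dependency set reads MRC
## maps, so the 1024-byte header is handled directly.

#' Write a density grid as a CCP4/MRC map (mode 2)
#'
#' @param grid a [density_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(grid$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NC, NR, NS
  wi(2)                      # MODE 2: float32
  wi(c(0, 0, 0))             # NCSTART, NRSTART, NSSTART
  wi(d)                      # MX, MY, MZ (sampling = grid size: full cell)
  wf(grid$cell)              # CELLA
  wf(c(90, 90, 90))          # CELLB (orthogonal only)
  wi(c(1, 2, 3))             # MAPC, MAPR, MAPS
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))  # DMIN, DMAX, DMEAN
  wi(1)                      # ISPG = P1
  wi(0)                      # NSYMBT
  wi(rep(0, 25))             # EXTRA (words 25-49)
  wf(grid$origin)            # ORIGIN (MRC2014 words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sqrt(mean((v - mean(v))^2)))  # RMS
  wi(1)                      # NLABL
  lab <- sprintf("%-80s", "Created by natrace")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720, eos = NULL)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC map as a density grid
#'
#' Supports mode-2 (float32) maps with orthogonal cells. Axis permutations
#' (MAPC/MAPR/MAPS) and non-zero start indices are honoured; the map is
#' treated as covering a full P1 cell.
#'
#' @param path map file path.
#' @return A [density_grid()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  ncrs <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) maps are supported")
  start <- ri(3)
  mxyz <- ri(3)
  cella <- rf(3)
  cellb <- rf(3)
  if (max(abs(cellb - 90)) > 1e-3)
    stop("only orthogonal cells are supported")
  mapcrs <- ri(3)
  ri(3)            # dmin dmax dmean (skip; recomputed)
  ri(1)            # ispg
  nsymbt <- ri(1)
  ri(25)
  origin <- rf(3)
  readBin(con, "raw", n = 4)  # MAP magic
  readBin(con, "raw", n = 4)  # MACHST
  rf(1)            # rms
  ri(1)            # nlabl
  readBin(con, "raw", n = 800)
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  v <- rf(prod(ncrs))
  arr <- array(v, dim = ncrs)
  # permute from column/row/section storage to x, y, z axis order
  perm <- order(mapcrs)            # position of axis x, y, z in (C, R, S)
  arr <- aperm(arr, perm)
  dims <- dim(arr)
  spacing <- cella / mxyz
  org <- origin + start[perm] * spacing
  density_grid(arr, spacing, org)
}
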