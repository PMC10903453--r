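# Minimal MRC2014 reader/writer for label volumes. Mode 0 (signed 8-bit)
# is used for labels; modes 1 (int16) and 2 (float32) are also read.
# MRC cell dimensions are conventionally in Angstrom; voxel sizes are
# converted from/to nm at the boundary.

#' Write a label volume as MRC2014
#'
#' Writes mode 0 (8-bit signed) labels with the voxel size recorded in the
#' header cell dimensions (nm converted to Angstrom) and the world origin
#' in the origin fields.
#'
#' @param volume A [label_volume()].
#' @param path Output path (conventionally `.mrc`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  g <- volume$grid
  if (max(g) > 127L) abort_param("labels above 127 cannot be stored in 8-bit MRC")
  d <- dim(g)
  h_ang <- volume$voxel_nm * 10
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(0L)                     # mode 0: int8
  wi(c(0L, 0L, 0L))          # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * h_ang)              # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))  # dmin dmax dmean
  wi(0L)                     # ispg
  wi(0L)                     # nsymbt
  writeBin(raw(100L), con)   # extra
  wf(volume$origin_nm * 10)  # origin (Angstrom)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(sd(as.numeric(g)))      # rms
  wi(1L)                     # nlabl
  lab <- "cristamorph label volume"
  writeChar(sprintf("%-80s", lab), con, nchars = 80L, eos = NULL)
  writeBin(raw(9L * 80L), con)
  writeBin(as.integer(g), con, size = 1L)
  invisible(path)
}

#' Read an MRC2014 volume as a label volume
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32, rounded to integer
#' labels). The voxel size is derived from the cell dimensions.
#'
#' @param path Path to an `.mrc` file.
#' @return A [label_volume()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_param("file '%s' does not exist", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  ri(3L)                     # nstart
  m <- ri(3L)
  cella <- rf(3L)
  rf(3L)                     # cellb
  ri(3L)                     # mapc/r/s
  rf(3L)                     # dmin dmax dmean
  ri(1L); ri(1L)             # ispg nsymbt
  readBin(con, "raw", n = 100L)
  origin <- rf(3L)
  readBin(con, "raw", n = 4L)  # MAP
  readBin(con, "raw", n = 4L)  # machst
  rf(1L)                     # rms
  ri(1L)                     # nlabl
  readBin(con, "raw", n = 800L)
  n <- prod(d)
  vals <- switch(as.character(mode),
    "0" = as.integer(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.integer(readBin(con, "integer", n = n, size = 2L, endian = "little")),
    "2" = as.integer(round(readBin(con, "numeric", n = n, size = 4L, endian = "little"))),
    abort_param("unsupported MRC mode %d", mode)
  )
  voxel_nm <- cella[1L] / max(m[1L], 1L) / 10
  label_volume(array(vals, dim = d), voxel_nm = voxel_nm,
               origin_nm = origin / 10)
}
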