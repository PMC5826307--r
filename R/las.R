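# Minimal binary LAS 1.x I/O.  Only the coordinates are used by this
# package, so the reader extracts X/Y/Z from any point record format whose
# records begin with three int32 words (formats 0-10 all do), and the writer
# emits LAS 1.2 / point format 0.

#' Read coordinates from a binary LAS file
#'
#' Parses the LAS public header block, applies the scale and offset, and
#' returns the XYZ coordinates.  All point record formats whose records
#' start with the standard three scaled int32 coordinates are accepted;
#' attributes beyond XYZ are ignored.
#'
#' @param path LAS file path.
#' @return numeric matrix with columns x, y, z (metres, georeferenced).
#' @export
read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", 4L))
  if (sig != "LASF") stop(sprintf("'%s' is not a LAS file", path))
  readBin(con, "raw", 20L)                                  # source id .. GUID
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  readBin(con, "raw", 64L)                                  # system/software id
  readBin(con, "raw", 4L)                                   # day/year
  readBin(con, "integer", 1L, size = 2L, signed = FALSE)    # header size
  offset_to_points <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 4L)                    # number of VLRs
  fmt <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  reclen <- readBin(con, "integer", 1L, size = 2L, signed = FALSE)
  npts <- readBin(con, "integer", 1L, size = 4L)
  if (is.na(npts) || npts < 0) stop("LAS point count exceeds supported range")
  readBin(con, "integer", 5L, size = 4L)                    # points by return
  sc <- readBin(con, "double", 6L)                          # scales, offsets
  if (fmt > 127L) {
    stop(sprintf("'%s' uses compressed LAZ point records; not supported", path))
  }
  if (reclen < 12L) stop("invalid LAS point record length")
  seek(con, where = offset_to_points, origin = "start")
  raw_all <- readBin(con, "raw", n = npts * reclen)
  if (length(raw_all) < npts * reclen) stop("truncated LAS point data")
  rec <- matrix(raw_all, nrow = reclen)
  xyz_raw <- as.vector(rec[1:12, , drop = FALSE])
  ints <- readBin(xyz_raw, "integer", n = 3L * npts, size = 4L)
  m <- matrix(ints, ncol = 3L, byrow = TRUE)
  cbind(x = m[, 1] * sc[1] + sc[4],
        y = m[, 2] * sc[2] + sc[5],
        z = m[, 3] * sc[3] + sc[6])
}

#' Write coordinates to a binary LAS 1.2 file
#'
#' Emits point record format 0 with a coordinate resolution of 1 mm.
#'
#' @param points n x 3 numeric matrix (x, y, z in metres).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_las <- function(points, path) {
  points <- as.matrix(points)[, 1:3, drop = FALSE]
  n <- nrow(points)
  scale <- c(0.001, 0.001, 0.001)
  off <- apply(points, 2, min)
  ints <- round(sweep(sweep(points, 2, off), 2, scale, "/"))
  if (any(abs(ints) >= 2^31)) stop("coordinates out of range for LAS int32")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LASF"), con)
  writeBin(as.integer(0), con, size = 2L)                   # source id
  writeBin(as.integer(0), con, size = 2L)                   # global encoding
  writeBin(raw(16L), con)                                   # GUID
  writeBin(as.integer(c(1L, 2L)), con, size = 1L)           # version 1.2
  sysid <- raw(32L); gensw <- raw(32L)
  id <- charToRaw("crownarch"); sysid[seq_along(id)] <- id
  gensw[seq_along(id)] <- id
  writeBin(sysid, con); writeBin(gensw, con)
  writeBin(as.integer(c(1L, 2026L)), con, size = 2L)        # day, year
  writeBin(as.integer(227L), con, size = 2L)                # header size
  writeBin(as.integer(227L), con, size = 4L)                # offset to points
  writeBin(as.integer(0L), con, size = 4L)                  # number of VLRs
  writeBin(as.integer(0L), con, size = 1L)                  # point format 0
  writeBin(as.integer(20L), con, size = 2L)                 # record length
  writeBin(as.integer(n), con, size = 4L)
  writeBin(as.integer(c(n, 0L, 0L, 0L, 0L)), con, size = 4L)
  writeBin(as.double(c(scale, off)), con)
  rng <- apply(points, 2, range)
  writeBin(as.double(c(rng[2, 1], rng[1, 1], rng[2, 2],
                       rng[1, 2], rng[2, 3], rng[1, 3])), con)
  # point records: X Y Z int32, then 8 zero bytes of attributes
  tail8 <- raw(8L)        # intensity(2) flags(1) class(1) angle(1) user(1) source(2)
  tail8[3] <- as.raw(9L)  # return number 1 of 1
  rec <- vapply(seq_len(n), function(i) {
    c(writeBin(as.integer(ints[i, ]), raw(), size = 4L), tail8)
  }, raw(20L))
  writeBin(as.vector(rec), con)
  invisible(path)
}
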