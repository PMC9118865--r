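#' Read a LAS point-cloud file (geometry only)
#'
#' Minimal LAS 1.2--1.4 reader for point record formats 0--3. Only the scaled
#' coordinates are returned: each record's stored integer X/Y/Z is mapped to
#' `scale * raw + offset` per the header. Classification, intensity and return
#' attributes are dropped -- the measurement pipeline is purely geometric.
#'
#' @param path path to a `.las` file.
#' @return A `pointcloud` tibble in file order.
#' @export
read_las <- function(path) {
  if (!file.exists(path)) stop("read_las: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 375)
  if (length(hdr_raw) < 227) stop("read_las: file too short for a LAS header")
  if (rawToChar(hdr_raw[1:4]) != "LASF") stop("read_las: bad magic, not a LAS file")

  u16 <- function(off) readBin(hdr_raw[(off + 1):(off + 2)], "integer",
                               size = 2, endian = "little", signed = FALSE)
  u32 <- function(off) readBin(hdr_raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = "little")
  f64 <- function(off) readBin(hdr_raw[(off + 1):(off + 8)], "double",
                               size = 8, endian = "little")

  ver_major <- as.integer(hdr_raw[25])
  ver_minor <- as.integer(hdr_raw[26])
  if (ver_major != 1 || ver_minor < 2) {
    stop("read_las: unsupported LAS version ", ver_major, ".", ver_minor)
  }
  data_offset <- u32(96)
  pdf <- as.integer(hdr_raw[105])
  compressed <- bitwAnd(pdf, 0x80L) != 0L
  pdf <- bitwAnd(pdf, 0x7FL)
  if (compressed) stop("read_las: LAZ-compressed point data is not supported")
  if (pdf > 3) {
    stop("read_las: unsupported point data format ", pdf, " (formats 0-3 supported)")
  }
  rec_len <- u16(105)
  n_pts <- u32(107)
  if (n_pts == 0 && ver_minor >= 4 && length(hdr_raw) >= 255) {
    lo <- u32(247)
    hi <- u32(251)
    if (hi != 0) stop("read_las: point count exceeds supported range")
    n_pts <- lo
  }
  scale <- c(f64(131), f64(139), f64(147))
  offset <- c(f64(155), f64(163), f64(171))

  if (n_pts == 0) return(pointcloud())

  seek(con, where = data_offset, origin = "start")
  blob <- readBin(con, "raw", n = rec_len * n_pts)
  if (length(blob) < rec_len * n_pts) stop("read_las: point data section truncated")

  coord_int <- function(axis_off) {
    idx <- as.vector(outer(seq_len(4), (seq_len(n_pts) - 1) * rec_len + axis_off, "+"))
    readBin(blob[idx], "integer", n = n_pts, size = 4, endian = "little")
  }
  pointcloud(
    x = scale[1] * coord_int(0) + offset[1],
    y = scale[2] * coord_int(4) + offset[2],
    z = scale[3] * coord_int(8) + offset[3]
  )
}

#' Convert a LAS file to PCD
#'
#' Reads the LAS geometry (see [read_las()]) and writes it as a PCD file, the
#' working format of the rest of the pipeline.
#'
#' @param las_path input `.las` path.
#' @param pcd_path output `.pcd` path.
#' @param dialect PCD data dialect, `"ascii"` or `"binary"`.
#' @return Number of points converted, invisibly.
#' @export
las_to_pcd <- function(las_path, pcd_path, dialect = "binary") {
  cloud <- read_las(las_path)
  write_pcd(cloud, pcd_path, dialect = dialect)
  invisible(nrow(cloud))
}
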