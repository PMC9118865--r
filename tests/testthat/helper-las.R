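# minimal LAS 1.2 writer (point format 0) used to build fixtures at test
# time; LAS writing is deliberately not part of the package API

write_las_fixture <- function(path, x, y, z,
                              scale = c(0.001, 0.001, 0.001),
                              offset = c(0, 0, 0)) {
  n <- length(x)
  xi <- as.integer(round((x - offset[1]) / scale[1]))
  yi <- as.integer(round((y - offset[2]) / scale[2]))
  zi <- as.integer(round((z - offset[3]) / scale[3]))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_f64 <- function(v) writeBin(as.double(v), con, size = 8, endian = "little")
  w_u8 <- function(v) writeBin(as.raw(v), con)

  writeChar("LASF", con, nchars = 4, eos = NULL)
  w_u16(0)                      # file source id
  w_u16(0)                      # global encoding
  w_u8(rep(0, 16))              # project GUID
  w_u8(c(1, 2))                 # version 1.2
  w_u8(rep(0, 32))              # system identifier
  w_u8(rep(0, 32))              # generating software
  w_u16(1)                      # creation day
  w_u16(2021)                   # creation year
  w_u16(227)                    # header size
  w_u32(227)                    # offset to point data
  w_u32(0)                      # number of VLRs
  w_u8(0)                       # point data format 0
  w_u16(20)                     # point record length
  w_u32(n)                      # number of point records
  w_u32(c(n, 0, 0, 0, 0))       # points by return
  w_f64(scale)                  # x/y/z scale
  w_f64(offset)                 # x/y/z offset
  if (n > 0) {
    w_f64(c(max(x), min(x), max(y), min(y), max(z), min(z)))
  } else {
    w_f64(rep(0, 6))
  }
  for (i in seq_len(n)) {
    w_u32(c(xi[i], yi[i], zi[i]))
    w_u16(0)                    # intensity
    w_u8(c(1, 0))               # return bits, classification
    w_u8(c(0, 0))               # scan angle, user data
    w_u16(0)                    # point source id
  }
  invisible(path)
}
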