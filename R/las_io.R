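#' Read a LAS point cloud
#'
#' Minimal reader for uncompressed LAS 1.0-1.4 files with point data
#' record formats 0-5 (the fields used here - coordinates, return
#' number, classification - share a common layout across those
#' formats). Compressed LAZ is not supported and is rejected with an
#' informative error.
#'
#' @param path Path to a `.las` file.
#' @param first_returns_only If `TRUE`, keep only points with
#'   `return_number == 1`.
#' @return A [point_cloud()]; empty files yield an empty cloud.
#' @seealso [write_las()]
#' @export
read_point_cloud <- function(path, first_returns_only = FALSE) {
  if (!file.exists(path))
    stop(sprintf("point cloud file does not exist: %s", path), call. = FALSE)
  sz <- file.info(path)$size
  if (sz < 227)
    stop(sprintf("not a valid LAS file (too short): %s", path), call. = FALSE)
  raw <- readBin(path, "raw", n = sz)
  sig <- rawToChar(raw[1:4])
  if (sig == "LASF" && sz >= 231 &&
      identical(rawToChar(raw[228:231]), "LASz"))
    stop(sprintf("compressed LAZ is not supported, decompress first: %s", path),
         call. = FALSE)
  if (sig != "LASF")
    stop(sprintf("not a LAS file (bad signature): %s", path), call. = FALSE)

  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = "little")
  f64 <- function(off) readBin(raw[(off + 1):(off + 8)], "double",
                               size = 8, endian = "little")
  offset_pts <- u32(96)
  pdrf <- as.integer(raw[105])
  if (pdrf >= 128L)  # laszip flags compression in the format byte
    stop(sprintf("compressed LAZ is not supported, decompress first: %s", path),
         call. = FALSE)
  if (pdrf > 5L)
    stop(sprintf("unsupported LAS point data record format %d in %s",
                 pdrf, path), call. = FALSE)
  reclen <- u16(105)
  n <- u32(107)
  if (n == 0L) {  # LAS 1.4 stores the count at offset 247
    hdr_size <- u16(94)
    if (hdr_size >= 375) n <- u32(247)
  }
  scl <- c(f64(131), f64(139), f64(147))
  off <- c(f64(155), f64(163), f64(171))
  if (n == 0L) return(point_cloud())
  if (offset_pts + as.double(n) * reclen > sz)
    stop(sprintf("corrupt LAS file (truncated point records): %s", path),
         call. = FALSE)

  base <- offset_pts + (seq_len(n) - 1) * reclen
  int_at <- function(b0) {
    idx <- as.vector(outer(1:4, base + b0, `+`))
    readBin(raw[idx], "integer", n = n, size = 4, endian = "little")
  }
  x <- int_at(0) * scl[1] + off[1]
  y <- int_at(4) * scl[2] + off[2]
  z <- int_at(8) * scl[3] + off[3]
  flags <- as.integer(raw[base + 15])
  rn <- flags %% 8L
  rn[rn == 0L] <- 1L
  cls <- as.integer(raw[base + 16]) %% 32L  # mask LAS 1.0-1.3 class flag bits
  pc <- point_cloud(x, y, z, rn, cls)
  if (first_returns_only) pc <- as_point_cloud(pc[pc$return_number == 1L, ])
  pc
}

#' Write a point cloud to LAS 1.2
#'
#' Writes point data record format 0 with a 0.001 m coordinate scale,
#' which round-trips coordinates to within 0.0005 m.
#'
#' @param cloud A [point_cloud()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path) {
  n <- nrow(cloud)
  scale <- 0.001
  offs <- if (n > 0) c(floor(min(cloud$x)), floor(min(cloud$y)),
                       floor(min(cloud$z))) else c(0, 0, 0)

  w_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  w_u32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")
  w_f64 <- function(v) writeBin(as.double(v), raw(), size = 8, endian = "little")
  pad <- function(nbytes) as.raw(rep(0L, nbytes))

  mins <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  maxs <- if (n > 0) c(max(cloud$x), max(cloud$y), max(cloud$z)) else c(0, 0, 0)
  nret <- integer(5)
  if (n > 0) {
    tb <- table(factor(pmin(cloud$return_number, 5L), levels = 1:5))
    nret <- as.integer(tb)
  }
  header <- c(
    charToRaw("LASF"),
    w_u16(0), w_u16(0),          # file source id, global encoding
    pad(16),                     # project GUID
    as.raw(c(1L, 2L)),           # version 1.2
    pad(32), pad(32),            # system id, generating software
    w_u16(1), w_u16(2020),       # file day/year (fixed: reproducible output)
    w_u16(227), w_u32(227),      # header size, offset to point data
    w_u32(0),                    # number of VLRs
    as.raw(0L), w_u16(20),       # point format 0, record length
    w_u32(n), w_u32(nret),
    w_f64(scale), w_f64(scale), w_f64(scale),
    w_f64(offs[1]), w_f64(offs[2]), w_f64(offs[3]),
    w_f64(maxs[1]), w_f64(mins[1]),
    w_f64(maxs[2]), w_f64(mins[2]),
    w_f64(maxs[3]), w_f64(mins[3])
  )
  stopifnot(length(header) == 227L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  if (n > 0) {
    m <- matrix(as.raw(0L), nrow = 20L, ncol = n)
    put_i32 <- function(row0, vals) {
      m[row0 + 1:4, ] <<- matrix(writeBin(as.integer(round(vals)), raw(),
                                          size = 4, endian = "little"),
                                 nrow = 4)
    }
    put_i32(0L, (cloud$x - offs[1]) / scale)
    put_i32(4L, (cloud$y - offs[2]) / scale)
    put_i32(8L, (cloud$z - offs[3]) / scale)
    rn <- pmin(cloud$return_number, 7L)
    m[15L, ] <- as.raw(rn + 8L * rn)  # return i of i
    m[16L, ] <- as.raw(cloud$classification %% 32L)
    writeBin(as.vector(m), con)
  }
  invisible(path)
}
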