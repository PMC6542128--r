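# Minimal ZIP writer (store-only) used for the output bundle.
#
# Entries are stored uncompressed with fixed 1980-01-01 00:00 timestamps and
# written in sorted name order, so the archive bytes depend only on the file
# contents -- re-running a pipeline yields a byte-identical bundle. Readable
# by any ZIP tool, including utils::unzip's internal method.

# CRC32 of a raw vector, via the trailer of base R's gzip stream
# (RFC 1952: the last 8 bytes are CRC32 then length, little-endian)
crc32_raw <- function(data) {
  gz <- memCompress(data, type = "gzip")
  L <- length(gz)
  gz[(L - 7):(L - 4)]
}

# non-negative integer (as double) to little-endian raw of given width
le_raw <- function(x, width) {
  out <- raw(width)
  for (k in seq_len(width)) {
    out[k] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' Write a ZIP archive of files
#'
#' Store-only (uncompressed) ZIP with fixed epoch timestamps and entries
#' sorted by name, so identical file contents always produce an identical
#' archive.
#'
#' @param zipfile output path.
#' @param files paths of the files to archive.
#' @param names entry names inside the archive (default: basenames).
#' @return `zipfile`, invisibly.
#' @export
write_zip <- function(zipfile, files, names = basename(files)) {
  stopifnot(length(files) == length(names), !anyDuplicated(names))
  ord <- order(names)
  files <- files[ord]; names <- names[ord]
  dos_time <- le_raw(0, 2)        # 00:00:00
  dos_date <- le_raw(33, 2)       # 1980-01-01
  con <- file(zipfile, "wb")
  on.exit(close(con), add = TRUE)
  central <- raw(0)
  offset <- 0
  for (k in seq_along(files)) {
    data <- readBin(files[k], "raw", n = file.size(files[k]))
    crc <- crc32_raw(data)
    nm <- charToRaw(names[k])
    sz <- le_raw(length(data), 4)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),  # PK\3\4
                   le_raw(20, 2),                       # version needed
                   le_raw(0, 2),                        # flags
                   le_raw(0, 2),                        # method: store
                   dos_time, dos_date, crc, sz, sz,
                   le_raw(length(nm), 2), le_raw(0, 2))
    writeBin(c(local_hdr, nm, data), con)
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)),     # PK\1\2
                 le_raw(20, 2), le_raw(20, 2), le_raw(0, 2), le_raw(0, 2),
                 dos_time, dos_date, crc, sz, sz,
                 le_raw(length(nm), 2), le_raw(0, 2), le_raw(0, 2),
                 le_raw(0, 2), le_raw(0, 2), le_raw(0, 4),
                 le_raw(offset, 4), nm)
    offset <- offset + length(local_hdr) + length(nm) + length(data)
  }
  writeBin(central, con)
  n <- length(files)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),         # PK\5\6
             le_raw(0, 2), le_raw(0, 2), le_raw(n, 2), le_raw(n, 2),
             le_raw(length(central), 4), le_raw(offset, 4), le_raw(0, 2)),
           con)
  invisible(zipfile)
}
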