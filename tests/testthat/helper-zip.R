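## Minimal writer for ZIP archives with stored (uncompressed) entries,
## used only to build zip-reading fixtures at test time. Pure R: the test
## image ships no `zip` binary, and binary fixtures cannot be checked in.

.crcTable <- vapply(0:255, function(n) {
  c <- n
  for (k in 1:8) {
    odd <- c %% 2 == 1
    c <- floor(c / 2)
    if (odd) {                      # xor 0xEDB88320 in 16-bit chunks
      lo <- bitwXor(as.integer(c %% 65536), 0x8320L)
      hi <- bitwXor(as.integer(floor(c / 65536)), 0xEDB8L)
      c <- hi * 65536 + lo
    }
  }
  c
}, numeric(1))

crc32 <- function(bytes) {
  c <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwXor(as.integer(c %% 256), b) + 1L
    c <- floor(c / 256)
    t <- .crcTable[idx]
    lo <- bitwXor(as.integer(c %% 65536), as.integer(t %% 65536))
    hi <- bitwXor(as.integer(floor(c / 65536)),
                  as.integer(floor(t / 65536)))
    c <- hi * 65536 + lo
  }
  4294967295 - c
}

writeLE <- function(con, value, size) {
  bytes <- integer(size)
  v <- value
  for (i in seq_len(size)) { bytes[i] <- v %% 256; v <- floor(v / 256) }
  writeBin(as.raw(bytes), con)
}

## files: named character vector, names = member names, values = paths.
makeStoredZip <- function(files, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  entries <- list()
  offset <- 0
  for (nm in names(files)) {
    data <- readBin(files[[nm]], "raw", file.info(files[[nm]])$size)
    crc <- crc32(data)
    nameRaw <- charToRaw(nm)
    writeLE(con, 0x04034b50, 4); writeLE(con, 20, 2); writeLE(con, 0, 2)
    writeLE(con, 0, 2)                               # method 0 = stored
    writeLE(con, 0, 2); writeLE(con, 0, 2)           # time, date
    writeLE(con, crc, 4)
    writeLE(con, length(data), 4); writeLE(con, length(data), 4)
    writeLE(con, length(nameRaw), 2); writeLE(con, 0, 2)
    writeBin(nameRaw, con); writeBin(data, con)
    entries[[nm]] <- list(crc = crc, size = length(data), offset = offset)
    offset <- offset + 30 + length(nameRaw) + length(data)
  }
  cdStart <- offset
  for (nm in names(entries)) {
    e <- entries[[nm]]
    nameRaw <- charToRaw(nm)
    writeLE(con, 0x02014b50, 4); writeLE(con, 20, 2); writeLE(con, 20, 2)
    writeLE(con, 0, 2); writeLE(con, 0, 2)
    writeLE(con, 0, 2); writeLE(con, 0, 2)
    writeLE(con, e$crc, 4); writeLE(con, e$size, 4); writeLE(con, e$size, 4)
    writeLE(con, length(nameRaw), 2)
    for (z in 1:3) writeLE(con, 0, 2)                # extra, comment, disk
    writeLE(con, 0, 2); writeLE(con, 0, 4)           # int/ext attrs
    writeLE(con, e$offset, 4)
    writeBin(nameRaw, con)
    offset <- offset + 46 + length(nameRaw)
  }
  writeLE(con, 0x06054b50, 4)
  writeLE(con, 0, 2); writeLE(con, 0, 2)
  writeLE(con, length(entries), 2); writeLE(con, length(entries), 2)
  writeLE(con, offset - cdStart, 4); writeLE(con, cdStart, 4)
  writeLE(con, 0, 2)
  invisible(zipfile)
}
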