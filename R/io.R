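# Binary containers: 4-byte magic + 1 version byte + payload.

write_magic_file <- function(path, magic, payload) {
  stopifnot(nchar(magic) == 4, is.raw(payload))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(magic), con)
  writeBin(as.raw(1L), con)
  writeBin(payload, con)
  invisible(path)
}

read_magic_file <- function(path, magic) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  got <- rawToChar(readBin(con, "raw", 4))
  if (!identical(got, magic)) {
    stop("format error: expected magic ", magic, " in ", path, ", got ", got)
  }
  ver <- readBin(con, "raw", 1)
  if (as.integer(ver) != 1L) stop("format error: unsupported version in ", path)
  readBin(con, "raw", sz - 5)
}

#' Write a ciphertext to its container file
#'
#' Layout: magic `FCG1`, version byte, backend id byte (1 toy, 2 emulated),
#' level, scale (float64), slot count, then the payload blob.
#' @param ct a `he_ciphertext`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ciphertext <- function(ct, path) {
  head <- c(as.raw(if (ct$backend == "toy_ckks") 1L else 2L))
  meta <- writeBin(c(as.numeric(ct$level), ct$scale, as.numeric(ct$n_slots)),
                   raw(), size = 8)
  write_magic_file(path, "FCG1", c(head, meta, serialize(ct$payload, NULL)))
}

#' Read a ciphertext container written by [write_ciphertext()]
#' @param path input path
#' @return a `he_ciphertext`
#' @export
read_ciphertext <- function(path) {
  blob <- read_magic_file(path, "FCG1")
  backend <- if (as.integer(blob[1]) == 1L) "toy_ckks" else "emulated"
  meta <- readBin(blob[2:25], "numeric", 3, size = 8)
  payload <- unserialize(blob[-(1:25)])
  new_ciphertext(backend, payload, level = meta[1], scale = meta[2],
                 n_slots = as.integer(meta[3]))
}

#' Read or write a plaintext matrix as headerless TSV
#' @param m numeric matrix
#' @param path file path
#' @return the matrix (read) or `path` invisibly (write)
#' @export
write_plain_matrix <- function(m, path) {
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_plain_matrix
#' @export
read_plain_matrix <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE))
}

# encrypted-matrix container: rows, cols, stride, block count, blocks
write_encrypted_matrix <- function(em, path) {
  payload <- serialize(list(rows = em$rows, cols = em$cols, stride = em$stride,
                            blocks = em$blocks), NULL)
  write_magic_file(path, "FEM1", payload)
}

read_encrypted_matrix <- function(path) {
  x <- unserialize(read_magic_file(path, "FEM1"))
  structure(x, class = "encrypted_matrix")
}
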