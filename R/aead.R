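# Authenticated symmetric encryption built from the package's SHA-256
# primitive: CTR keystream from SHA256(key||nonce||counter) and an
# encrypt-then-MAC HMAC-SHA256 tag. Protects key shares (under
# passphrase-derived keys) and partial decryptions (under the shared
# symmetric key) while they sit in the shared space.

rand_bytes <- function(n) as.raw(sample(0:255, n, replace = TRUE))

#' Derive a 256-bit key from a passphrase
#' @param passphrase character scalar
#' @param salt raw vector (any length); defaults to a fixed context string
#' @param iters hash iterations
#' @return raw vector of 32 bytes
#' @export
derive_key <- function(passphrase, salt = charToRaw("fedhegwas.dsk"),
                       iters = 1000L) {
  x <- sha256_cpp(c(charToRaw(passphrase), salt))
  for (i in seq_len(iters - 1L)) x <- sha256_cpp(c(x, salt))
  x
}

#' Authenticated encryption of a raw payload
#' @param key 32-byte raw key
#' @param plaintext raw vector
#' @param aad additional authenticated data (raw), bound into the tag
#' @return raw vector `nonce(16) || tag(32) || ciphertext`
#' @export
aead_encrypt <- function(key, plaintext, aad = raw(0)) {
  stopifnot(is.raw(key), length(key) == 32)
  nonce <- rand_bytes(16)
  enc_key <- sha256_cpp(c(key, charToRaw("enc")))
  mac_key <- sha256_cpp(c(key, charToRaw("mac")))
  ks <- keystream_cpp(enc_key, nonce, length(plaintext))
  ct <- xor(plaintext, ks)
  tag <- hmac_sha256_cpp(mac_key, c(nonce, aad, ct))
  c(nonce, tag, ct)
}

#' Authenticated decryption; errors on any tampering
#' @param key 32-byte raw key
#' @param blob output of [aead_encrypt()]
#' @param aad additional authenticated data used at encryption
#' @return the plaintext raw vector
#' @export
aead_decrypt <- function(key, blob, aad = raw(0)) {
  stopifnot(is.raw(key), length(key) == 32)
  if (length(blob) < 48) stop("authentication failure: truncated payload")
  nonce <- blob[1:16]
  tag <- blob[17:48]
  ct <- blob[-(1:48)]
  mac_key <- sha256_cpp(c(key, charToRaw("mac")))
  expect <- hmac_sha256_cpp(mac_key, c(nonce, aad, ct))
  if (!identical(as.integer(expect), as.integer(tag))) {
    stop("authentication failure: AEAD tag mismatch")
  }
  enc_key <- sha256_cpp(c(key, charToRaw("enc")))
  xor(ct, keystream_cpp(enc_key, nonce, length(ct)))
}
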