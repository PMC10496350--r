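# Shared-space contract and the multiparty building blocks, on the
# emulated backend (fast) with a toy spot-check for collective decryption.

test_that("shared space enforces immutability, probing and stalls", {
  sp <- shared_space(tempfile("space_"), poll_interval = 0.05, timeout = 0.5)
  expect_false(space_probe(sp, "a.bin"))
  space_upload(sp, "a.bin", as.raw(1:4))
  expect_true(space_probe(sp, "a.bin"))
  expect_identical(space_download(sp, "a.bin"), as.raw(1:4))
  expect_error(space_upload(sp, "a.bin", as.raw(9)), "immutability")
  expect_identical(space_download(sp, "a.bin"), as.raw(1:4))
  t0 <- Sys.time()
  expect_error(space_wait_for(sp, "absent.bin"), "stall error")
  expect_gt(as.numeric(Sys.time() - t0, units = "secs"), 0.4)
})

test_that("collective matrix decryption is consistent across sites", {
  set.seed(30)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(em_bundle64)
  m <- matrix(c(1.5, -2, 0.25, 4), 2, 2)
  em <- encrypt_matrix(m, em_bundle64$public_key, em_params64)
  out <- collective_decrypt_matrix(em, sites, sp, tag = "t")
  expect_lt(max(abs(out - m)), 1e-2)
  per_site <- attr(out, "per_site")
  expect_length(per_site, 3)
  for (k in 2:3) expect_lt(max(abs(per_site[[k]] - per_site[[1]])), 1e-6)
})

test_that("collective decryption detects tampered partials", {
  set.seed(31)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(em_bundle64)
  em <- encrypt_matrix(matrix(1:4, 2, 2), em_bundle64$public_key, em_params64)
  # sites 2 and 3 publish honest partials; an attacker plants a forged blob
  # under site 1's name before site 1 gets to it
  r <- fedhegwas:::next_round(sp)
  fedhegwas:::cdm_upload_partials(em, sites[2:3], sp, "t", r)
  space_upload(sp, sprintf("r%d_s1_t_b1.pardec", r), as.raw(rep(7, 80)))
  expect_error(fedhegwas:::cdm_aggregate(em, sites, sp, "t", r),
               "authentication failure")
})

test_that("toy-backend collective decryption matches the plaintext", {
  set.seed(32)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(toy_bundle_hp)
  m <- matrix(c(2, -1, 0.5, 3), 2, 2)
  em <- encrypt_matrix(m, toy_bundle_hp$public_key, toy_params_hp)
  out <- collective_decrypt_matrix(em, sites, sp, tag = "t")
  expect_lt(max(abs(out - m)), 1e-2)
})

test_that("masked collaborative inversion recovers known inverses", {
  set.seed(33)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(em_bundle64)
  # diag(2, 4) split additively across 3 sites
  target <- diag(c(2, 4))
  parts <- list(0.2 * target, 0.3 * target, 0.5 * target)
  inv_enc <- masked_collaborative_inverse(parts, sites, sp)
  got <- collective_decrypt_matrix(inv_enc, sites, sp, tag = "chk")
  expect_equal(dim(got), c(2, 2))
  expect_lt(max(abs(got - diag(c(0.5, 0.25)))), 1e-4)
  # identity
  sp2 <- shared_space(tempfile("space_"))
  inv_I <- masked_collaborative_inverse(list(diag(3) / 3, diag(3) / 3, diag(3) / 3),
                                        sites, sp2)
  gotI <- collective_decrypt_matrix(inv_I, sites, sp2, tag = "chk")
  expect_lt(max(abs(gotI[1:3, 1:3] - diag(3))), 1e-3)
  expect_equal(dim(gotI), c(4, 4))           # padded to the next power of 2
  expect_lt(max(abs(gotI[4, ])), 1e-3)       # zero padding outside the block
})

test_that("masked inversion of a random SPD matrix has small residual", {
  set.seed(34)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(em_bundle64)
  A <- crossprod(matrix(rnorm(64), 8, 8)) + diag(8)
  parts <- list(0.5 * A, 0.25 * A, 0.25 * A)
  inv_enc <- masked_collaborative_inverse(parts, sites, sp)
  got <- collective_decrypt_matrix(inv_enc, sites, sp, tag = "chk")[1:8, 1:8]
  expect_lt(max(abs(A %*% got - diag(8))), 1e-3)
})

test_that("collective refresh restores level and preserves values", {
  set.seed(35)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(em_bundle64)
  params <- em_params64
  m <- matrix(runif(4, -3, 3), 2, 2)
  em <- encrypt_matrix(m, em_bundle64$public_key, params)
  # burn the whole budget
  ones <- matrix(1, 2, 2)
  for (i in seq_len(params$max_level)) em <- emat_mul_plain(em, ones, params)
  expect_equal(fedhegwas:::emat_level(em), 0)
  expect_error(emat_mul_plain(em, ones, params), "depth error")
  fresh <- collective_refresh(em, sites, sp, mask_sd = 100)
  expect_equal(fedhegwas:::emat_level(fresh), params$max_level)
  expect_equal(fedhegwas:::emat_scale(fresh), params$scale)
  v1 <- collective_decrypt_matrix(fresh, sites, sp, tag = "chk")
  expect_lt(max(abs(v1 - m)), 1e-2)
  # refresh twice: still within twice the tolerance
  again <- collective_refresh(fresh, sites, sp, tag = "again", mask_sd = 100)
  v2 <- collective_decrypt_matrix(again, sites, sp, tag = "chk2")
  expect_lt(max(abs(v2 - m)), 2e-2)
})

test_that("no exchanged file matches a site's raw data (transcript privacy)", {
  set.seed(36)
  sp <- shared_space(tempfile("space_"))
  sites <- make_sites(em_bundle64)
  params <- em_params64
  secret <- matrix(runif(4, -1, 1), 2, 2)
  em <- encrypt_matrix(secret, em_bundle64$public_key, params)
  masked <- collective_refresh(em, sites, sp, mask_sd = 100)
  out <- collective_decrypt_matrix(masked, sites, sp, tag = "chk")
  expect_lt(max(abs(out - secret)), 1e-2)
  flat <- as.vector(t(secret))
  for (f in list.files(sp$dir, full.names = TRUE)) {
    blob <- readBin(f, "raw", file.info(f)$size)
    # interpret any stored doubles and look for the secret in the clear
    if (length(blob) >= 8 * length(flat)) {
      doubles <- suppressWarnings(tryCatch(
        readBin(blob, "numeric", length(blob) %/% 8), error = function(e) numeric(0)))
      if (length(doubles) >= length(flat)) {
        hits <- vapply(seq_len(length(doubles) - length(flat) + 1), function(i) {
          all(abs(doubles[i:(i + length(flat) - 1)] - flat) < 1e-6)
        }, logical(1))
        expect_false(any(hits), info = paste("raw data leaked in", basename(f)))
      }
    }
  }
  # the decrypted transcript files never hold the unmasked value either:
  # every decrypted object in the space is masked at distance >> data scale
  masked_plain <- collective_decrypt_matrix(
    fedhegwas:::download_encmat(sp, grep("_masked\\.encmat$", list.files(sp$dir),
                                         value = TRUE)[1]),
    sites, sp, tag = "audit")
  expect_gt(max(abs(masked_plain - secret)), 5 * sd(secret))
})

test_that("protocol transcripts are reproducible under fixed seeds", {
  run_once <- function() {
    set.seed(40)
    sp <- shared_space(tempfile("space_"))
    sites <- make_sites(em_bundle64, seed = 900)
    em <- encrypt_matrix(matrix(1:4, 2, 2), em_bundle64$public_key, em_params64)
    out <- collective_decrypt_matrix(em, sites, sp, tag = "t")
    files <- sort(list.files(sp$dir))
    digests <- vapply(files, function(f) {
      paste(head(format(fedhegwas:::sha256_cpp(readBin(file.path(sp$dir, f), "raw",
        file.info(file.path(sp$dir, f))$size))), 8), collapse = "")
    }, character(1))
    list(out = out, digests = digests)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$digests, b$digests)
  expect_identical(a$out, b$out)
})
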