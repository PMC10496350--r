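# Contract suite run identically against the toy RLWE backend and the
# plaintext emulation.

test_that("encoding pads to the slot capacity and rejects overflow", {
  p16k <- he_params(poly_degree = 16384, backend = "emulated")
  expect_equal(p16k$slot_size, 8192)
  pt <- he_encode(numeric(0), toy_params64)
  expect_equal(pt$slots, numeric(32))
  expect_error(he_encode(numeric(33), toy_params64), "capacity error")
  # canonical-embedding round trip at the encoding scale
  v <- runif(32, -5, 5)
  coeffs <- fedhegwas:::embed_encode(v, 64)
  expect_lt(max(abs(fedhegwas:::embed_decode(coeffs, 64) - v)), 1e-10)
})

for (bk in names(backend_fixtures)) {
  fx <- backend_fixtures[[bk]]
  params <- fx$params
  bundle <- fx$bundle
  msk <- bundle$master_key
  pk <- bundle$public_key
  evk <- bundle$eval_keys
  enc <- function(v, scale = params$scale) {
    he_encrypt(he_encode(v, params, scale), pk, params)
  }
  dec <- function(ct) he_decrypt_master(ct, msk, params)

  test_that(paste0(bk, ": encryption round trip and additive identity"), {
    set.seed(1)
    v <- c(1, 2, 3)
    ct <- enc(v)
    expect_equal(ct$level, params$max_level)
    expect_lt(max(abs(dec(ct)[1:3] - v)), 1e-3)
    z <- he_add(ct, enc(numeric(3)))
    expect_lt(max(abs(dec(z)[1:3] - v)), 1e-3)
  })

  test_that(paste0(bk, ": two encryptions of one plaintext differ"), {
    set.seed(2)
    a <- enc(c(5, 5))
    b <- enc(c(5, 5))
    expect_false(identical(a$payload, b$payload))
  })

  test_that(paste0(bk, ": add, sub and associativity track plaintext"), {
    set.seed(3)
    x <- runif(8, -3, 3); y <- runif(8, -3, 3); z <- runif(8, -3, 3)
    a <- enc(x); b <- enc(y); cts <- enc(z)
    expect_lt(max(abs(dec(he_add(a, b))[1:8] - (x + y))), 1e-3)
    expect_lt(max(abs(dec(he_sub(a, a))[1:8])), 1e-3)
    lhs <- dec(he_add(he_add(a, b), cts))[1:8]
    rhs <- dec(he_add(a, he_add(b, cts)))[1:8]
    expect_lt(max(abs(lhs - rhs)), 1e-5)
  })

  test_that(paste0(bk, ": multiplication, identity and depth budget"), {
    set.seed(4)
    a <- enc(c(2, 3)); b <- enc(c(4, 5))
    m <- he_mul(a, b, evk, params)
    expect_lt(max(abs(dec(m)[1:2] - c(8, 15))), 1e-3)
    expect_equal(m$level, params$max_level - 1)
    ones <- he_mul_plain(a, he_encode(rep(1, params$slot_size), params), params)
    expect_lt(max(abs(dec(ones)[1:2] - c(2, 3))), 1e-3)
    expect_equal(ones$level, a$level - 1)
    # exhaust the budget: max_level multiplications succeed, one more fails
    ct <- enc(rep(1, 4))
    for (i in seq_len(params$max_level)) {
      ct <- he_mul_plain(ct, he_encode(rep(1, params$slot_size), params), params)
    }
    expect_equal(ct$level, 0)
    expect_error(he_mul_plain(ct, he_encode(rep(1, params$slot_size), params),
                              params), "depth error")
  })

  test_that(paste0(bk, ": rotations shift slots and compose to identity"), {
    set.seed(5)
    v <- c(1, 2, 3, 4, numeric(params$slot_size - 4))
    ct <- enc(v)
    r1 <- dec(he_rotate(ct, 1, evk, params))
    expect_lt(max(abs(r1 - c(v[-1], v[1]))), 1e-2)
    full <- dec(he_rotate(ct, params$slot_size, evk, params))
    expect_lt(max(abs(full - v)), 1e-2)
    t <- 5
    back <- he_rotate(he_rotate(ct, t, evk, params),
                      params$slot_size - t, evk, params)
    expect_lt(max(abs(dec(back) - v)), 1e-2)
  })

  test_that(paste0(bk, ": homomorphism against the plaintext oracle"), {
    set.seed(6)
    v <- runif(params$slot_size, -2, 2)
    w <- runif(params$slot_size, -2, 2)
    sum_dec <- threshold_decrypt(he_add(enc(v), enc(w)), bundle, params)
    expect_lt(max(abs(sum_dec - (v + w))), 0.05)
    prod_dec <- threshold_decrypt(he_mul(enc(v), enc(w), evk, params),
                                  bundle, params)
    expect_lt(max(abs(prod_dec - v * w)), 0.05)
  })

  test_that(paste0(bk, ": aggregation protocol errors"), {
    set.seed(7)
    ct <- enc(c(5, -1))
    shares <- open_shares(bundle)
    partials <- lapply(1:3, function(s) {
      partial_decrypt(ct, shares[[s]], params, include_c0 = s == 1)
    })
    expect_error(aggregate_partials(partials[1:2], params), "incompleteness")
    both_c0 <- partials
    both_c0[[2]] <- partial_decrypt(ct, shares[[2]], params, include_c0 = TRUE)
    expect_error(aggregate_partials(both_c0, params), "protocol error")
    none_c0 <- partials
    none_c0[[1]] <- partial_decrypt(ct, shares[[1]], params, include_c0 = FALSE)
    expect_error(aggregate_partials(none_c0, params), "protocol error")
  })
}

test_that("threshold round trip at default parameters recovers [5, -1]", {
  set.seed(8)
  pe <- he_params(n_sites = 3, backend = "emulated")  # defaults: n=16384, sm=40
  be <- make_key_bundle(pe, seed = 9)
  ct <- he_encrypt(he_encode(c(5, -1), pe), be$public_key, pe)
  got <- threshold_decrypt(ct, be, pe)
  expect_lt(max(abs(got[1:2] - c(5, -1))), 1e-2)
})

test_that("noiseless partial decryption matches the exact formula", {
  p0 <- fedhegwas:::toy_test_params(n = 64, n_sites = 3, smudging_bits = 0)
  b0 <- make_key_bundle(p0, seed = 11, keep_master = TRUE)
  ct <- he_encrypt(he_encode(c(2, 4), p0), b0$public_key, p0)
  sh <- open_key_bundle(b0, 2)$share
  pd <- partial_decrypt(ct, sh, p0, include_c0 = FALSE)
  manual <- fedhegwas:::ring_mul(ct$payload$c1, sh$res, p0)
  expect_identical(pd$payload, manual)
  pd_c0 <- partial_decrypt(ct, sh, p0, include_c0 = TRUE)
  expect_identical(pd_c0$payload, fedhegwas:::ring_add(manual, ct$payload$c0, p0))
})

test_that("default smudging noise has ring-layer sd near 2^20", {
  p <- fedhegwas:::toy_test_params(n = 1024, n_sites = 3)  # smudging 40 bits
  b <- make_key_bundle(p, seed = 12, keep_master = TRUE)
  ct <- he_encrypt(he_encode(c(1, 2), p), b$public_key, p)
  sh <- open_key_bundle(b, 1)$share
  clean <- fedhegwas:::ring_mul(ct$payload$c1, sh$res, p)
  pd <- partial_decrypt(ct, sh, p, include_c0 = FALSE, seed = 13)
  noise <- fedhegwas:::ring_center(fedhegwas:::ring_sub(pd$payload, clean, p), p)
  expect_gt(sd(noise), 0.5 * 2^20)
  expect_lt(sd(noise), 2 * 2^20)
})

test_that("aggregate error vs master-key decryption is smudging-dominated", {
  set.seed(14)
  v <- runif(32, -3, 3)
  ct <- he_encrypt(he_encode(v, toy_params_hp), toy_bundle_hp$public_key,
                   toy_params_hp)
  via_master <- he_decrypt_master(ct, toy_bundle_hp$master_key, toy_params_hp)
  errs <- replicate(20, {
    max_seed <- sample.int(10000, 1)
    agg <- threshold_decrypt(ct, toy_bundle_hp, toy_params_hp, seed = max_seed)
    sd(agg - via_master)
  })
  # decoded sd ~ sqrt(n/2 * S) * 2^(sm/2) / scale at the slot layer
  expected <- sqrt(toy_params_hp$poly_degree / 2 * 3) * 2^20 / 2^35
  expect_gt(median(errs), expected / 3)
  expect_lt(median(errs), expected * 3)
})

test_that("ciphertext files round-trip with their container header", {
  set.seed(15)
  ct <- he_encrypt(he_encode(c(7, -2), toy_params64), toy_bundle64$public_key,
                   toy_params64)
  path <- tempfile(fileext = ".ct")
  write_ciphertext(ct, path)
  con <- file(path, "rb"); magic <- rawToChar(readBin(con, "raw", 4)); close(con)
  expect_equal(magic, "FCG1")
  back <- read_ciphertext(path)
  expect_equal(back$level, ct$level)
  expect_equal(back$scale, ct$scale)
  expect_lt(max(abs(he_decrypt_master(back, toy_bundle64$master_key,
                                      toy_params64)[1:2] - c(7, -2))), 1e-3)
})
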