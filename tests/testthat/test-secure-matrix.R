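# Encrypted matrix algebra against plaintext oracles (both backends where
# it matters; the emulated backend carries the larger random cases).

params <- toy_params64
bundle <- toy_bundle64
pk <- bundle$public_key
evk <- bundle$eval_keys
msk <- bundle$master_key
decm <- function(em) fedhegwas:::decrypt_matrix_master(em, msk, params)

test_that("ciphertext block counts follow the packing rule", {
  expect_equal(blocks_needed(1, 57344, 8192), 7L)
  expect_equal(blocks_needed(1, 557056, 8192), 68L)
  expect_equal(blocks_needed(3, 3, 8192), 1L)
  expect_equal(blocks_needed(100, 100, 8192), 2L)
})

test_that("matrix encryption flattens row-major and round-trips", {
  set.seed(20)
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  em <- encrypt_matrix(m, pk, params)
  expect_length(em$blocks, 1)
  slots <- he_decrypt_master(em$blocks[[1]], msk, params)
  expect_lt(max(abs(slots[1:9] - 1:9)), 1e-3)     # row-major order
  expect_lt(max(abs(slots[10:32])), 1e-3)         # trailing slots zero
  expect_lt(max(abs(decm(em) - m)), 1e-3)
  # multi-block round trip
  m2 <- matrix(runif(6 * 8, -2, 2), 6, 8)  # 48 values: 2 blocks of 32
  em2 <- encrypt_matrix(m2, pk, params)
  expect_length(em2$blocks, 2)
  expect_lt(max(abs(decm(em2) - m2)), 1e-3)
})

test_that("padding and scaling behave as declared", {
  m <- matrix(1:9, 3, 3)
  p4 <- pad_matrix(m, 4, 4)
  expect_equal(dim(p4), c(4, 4))
  expect_equal(p4[1:3, 1:3], m)
  expect_equal(p4[4, ], numeric(4))
  expect_equal(pad_matrix(m, 3, 3), m)
  expect_error(pad_matrix(m, 2, 3), "shape error")
  expect_equal(fedhegwas:::next_pow2(9), 16)
  s <- scale_matrix(m, 2)
  expect_equal(attr(scale_matrix(s, 0.5), "scale_factor"), 1)
  expect_equal(unclass(scale_matrix(s, 0.5))[1:9], as.numeric(m)[1:9])
  expect_error(scale_matrix(m, 0), "parameter error")
})

test_that("plaintext expansions replicate columns and rows", {
  ce <- expand_columns(matrix(c(1, 2), 2, 1), 3)
  expect_equal(ce[[1]], matrix(c(1, 1, 1, 2, 2, 2), 2, 3, byrow = TRUE))
  re <- expand_rows(matrix(c(1, 2, 3), 1, 3), 2)
  expect_equal(re[[1]], matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE))
  # distributive over addition
  set.seed(21)
  m1 <- matrix(rnorm(12), 3, 4); m2 <- matrix(rnorm(12), 3, 4)
  for (i in 1:3) {
    expect_lt(max(abs(expand_rows(m1 + m2, 5)[[i]] -
                        (expand_rows(m1, 5)[[i]] + expand_rows(m2, 5)[[i]]))), 1e-12)
  }
})

test_that("encrypted row expansion matches the plaintext oracle", {
  set.seed(22)
  m <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  em <- encrypt_matrix(m, pk, params)
  reset_rotation_counts()
  ex <- expand_rows_encrypted(em, 2, evk, params)
  expect_lt(max(abs(decm(ex[[1]]) - matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE))), 1e-2)
  expect_lt(max(abs(decm(ex[[2]]) - matrix(c(3, 4, 3, 4), 2, 2, byrow = TRUE))), 1e-2)
  # replication rotations: rows * log2(width)
  counts <- get_rotation_counts()
  expect_equal(unname(counts["replication"]), 2 * log2(2))
  # scalar broadcast
  em1 <- encrypt_matrix(matrix(5), pk, params)
  b <- expand_rows_encrypted(em1, 4, evk, params)[[1]]
  expect_lt(max(abs(decm(b) - matrix(5, 4, 1))), 1e-2)
  expect_error(expand_rows_encrypted(em, 3, evk, params), "shape error")
})

test_that("expansion-based matmul reproduces matrix products", {
  set.seed(23)
  A <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  B <- matrix(c(5, 6, 7, 8), 2, 2, byrow = TRUE)
  ceA <- encrypt_expansion(expand_columns(A, 2), pk, params)
  reB <- expand_rows(B, 2)
  got <- decm(matmul_expansions(ceA, reB, evk, params))
  expect_lt(max(abs(got - A %*% B)), 1e-3)
  # identity
  I2 <- diag(2)
  gotI <- decm(matmul_expansions(encrypt_expansion(expand_columns(I2, 2), pk, params),
                                 expand_rows(B, 2), evk, params))
  expect_lt(max(abs(gotI - B)), 1e-3)
  # random 4x4, both sides encrypted
  A4 <- matrix(runif(16, -2, 2), 4, 4)
  B4 <- matrix(runif(16, -2, 2), 4, 4)
  ce4 <- encrypt_expansion(expand_columns(A4, 4), pk, params)
  re4 <- encrypt_expansion(expand_rows(B4, 4), pk, params)
  got4 <- decm(matmul_expansions(ce4, re4, evk, params))
  expect_lt(max(abs(got4 - A4 %*% B4)), 1e-2)
})

test_that("row-row inner products use log2(b) rotations and match brute force", {
  A <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 2, 4, byrow = TRUE)
  emA <- encrypt_matrix(A, pk, params)
  emB <- encrypt_matrix(A, pk, params)
  reset_rotation_counts()
  r2r <- row_row_inner(emA, emB, evk, params)
  expect_equal(unname(get_rotation_counts()["accumulation"]),
               log2(4) * length(emA$blocks))
  got <- decm(r2r)
  expect_equal(dim(got), c(2, 1))
  expect_lt(max(abs(got - c(4, 16))), 1e-2)
  # against zero
  emZ <- encrypt_matrix(matrix(0, 2, 4), pk, params)
  expect_lt(max(abs(fedhegwas:::decrypt_matrix_master(
    row_row_inner(emA, emZ, evk, params), msk, params))), 1e-2)
  expect_error(row_row_inner(encrypt_matrix(matrix(1, 2, 3), pk, params),
                             encrypt_matrix(matrix(1, 2, 3), pk, params),
                             evk, params), "shape error")
})

test_that("row-row inner products on larger matrices (emulated backend)", {
  set.seed(24)
  pe <- em_params64
  be <- em_bundle64
  A <- matrix(runif(8 * 16, -2, 2), 8, 16)
  B <- matrix(runif(8 * 16, -2, 2), 8, 16)
  emA <- encrypt_matrix(A, be$public_key, pe)
  emB <- encrypt_matrix(B, be$public_key, pe)
  got <- fedhegwas:::decrypt_matrix_master(
    row_row_inner(emA, emB, be$eval_keys, pe), be$master_key, pe)
  expect_equal(dim(got), c(8, 1))
  expect_lt(max(abs(drop(got) - rowSums(A * B))), 1e-2)
})

test_that("masks are reproducible, removable and decorrelating", {
  set.seed(25)
  m1 <- make_mask(4, 4, sd = 1, seed = 31)
  expect_identical(m1, make_mask(4, 4, sd = 1, seed = 31))
  data <- matrix(runif(4, -1, 1), 2, 2)
  em <- encrypt_matrix(data, pk, params)
  mask <- make_mask(2, 2, sd = 5, seed = 32)
  masked <- apply_mask_add(em, mask, pk, params)
  rec <- remove_mask_add(decm(masked), mask)
  expect_lt(max(abs(rec - data)), 1e-3)
  # masked values are uncorrelated with the data when the mask dominates
  set.seed(26)
  x <- rnorm(1000, 0, 1)
  masked_x <- x + rnorm(1000, 0, 100)
  expect_lt(abs(cor(x, masked_x)), 0.1)
  # multiplicative masking in slot layout divides out exactly
  cm <- matrix(runif(2, 0.5, 1.5), 2, 1)
  emv <- encrypt_matrix(matrix(c(3, -4), 2, 1), pk, params)
  mm <- apply_mask_mul(emv, cm, params)
  expect_lt(max(abs(remove_mask_mul(decm(mm), cm) - c(3, -4))), 1e-2)
})

test_that("scaling near-zero entries before encryption reduces relative error", {
  set.seed(27)
  errs <- replicate(10, {
    v <- runif(8, 1e-4, 5e-4)
    ct <- he_encrypt(he_encode(c(v, numeric(24)), params), pk, params)
    plain <- he_decrypt_master(ct, msk, params)[1:8]
    ct_s <- he_encrypt(he_encode(c(v * 1e3, numeric(24)), params), pk, params)
    plain_s <- he_decrypt_master(ct_s, msk, params)[1:8] / 1e3
    c(unscaled = max(abs(plain - v) / v), scaled = max(abs(plain_s - v) / v))
  })
  expect_lt(median(errs["scaled", ]), median(errs["unscaled", ]))
})

test_that("plain matrices round-trip through TSV", {
  m <- matrix(rnorm(12), 3, 4)
  path <- tempfile(fileext = ".tsv")
  write_plain_matrix(m, path)
  expect_equal(unname(read_plain_matrix(path)), m, tolerance = 1e-12)
})
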