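# Slot-packed encrypted matrix algebra: row-major flattening into ciphertext
# blocks, zero padding, row/column expansions, expansion-based matrix
# multiplication, shift-and-add row-row inner products and Gaussian masks.

#' Ciphertext blocks needed for an a x b matrix
#'
#' `ceiling(a*b / slot_size)`: e.g. 57,344 packed values need 7 ciphertexts
#' at 8,192 slots, and 557,056 need 68.
#' @param a,b matrix dimensions
#' @param slot_size slots per ciphertext (n/2)
#' @return integer block count
#' @export
blocks_needed <- function(a, b, slot_size) {
  as.integer(ceiling(a * b / slot_size))
}

flatten_rowmajor <- function(m) as.vector(t(m))

# slot layout: with stride = s, packed value i of a column vector sits at
# slot ((i-1) mod per_block)*s + 1 of block ceil(i/per_block),
# per_block = slot_size/s. stride > 1 is only used for a x 1 results of
# row-row products so they stay aligned with other strided vectors.
layout_blocks <- function(values, slot_size, stride) {
  if (stride == 1) {
    nb <- max(1L, as.integer(ceiling(length(values) / slot_size)))
    lapply(seq_len(nb), function(k) {
      seg <- values[((k - 1) * slot_size + 1):min(k * slot_size, length(values))]
      c(seg, numeric(slot_size - length(seg)))
    })
  } else {
    stopifnot(slot_size %% stride == 0)
    per_block <- slot_size %/% stride
    nb <- max(1L, as.integer(ceiling(length(values) / per_block)))
    lapply(seq_len(nb), function(k) {
      seg <- values[((k - 1) * per_block + 1):min(k * per_block, length(values))]
      slots <- numeric(slot_size)
      slots[(seq_along(seg) - 1) * stride + 1] <- seg
      slots
    })
  }
}

unlayout_blocks <- function(slot_list, n_values, stride) {
  if (stride == 1) {
    out <- unlist(slot_list)[seq_len(n_values)]
  } else {
    per_block <- length(slot_list[[1]]) %/% stride
    out <- unlist(lapply(slot_list, function(s) s[(seq_len(per_block) - 1) * stride + 1]))
    out <- out[seq_len(n_values)]
  }
  out
}

#' Encrypt a plaintext matrix into slot-packed ciphertext blocks
#'
#' The matrix is flattened row-major and split into
#' `ceiling(a*b/slot_size)` ciphertexts; trailing slots are zero.
#'
#' @param m numeric matrix
#' @param pk common public key
#' @param params an [he_params()] object
#' @param stride slot stride (1 for dense packing; internal strided layouts
#'   keep row-row results aligned)
#' @param scale encoding scale for the blocks
#' @return an `encrypted_matrix`
#' @export
encrypt_matrix <- function(m, pk, params, stride = 1L, scale = params$scale) {
  m <- as.matrix(m)
  if (stride > 1 && ncol(m) != 1) {
    stop("shape error: strided packing applies to column vectors only")
  }
  blocks <- lapply(layout_blocks(flatten_rowmajor(m), params$slot_size, stride),
                   function(slots) he_encrypt(he_encode(slots, params, scale), pk, params))
  structure(list(rows = nrow(m), cols = ncol(m), stride = as.integer(stride),
                 blocks = blocks),
            class = "encrypted_matrix")
}

#' @export
print.encrypted_matrix <- function(x, ...) {
  cat("<encrypted_matrix>", x$rows, "x", x$cols, "in", length(x$blocks),
      "block(s), stride", x$stride, ", level", x$blocks[[1]]$level, "\n")
  invisible(x)
}

# rebuild the matrix from decoded slot vectors
matrix_from_slots <- function(em, slot_list) {
  vals <- unlayout_blocks(slot_list, em$rows * em$cols, em$stride)
  matrix(vals, em$rows, em$cols, byrow = TRUE)
}

# test-only master-key decryption of a whole matrix
decrypt_matrix_master <- function(em, msk, params) {
  matrix_from_slots(em, lapply(em$blocks, he_decrypt_master, msk = msk,
                               params = params))
}

# plaintext blocks for plain-by-cipher products, in a given layout
plain_blocks <- function(m, params, stride = 1L, scale = params$scale) {
  lapply(layout_blocks(flatten_rowmajor(as.matrix(m)), params$slot_size, stride),
         function(slots) he_encode(slots, params, scale))
}

# blockwise wrappers ---------------------------------------------------------

emat_map2 <- function(a, b, f) {
  stopifnot(a$rows == b$rows, a$cols == b$cols, a$stride == b$stride,
            length(a$blocks) == length(b$blocks))
  a$blocks <- Map(f, a$blocks, b$blocks)
  a
}

#' Elementwise arithmetic on encrypted matrices
#' @param a,b `encrypted_matrix` objects of identical shape and layout
#' @param evk evaluation keys (multiplication only)
#' @param params an [he_params()] object (multiplication only)
#' @return an `encrypted_matrix`
#' @export
emat_add <- function(a, b) emat_map2(a, b, he_add)

#' @rdname emat_add
#' @export
emat_sub <- function(a, b) emat_map2(a, b, he_sub)

#' @rdname emat_add
#' @export
emat_mul <- function(a, b, evk, params) {
  emat_map2(a, b, function(x, y) he_mul(x, y, evk, params))
}

#' Multiply an encrypted matrix elementwise by a plaintext matrix
#' @param em an `encrypted_matrix`
#' @param m plaintext matrix of the same shape
#' @param params an [he_params()] object
#' @param scale encoding scale for the plaintext
#' @return an `encrypted_matrix` one level down
#' @export
emat_mul_plain <- function(em, m, params, scale = params$scale) {
  pts <- plain_blocks(m, params, em$stride, scale)
  em$blocks <- Map(function(ct, pt) he_mul_plain(ct, pt, params), em$blocks, pts)
  em
}

emat_level_drop <- function(em, level) {
  em$blocks <- lapply(em$blocks, he_level_drop, level = level)
  em
}

emat_scale_up <- function(em, log2_factor, params) {
  em$blocks <- lapply(em$blocks, he_scale_up, log2_factor = log2_factor,
                      params = params)
  em
}

emat_level <- function(em) em$blocks[[1]]$level
emat_scale <- function(em) em$blocks[[1]]$scale

# align b to a's level/scale (power-of-two scale ratio required)
emat_align_to <- function(b, level, scale, params) {
  ratio <- log2(scale) - log2(emat_scale(b))
  if (abs(ratio - round(ratio)) > 1e-6 || ratio < 0) {
    stop("alignment error: scale ratio 2^", ratio, " is not a non-negative power of 2")
  }
  if (ratio > 0) b <- emat_scale_up(b, round(ratio), params)
  if (emat_level(b) > level) b <- emat_level_drop(b, level)
  b
}

# padding and scaling --------------------------------------------------------

#' Zero-pad a matrix to a larger shape
#'
#' The input occupies the top-left block; added rows and columns are zero.
#' @param m numeric matrix (a x b)
#' @param c,d target dimensions, `c >= a`, `d >= b`
#' @return the padded c x d matrix
#' @export
pad_matrix <- function(m, c, d) {
  m <- as.matrix(m)
  if (c < nrow(m) || d < ncol(m)) {
    stop("shape error: pad target ", c, "x", d, " smaller than input ",
         nrow(m), "x", ncol(m))
  }
  out <- matrix(0, c, d)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' Scale a matrix, remembering the factor for later unscaling
#' @param m numeric matrix
#' @param factor nonzero scalar
#' @return the scaled matrix with attribute `scale_factor`
#' @export
scale_matrix <- function(m, factor) {
  if (factor == 0) stop("parameter error: scale factor must be nonzero")
  prev <- attr(m, "scale_factor")
  out <- m * factor
  attr(out, "scale_factor") <- if (is.null(prev)) factor else prev * factor
  out
}

# expansions -----------------------------------------------------------------

#' Column and row expansions of a plaintext matrix
#'
#' `expand_columns(m, c)[[i]]` is the a x c matrix whose columns all equal
#' column i of `m`; `expand_rows(m, a)[[i]]` is the a x b matrix whose rows
#' all equal row i. Matrix product A (a x b) times B (b x c) equals
#' `sum_i ce_i(A) * re_i(B)` elementwise, which is how encrypted matmul is
#' assembled.
#' @param m numeric matrix
#' @param c,a replication width / height
#' @return list of matrices (an expansion set)
#' @export
expand_columns <- function(m, c) {
  m <- as.matrix(m)
  out <- lapply(seq_len(ncol(m)), function(i) matrix(m[, i], nrow(m), c))
  structure(out, kind = "column", class = "expansion_set")
}

#' @rdname expand_columns
#' @export
expand_rows <- function(m, a) {
  m <- as.matrix(m)
  out <- lapply(seq_len(nrow(m)), function(i) matrix(m[i, ], a, ncol(m), byrow = TRUE))
  structure(out, kind = "row", class = "expansion_set")
}

#' Encrypt every matrix of an expansion set
#' @param es an `expansion_set`
#' @param pk,params key material and parameters
#' @return list of `encrypted_matrix` objects
#' @export
encrypt_expansion <- function(es, pk, params) {
  structure(lapply(es, encrypt_matrix, pk = pk, params = params),
            kind = attr(es, "kind"), class = "expansion_set")
}

#' Row expansions of an encrypted matrix by shift-and-add
#'
#' Each row of `em` (which must fit one ciphertext block) is isolated with a
#' 0/1 selector plaintext (one level), hoisted to the top of the block (one
#' alignment rotation) and replicated to `width` rows with `log2(width)`
#' shift-and-add doubling rounds, counted as replication rotations.
#'
#' @param em an `encrypted_matrix`, a x b with b a power of two
#' @param width target number of rows, a power of two with
#'   `width * b <= slot_size`
#' @param evk,params evaluation keys and parameters
#' @return an `expansion_set` of `a` encrypted width x b matrices
#' @export
expand_rows_encrypted <- function(em, width, evk, params) {
  b <- em$cols
  if (!is_pow2(width)) stop("shape error: expansion width must be a power of 2")
  if (!is_pow2(b) || width * b > params$slot_size) {
    stop("shape error: need power-of-2 columns and width*cols <= slot_size")
  }
  if (length(em$blocks) != 1) {
    stop("shape error: encrypted row expansion needs a single-block matrix")
  }
  ct <- em$blocks[[1]]
  out <- lapply(seq_len(em$rows), function(i) {
    if (em$rows == 1) {
      # a single-row matrix is already isolated in its block: no selector
      # level and no alignment rotation are needed
      y <- ct
    } else {
      sel <- numeric(params$slot_size)
      sel[((i - 1) * b + 1):(i * b)] <- 1
      y <- he_mul_plain(ct, he_encode(sel, params), params)
      if (i > 1) y <- he_rotate(y, (i - 1) * b, evk, params, count_as = "alignment")
    }
    k <- 1
    while (k < width) {
      y <- he_add(y, he_rotate(y, params$slot_size - b * k, evk, params,
                               count_as = "replication"))
      k <- k * 2
    }
    structure(list(rows = as.integer(width), cols = b, stride = 1L,
                   blocks = list(y)), class = "encrypted_matrix")
  })
  structure(out, kind = "row", class = "expansion_set")
}

# expansion-based matrix multiplication --------------------------------------

# multiply one ce element by one re element; either side may be plaintext
mul_expansion_pair <- function(ce_i, re_i, evk, params) {
  ce_enc <- inherits(ce_i, "encrypted_matrix")
  re_enc <- inherits(re_i, "encrypted_matrix")
  if (ce_enc && re_enc) emat_mul(ce_i, re_i, evk, params)
  else if (ce_enc) emat_mul_plain(ce_i, re_i, params)
  else if (re_enc) emat_mul_plain(re_i, ce_i, params)
  else stop("shape error: at least one expansion side must be encrypted")
}

# replicate a single-block re element across the block structure of the ce
# side (a x c result larger than one block tiles the same expanded row block)
tile_blocks <- function(x, nblocks) {
  if (length(x$blocks) == nblocks) return(x)
  stopifnot(length(x$blocks) == 1)
  x$blocks <- rep(x$blocks, nblocks)
  x
}

#' Matrix product from column and row expansions
#'
#' Computes `sum_i ce_i * re_i` elementwise: the encrypted realisation of
#' the matrix product A %*% B given the column expansions of A and the row
#' expansions of B. Consumes one multiplicative level.
#'
#' @param ce expansion set (encrypted or plaintext) of A's columns
#' @param re expansion set (encrypted or plaintext) of B's rows, same length
#' @param evk,params evaluation keys and parameters
#' @return an `encrypted_matrix` holding A %*% B
#' @export
matmul_expansions <- function(ce, re, evk, params) {
  if (length(ce) != length(re)) {
    stop("shape error: expansion sets have different inner dimension (",
         length(ce), " vs ", length(re), ")")
  }
  shape_of <- function(x) if (inherits(x, "encrypted_matrix")) c(x$rows, x$cols) else dim(x)
  nblocks <- function(x, shp, params) blocks_needed(shp[1], shp[2], params$slot_size)
  acc <- NULL
  for (i in seq_along(ce)) {
    ce_i <- ce[[i]]; re_i <- re[[i]]
    shp <- shape_of(ce_i)
    nb <- nblocks(ce_i, shp, params)
    if (inherits(re_i, "encrypted_matrix") && length(re_i$blocks) < nb) {
      re_i <- tile_blocks(re_i, nb)
      re_i$rows <- shp[1]
    }
    term <- mul_expansion_pair(ce_i, re_i, evk, params)
    acc <- if (is.null(acc)) term else emat_add(acc, term)
  }
  acc
}

# row-row inner products -----------------------------------------------------

#' Row-row inner products by recursive shift-and-add
#'
#' For equal-shape a x b matrices (b a power of two dividing the slot size,
#' rows never straddling blocks), computes the a-vector of per-row inner
#' products `<A_i, B_i>`: one elementwise ciphertext product, then
#' `log2(b)` rotate-and-add accumulation rounds per block, then a 0/1
#' selector keeping every b-th slot. The result is an a x 1 encrypted vector
#' in stride-b layout.
#'
#' @param A,B `encrypted_matrix` objects of identical shape
#' @param evk,params evaluation keys and parameters
#' @return an a x 1 `encrypted_matrix` with `stride = b`
#' @export
row_row_inner <- function(A, B, evk, params) {
  b <- A$cols
  if (!is_pow2(b) || params$slot_size %% b != 0) {
    stop("shape error: column count must be a power of 2 dividing slot_size; pad first")
  }
  stopifnot(A$rows == B$rows, A$cols == B$cols, A$stride == 1, B$stride == 1)
  sel <- numeric(params$slot_size)
  sel[seq(1, params$slot_size, by = b)] <- 1
  sel_pt <- he_encode(sel, params)
  blocks <- Map(function(x, y) {
    r <- he_mul(x, y, evk, params)
    t <- 1
    while (t < b) {
      r <- he_add(r, he_rotate(r, t, evk, params, count_as = "accumulation"))
      t <- 2 * t
    }
    he_mul_plain(r, sel_pt, params)
  }, A$blocks, B$blocks)
  structure(list(rows = A$rows, cols = 1L, stride = as.integer(b),
                 blocks = blocks), class = "encrypted_matrix")
}

# masks ----------------------------------------------------------------------

#' Gaussian mask matrices
#'
#' `make_mask` draws a reproducible Gaussian matrix; for square masks meant
#' to be inverted, seeds yielding condition number above 1e8 are skipped
#' (next seed tried).
#' @param nrow,ncol shape
#' @param sd entry standard deviation
#' @param seed integer seed
#' @param invertible require a well-conditioned square mask
#' @return numeric matrix with attribute `seed` (the seed actually used)
#' @export
make_mask <- function(nrow, ncol = nrow, sd = 1, seed, invertible = FALSE) {
  for (try in 0:20) {
    m <- with_seed(seed + try, matrix(rnorm(nrow * ncol, 0, sd), nrow, ncol))
    if (!invertible || (nrow == ncol && kappa(m) < 1e8)) {
      attr(m, "seed") <- seed + try
      return(m)
    }
  }
  stop("condition error: no well-conditioned mask found near seed ", seed)
}

#' Additive and multiplicative masking of encrypted matrices
#'
#' `apply_mask_add` homomorphically adds an encryption of the mask;
#' `remove_mask_add` subtracts it from the decrypted plaintext.
#' `apply_mask_mul` multiplies slotwise by a plaintext mask in the matrix's
#' own slot layout (used for the positive per-variant masks on score
#' statistics); `remove_mask_mul` divides it out after decryption.
#' @param em an `encrypted_matrix`
#' @param mask numeric matrix of matching shape
#' @param pk,params key material and parameters
#' @param decrypted plaintext matrix after collective decryption
#' @return an `encrypted_matrix` (apply) or plaintext matrix (remove)
#' @export
apply_mask_add <- function(em, mask, pk, params) {
  enc <- encrypt_matrix(mask, pk, params, stride = em$stride,
                        scale = emat_scale(em))
  enc <- emat_level_drop(enc, emat_level(em))
  emat_add(em, enc)
}

#' @rdname apply_mask_add
#' @export
remove_mask_add <- function(decrypted, mask) decrypted - mask

#' @rdname apply_mask_add
#' @export
apply_mask_mul <- function(em, mask, params) {
  emat_mul_plain(em, mask, params)
}

#' @rdname apply_mask_add
#' @export
remove_mask_mul <- function(decrypted, mask) decrypted / mask
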