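# Shared-space file exchange (star topology over a local directory) and the
# multiparty building blocks: collective matrix decryption, masked
# collaborative inversion and collective ciphertext refresh. The driver runs
# all sites round-robin in one process; every quantity that crosses a site
# boundary passes through the shared space as an encrypted or AEAD-protected
# file, and one designated site (the lowest id) publishes the canonical copy
# of pooled ciphertexts so that partial decryptions refer to one object.

#' Create a shared-space handle over a local directory
#'
#' Files are immutable once uploaded; `probe` is side-effect-free;
#' `wait_for` polls until a file appears or the timeout elapses.
#' @param dir directory used as the shared space (created if needed)
#' @param poll_interval seconds between polls
#' @param timeout seconds before a stall error
#' @return a `shared_space` handle
#' @export
shared_space <- function(dir, poll_interval = 0.1, timeout = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- new.env(parent = emptyenv())
  sp$dir <- dir
  sp$poll_interval <- poll_interval
  sp$timeout <- timeout
  sp$round <- 0L
  class(sp) <- "shared_space"
  sp
}

next_round <- function(space) {
  space$round <- space$round + 1L
  space$round
}

space_path <- function(space, name) file.path(space$dir, name)

#' Shared-space file operations
#' @param space a `shared_space`
#' @param name file name within the space
#' @param payload raw vector to store
#' @return `upload`: the name invisibly; `download`: the raw payload;
#'   `probe`: logical; `wait_for`: the name invisibly once present
#' @export
space_upload <- function(space, name, payload) {
  path <- space_path(space, name)
  if (file.exists(path)) {
    stop("immutability error: ", name, " already uploaded")
  }
  writeBin(payload, path)
  invisible(name)
}

#' @rdname space_upload
#' @export
space_download <- function(space, name) {
  path <- space_path(space, name)
  if (!file.exists(path)) stop("missing file: ", name)
  readBin(path, "raw", file.info(path)$size)
}

#' @rdname space_upload
#' @export
space_probe <- function(space, name) file.exists(space_path(space, name))

#' @rdname space_upload
#' @export
space_wait_for <- function(space, name) {
  t0 <- Sys.time()
  while (!space_probe(space, name)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > space$timeout) {
      stop("stall error: timed out waiting for ", name,
           " (round ", space$round, ")")
    }
    Sys.sleep(space$poll_interval)
  }
  invisible(name)
}

upload_encmat <- function(space, name, em) {
  space_upload(space, name, serialize(unclass(em), NULL))
}

download_encmat <- function(space, name) {
  space_wait_for(space, name)
  structure(unserialize(space_download(space, name)), class = "encrypted_matrix")
}

#' Per-site protocol context
#'
#' Holds one site's key material and an independent deterministic seed
#' stream; a site never sees another site's secret share.
#' @param site_id integer site id (1-based)
#' @param bundle the common `he_key_bundle`
#' @param passphrase site passphrase for opening the bundle
#' @param seed base seed of the site's randomness stream
#' @return a `site_context`
#' @export
site_context <- function(site_id, bundle, passphrase = sprintf("site-%d-pass", site_id),
                         seed = 1000 + site_id) {
  opened <- open_key_bundle(bundle, site_id, passphrase)
  ctx <- new.env(parent = emptyenv())
  ctx$site_id <- site_id
  ctx$params <- bundle$params
  ctx$pk <- bundle$public_key
  ctx$evk <- bundle$eval_keys
  ctx$share <- opened$share
  ctx$symkey <- opened$symkey
  ctx$seed <- seed
  ctx$draw <- 0L
  class(ctx) <- "site_context"
  ctx
}

# next seed in this site's deterministic stream
ctx_seed <- function(ctx) {
  ctx$draw <- ctx$draw + 1L
  (ctx$seed * 2654435761 + ctx$draw * 40503) %% 2147483629
}

lead_site <- function(sites) {
  ids <- vapply(sites, function(s) s$site_id, numeric(1))
  sites[[which.min(ids)]]
}

#' Collectively decrypt an encrypted matrix
#'
#' Every site computes AEAD-protected partial decryptions of each block
#' (the lowest site id contributes the c0 term), uploads them, then
#' downloads and authenticates all partials and aggregates. All sites obtain
#' the same plaintext; the per-site copies are attached as an attribute.
#'
#' @param em the canonical `encrypted_matrix` to decrypt
#' @param sites list of `site_context` objects
#' @param space a `shared_space`
#' @param tag file-name tag for this decryption
#' @return the decrypted plaintext matrix (attribute `per_site`: all copies)
#' @export
collective_decrypt_matrix <- function(em, sites, space, tag = "dec") {
  r <- next_round(space)
  cdm_upload_partials(em, sites, space, tag, r)
  cdm_aggregate(em, sites, space, tag, r)
}

cdm_upload_partials <- function(em, sites, space, tag, r) {
  params <- sites[[1]]$params
  lead <- lead_site(sites)$site_id
  for (ctx in sites) {
    for (k in seq_along(em$blocks)) {
      pd <- partial_decrypt(em$blocks[[k]], ctx$share, params,
                            include_c0 = ctx$site_id == lead,
                            seed = ctx_seed(ctx))
      name <- sprintf("r%d_s%d_%s_b%d.pardec", r, ctx$site_id, tag, k)
      blob <- aead_encrypt(ctx$symkey, serialize(pd, NULL), aad = charToRaw(name))
      space_upload(space, name, blob)
    }
  }
}

cdm_aggregate <- function(em, sites, space, tag, r) {
  params <- sites[[1]]$params
  per_site <- lapply(sites, function(ctx) {
    slot_list <- lapply(seq_along(em$blocks), function(k) {
      partials <- lapply(sites, function(other) {
        name <- sprintf("r%d_s%d_%s_b%d.pardec", r, other$site_id, tag, k)
        space_wait_for(space, name)
        unserialize(aead_decrypt(ctx$symkey, space_download(space, name),
                                 aad = charToRaw(name)))
      })
      aggregate_partials(partials, params)$slots
    })
    matrix_from_slots(em, slot_list)
  })
  out <- per_site[[1]]
  attr(out, "per_site") <- per_site
  out
}

#' Masked collaborative matrix inversion
#'
#' Inverts a pooled p x p matrix Upsilon = sum_s Upsilon_s without revealing
#' it: sites pool encrypted Gaussian masks H = sum_s H_s (exchanged as
#' encrypted row/column expansions), each site multiplies its own plaintext
#' Upsilon_s into the encrypted mask, the pooled Upsilon*H is collectively
#' decrypted, inverted in plaintext (yielding H^-1 Upsilon^-1), and the mask
#' is removed homomorphically, leaving the zero-padded encrypted inverse
#' pad(Upsilon^-1) at the next power-of-two size.
#'
#' @param upsilons list (one per site) of that site's plaintext p x p
#'   local term; site s only ever touches its own entry
#' @param sites list of `site_context` objects
#' @param space a `shared_space`
#' @param mask_sd standard deviation of the Gaussian mask entries
#' @return an encrypted c x c matrix, c = next power of two above p,
#'   holding pad(Upsilon^-1)
#' @export
masked_collaborative_inverse <- function(upsilons, sites, space, mask_sd = 1) {
  params <- sites[[1]]$params
  p0 <- nrow(upsilons[[1]])
  cc <- next_pow2(p0)
  r <- next_round(space)
  # step 1: every site uploads encrypted expansions of its own mask
  masks <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    H_s <- make_mask(p0, p0, sd = mask_sd, seed = ctx_seed(ctx))
    masks[[i]] <- H_s
    re_enc <- encrypt_expansion(expand_rows(H_s, p0), ctx$pk, params)
    ce_enc <- encrypt_expansion(expand_columns(pad_matrix(H_s, cc, cc), cc),
                                ctx$pk, params)
    for (j in seq_len(p0)) {
      upload_encmat(space, sprintf("r%d_s%d_maskre_%d.encmat", r, ctx$site_id, j),
                    re_enc[[j]])
    }
    for (j in seq_len(cc)) {
      upload_encmat(space, sprintf("r%d_s%d_maskce_%d.encmat", r, ctx$site_id, j),
                    ce_enc[[j]])
    }
  }
  # step 2: each site pools the mask expansions and multiplies in its own
  # plaintext local term; uploads encrypted Upsilon_s * H
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    re_H <- lapply(seq_len(p0), function(j) {
      Reduce(emat_add, lapply(sites, function(other) {
        download_encmat(space, sprintf("r%d_s%d_maskre_%d.encmat", r, other$site_id, j))
      }))
    })
    ups_H <- matmul_expansions(expand_columns(upsilons[[i]], p0), re_H,
                               ctx$evk, params)
    upload_encmat(space, sprintf("r%d_s%d_upsH.encmat", r, ctx$site_id), ups_H)
  }
  # step 3: the lead site publishes the canonical pooled Upsilon*H
  lead <- lead_site(sites)
  pooled <- Reduce(emat_add, lapply(sites, function(other) {
    download_encmat(space, sprintf("r%d_s%d_upsH.encmat", r, other$site_id))
  }))
  upload_encmat(space, sprintf("r%d_pooled_upsH.encmat", r), pooled)
  # step 4: collective decryption of the masked pooled matrix
  upsH_plain <- collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_pooled_upsH.encmat", r)),
    sites, space, tag = sprintf("upsHdec%d", r))
  if (!all(is.finite(upsH_plain)) || kappa(upsH_plain) > 1e8) {
    stop("condition error: masked pooled matrix is numerically singular; ",
         "rerun with fresh mask seeds")
  }
  # step 5: plaintext inversion gives H^-1 Upsilon^-1; the lead site removes
  # the mask homomorphically using the pooled encrypted column expansions
  HinvUinv <- pad_matrix(solve(upsH_plain), cc, cc)
  ce_H <- lapply(seq_len(cc), function(j) {
    Reduce(emat_add, lapply(sites, function(other) {
      download_encmat(space, sprintf("r%d_s%d_maskce_%d.encmat", r, other$site_id, j))
    }))
  })
  inv_enc <- matmul_expansions(ce_H, expand_rows(HinvUinv, cc), lead$evk, params)
  upload_encmat(space, sprintf("r%d_pad_inv.encmat", r), inv_enc)
  download_encmat(space, sprintf("r%d_pad_inv.encmat", r))
}

#' Collective ciphertext refresh
#'
#' Restores a (possibly depth-exhausted, scale-grown) encrypted matrix to a
#' fresh encryption at maximum level and base scale without revealing its
#' value: sites pool an additive collective mask, the masked matrix is
#' collectively decrypted, re-encrypted fresh by the lead site, and the mask
#' is removed homomorphically.
#'
#' @param em the canonical `encrypted_matrix`
#' @param sites list of `site_context` objects
#' @param space a `shared_space`
#' @param tag file-name tag
#' @param mask_sd additive mask standard deviation (choose well above the
#'   data scale)
#' @return a fresh `encrypted_matrix` with the same plaintext value
#' @export
collective_refresh <- function(em, sites, space, tag = "refresh", mask_sd = 1e3) {
  params <- sites[[1]]$params
  r <- next_round(space)
  if (params$backend == "toy_ckks") {
    # the mask is encoded at the ciphertext's grown scale; keep
    # 6*sd*S*scale safely below q/2 so the masked encoding cannot wrap
    cap <- 2^(params$qbits - 1 - log2(emat_scale(em)) - 5 -
                log2(params$n_sites))
    mask_sd <- min(mask_sd, cap)
    if (mask_sd <= 0 || !is.finite(mask_sd)) {
      stop("depth error: no modulus headroom left to refresh at scale 2^",
           round(log2(emat_scale(em))))
    }
  }
  shape_r <- em$rows; shape_c <- em$cols
  masks <- list()
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    R_s <- make_mask(shape_r, shape_c, sd = mask_sd, seed = ctx_seed(ctx))
    masks[[i]] <- R_s
    enc_old <- encrypt_matrix(R_s, ctx$pk, params, stride = em$stride,
                              scale = emat_scale(em))
    enc_new <- encrypt_matrix(R_s, ctx$pk, params, stride = em$stride)
    upload_encmat(space, sprintf("r%d_s%d_%s_maskold.encmat", r, ctx$site_id, tag), enc_old)
    upload_encmat(space, sprintf("r%d_s%d_%s_masknew.encmat", r, ctx$site_id, tag), enc_new)
  }
  pooled_old <- Reduce(emat_add, lapply(sites, function(other) {
    download_encmat(space, sprintf("r%d_s%d_%s_maskold.encmat", r, other$site_id, tag))
  }))
  masked <- emat_add(em, emat_level_drop(pooled_old, emat_level(em)))
  upload_encmat(space, sprintf("r%d_%s_masked.encmat", r, tag), masked)
  masked_plain <- collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_%s_masked.encmat", r, tag)),
    sites, space, tag = sprintf("%sdec%d", tag, r))
  lead <- lead_site(sites)
  fresh <- encrypt_matrix(masked_plain, lead$pk, params, stride = em$stride)
  pooled_new <- Reduce(emat_add, lapply(sites, function(other) {
    download_encmat(space, sprintf("r%d_s%d_%s_masknew.encmat", r, other$site_id, tag))
  }))
  out <- emat_sub(fresh, pooled_new)
  upload_encmat(space, sprintf("r%d_%s_fresh.encmat", r, tag), out)
  download_encmat(space, sprintf("r%d_%s_fresh.encmat", r, tag))
}

# refresh when the remaining depth budget (or, on the toy backend, the
# modulus headroom left for the scale) cannot cover the upcoming chain:
# `need_levels` more multiplications whose partner scales contribute
# `extra_scale_log2` additional bits to the final recorded scale
ensure_capacity <- function(em, need_levels, sites, space, tag, mask_sd = 1e3,
                            extra_scale_log2 = NULL) {
  params <- sites[[1]]$params
  if (is.null(extra_scale_log2)) {
    extra_scale_log2 <- need_levels * params$scale_bits
  }
  need_refresh <- emat_level(em) < need_levels
  if (!need_refresh && params$backend == "toy_ckks") {
    head <- params$qbits - (log2(emat_scale(em)) + extra_scale_log2)
    need_refresh <- head < 15
  }
  if (need_refresh) collective_refresh(em, sites, space, tag, mask_sd) else em
}
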