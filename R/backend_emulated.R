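# EmulatedCKKS: plaintext slot vectors with CKKS semantics. Slot values are
# stored whitened by a pseudo-random offset keyed to a per-ciphertext nonce
# so that no exchanged file contains raw data; every operation adds a small
# Gaussian perturbation (sd 2^-scale_bits per slot) to mimic approximation
# noise, and the level/scale bookkeeping is identical to the toy backend.

EM_WHITEN_HW <- 2^20  # half-width of the whitening offset

em_values <- function(ct) {
  ct$payload$w + prf_uniform(ct$payload$nonce, 0, length(ct$payload$w), EM_WHITEN_HW)
}

em_wrap <- function(values, level, scale, sb) {
  values <- values + rnorm(length(values), 0, 2^(-sb))
  nonce <- fresh_nonce()
  w <- values - prf_uniform(nonce, 0, length(values), EM_WHITEN_HW)
  new_ciphertext("emulated", list(w = w, nonce = nonce, sb = sb),
                 level = level, scale = scale, n_slots = length(values))
}

em_encrypt <- function(pt, params) {
  em_wrap(pt$slots, level = params$max_level, scale = pt$scale,
          sb = params$scale_bits)
}

em_add <- function(a, b) {
  em_wrap(em_values(a) + em_values(b), a$level, a$scale, a$payload$sb)
}

em_sub <- function(a, b) {
  em_wrap(em_values(a) - em_values(b), a$level, a$scale, a$payload$sb)
}

em_mul <- function(a, b) {
  em_wrap(em_values(a) * em_values(b), a$level - 1, a$scale * b$scale,
          a$payload$sb)
}

em_mul_plain <- function(a, pt) {
  em_wrap(em_values(a) * pt$slots, a$level - 1, a$scale * pt$scale,
          a$payload$sb)
}

em_rotate <- function(a, t) {
  v <- em_values(a)
  n <- length(v)
  em_wrap(v[((seq_len(n) - 1 + t) %% n) + 1], a$level, a$scale, a$payload$sb)
}

em_partial_decrypt <- function(ct, share, params, include_c0) {
  v <- ct$payload$w
  n <- length(v)
  S <- params$n_sites
  s <- share$site_id
  nonce <- ct$payload$nonce
  # shares u_1..u_S are pseudo-random vectors, derivable from the public
  # nonce, summing to the whitening offset; the c0 analogue is the whitened
  # payload itself, so partials aggregate to the slot values
  r <- prf_uniform(nonce, 0, n, EM_WHITEN_HW)
  if (s < S) {
    u <- prf_uniform(nonce, 1000 + s, n, EM_WHITEN_HW)
  } else {
    u <- r
    for (k in seq_len(S - 1)) u <- u - prf_uniform(nonce, 1000 + k, n, EM_WHITEN_HW)
  }
  # ring-layer smudging of variance 2^smudging_bits decodes to a
  # perturbation of sd 2^(smudging_bits/2)/scale: 2^(sm/2 - scale_bits) on a
  # fresh ciphertext, decaying as the scale grows under multiplication
  sm_sd <- 2^(params$smudging_bits / 2) / ct$scale
  pd <- u + rnorm(n, 0, sm_sd)
  if (include_c0) pd <- pd + v
  structure(list(site_id = s, payload = pd, includes_c0 = include_c0,
                 backend = "emulated", scale = ct$scale, n_slots = n),
            class = "partial_decryption")
}

em_aggregate <- function(partials, params) {
  slots <- Reduce(`+`, lapply(partials, `[[`, "payload"))
  structure(list(slots = slots, scale = 1), class = "he_plaintext")
}
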