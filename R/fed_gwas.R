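# Federated GWAS for binary phenotypes: IRLS null-model fitting with masked
# collaborative inversion of the pooled information matrix, then per-variant
# score-test statistics (score numerator T and variance S) pooled, squared,
# masked and collectively decrypted, with chi-squared(1) p-values.

#' Assemble a per-site cohort
#'
#' @param X N x p covariate matrix, intercept column first
#' @param y length-N binary phenotype (0/1)
#' @param G N x M genotype dosage matrix (0/1/2 scale; NAs allowed before
#'   imputation)
#' @return a `site_cohort`
#' @export
site_cohort <- function(X, y, G) {
  X <- as.matrix(X); G <- as.matrix(G); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(G) == length(y))
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  structure(list(X = X, y = y, G = G, N = length(y), p = ncol(X), M = ncol(G)),
            class = "site_cohort")
}

#' Mean-impute missing genotype dosages
#'
#' Missing entries are replaced by the per-variant mean of the observed
#' dosages, computed site-locally. All-missing variants are flagged in the
#' attribute `flagged` and set to zero dosage.
#' @param G genotype matrix with NAs
#' @return imputed matrix with attributes `n_missing` and `flagged`
#' @export
mean_impute <- function(G) {
  G <- as.matrix(G)
  nmiss <- colSums(is.na(G))
  flagged <- which(nmiss == nrow(G))
  for (j in which(nmiss > 0)) {
    mu <- mean(G[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    G[is.na(G[, j]), j] <- mu
  }
  attr(G, "n_missing") <- nmiss
  attr(G, "flagged") <- flagged
  G
}

#' One site's IRLS working quantities at the current weights
#'
#' mu0 = logistic(X alpha) clamped to (1e-8, 1-1e-8); W = mu0 (1 - mu0);
#' working response z = X alpha + (y - mu0)/W; and the aggregates
#' Upsilon_s = X'WX (p x p) and X'Wz (p x 1).
#' @param cohort a `site_cohort`
#' @param alpha current null-model weight vector (length p)
#' @return list with mu0, W, z, upsilon, xwz
#' @export
irls_local_terms <- function(cohort, alpha) {
  if (!all(is.finite(alpha))) stop("state error: non-finite weights")
  eta <- drop(cohort$X %*% alpha)
  mu0 <- pmin(pmax(plogis(eta), 1e-8), 1 - 1e-8)
  W <- mu0 * (1 - mu0)
  z <- eta + (cohort$y - mu0) / W
  list(mu0 = mu0, W = W, z = z,
       upsilon = crossprod(cohort$X, cohort$X * W),
       xwz = crossprod(cohort$X, W * z))
}

gwas_cc <- function(p) next_pow2(p)

#' One epoch of the federated IRLS null model
#'
#' Each site computes its plaintext local terms, the pooled information
#' matrix is inverted through the masked collaborative protocol (the
#' encrypted padded inverse is retained in the state), the pooled X'Wz is
#' summed encrypted, the update alpha_new = pad(Upsilon^-1) %*% pad(X'Wz)
#' is evaluated with an encrypted row expansion and a row-row product, and
#' alpha_new is collectively decrypted and broadcast.
#'
#' @param cohorts list of `site_cohort` objects (site s touches entry s)
#' @param sites list of `site_context` objects
#' @param space a `shared_space`
#' @param state previous state (NULL to start from alpha = 0)
#' @param mask_sd Gaussian mask sd for the collaborative inversion
#' @return an updated `null_model_state` with fields alpha, epoch,
#'   converged, delta, enc_inverse
#' @export
null_model_epoch <- function(cohorts, sites, space, state = NULL, mask_sd = 1) {
  params <- sites[[1]]$params
  p <- cohorts[[1]]$p
  if (any(vapply(cohorts, function(ch) ch$p, numeric(1)) != p)) {
    stop("protocol error: covariate count differs across sites")
  }
  cc <- gwas_cc(p)
  alpha <- if (is.null(state)) numeric(p) else state$alpha
  epoch <- if (is.null(state)) 0L else state$epoch
  locals <- lapply(cohorts, irls_local_terms, alpha = alpha)
  # masked collaborative inversion of pooled X'WX
  enc_inv <- masked_collaborative_inverse(lapply(locals, `[[`, "upsilon"),
                                          sites, space, mask_sd = mask_sd)
  # upcoming chain: the r2r update aligns both operands to the larger scale
  # and multiplies, then applies its selector, so the final recorded scale
  # is 2*max(scale(inv), scale(re)) * Delta; the row expansion of the
  # single-row X'Wz costs no selector level and stays at base scale
  sb <- params$scale_bits
  own <- log2(emat_scale(enc_inv))
  enc_inv <- ensure_capacity(enc_inv, 2, sites, space, tag = "inv",
                             extra_scale_log2 = 2 * max(own, sb) + sb - own)
  # pooled encrypted X'Wz, padded to cc
  r <- next_round(space)
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    xwz_pad <- pad_matrix(locals[[i]]$xwz, cc, 1)
    upload_encmat(space, sprintf("r%d_s%d_xwz.encmat", r, ctx$site_id),
                  encrypt_matrix(t(xwz_pad), ctx$pk, params))  # 1 x cc row
  }
  pooled_xwz <- Reduce(emat_add, lapply(sites, function(other) {
    download_encmat(space, sprintf("r%d_s%d_xwz.encmat", r, other$site_id))
  }))
  lead <- lead_site(sites)
  # encrypted row expansion of (X'Wz)' to cc rows, then row-row product
  re_xwz <- expand_rows_encrypted(pooled_xwz, cc, lead$evk, params)[[1]]
  lvl <- min(emat_level(enc_inv), emat_level(re_xwz))
  sc <- max(emat_scale(enc_inv), emat_scale(re_xwz))
  A <- emat_align_to(enc_inv, lvl, sc, params)
  B <- emat_align_to(re_xwz, lvl, sc, params)
  alpha_enc <- row_row_inner(A, B, lead$evk, params)
  upload_encmat(space, sprintf("r%d_alpha.encmat", r), alpha_enc)
  alpha_mat <- collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_alpha.encmat", r)),
    sites, space, tag = sprintf("alpha%d", r))
  alpha_new <- drop(alpha_mat)[seq_len(p)]
  delta <- max(abs(alpha_new - alpha))
  structure(list(alpha = alpha_new, epoch = epoch + 1L, delta = delta,
                 converged = FALSE, enc_inverse = enc_inv, locals = locals),
            class = "null_model_state")
}

#' Fit the federated logistic null model
#'
#' Iterates [null_model_epoch()] from alpha = 0 until the maximum absolute
#' weight change drops below `tol` or `max_epochs` is reached.
#' @param cohorts,sites,space as in [null_model_epoch()]
#' @param tol convergence tolerance on max |delta alpha|
#' @param max_epochs epoch cap
#' @param mask_sd inversion mask sd
#' @param verbose print per-epoch progress
#' @return the final `null_model_state`
#' @export
fit_null_model <- function(cohorts, sites, space, tol = 1e-4, max_epochs = 10,
                           mask_sd = 1, verbose = FALSE) {
  state <- NULL
  for (e in seq_len(max_epochs)) {
    state <- null_model_epoch(cohorts, sites, space, state, mask_sd = mask_sd)
    if (verbose) {
      message(sprintf("epoch %d: max|dalpha| = %.3g", state$epoch, state$delta))
    }
    if (state$delta < tol) {
      state$converged <- TRUE
      break
    }
  }
  if (!state$converged && state$delta >= tol) {
    warning("null model did not converge in ", max_epochs,
            " epochs (max|dalpha| = ", signif(state$delta, 3), ")")
  }
  # scoring reuses the final epoch's W, mu0 and encrypted inverse (the
  # weights they were computed at differ from the returned alpha by less
  # than the convergence tolerance)
  state
}

#' One site's encrypted score-test terms
#'
#' With the fitted null model (weights W and fitted probabilities mu0 from
#' the final epoch), computes the site's score numerator
#' T_s = G'(y - mu0), the per-variant diagonal of G'WG, the padded G'WX and
#' its encrypted product with pad(Upsilon^-1).
#'
#' @param cohort a `site_cohort` (genotypes already imputed)
#' @param local that site's `irls_local_terms` at the final weights
#' @param enc_inv the encrypted padded inverse from the null model state
#' @param ctx the site's `site_context`
#' @param params an [he_params()] object
#' @return list of encrypted matrices: T_s (M x 1 dense), s1 (M x 1,
#'   stride cc), s21 (M x cc), s22 (M x cc, the product with the inverse)
#' @export
score_local_terms <- function(cohort, local, enc_inv, ctx, params) {
  cc <- enc_inv$cols
  G <- cohort$G
  T_s <- crossprod(G, cohort$y - local$mu0)              # M x 1
  d_s <- colSums(G * G * local$W)                        # diag(G'WG)
  gwx <- crossprod(G, local$W * cohort$X)                # M x p
  gwx_pad <- pad_matrix(gwx, nrow(gwx), cc)
  # plaintext column expansions of G'WX times the encrypted row expansions
  # of the padded inverse; rows are expanded to fill whole blocks so the
  # single-block expansions tile across the M x cc block structure
  re_inv <- expand_rows_encrypted(enc_inv, params$slot_size / cc, ctx$evk, params)
  ce_gwx <- expand_columns(gwx_pad, cc)
  s22 <- matmul_expansions(ce_gwx, re_inv, ctx$evk, params)
  s22$rows <- nrow(gwx_pad); s22$cols <- cc
  list(T_s = encrypt_matrix(T_s, ctx$pk, params),
       s1 = encrypt_matrix(matrix(d_s, ncol = 1), ctx$pk, params, stride = cc),
       s21 = encrypt_matrix(gwx_pad, ctx$pk, params),
       s22 = s22)
}

#' Pool score terms, mask, decrypt and assign p-values
#'
#' Pools the sites' encrypted terms, computes the score variance
#' S = diag(G'WG) - rowdot(G'WX, G'WX Upsilon^-1) with a row-row product,
#' squares the pooled T homomorphically, applies a common positive
#' per-variant mask (the sum of per-site Uniform(0.5, 1.5) masks, applied
#' identically to T^2 and S), collectively decrypts the masked pair and
#' assigns chi-squared(1) upper-tail p-values to T^2/S.
#'
#' @param terms list (one per site) of [score_local_terms()] outputs
#' @param sites,space protocol handles
#' @param variant_ids optional variant names
#' @param af per-variant alternate-allele frequencies to report
#' @param n_missing per-variant missing counts to report
#' @return a `gwas_result` data frame: variant, stat, p, af, n_missing
#' @export
pool_and_finalize <- function(terms, sites, space, variant_ids = NULL,
                              af = NULL, n_missing = NULL) {
  params <- sites[[1]]$params
  lead <- lead_site(sites)
  r <- next_round(space)
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    for (nm in c("T_s", "s1", "s21", "s22")) {
      upload_encmat(space, sprintf("r%d_s%d_%s.encmat", r, ctx$site_id, nm),
                    terms[[i]][[nm]])
    }
  }
  pool <- function(nm) {
    Reduce(emat_add, lapply(sites, function(other) {
      download_encmat(space, sprintf("r%d_s%d_%s.encmat", r, other$site_id, nm))
    }))
  }
  T_enc <- pool("T_s"); S1 <- pool("s1"); S21 <- pool("s21"); S22 <- pool("s22")
  M <- T_enc$rows
  cc <- S21$cols
  # S2 = rowdot(S21, S22) via shift-and-add; S22 may need a refresh first
  # (the r2r aligns to the larger scale, multiplies, then its selector)
  sb <- params$scale_bits
  own <- log2(emat_scale(S22))
  S22 <- ensure_capacity(S22, 2, sites, space, tag = "s22", mask_sd = 1e3,
                         extra_scale_log2 =
                           2 * max(own, log2(emat_scale(S21))) + sb - own)
  lvl <- min(emat_level(S21), emat_level(S22))
  sc <- max(emat_scale(S21), emat_scale(S22))
  S2 <- row_row_inner(emat_align_to(S21, lvl, sc, params),
                      emat_align_to(S22, lvl, sc, params), lead$evk, params)
  S1a <- emat_align_to(S1, emat_level(S2), emat_scale(S2), params)
  S_enc <- emat_sub(S1a, S2)
  # T^2, homomorphically
  T2 <- emat_mul(T_enc, T_enc, lead$evk, params)
  T2 <- ensure_capacity(T2, 1, sites, space, tag = "t2", mask_sd = 1e3)
  S_enc <- ensure_capacity(S_enc, 1, sites, space, tag = "svar", mask_sd = 1e3)
  # common positive per-variant mask: sum over sites of Uniform(0.5, 1.5)
  # masks, applied identically to T^2 and S in their own slot layouts
  r2 <- next_round(space)
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    cmask <- with_seed(ctx_seed(ctx), matrix(runif(M, 0.5, 1.5), ncol = 1))
    upload_encmat(space, sprintf("r%d_s%d_maskedT2.encmat", r2, ctx$site_id),
                  apply_mask_mul(T2, cmask, params))
    upload_encmat(space, sprintf("r%d_s%d_maskedS.encmat", r2, ctx$site_id),
                  apply_mask_mul(S_enc, cmask, params))
  }
  pool2 <- function(nm) {
    Reduce(emat_add, lapply(sites, function(other) {
      download_encmat(space, sprintf("r%d_s%d_%s.encmat", r2, other$site_id, nm))
    }))
  }
  maskedT2 <- pool2("maskedT2"); maskedS <- pool2("maskedS")
  upload_encmat(space, sprintf("r%d_maskedT2.encmat", r2), maskedT2)
  upload_encmat(space, sprintf("r%d_maskedS.encmat", r2), maskedS)
  t2_plain <- drop(collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_maskedT2.encmat", r2)),
    sites, space, tag = "t2dec"))
  s_plain <- drop(collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_maskedS.encmat", r2)),
    sites, space, tag = "sdec"))
  stat <- t2_plain / s_plain
  bad <- !is.finite(stat) | s_plain <= 0
  stat[bad] <- NA_real_
  pval <- pchisq(stat, df = 1, lower.tail = FALSE)
  structure(data.frame(
    variant = if (is.null(variant_ids)) paste0("v", seq_len(M)) else variant_ids,
    stat = stat, p = pval,
    af = if (is.null(af)) NA_real_ else af,
    n_missing = if (is.null(n_missing)) 0L else n_missing,
    stringsAsFactors = FALSE), class = c("gwas_result", "data.frame"))
}

#' Run the full secure federated GWAS
#'
#' Convenience driver: mean-imputes genotypes, fits the federated null
#' model, computes and pools the encrypted score terms, and assigns
#' p-values.
#' @param cohorts list of `site_cohort` objects
#' @param sites list of `site_context` objects
#' @param space a `shared_space`
#' @param tol,max_epochs IRLS stopping rule
#' @param verbose print progress
#' @return a `gwas_result` data frame
#' @export
run_secure_gwas <- function(cohorts, sites, space, tol = 1e-4, max_epochs = 10,
                            verbose = FALSE) {
  params <- sites[[1]]$params
  nmiss <- Reduce(`+`, lapply(cohorts, function(ch) colSums(is.na(ch$G))))
  cohorts <- lapply(cohorts, function(ch) {
    ch$G <- mean_impute(ch$G)
    ch
  })
  state <- fit_null_model(cohorts, sites, space, tol = tol,
                          max_epochs = max_epochs, verbose = verbose)
  enc_inv <- state$enc_inverse
  terms <- lapply(seq_along(cohorts), function(i) {
    score_local_terms(cohorts[[i]], state$locals[[i]], enc_inv,
                      sites[[i]], params)
  })
  ac <- Reduce(`+`, lapply(cohorts, function(ch) colSums(ch$G)))
  an <- sum(vapply(cohorts, function(ch) ch$N, numeric(1)))
  res <- pool_and_finalize(terms, sites, space,
                           af = ac / (2 * an), n_missing = nmiss)
  attr(res, "null_model") <- state[c("alpha", "epoch", "converged", "delta")]
  res
}

#' Plaintext federated GWAS (reference protocol without encryption)
#'
#' Runs the identical federated computation on plaintext aggregates: pooled
#' IRLS on summed per-site X'WX / X'Wz, then the pooled score test. Used as
#' the unprotected baseline the secure protocol is compared against.
#' @param cohorts list of `site_cohort` objects
#' @param tol,max_epochs IRLS stopping rule
#' @return a `gwas_result` data frame
#' @export
plain_federated_gwas <- function(cohorts, tol = 1e-4, max_epochs = 10) {
  cohorts <- lapply(cohorts, function(ch) { ch$G <- mean_impute(ch$G); ch })
  p <- cohorts[[1]]$p
  alpha <- numeric(p)
  for (e in seq_len(max_epochs)) {
    locals <- lapply(cohorts, irls_local_terms, alpha = alpha)
    ups <- Reduce(`+`, lapply(locals, `[[`, "upsilon"))
    xwz <- Reduce(`+`, lapply(locals, `[[`, "xwz"))
    alpha_new <- drop(solve(ups, xwz))
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
  }
  # like the secure protocol, score with the final epoch's W, mu0, inverse
  ups_inv <- solve(Reduce(`+`, lapply(locals, `[[`, "upsilon")))
  T_pool <- Reduce(`+`, lapply(seq_along(cohorts), function(i) {
    crossprod(cohorts[[i]]$G, cohorts[[i]]$y - locals[[i]]$mu0)
  }))
  S1 <- Reduce(`+`, lapply(seq_along(cohorts), function(i) {
    colSums(cohorts[[i]]$G^2 * locals[[i]]$W)
  }))
  GWX <- Reduce(`+`, lapply(seq_along(cohorts), function(i) {
    crossprod(cohorts[[i]]$G, locals[[i]]$W * cohorts[[i]]$X)
  }))
  S <- S1 - rowSums((GWX %*% ups_inv) * GWX)
  stat <- drop(T_pool)^2 / S
  stat[S <= 0] <- NA_real_
  structure(data.frame(
    variant = paste0("v", seq_along(stat)),
    stat = stat, p = pchisq(stat, 1, lower.tail = FALSE),
    af = NA_real_, n_missing = 0L, stringsAsFactors = FALSE),
    class = c("gwas_result", "data.frame"))
}
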