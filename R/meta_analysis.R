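# Secure meta-analysis: each site fits its own plaintext null model and
# computes per-variant score statistics T_s and S_s; the encrypted
# statistics are pooled by summation, the pooled T is squared
# homomorphically, a common positive mask is applied to (sum T)^2 and
# sum S, and the masked pair is collectively decrypted for chi-squared(1)
# p-values.

#' Local plaintext score-test summary for one site
#'
#' Fits the site's own logistic null model by IRLS (plaintext, no
#' federation) and computes T_s = G'(y - mu0) and
#' S_s = diag(G'WG) - rowdot(G'WX (X'WX)^-1, G'WX).
#' @param cohort a `site_cohort`
#' @param tol,max_epochs IRLS stopping rule
#' @return a `site_summary` with fields T, S, converged
#' @export
local_site_summary <- function(cohort, tol = 1e-4, max_epochs = 25) {
  cohort$G <- mean_impute(cohort$G)
  alpha <- numeric(cohort$p)
  converged <- FALSE
  for (e in seq_len(max_epochs)) {
    local <- irls_local_terms(cohort, alpha)
    alpha_new <- drop(solve(local$upsilon, local$xwz))
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("site-local null model did not converge; summary emitted anyway")
  }
  local <- irls_local_terms(cohort, alpha)
  T_s <- drop(crossprod(cohort$G, cohort$y - local$mu0))
  gwx <- crossprod(cohort$G, local$W * cohort$X)
  S_s <- colSums(cohort$G^2 * local$W) -
    rowSums((gwx %*% solve(local$upsilon)) * gwx)
  structure(list(T = T_s, S = S_s, converged = converged, alpha = alpha),
            class = "site_summary")
}

#' Securely combine per-site score summaries
#'
#' Sites encrypt their local T_s and S_s vectors, the encrypted statistics
#' are pooled by summation, (sum T)^2 is formed homomorphically, both
#' quantities receive the same positive per-variant collective mask (sum of
#' per-site Uniform(0.5, 1.5) masks), and the masked pair is collectively
#' decrypted. The statistic (sum T)^2 / (sum S) is chi-squared(1) under the
#' null.
#'
#' @param summaries list of `site_summary` objects, identical variant order
#' @param sites list of `site_context` objects
#' @param space a `shared_space`
#' @param variant_ids optional variant names
#' @return a `gwas_result` data frame
#' @export
secure_meta_combine <- function(summaries, sites, space, variant_ids = NULL) {
  params <- sites[[1]]$params
  lead <- lead_site(sites)
  M <- length(summaries[[1]]$T)
  if (any(vapply(summaries, function(s) length(s$T), numeric(1)) != M)) {
    stop("alignment error: variant sets differ across sites")
  }
  r <- next_round(space)
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    upload_encmat(space, sprintf("r%d_s%d_metaT.encmat", r, ctx$site_id),
                  encrypt_matrix(matrix(summaries[[i]]$T, ncol = 1), ctx$pk, params))
    upload_encmat(space, sprintf("r%d_s%d_metaS.encmat", r, ctx$site_id),
                  encrypt_matrix(matrix(summaries[[i]]$S, ncol = 1), ctx$pk, params))
  }
  pool <- function(nm) {
    Reduce(emat_add, lapply(sites, function(other) {
      download_encmat(space, sprintf("r%d_s%d_%s.encmat", r, other$site_id, nm))
    }))
  }
  T_enc <- pool("metaT"); S_enc <- pool("metaS")
  T2 <- emat_mul(T_enc, T_enc, lead$evk, params)
  r2 <- next_round(space)
  for (i in seq_along(sites)) {
    ctx <- sites[[i]]
    cmask <- with_seed(ctx_seed(ctx), matrix(runif(M, 0.5, 1.5), ncol = 1))
    upload_encmat(space, sprintf("r%d_s%d_mmT2.encmat", r2, ctx$site_id),
                  apply_mask_mul(T2, cmask, params))
    upload_encmat(space, sprintf("r%d_s%d_mmS.encmat", r2, ctx$site_id),
                  apply_mask_mul(S_enc, cmask, params))
  }
  pool2 <- function(nm) {
    Reduce(emat_add, lapply(sites, function(other) {
      download_encmat(space, sprintf("r%d_s%d_%s.encmat", r2, other$site_id, nm))
    }))
  }
  mT2 <- pool2("mmT2"); mS <- pool2("mmS")
  upload_encmat(space, sprintf("r%d_meta_maskedT2.encmat", r2), mT2)
  upload_encmat(space, sprintf("r%d_meta_maskedS.encmat", r2), mS)
  t2_plain <- drop(collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_meta_maskedT2.encmat", r2)),
    sites, space, tag = "metat2dec"))
  s_plain <- drop(collective_decrypt_matrix(
    download_encmat(space, sprintf("r%d_meta_maskedS.encmat", r2)),
    sites, space, tag = "metasdec"))
  stat <- t2_plain / s_plain
  stat[!is.finite(stat) | s_plain <= 0] <- NA_real_
  structure(data.frame(
    variant = if (is.null(variant_ids)) paste0("v", seq_len(M)) else variant_ids,
    stat = stat, p = pchisq(stat, 1, lower.tail = FALSE),
    af = NA_real_, n_missing = 0L, stringsAsFactors = FALSE),
    class = c("gwas_result", "data.frame"))
}

#' Read and write per-site summary TSV files
#' @param summary a `site_summary`
#' @param path file path
#' @param variant_ids optional variant names
#' @return the summary (read) or `path` invisibly (write)
#' @export
write_site_summary <- function(summary, path, variant_ids = NULL) {
  df <- data.frame(
    variant = if (is.null(variant_ids)) paste0("v", seq_along(summary$T)) else variant_ids,
    T = summary$T, S = summary$S)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_site_summary
#' @export
read_site_summary <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  structure(list(T = df$T, S = df$S, converged = NA), class = "site_summary")
}
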