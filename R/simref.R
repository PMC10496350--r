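# Synthetic multi-site cohort generator (Balding-Nichols population
# structure, logistic-threshold binary phenotype) and plaintext reference
# oracles: pooled IRLS score test, pooled per-variant Wald test and the
# squared Spearman rank correlation used for concordance reporting.

#' Simulation configuration
#'
#' Defaults emulate a 3-population federated design: per-population allele
#' frequencies drawn from a Balding-Nichols Beta around ancestral
#' frequencies Uniform(0.05, 0.95); 20 causal variants with effects
#' Uniform(-0.5, 0.5); a constant gender effect of 0.1 (half of each cohort
#' female); environmental noise Normal(0, variance 0.5); phenotype 1 iff the
#' linear predictor is positive; covariates are an intercept, gender and the
#' top 8 pooled-genotype principal components.
#'
#' @param n_sites number of sites (populations)
#' @param subjects_per_site cohort size per site
#' @param n_variants variant count M
#' @param n_causal number of causal variants
#' @param beta_range causal effects are Uniform(-beta_range, beta_range)
#' @param gender_effect fixed gender effect size
#' @param env_noise_var environmental noise variance
#' @param n_pcs number of principal-component covariates
#' @param fst population differentiation parameter in (0, 1)
#' @param seed integer seed; the cohort set is a pure function of the config
#' @return a `sim_config`
#' @export
sim_config <- function(n_sites = 3, subjects_per_site = 400, n_variants = 2048,
                       n_causal = 20, beta_range = 0.5, gender_effect = 0.1,
                       env_noise_var = 0.5, n_pcs = 8, fst = 0.05, seed = 1) {
  stopifnot(n_causal <= n_variants, fst > 0, fst < 1)
  structure(list(n_sites = n_sites, subjects_per_site = subjects_per_site,
                 n_variants = n_variants, n_causal = n_causal,
                 beta_range = beta_range, gender_effect = gender_effect,
                 env_noise_var = env_noise_var, n_pcs = n_pcs, fst = fst,
                 seed = seed), class = "sim_config")
}

#' Simulate population-structured genotype matrices
#'
#' Ancestral frequencies p0 ~ Uniform(0.05, 0.95); per-population
#' frequencies from Beta(p0 (1-fst)/fst, (1-p0)(1-fst)/fst); genotypes
#' Binomial(2, p_pop), independent across variants (no LD).
#' @param cfg a `sim_config`
#' @return list of per-site N x M dosage matrices, with attribute
#'   `pop_freqs` (M x n_sites)
#' @export
simulate_genotypes <- function(cfg) {
  with_seed(cfg$seed, {
    M <- cfg$n_variants; N <- cfg$subjects_per_site
    p0 <- runif(M, 0.05, 0.95)
    a <- (1 - cfg$fst) / cfg$fst
    pop_freqs <- vapply(seq_len(cfg$n_sites), function(s) {
      pmin(pmax(rbeta(M, p0 * a, (1 - p0) * a), 1e-4), 1 - 1e-4)
    }, numeric(M))
    out <- lapply(seq_len(cfg$n_sites), function(s) {
      matrix(rbinom(N * M, 2, rep(pop_freqs[, s], each = N)), N, M)
    })
    attr(out, "pop_freqs") <- pop_freqs
    attr(out, "ancestral") <- p0
    out
  })
}

#' Principal-component covariates from the pooled genotypes
#'
#' Standardizes the pooled genotype matrix (dropping monomorphic variants),
#' extracts the top `n_pcs` principal-component scores and splits them back
#' per site.
#' @param genos list of per-site genotype matrices
#' @param n_pcs number of components
#' @return list of per-site N x n_pcs score matrices
#' @export
pc_covariates <- function(genos, n_pcs) {
  ns <- vapply(genos, nrow, numeric(1))
  if (n_pcs == 0) {
    return(lapply(ns, function(n) matrix(0, n, 0)))
  }
  pooled <- do.call(rbind, genos)
  if (n_pcs >= min(dim(pooled))) {
    stop("parameter error: n_pcs must be below min(subjects, variants)")
  }
  keep <- apply(pooled, 2, sd) > 0
  Z <- scale(pooled[, keep, drop = FALSE])
  sv <- svd(Z, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  idx <- split(seq_len(nrow(pooled)), rep(seq_along(genos), ns))
  lapply(idx, function(i) scores[i, , drop = FALSE])
}

#' Simulate binary phenotypes over the genotype cohorts
#'
#' eta_i = sum_j G_ij beta_j + gender_i * gender_effect + eps_i with
#' eps ~ Normal(0, env_noise_var); Y = 1 iff eta > 0 (the logistic of eta
#' exceeds one half); the boundary eta = 0 maps to Y = 0. If any site comes
#' out all-case or all-control the draw is repeated with the next seed.
#' @param genos list of per-site genotype matrices
#' @param genders list of per-site 0/1 gender vectors
#' @param cfg a `sim_config`
#' @return list with per-site `y` plus the truth (causal indices, beta)
#' @export
simulate_phenotypes <- function(genos, genders, cfg) {
  for (attempt in 0:20) {
    out <- with_seed(cfg$seed + 77 + attempt, {
      M <- cfg$n_variants
      causal <- sort(sample.int(M, cfg$n_causal))
      beta <- numeric(M)
      beta[causal] <- runif(cfg$n_causal, -cfg$beta_range, cfg$beta_range)
      ys <- lapply(seq_along(genos), function(s) {
        eta <- drop(genos[[s]] %*% beta) +
          genders[[s]] * cfg$gender_effect +
          rnorm(nrow(genos[[s]]), 0, sqrt(cfg$env_noise_var))
        as.numeric(eta > 0)
      })
      list(y = ys, causal = causal, beta = beta)
    })
    rates <- vapply(out$y, mean, numeric(1))
    if (all(rates > 0 & rates < 1)) return(out)
    warning("degenerate all-case/all-control site; redrawing phenotypes")
  }
  stop("could not simulate a non-degenerate phenotype")
}

#' Simulate a full multi-site cohort set
#'
#' Genotypes, gender (first half of each cohort female), pooled-PC
#' covariates and thresholded logistic phenotypes, packaged as
#' `site_cohort` objects with intercept + gender + PCs as covariates.
#' @param cfg a `sim_config`
#' @return list with `cohorts` (list of `site_cohort`) and `truth`
#' @export
simulate_cohorts <- function(cfg) {
  genos <- simulate_genotypes(cfg)
  genders <- lapply(genos, function(g) {
    n <- nrow(g)
    as.numeric(seq_len(n) > n / 2)  # first half female (0), second male (1)
  })
  pcs <- pc_covariates(genos, cfg$n_pcs)
  ph <- simulate_phenotypes(genos, genders, cfg)
  cohorts <- lapply(seq_along(genos), function(s) {
    X <- cbind(intercept = 1, gender = genders[[s]], pcs[[s]])
    site_cohort(X, ph$y[[s]], genos[[s]])
  })
  list(cohorts = cohorts,
       truth = list(causal = ph$causal, beta = ph$beta,
                    gender_effect = cfg$gender_effect))
}

#' Write a simulated cohort set to per-site TSV files
#' @param sim output of [simulate_cohorts()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_cohorts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(sim$cohorts)) {
    ch <- sim$cohorts[[s]]
    sd <- file.path(dir, sprintf("site_%d", s))
    dir.create(sd, showWarnings = FALSE)
    write.table(ch$X, file.path(sd, "covars.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(data.frame(y = ch$y), file.path(sd, "pheno.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(ch$G, file.path(sd, "geno.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read per-site cohort TSVs written by [write_cohorts()]
#' @param dir cohort directory
#' @param n_sites number of site subdirectories
#' @return list of `site_cohort` objects
#' @export
read_cohorts <- function(dir, n_sites) {
  lapply(seq_len(n_sites), function(s) {
    sd <- file.path(dir, sprintf("site_%d", s))
    X <- as.matrix(read.table(file.path(sd, "covars.tsv"), header = TRUE, sep = "\t"))
    y <- read.table(file.path(sd, "pheno.tsv"), header = TRUE, sep = "\t")$y
    G <- as.matrix(read.table(file.path(sd, "geno.tsv"), header = FALSE, sep = "\t"))
    site_cohort(X, y, G)
  })
}

# reference oracles ----------------------------------------------------------

#' Centralized score test on the pooled data
#'
#' Fits the covariate-only logistic null model on the pooled cohort with
#' `stats::glm` and computes, per variant, the score statistic
#' T^2 / (G'WG - G'WX (X'WX)^-1 X'WG) with T = G'(y - mu0), chi-squared(1)
#' under the null. Serves as the independent centralized oracle for the
#' federated protocols.
#' @param cohorts list of `site_cohort` objects
#' @return a `gwas_result` data frame
#' @export
pooled_score_test <- function(cohorts) {
  cohorts <- lapply(cohorts, function(ch) { ch$G <- mean_impute(ch$G); ch })
  X <- do.call(rbind, lapply(cohorts, `[[`, "X"))
  y <- unlist(lapply(cohorts, `[[`, "y"))
  G <- do.call(rbind, lapply(cohorts, `[[`, "G"))
  fit <- glm.fit(X, y, family = binomial())
  mu0 <- fit$fitted.values
  W <- mu0 * (1 - mu0)
  T_vec <- drop(crossprod(G, y - mu0))
  gwx <- crossprod(G, W * X)
  xwx_inv <- solve(crossprod(X, X * W))
  S_vec <- colSums(G^2 * W) - rowSums((gwx %*% xwx_inv) * gwx)
  stat <- T_vec^2 / S_vec
  stat[S_vec <= 0] <- NA_real_
  structure(data.frame(variant = paste0("v", seq_along(stat)), stat = stat,
                       p = pchisq(stat, 1, lower.tail = FALSE),
                       af = colSums(G) / (2 * nrow(G)), n_missing = 0L,
                       stringsAsFactors = FALSE),
            class = c("gwas_result", "data.frame"))
}

#' Per-variant logistic Wald test on the pooled data
#'
#' Refits, for each variant, a logistic regression of the phenotype on the
#' covariates plus the genotype dosage and reports the Wald p-value of the
#' genotype coefficient (the plink2 --glm analogue). Variants whose fit
#' fails or separates get a missing p-value.
#' @param cohorts list of `site_cohort` objects
#' @return a `gwas_result` data frame
#' @export
pooled_wald_test <- function(cohorts) {
  cohorts <- lapply(cohorts, function(ch) { ch$G <- mean_impute(ch$G); ch })
  X <- do.call(rbind, lapply(cohorts, `[[`, "X"))
  y <- unlist(lapply(cohorts, `[[`, "y"))
  G <- do.call(rbind, lapply(cohorts, `[[`, "G"))
  M <- ncol(G)
  stat <- rep(NA_real_, M)
  for (j in seq_len(M)) {
    g <- G[, j]
    if (sd(g) == 0) next
    fit <- tryCatch(
      suppressWarnings(glm.fit(cbind(X, g), y, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    # Wald z from the inverse Fisher information at the fit
    Xg <- cbind(X, g)
    W <- fit$fitted.values * (1 - fit$fitted.values)
    cov <- tryCatch(solve(crossprod(Xg, Xg * W)), error = function(e) NULL)
    if (is.null(cov)) next
    se <- sqrt(diag(cov))[ncol(Xg)]
    b <- fit$coefficients[ncol(Xg)]
    if (!is.finite(se) || se > 100) next   # separation guard
    stat[j] <- (b / se)^2
  }
  structure(data.frame(variant = paste0("v", seq_len(M)), stat = stat,
                       p = pchisq(stat, 1, lower.tail = FALSE),
                       af = colSums(G) / (2 * nrow(G)), n_missing = 0L,
                       stringsAsFactors = FALSE),
            class = c("gwas_result", "data.frame"))
}

#' Squared Spearman rank correlation
#'
#' Ties are mid-ranked; pairs with missing values are dropped. Used to
#' report p-value concordance between methods.
#' @param p1,p2 equal-length numeric vectors (at least 3 finite pairs)
#' @return squared Spearman correlation in [0, 1]
#' @export
spearman_r2 <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  ok <- is.finite(p1) & is.finite(p2)
  if (sum(ok) < 3) stop("need at least 3 finite pairs")
  if (sd(p1[ok]) == 0 || sd(p2[ok]) == 0) {
    stop("undefined error: constant input has no rank correlation")
  }
  cor(p1[ok], p2[ok], method = "spearman")^2
}
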