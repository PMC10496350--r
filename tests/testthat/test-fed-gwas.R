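# Federated GWAS: imputation, IRLS working quantities, null model epochs
# against the centralized oracle, score terms and p-value assignment.

test_that("mean imputation fills missing dosages with observed means", {
  G <- matrix(c(0, 2, NA, 2), 4, 1)
  gi <- mean_impute(G)
  expect_equal(gi[3, 1], 4 / 3)
  expect_equal(attr(gi, "n_missing"), 1)
  G2 <- matrix(c(0, 1, 2, 1), 4, 1)
  expect_equal(unname(mean_impute(G2)[, 1]), c(0, 1, 2, 1))
  G3 <- cbind(c(1, 2, 0), c(NA, NA, NA))
  gi3 <- mean_impute(G3)
  expect_equal(attr(gi3, "flagged"), 2L)
  expect_equal(gi3[, 2], c(0, 0, 0))
})

test_that("IRLS local terms have their closed form at alpha = 0", {
  ch <- tiny_cohort(n = 40, p = 3, m = 4, seed = 2)
  lt <- irls_local_terms(ch, numeric(3))
  expect_equal(lt$mu0, rep(0.5, 40))
  expect_equal(lt$W, rep(0.25, 40))
  expect_equal(lt$z, 4 * (ch$y - 0.5))
  # balanced y with intercept only: X'Wz = 0
  n <- 30
  chb <- site_cohort(matrix(1, n, 1), rep(c(0, 1), n / 2),
                     matrix(rbinom(n, 2, 0.4), n, 1))
  expect_equal(drop(irls_local_terms(chb, 0)$xwz), 0)
  # brute-force X'WX
  W <- lt$W
  expect_lt(max(abs(lt$upsilon - t(ch$X) %*% diag(W) %*% ch$X)), 1e-10)
  expect_error(irls_local_terms(ch, c(1, NA, 0)), "state error")
})

test_that("a federated epoch reproduces the centralized IRLS iterate", {
  set.seed(50)
  ch <- tiny_cohort(n = 80, p = 3, m = 4, seed = 3)
  sites1 <- make_sites(em_bundle64)[1]
  # single site: compare against the hand-rolled pooled iterate
  p1 <- he_params(poly_degree = 64, n_sites = 1, backend = "emulated")
  b1 <- make_key_bundle(p1, seed = 60)
  ctx1 <- list(site_context(1, b1, seed = 70))
  sp <- shared_space(tempfile("space_"))
  st <- null_model_epoch(list(ch), ctx1, sp)
  lt <- irls_local_terms(ch, numeric(3))
  alpha_oracle <- drop(solve(lt$upsilon, lt$xwz))
  expect_lt(max(abs(st$alpha - alpha_oracle)), 1e-4)

  # three sites whose concatenation is the one-site cohort: same trajectory
  idx <- split(1:80, rep(1:3, length.out = 80))
  chs <- lapply(idx, function(i) site_cohort(ch$X[i, ], ch$y[i], ch$G[i, , drop = FALSE]))
  sp3 <- shared_space(tempfile("space_"))
  sites3 <- make_sites(em_bundle64)
  st3 <- null_model_epoch(chs, sites3, sp3)
  expect_lt(max(abs(st3$alpha - alpha_oracle)), 1e-3)
  st3b <- null_model_epoch(chs, sites3, sp3, st3)
  lt2 <- irls_local_terms(ch, st3$alpha)
  expect_lt(max(abs(st3b$alpha - drop(solve(lt2$upsilon, lt2$xwz)))), 1e-3)
})

test_that("the null model recovers generating weights and flags pathologies", {
  set.seed(51)
  n <- 1200
  X <- cbind(1, matrix(rnorm(n * 7), n, 7))
  alpha_true <- c(-0.3, runif(7, -0.4, 0.4))
  y <- rbinom(n, 1, plogis(drop(X %*% alpha_true)))
  idx <- split(seq_len(n), rep(1:3, length.out = n))
  chs <- lapply(idx, function(i) site_cohort(X[i, ], y[i],
                                             matrix(rbinom(length(i), 2, 0.3))))
  pe <- he_params(poly_degree = 256, n_sites = 3, backend = "emulated")
  be <- make_key_bundle(pe, seed = 61)
  sites <- lapply(1:3, function(s) site_context(s, be, seed = 80 + s))
  sp <- shared_space(tempfile("space_"))
  st <- fit_null_model(chs, sites, sp)
  expect_true(st$converged)
  # compare to glm with standard errors
  fit <- glm(y ~ X - 1, family = binomial())
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(st$alpha - alpha_true) < 3.5 * se + 0.05))
  expect_lt(max(abs(st$alpha - coef(fit))), 1e-3)

  # tol = Inf stops after one epoch
  sp2 <- shared_space(tempfile("space_"))
  st1 <- fit_null_model(chs, sites, sp2, tol = Inf)
  expect_equal(st1$epoch, 1L)

  # perfectly separable cohort: warning, capped epochs
  ns <- 40
  Xs <- cbind(1, c(rep(-1, ns / 2), rep(1, ns / 2)))
  ys <- as.numeric(Xs[, 2] > 0)
  chsep <- site_cohort(Xs, ys, matrix(rbinom(ns, 2, 0.4)))
  p1 <- he_params(poly_degree = 64, n_sites = 1, backend = "emulated")
  b1 <- make_key_bundle(p1, seed = 62)
  sp3 <- shared_space(tempfile("space_"))
  expect_warning(
    stx <- fit_null_model(list(chsep), list(site_context(1, b1, seed = 90)),
                          sp3, max_epochs = 4),
    "did not converge")
  expect_equal(stx$epoch, 4L)
})

test_that("score terms match the dense-algebra oracle", {
  set.seed(52)
  ch <- tiny_cohort(n = 50, p = 4, m = 8, seed = 5)
  pe <- he_params(poly_degree = 256, n_sites = 1, backend = "emulated")
  be <- make_key_bundle(pe, seed = 63, keep_master = TRUE)
  ctx <- site_context(1, be, seed = 95)
  sp <- shared_space(tempfile("space_"))
  st <- fit_null_model(list(ch), list(ctx), sp)
  lt <- st$locals[[1]]
  terms <- score_local_terms(ch, lt, st$enc_inverse, ctx, pe)
  dm <- function(em) fedhegwas:::decrypt_matrix_master(em, be$master_key, pe)
  # oracle quantities
  T_o <- drop(crossprod(ch$G, ch$y - lt$mu0))
  d_o <- colSums(ch$G^2 * lt$W)
  gwx_o <- crossprod(ch$G, lt$W * ch$X)
  prod_o <- gwx_o %*% solve(lt$upsilon)
  expect_lt(max(abs(drop(dm(terms$T_s)) - T_o)), 1e-2)
  expect_lt(max(abs(drop(dm(terms$s1)) - d_o)), 1e-2)
  expect_lt(max(abs(dm(terms$s21)[, 1:4] - gwx_o)), 1e-2)
  expect_lt(max(abs(dm(terms$s22)[, 1:4] - prod_o)), 1e-2)

  # y == mu0 exactly gives a zero score numerator
  ch0 <- ch; ch0$y <- lt$mu0
  T_zero <- crossprod(ch0$G, ch0$y - lt$mu0)
  expect_equal(max(abs(T_zero)), 0)
  # monomorphic variant
  chm <- ch; chm$G[, 1] <- 0
  ltm <- irls_local_terms(chm, st$alpha)
  expect_equal(drop(crossprod(chm$G, chm$y - ltm$mu0))[1], 0)
  expect_equal(colSums(chm$G^2 * ltm$W)[1], 0)
})

test_that("chi-squared p-value assignment matches its distribution", {
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-4)
  # T = 0 means p = 1, via the full finalization path on crafted summaries
  set.seed(53)
  ch <- tiny_cohort(n = 40, p = 2, m = 4, seed = 7)
  s <- local_site_summary(ch)
  s$T <- rep(0, 4)
  pe <- he_params(poly_degree = 64, n_sites = 1, backend = "emulated")
  be <- make_key_bundle(pe, seed = 64)
  sp <- shared_space(tempfile("space_"))
  res <- secure_meta_combine(list(s), list(site_context(1, be, seed = 97)), sp)
  expect_true(all(res$p > 1 - 1e-4))
})

test_that("secure pipeline matches the plaintext score-test oracle end to end", {
  set.seed(54)
  cfg <- sim_config(n_sites = 3, subjects_per_site = 100, n_variants = 64,
                    n_pcs = 4, n_causal = 8, seed = 55)
  sim <- simulate_cohorts(cfg)
  pe <- he_params(n_sites = 3, backend = "emulated")
  be <- make_key_bundle(pe, seed = 65)
  sites <- lapply(1:3, function(s) site_context(s, be, seed = 200 + s))
  sp <- shared_space(tempfile("space_"))
  secure <- run_secure_gwas(sim$cohorts, sites, sp)
  plain <- plain_federated_gwas(sim$cohorts)
  ok <- is.finite(secure$p) & is.finite(plain$p)
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(log10(secure$p[ok]) - log10(plain$p[ok]))), 0.01)
  # mask invariance: the masked ratio is the unmasked ratio exactly in
  # plaintext arithmetic
  c_mask <- runif(10, 0.5, 1.5) + runif(10, 0.5, 1.5)
  T2 <- runif(10, 0, 9); S <- runif(10, 0.5, 4)
  expect_equal((c_mask * T2) / (c_mask * S), T2 / S)
})
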