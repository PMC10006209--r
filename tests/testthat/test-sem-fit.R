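# DWLS estimation, sandwich SEs, model chi-square, fit indices,
# standardization, smoothing.

saturated_spec <- function(obs) {
  pairs <- utils::combn(obs, 2)
  model_spec(observed = obs,
             params = rbind(variance(obs, "free"),
                            covariance(pairs[1, ], pairs[2, ], "free")),
             auto_var = FALSE, name = "saturated")
}

toy_gs <- function(seed = 5, k = 3) {
  set.seed(seed)
  A <- matrix(rnorm(k * k, 0, 0.3), k)
  S <- crossprod(A) / k + diag(k) * 0.5
  p <- k * (k + 1) / 2
  B <- matrix(rnorm(p * p, 0, 0.05), p)
  V <- (crossprod(B) / p + diag(p)) * 1e-4
  make_covstruct(S, V)
}

test_that("eigenvalue smoothing fixes indefinite matrices and leaves PD ones alone", {
  out <- smooth_to_pd(diag(3))
  expect_equal(out$max_change, 0)
  expect_equal(out$mat, diag(3))

  m <- matrix(c(1, 1.2, 1.2, 1), 2)
  sm <- smooth_to_pd(m, eps = 1e-8)
  ev <- eigen(sm$mat, symmetric = TRUE)$values
  expect_gte(min(ev), 1e-8 - 1e-12)
  # independent eigen-recomposition oracle
  e0 <- eigen(m, symmetric = TRUE)
  oracle <- e0$vectors %*% diag(pmax(e0$values, 1e-8)) %*% t(e0$vectors)
  expect_equal(sm$mat, oracle, tolerance = 1e-12)
  expect_equal(sm$max_change, max(abs(oracle - m)), tolerance = 1e-12)

  expect_error(smooth_to_pd(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("a saturated model fits exactly with zero objective and chi2", {
  gs <- toy_gs()
  sp <- saturated_spec(gs$trait_names)
  fit <- fit_dwls(sp, gs, n_restarts = 1)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-9)
  expect_equal(fit$implied, fit$S, tolerance = 1e-7)
  expect_equal(fit$chi2, 0)
  expect_equal(fit$p_model, 1)
  expect_equal(fit$df, 0)
})

test_that("saturated-model sandwich SEs equal the jackknife SDs from V", {
  gs <- toy_gs(seed = 6)
  sp <- saturated_spec(gs$trait_names)
  fit <- fit_dwls(sp, gs, n_restarts = 1)
  # Delta reduces to a permutation of the identity, so each parameter's SE
  # is the square root of its element's V diagonal entry
  idx <- vech_index(3)
  nm <- paste0(gs$trait_names[idx$col], "~~", gs$trait_names[idx$row])
  nm[idx$row == idx$col] <- paste0(gs$trait_names[idx$row][idx$row == idx$col],
                                   "~~",
                                   gs$trait_names[idx$row][idx$row == idx$col])
  expect_equal(unname(fit$se[nm]), unname(sqrt(diag(fit$V))),
               tolerance = 1e-6)
})

test_that("an exact one-factor covariance is recovered to optimizer precision", {
  lam <- c(0.8, 0.7, 0.6)
  S <- outer(lam, lam)
  diag(S) <- 1
  gs <- make_covstruct(S, diag(6) * 1e-4)
  sp <- model_spec(
    observed = gs$trait_names, latents = "F1",
    params = rbind(loading("F1", gs$trait_names, "free"),
                   variance("F1", "fixed:1"),
                   variance(gs$trait_names, "free")),
    auto_var = FALSE)
  fit <- fit_dwls(sp, gs, n_restarts = 2)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[1:3]), lam, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$srmr, 1e-6)
})

test_that("one-free-parameter DWLS matches a brute-force grid search", {
  S <- matrix(c(1, 0.31, 0.31, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  V <- diag(c(3, 1.5, 2)) * 1e-3
  gs <- make_covstruct(S, V)
  sp <- model_spec(observed = c("a", "b"),
                   params = rbind(variance(c("a", "b"), "fixed:1"),
                                  covariance("a", "b", "free")),
                   auto_var = FALSE)
  fit <- fit_dwls(sp, gs, n_restarts = 1)
  # independent oracle: exhaustive grid on the single covariance parameter
  grid <- seq(-1, 1, by = 1e-5)
  s <- vech(smooth_to_pd(S)$mat)
  W <- 1 / diag(V)
  objs <- vapply(grid, function(g) {
    sig <- c(1, g, 1)
    sum(W * (s - sig)^2)
  }, numeric(1))
  expect_equal(unname(fit$theta), grid[which.min(objs)], tolerance = 2e-5)
})

test_that("with diagonal V the sandwich collapses to (J'WJ)^-1 and V-scaling doubles SEs", {
  gs <- toy_gs(seed = 8)
  gs$V <- diag(diag(gs$V))
  sp <- model_spec(
    observed = gs$trait_names, latents = "F1",
    params = rbind(loading("F1", gs$trait_names, "free"),
                   variance("F1", "fixed:1"),
                   variance(gs$trait_names, "free")),
    auto_var = FALSE)
  fit <- suppressWarnings(fit_dwls(sp, gs, n_restarts = 1))
  J <- ldsem:::.sigma_jacobian_analytic(sp, fit$theta)
  W <- 1 / diag(gs$V)
  naive <- sqrt(diag(solve(crossprod(J, J * W))))
  expect_equal(unname(fit$se), naive, tolerance = 1e-6)

  gs4 <- gs
  gs4$V <- gs$V * 4
  fit4 <- suppressWarnings(fit_dwls(sp, gs4, n_restarts = 1))
  expect_equal(unname(fit4$se), 2 * unname(fit$se), tolerance = 1e-4)
})

test_that("fit indices follow their definitions", {
  fi <- fit_indices(chi2 = 33.82, df = 5, q = 10, chi2_indep = 500,
                    df_indep = 10, residuals = rep(0, 15), S = diag(5))
  expect_equal(fi$aic, 53.82)
  expect_equal(fi$srmr, 0)
  fi2 <- fit_indices(chi2 = 3, df = 5, q = 2, chi2_indep = 100, df_indep = 6,
                     residuals = rep(0.1, 15), S = diag(5))
  expect_equal(fi2$cfi, 1)  # chi2 <= df clips to 1
  expect_warning(
    fi3 <- fit_indices(chi2 = 10, df = 5, q = 2, chi2_indep = 4,
                       df_indep = 6, residuals = rep(0, 15), S = diag(5)),
    "baseline")
  expect_equal(fi3$cfi, 1)
})

test_that("standardization fixes variances to 1 and is idempotent on standardized input", {
  lam <- c(0.8, 0.6, 0.5)
  S <- outer(lam, lam)
  diag(S) <- 1
  gs <- make_covstruct(S, diag(6) * 1e-4)
  sp <- model_spec(
    observed = gs$trait_names, latents = "F1",
    params = rbind(loading("F1", gs$trait_names, "free"),
                   variance("F1", "fixed:1"),
                   variance(gs$trait_names, "free")),
    auto_var = FALSE)
  fit <- fit_dwls(sp, gs, n_restarts = 1)
  std <- fit$standardized
  # input is already a correlation matrix: standardized == unstandardized
  expect_equal(std$est_std, std$est, tolerance = 1e-5)

  # single-indicator convention gives a standardized loading of exactly 1
  S2 <- matrix(c(0.04, 0.01, 0.01, 0.09), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  gs2 <- make_covstruct(S2, diag(3) * 1e-5)
  sp2 <- model_spec(observed = c("a", "b"), latents = "Fa",
                    params = rbind(loading("Fa", "a", "fixed:1"),
                                   variance("Fa", "free"),
                                   variance("a", "fixed:0"),
                                   variance("b", "free"),
                                   covariance("Fa", "b", "free")),
                    auto_var = FALSE)
  fit2 <- fit_dwls(sp2, gs2, n_restarts = 1)
  std2 <- fit2$standardized
  expect_equal(std2$est_std[std2$param == "Fa=~a"], 1, tolerance = 1e-6)
})

test_that("covariances standardize to correlations", {
  # covariance 0.02 between factors with variances 0.04 and 0.01 -> r = 1
  S <- matrix(c(0.04, 0.02, 0.02, 0.01), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  gs <- make_covstruct(S, diag(3) * 1e-6)
  sp <- saturated_spec(c("a", "b"))
  fit <- fit_dwls(sp, gs, n_restarts = 1)
  std <- fit$standardized
  expect_equal(std$est_std[std$param == "a~~b"], 1, tolerance = 1e-6)
})

test_that("estimates are invariant under reordering of observed variables", {
  gs <- toy_gs(seed = 9)
  sp1 <- model_spec(
    observed = gs$trait_names, latents = "F1",
    params = rbind(loading("F1", gs$trait_names, "free"),
                   variance("F1", "fixed:1"),
                   variance(gs$trait_names, "free")),
    auto_var = FALSE)
  perm <- c("T3", "T1", "T2")
  sp2 <- model_spec(
    observed = perm, latents = "F1",
    params = rbind(loading("F1", perm, "free"),
                   variance("F1", "fixed:1"),
                   variance(perm, "free")),
    auto_var = FALSE)
  f1 <- fit_dwls(sp1, gs, n_restarts = 1)
  f2 <- fit_dwls(sp2, gs, n_restarts = 1)
  common <- intersect(names(f1$theta), names(f2$theta))
  expect_equal(f1$theta[common], f2$theta[common], tolerance = 1e-4)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-4)
})

test_that("objective at the optimum does not exceed the objective at truth", {
  lam <- c(0.7, 0.6, 0.5)
  S <- outer(lam, lam); diag(S) <- 1
  gs <- make_covstruct(S, diag(6) * 1e-4)
  sp <- model_spec(
    observed = gs$trait_names, latents = "F1",
    params = rbind(loading("F1", gs$trait_names, "free"),
                   variance("F1", "fixed:1"),
                   variance(gs$trait_names, "free")),
    auto_var = FALSE)
  fit <- fit_dwls(sp, gs, n_restarts = 1)
  s <- vech(fit$S)
  W <- 1 / pmax(diag(fit$V), 1e-10)
  at_truth <- sum(W * (s - vech(implied_sigma(sp, c(lam, 1 - lam^2))))^2)
  expect_lte(fit$objective, at_truth + 1e-9)
})

test_that("the residual chi-square is exactly calibrated when V is known", {
  set.seed(42)
  lam <- c(0.8, 0.7, 0.6, 0.5)
  S0 <- outer(lam, lam); diag(S0) <- 1
  dimnames(S0) <- list(paste0("y", 1:4), paste0("y", 1:4))
  s0 <- vech(S0)
  p <- length(s0)
  A <- matrix(rnorm(p * p, 0, 0.1), p)
  V0 <- (diag(p) + crossprod(A)) * 2e-5
  Lv <- t(chol(V0))
  sp <- model_spec(
    observed = rownames(S0), latents = "F1",
    params = rbind(loading("F1", rownames(S0), "free"),
                   variance("F1", "fixed:1"),
                   variance(rownames(S0), "free")),
    auto_var = FALSE)
  stat <- vapply(1:200, function(i) {
    s <- s0 + drop(Lv %*% rnorm(p))
    gs <- make_covstruct(unvech(s), V0, traits = rownames(S0))
    f <- fit_dwls(sp, gs, n_restarts = 0, se = FALSE)
    ch <- model_chi2(sp, gs, f$theta)
    c(ch$chi2, ch$p < 0.05)
  }, numeric(2))
  df <- count_params_df(sp)$df
  expect_lt(abs(mean(stat[1, ]) / df - 1), 0.25)
  expect_lt(mean(stat[2, ]), 0.12)
  expect_gt(mean(stat[2, ]), 0.005)
})
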