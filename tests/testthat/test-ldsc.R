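# LD score regression: heritability, covariance, liability scale, S/V.

test_that("h2 regression is exact when chi-square lies on the model line", {
  set.seed(21)
  M <- 2000
  ref <- mk_ref(M, n_blocks = 20)
  N <- 10000
  chi2 <- 1 + N * 0.4 * ref$L2 / M
  ss <- mk_ss(ref$SNP, ref$A1, ref$A2, z = sqrt(chi2), n = N)
  est <- estimate_h2(ss, ref, M = M, n_blocks = 20)
  expect_equal(unname(est$h2_obs), 0.4, tolerance = 1e-8)
  expect_equal(unname(est$intercept), 1.0, tolerance = 1e-8)
  expect_lt(est$se_h2, 1e-6)
})

test_that("null z-statistics give h2 near 0 and intercept near 1", {
  ref <- simulate_ld_reference(20000, 200, seed = 31)
  tr <- truth_config("T1", h2 = 0, N = 10000,
                     Lambda_std = matrix(0, 1, 1), Phi = matrix(1, 1, 1),
                     M = 20000, n_blocks = 200, seed = 31)
  ss <- simulate_sumstats(tr, ref)
  est <- estimate_h2(ss[[1]], ref, M = 20000, n_blocks = 200)
  expect_lt(abs(est$h2_obs), 3 * est$se_h2)
  expect_lt(abs(est$intercept - 1), 3 * est$se_intercept)
})

test_that("uniform chi-square inflation moves only the intercept", {
  set.seed(22)
  ref <- mk_ref(1000, n_blocks = 10)
  ss <- mk_ss(ref$SNP, ref$A1, ref$A2, z = rep(sqrt(1.3), 1000), n = 5000)
  est <- estimate_h2(ss, ref, M = 1000, n_blocks = 10)
  expect_equal(unname(est$h2_obs), 0, tolerance = 1e-10)
  expect_equal(unname(est$intercept), 1.3, tolerance = 1e-10)
})

test_that("self-covariance equals heritability and gcov is symmetric", {
  ref <- simulate_ld_reference(4000, 40, seed = 41)
  tr <- small_truth(seed = 41)
  ss <- simulate_sumstats(tr, ref)
  eh <- estimate_h2(ss$T1, ref, M = 4000, n_blocks = 40)
  eg <- estimate_gcov(ss$T1, ss$T1, ref, M = 4000, n_blocks = 40)
  expect_identical(unname(eg$gcov), unname(eh$h2_obs))
  g12 <- estimate_gcov(ss$T1, ss$T2, ref, M = 4000, n_blocks = 40)
  g21 <- estimate_gcov(ss$T2, ss$T1, ref, M = 4000, n_blocks = 40)
  expect_identical(g12$gcov, g21$gcov)
  expect_identical(g12$se_gcov, g21$se_gcov)
})

test_that("gcov regression recovers an exact-line construction", {
  set.seed(23)
  M <- 2000
  ref <- mk_ref(M, n_blocks = 20)
  N1 <- 10000; N2 <- 20000
  # z1*z2 = 0.2 + sqrt(N1 N2) * 0.1 * l / M exactly
  prod <- 0.2 + sqrt(N1 * N2) * 0.1 * ref$L2 / M
  z1 <- sqrt(prod)
  ss1 <- mk_ss(ref$SNP, ref$A1, ref$A2, z = z1, n = N1)
  ss2 <- mk_ss(ref$SNP, ref$A1, ref$A2, z = z1, n = N2)
  est <- estimate_gcov(ss1, ss2, ref, M = M, n_blocks = 20)
  expect_equal(unname(est$gcov), 0.1, tolerance = 1e-8)
  expect_equal(unname(est$intercept), 0.2, tolerance = 1e-8)
})

test_that("independent null traits have gcov within 3 SE of zero", {
  ref <- simulate_ld_reference(10000, 100, seed = 43)
  tr <- truth_config(c("T1", "T2"), h2 = c(0.3, 0.3), N = c(20000, 20000),
                     Lambda_std = diag(sqrt(c(0.3, 0.3))), Phi = diag(2),
                     M = 10000, n_blocks = 100, seed = 43)
  ss <- simulate_sumstats(tr, ref)
  est <- estimate_gcov(ss$T1, ss$T2, ref, M = 10000, n_blocks = 100)
  expect_lt(abs(est$gcov), 3 * est$se_gcov)
})

test_that("liability conversion matches closed form and a numeric threshold-model oracle", {
  expect_equal(liability_scale(1, 0.5, 0.5), pi / 2, tolerance = 1e-6)
  expect_equal(liability_scale(0, 0.3, 0.1), 0)
  # P = K: factor reduces to K(1-K)/phi(t)^2; oracle from numerically
  # differentiating the threshold model P(case | liability shift g)
  for (K in c(0.05, 0.2, 0.4)) {
    t <- qnorm(1 - K)
    h <- 1e-5
    dPdg <- (pnorm(t - h, lower.tail = FALSE) -
               pnorm(t + h, lower.tail = FALSE)) / (2 * h)
    oracle <- K * (1 - K) / dPdg^2
    expect_equal(liability_factor(K, K), oracle, tolerance = 1e-4)
  }
  expect_error(liability_factor(0, 0.1), "P")
  expect_error(liability_factor(0.5, 1), "K")
})

test_that("liability conversion is monotone in h2 and identity at factor 1", {
  h <- seq(0, 0.5, by = 0.1)
  out <- vapply(h, liability_scale, numeric(1), P = 0.5, K = 0.2)
  expect_true(all(diff(out) > 0))
  # a (P, K) pair with conversion factor 1 leaves the estimate unchanged
  f <- function(K) liability_factor(0.5, K) - 1
  K1 <- uniroot(f, c(0.01, 0.3), tol = 1e-12)$root
  expect_equal(liability_scale(0.123, 0.5, K1), 0.123, tolerance = 1e-6)
})

test_that("rg_from_S computes correlations and rejects bad diagonals", {
  expect_equal(rg_from_S(diag(2), 1, 2), 0)
  expect_equal(rg_from_S(matrix(c(0.04, 0.02, 0.02, 0.04), 2), 1, 2), 0.5)
  expect_equal(rg_from_S(matrix(c(0.04, 0.02, 0.02, 0.04), 2), 1, 1), 1)
  expect_error(rg_from_S(matrix(c(-0.01, 0, 0, 0.04), 2), 1, 2), "undefined")
})

test_that("build_S_V on duplicated traits gives rg = 1 and equal entries", {
  ref <- simulate_ld_reference(4000, 40, seed = 51)
  tr <- small_truth(seed = 51)
  ss <- simulate_sumstats(tr, ref)
  gs <- build_S_V(list(A = ss$T1, B = ss$T1), ref, M = 4000, n_blocks = 40)
  expect_equal(gs$S[1, 1], gs$S[2, 2], tolerance = 1e-12)
  expect_equal(gs$S[1, 2], gs$S[1, 1], tolerance = 1e-12)
  expect_equal(rg_from_S(gs$S, 1, 2), 1, tolerance = 1e-12)
})

test_that("noise-free construction yields a (near) zero jackknife V", {
  set.seed(24)
  M <- 2000
  ref <- mk_ref(M, n_blocks = 20)
  N <- 10000
  z <- sqrt(1 + N * 0.3 * ref$L2 / M)
  ss1 <- mk_ss(ref$SNP, ref$A1, ref$A2, z = z, n = N, trait = "T1")
  ss2 <- mk_ss(ref$SNP, ref$A1, ref$A2, z = z, n = N, trait = "T2")
  gs <- build_S_V(list(T1 = ss1, T2 = ss2), ref, M = M, n_blocks = 20)
  expect_lt(max(abs(gs$V)), 1e-12)
})

test_that("liability rescaling scales S rows/columns and V quadratically", {
  ref <- simulate_ld_reference(4000, 40, seed = 52)
  tr <- small_truth(seed = 52)
  ss <- simulate_sumstats(tr, ref)
  tabs <- list(T1 = ss$T1, T2 = ss$T2)
  gs0 <- build_S_V(tabs, ref, M = 4000, n_blocks = 40)
  K <- 0.15
  gs1 <- build_S_V(tabs, ref, M = 4000, n_blocks = 40,
                   prevalences = list(T1 = list(P = 0.5, K = K)))
  fac <- liability_factor(0.5, K)
  expect_equal(gs1$S[1, 1], fac * gs0$S[1, 1], tolerance = 1e-12)
  expect_equal(gs1$S[1, 2], sqrt(fac) * gs0$S[1, 2], tolerance = 1e-12)
  expect_equal(gs1$S[2, 2], gs0$S[2, 2], tolerance = 1e-12)
  expect_equal(gs1$V[1, 1], fac^2 * gs0$V[1, 1], tolerance = 1e-10)
  expect_equal(unname(gs1$scale["T1"]), "liability")
})

test_that("jackknife h2 SE is within a factor 1.5 of the replicate SD", {
  ref <- simulate_ld_reference(2000, 40, seed = 61)
  tr <- small_truth(M = 2000, n_blocks = 40)
  ests <- vapply(1:120, function(i) {
    ss <- simulate_sumstats(tr, ref, seed = 6000 + i)
    e <- estimate_h2(ss$T1, ref, M = 2000, n_blocks = 40)
    c(e$h2_obs, e$se_h2)
  }, numeric(2))
  emp_sd <- sd(ests[1, ])
  mean_se <- mean(ests[2, ])
  expect_gt(mean_se / emp_sd, 1 / 1.5)
  expect_lt(mean_se / emp_sd, 1.5)
})

test_that("intercepts are near their theoretical values without confounding or overlap", {
  ref <- simulate_ld_reference(10000, 100, seed = 62)
  tr <- small_truth(M = 10000, n_blocks = 100, seed = 62)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  ok <- unlist(lapply(1:12, function(i) {
    ss <- simulate_sumstats(tr, ref, seed = 6200 + i)
    diag_ok <- vapply(ss, function(s) {
      e <- estimate_h2(s, ref, M = 10000, n_blocks = 100)
      abs(e$intercept - 1) < 3 * e$se_intercept
    }, logical(1))
    off_ok <- vapply(pairs, function(p) {
      e <- estimate_gcov(ss[[p[1]]], ss[[p[2]]], ref, M = 10000,
                         n_blocks = 100)
      abs(e$intercept) < 3 * e$se_intercept
    }, logical(1))
    c(diag_ok, off_ok)
  }))
  expect_gte(mean(ok), 0.95)
})

test_that("overlap intercepts are recovered when traits share samples", {
  I0 <- matrix(c(1, 0.4, 0.4, 1), 2)
  tr <- truth_config(c("T1", "T2"), h2 = c(0.3, 0.2), N = c(30000, 30000),
                     Lambda_std = diag(sqrt(c(0.3, 0.2))), Phi = diag(2),
                     I0 = I0, M = 10000, n_blocks = 100, seed = 63)
  ref <- simulate_ld_reference(10000, 100, seed = 63)
  ss <- simulate_sumstats(tr, ref)
  est <- estimate_gcov(ss$T1, ss$T2, ref, M = 10000, n_blocks = 100)
  expect_lt(abs(est$intercept - 0.4), 3 * est$se_intercept)
})

test_that("covstruct serialization round-trips", {
  ref <- simulate_ld_reference(4000, 40, seed = 53)
  tr <- small_truth(seed = 53)
  ss <- simulate_sumstats(tr, ref)
  gs <- build_S_V(ss, ref, M = 4000, n_blocks = 40)
  path <- tempfile(fileext = ".json")
  write_covstruct(gs, path)
  back <- read_covstruct(path)
  expect_equal(back$S, gs$S, tolerance = 1e-12)
  expect_equal(back$V, gs$V, tolerance = 1e-12)
  expect_equal(back$vech_order, "lower-column-major")
})

test_that("estimate_h2 input guards fire", {
  ref <- mk_ref(100, n_blocks = 4)
  ss <- mk_ss(ref$SNP, ref$A1, ref$A2, z = rnorm(100))
  expect_error(estimate_h2(ss, ref, M = 100, n_blocks = 4), ">= 200")
  ref2 <- mk_ref(400, l2 = rep(10, 400), n_blocks = 4)
  ss2 <- mk_ss(ref2$SNP, ref2$A1, ref2$A2, z = rnorm(400))
  expect_error(estimate_h2(ss2, ref2, M = 400, n_blocks = 4), "degenerate")
  ss3 <- mk_ss(paste0("x", 1:300), "A", "G", z = rnorm(300))
  expect_error(estimate_gcov(ss3, mk_ss(paste0("y", 1:300), "A", "G",
                                        z = rnorm(300)), ref2),
               "shared")
})
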