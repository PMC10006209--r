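# Diagonally weighted least squares estimation of structural models on a
# genetic covariance matrix S with block-jackknife sampling covariance V.
#
# theta_hat minimizes F(theta) = (s - sigma(theta))' D^-1 (s - sigma(theta)),
# s = vech(S), D = diag(V). Inference uses the full V through the sandwich
# covariance; the model test is the residual-based pseudoinverse statistic.

#' Project a symmetric matrix to (near) positive definiteness
#'
#' Clips eigenvalues below `eps`, reconstructs, and reports the largest
#' absolute element-wise change. Matrices already satisfying the bound are
#' returned unchanged (change 0).
#'
#' @param m symmetric matrix.
#' @param eps minimum eigenvalue after smoothing (default 1e-8).
#' @param tol symmetry tolerance on `max |m - t(m)|`.
#' @return list with `mat` (smoothed matrix) and `max_change`.
#' @export
smooth_to_pd <- function(m, eps = 1e-8, tol = 1e-8) {
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stopf("matrix is not symmetric")
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) >= eps)
    return(list(mat = m, max_change = 0))
  vals <- pmax(ev$values, eps)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  list(mat = out, max_change = max(abs(out - m)))
}

# Restrict/reorder a covstruct to the given traits (S rows/cols and the
# matching rows/cols of V in half-vectorization order).
#' Subset or reorder genetic covariance structures
#'
#' @param gs `covstruct`.
#' @param traits trait names in the desired order.
#' @return `covstruct` over `traits`.
#' @export
subset_covstruct <- function(gs, traits) {
  miss <- setdiff(traits, gs$trait_names)
  if (length(miss)) stopf("traits absent from covstruct: %s",
                          paste(miss, collapse = ", "))
  old <- match(traits, gs$trait_names)
  k_old <- length(gs$trait_names)
  pos <- matrix(0L, k_old, k_old)
  idx_old <- vech_index(k_old)
  pos[cbind(idx_old$row, idx_old$col)] <- seq_len(nrow(idx_old))
  pos[cbind(idx_old$col, idx_old$row)] <- seq_len(nrow(idx_old))
  idx_new <- vech_index(length(traits))
  sel <- pos[cbind(old[idx_new$row], old[idx_new$col])]
  out <- gs
  out$S <- gs$S[old, old, drop = FALSE]
  out$V <- gs$V[sel, sel, drop = FALSE]
  out$intercepts <- gs$intercepts[old, old, drop = FALSE]
  out$trait_names <- traits
  out$scale <- gs$scale[old]
  out
}

# Evaluate with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Start values: loadings 0.5*sqrt(mean diag S); variances half the matching
# diagonal; covariances and regressions 0. Lower bounds keep variances >= 0.
.start_values <- function(spec, S) {
  pt <- spec$pt
  q <- spec$q
  start <- numeric(q); lower <- rep(-Inf, q)
  mdiag <- mean(diag(S))
  for (r in seq_len(nrow(pt))) {
    if (!pt$free[r]) next
    i <- pt$theta_idx[r]
    if (pt$op[r] == "=~") start[i] <- 0.5 * sqrt(max(mdiag, 1e-8))
    else if (pt$op[r] == "~") start[i] <- 0
    else if (pt$lhs[r] == pt$rhs[r]) {
      lower[i] <- 0
      dv <- if (pt$lhs[r] %in% spec$observed) S[pt$lhs[r], pt$lhs[r]] else mdiag
      start[i] <- 0.5 * max(dv, 1e-8)
    } else start[i] <- 0
  }
  list(start = start, lower = lower)
}

# Analytic Jacobian of sigma(theta) = vech(implied_sigma) from the RAM
# derivatives: with F = (I-A)^-1 and Sigma_all = F S F',
#   d Sigma_all / d A[i,j] = F[,i] Sigma_all[j,]' + (.)',
#   d Sigma_all / d S[i,j] = F[,i] F[,j]'   (summed over stored cells).
.sigma_jacobian_analytic <- function(spec, theta) {
  r <- spec$ram
  A <- r$A0; S <- r$S0
  if (length(r$iA)) A[r$iA] <- theta[r$tA]
  if (length(r$iS)) S[r$iS] <- theta[r$tS]
  Fi <- tryCatch(solve(diag(r$n) - A), error = function(e)
    stopf("non-recursive model: (I - B) is singular"))
  Sig <- Fi %*% S %*% t(Fi)
  obs <- r$obs_idx
  k <- length(obs)
  lt <- which(lower.tri(diag(k), diag = TRUE))
  J <- matrix(0, length(lt), spec$q)
  if (length(r$iA)) for (m in seq_along(r$iA)) {
    i <- r$posA[m, 1]; j <- r$posA[m, 2]
    Dk <- tcrossprod(Fi[, i], Sig[j, ])
    D <- Dk + t(Dk)
    J[, r$tA[m]] <- J[, r$tA[m]] + D[obs, obs][lt]
  }
  if (length(r$iS)) for (m in seq_along(r$iS)) {
    i <- r$posS[m, 1]; j <- r$posS[m, 2]
    D <- tcrossprod(Fi[, i], Fi[, j])
    J[, r$tS[m]] <- J[, r$tS[m]] + D[obs, obs][lt]
  }
  J
}

# Central finite-difference Jacobian of sigma(theta); retained as an
# independent cross-check of the analytic derivatives.
.sigma_jacobian <- function(spec, theta, step = 1e-6) {
  q <- length(theta)
  s0 <- vech(implied_sigma(spec, theta))
  J <- matrix(0, length(s0), q)
  for (i in seq_len(q)) {
    h <- step * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (vech(implied_sigma(spec, tp)) - vech(implied_sigma(spec, tm))) / (2 * h)
  }
  J
}

#' Fit a structural model by diagonally weighted least squares
#'
#' Minimizes `(s - sigma(theta))' D^-1 (s - sigma(theta))` with `s` the
#' half-vectorized genetic covariance matrix and `D = diag(V)`, using a
#' box-constrained quasi-Newton optimizer (variances kept non-negative),
#' deterministic start values plus jittered restarts, and retains the best
#' converged solution. S and V are eigenvalue-smoothed to positive
#' definiteness first; the maximum element-wise changes are reported.
#' The returned object carries sandwich standard errors, the residual-based
#' model chi-square, AIC/CFI/SRMR, and the fully standardized solution.
#'
#' @param spec `model_spec`.
#' @param gs `covstruct` covering (at least) the spec's observed traits.
#' @param n_restarts jittered restarts after the deterministic start
#'   (default 5; uniform +/-50% jitter, fixed seed per restart index).
#' @param se compute sandwich standard errors, chi-square, fit indices and
#'   the standardized solution (default TRUE; FALSE returns estimates only).
#' @param eps smoothing floor for eigenvalues of S and V.
#' @return `fit_result` list: `theta` (named estimates), `se`, `vcov_theta`,
#'   `chi2`, `df`, `p_model`, `aic`, `cfi`, `srmr`, `standardized`
#'   (data.frame of all parameters with standardized estimates, SEs, p-values
#'   and significance at 0.05), `converged`, `objective`,
#'   `smoothing_report`, `spec`, `S`, `implied`.
#' @export
fit_dwls <- function(spec, gs, n_restarts = 5, se = TRUE, eps = 1e-8) {
  gs <- subset_covstruct(gs, spec$observed)
  smS <- smooth_to_pd(gs$S, eps = eps)
  smV <- smooth_to_pd(gs$V, eps = eps)
  S <- smS$mat; V <- smV$mat
  s <- vech(S)
  D <- pmax(diag(V), 1e-10)
  if (any(diag(V) < 1e-10))
    warnf("%d non-positive jackknife variance(s) on diag(V) floored at 1e-10",
          sum(diag(V) < 1e-10))
  W <- 1 / D
  cdf <- count_params_df(spec)

  obj <- function(th) {
    sig <- tryCatch(vech(implied_sigma(spec, th)), error = function(e) NULL)
    if (is.null(sig) || any(!is.finite(sig))) return(1e12)
    sum(W * (s - sig)^2)
  }
  grad <- function(th) {
    sig <- tryCatch(vech(implied_sigma(spec, th)), error = function(e) NULL)
    if (is.null(sig) || any(!is.finite(sig))) return(rep(0, length(th)))
    J <- .sigma_jacobian_analytic(spec, th)
    drop(-2 * crossprod(J, W * (s - sig)))
  }

  sv <- .start_values(spec, S)
  best <- NULL
  for (r in 0:n_restarts) {
    st <- if (r == 0) sv$start else with_seed(1000 + r, {
      jit <- sv$start * stats::runif(length(sv$start), 0.5, 1.5)
      jit[sv$start == 0] <- stats::runif(sum(sv$start == 0), -0.1, 0.1)
      pmax(jit, sv$lower)
    })
    opt <- tryCatch(
      stats::nlminb(st, obj, gradient = grad, lower = sv$lower,
                    control = list(abs.tol = 1e-10, rel.tol = 1e-12,
                                   iter.max = 1000, eval.max = 5000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stopf("all optimizer restarts failed")

  theta <- best$par
  names(theta) <- vapply(seq_len(spec$q), function(i) {
    nm <- spec$pt$name[spec$pt$theta_idx %in% i]
    nm[1]
  }, character(1))

  # scale-free gradient criterion: gradient relative to the curvature scale
  # of the weighted objective (parameters pinned at a bound are exempt)
  g <- grad(theta)
  at_bound <- theta <= sv$lower + 1e-12
  g[at_bound & g > 0] <- 0
  J <- .sigma_jacobian_analytic(spec, theta)
  curv <- max(diag(crossprod(J, W * J)))
  grad_crit <- max(abs(g)) / max(1, abs(best$objective), curv)
  converged <- best$convergence == 0 && is.finite(grad_crit) && grad_crit < 1e-6

  fit <- list(theta = theta, objective = best$objective,
              converged = converged, grad_crit = grad_crit,
              q = cdf$q, df = cdf$df, p_star = cdf$p_star,
              smoothing_report = c(S = smS$max_change, V = smV$max_change),
              spec = spec, S = S, V = V,
              implied = implied_sigma(spec, theta))
  class(fit) <- "fit_result"
  if (!converged && !se) return(fit)

  if (se) {
    sw <- tryCatch(sandwich_se(spec, gs, theta, V = V, J = J),
                   error = function(e) {
                     warnf("sandwich SEs unavailable: %s", conditionMessage(e))
                     NULL
                   })
    if (!is.null(sw)) {
      fit$se <- sw$se
      fit$vcov_theta <- sw$vcov
    }
    ch <- model_chi2(spec, gs, theta, V = V, J = J)
    fit$chi2 <- ch$chi2; fit$p_model <- ch$p
    indep <- .fit_independence(S, V)
    fi <- fit_indices(ch$chi2, cdf$df, cdf$q, indep$chi2, indep$df,
                      residuals = s - vech(fit$implied), S = S)
    fit$aic <- fi$aic; fit$cfi <- fi$cfi; fit$srmr <- fi$srmr
    fit$chi2_indep <- indep$chi2; fit$df_indep <- indep$df
    if (!is.null(sw))
      fit$standardized <- standardize(fit, spec, S)
  }
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> '%s': chi2(%d) = %s, p = %s, AIC = %s, CFI = %s, SRMR = %s%s\n",
              x$spec$name, x$df,
              if (is.null(x$chi2)) "NA" else sprintf("%.2f", x$chi2),
              if (is.null(x$p_model)) "NA" else format.pval(x$p_model, digits = 3),
              if (is.null(x$aic)) "NA" else sprintf("%.2f", x$aic),
              if (is.null(x$cfi)) "NA" else sprintf("%.3f", x$cfi),
              if (is.null(x$srmr)) "NA" else sprintf("%.3f", x$srmr),
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$standardized)) print(x$standardized, digits = 3)
  invisible(x)
}

# Independence baseline for the CFI: free variances, all covariances 0.
# Under diagonal weights the solution is theta = diag(S) exactly.
.fit_independence <- function(S, V) {
  k <- nrow(S)
  p_star <- k * (k + 1) / 2
  idx <- vech_index(k)
  s <- vech(S)
  # implied vector has S_ii at diagonal positions, 0 elsewhere
  sig <- numeric(p_star)
  diag_pos <- which(idx$row == idx$col)
  sig[diag_pos] <- pmax(diag(S), 0)
  e <- s - sig
  D <- pmax(diag(V), 1e-10)
  W <- 1 / D
  # Jacobian: d sigma / d theta_i = indicator of diagonal position i
  J <- matrix(0, p_star, k)
  J[cbind(diag_pos, seq_len(k))] <- 1
  ch <- .resid_chi2(e, J, W, V, df = p_star - k)
  list(chi2 = ch$chi2, df = p_star - k)
}

#' Sandwich standard errors for a DWLS fit
#'
#' `vcov = (J'WJ)^-1 J'W V W J (J'WJ)^-1` with `W = diag(V)^-1` and `J` the
#' Jacobian of the implied moments in `theta`, computed analytically from
#' the model's path matrices (and verified against central finite
#' differences in the test suite).
#'
#' @param spec `model_spec`.
#' @param gs `covstruct` (only `V` is used; may be passed via `V`).
#' @param theta_hat parameter vector at the optimum.
#' @param V optional smoothed sampling covariance (defaults to `gs$V`).
#' @param J optional precomputed Jacobian.
#' @return list with `se` and `vcov`.
#' @export
sandwich_se <- function(spec, gs, theta_hat, V = NULL, J = NULL) {
  V <- V %||% subset_covstruct(gs, spec$observed)$V
  J <- J %||% .sigma_jacobian_analytic(spec, theta_hat)
  qr_J <- qr(J)
  if (qr_J$rank < ncol(J)) {
    bad <- colnames(J) %||% names(theta_hat)
    drop_idx <- qr_J$pivot[(qr_J$rank + 1):ncol(J)]
    stopf("model empirically under-identified: rank-deficient Jacobian (parameters: %s)",
          paste(bad[drop_idx] %||% drop_idx, collapse = ", "))
  }
  W <- 1 / pmax(diag(V), 1e-10)
  JW <- J * W
  bread <- solve(crossprod(J, JW))
  meat <- crossprod(JW, V %*% JW)
  vcov <- bread %*% meat %*% bread
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(theta_hat)
  list(se = se, vcov = vcov)
}

# Residual-based pseudoinverse chi-square shared by model and baseline.
.resid_chi2 <- function(e, J, W, V, df) {
  if (df <= 0) return(list(chi2 = 0, p = 1))
  JW <- J * W
  bread <- solve(crossprod(J, JW))
  P <- diag(length(e)) - J %*% bread %*% t(JW)
  Omega <- P %*% V %*% t(P)
  ev <- eigen((Omega + t(Omega)) / 2, symmetric = TRUE)
  keep <- seq_len(df)
  U <- ev$vectors[, keep, drop = FALSE] %*%
    ((1 / ev$values[keep]) * t(ev$vectors[, keep, drop = FALSE]))
  chi2 <- drop(crossprod(e, U %*% e))
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Residual-based model test statistic
#'
#' `T = e' U e` with `e = s - sigma(theta_hat)` and `U` the rank-`df`
#' Moore-Penrose pseudoinverse of the asymptotic residual covariance
#' `(I - J (J'WJ)^-1 J'W) V (...)'`; `p` from the chi-square distribution
#' with `df = p* - q`. Saturated models return `chi2 = 0`, `p = 1`.
#'
#' @inheritParams sandwich_se
#' @return list with `chi2`, `df`, `p`.
#' @export
model_chi2 <- function(spec, gs, theta_hat, V = NULL, J = NULL) {
  gs_sub <- if (is.null(V)) subset_covstruct(gs, spec$observed) else NULL
  V <- V %||% gs_sub$V
  S <- if (!is.null(gs_sub)) gs_sub$S else subset_covstruct(gs, spec$observed)$S
  J <- J %||% .sigma_jacobian_analytic(spec, theta_hat)
  cdf <- count_params_df(spec)
  e <- vech(S) - vech(implied_sigma(spec, theta_hat))
  W <- 1 / pmax(diag(V), 1e-10)
  ch <- .resid_chi2(e, J, W, V, df = cdf$df)
  list(chi2 = ch$chi2, df = cdf$df, p = ch$p)
}

#' Fit indices for a fitted structural model
#'
#' `aic = chi2 + 2q`; `cfi = ((chi2_indep - df_indep) - (chi2 - df)) /
#' (chi2_indep - df_indep)` clipped to `[0,1]`; `srmr` is the root mean
#' square over unique moments of the standardized residuals
#' `(S_ij - Sigma_ij) / sqrt(S_ii S_jj)`.
#'
#' @param chi2,df model statistic and degrees of freedom.
#' @param q free-parameter count.
#' @param chi2_indep,df_indep independence-baseline statistic and df.
#' @param residuals raw residual vector `s - sigma(theta_hat)` in
#'   half-vectorization order.
#' @param S observed (smoothed) covariance matrix.
#' @return list with `aic`, `cfi`, `srmr`.
#' @export
fit_indices <- function(chi2, df, q, chi2_indep, df_indep, residuals, S) {
  aic <- chi2 + 2 * q
  denom <- chi2_indep - df_indep
  if (!is.finite(denom) || denom <= 0) {
    warnf("degenerate baseline (chi2_indep <= df_indep); CFI reported as 1")
    cfi <- 1
  } else {
    cfi <- min(max((denom - (chi2 - df)) / denom, 0), 1)
  }
  idx <- vech_index(nrow(S))
  scale <- sqrt(diag(S)[idx$row] * diag(S)[idx$col])
  srmr <- sqrt(mean((residuals / scale)^2))
  list(aic = aic, cfi = cfi, srmr = srmr)
}

#' Fully standardized solution with delta-method standard errors
#'
#' Rescales every estimate so all latent and observed variables have unit
#' variance: loadings and regressions become standardized paths, covariances
#' become correlations, variances become variance proportions. Standard
#' errors are propagated from the sandwich covariance of the free parameters
#' by a numerical delta method.
#'
#' @param fit `fit_result` (needs `vcov_theta`).
#' @param spec `model_spec` (defaults to `fit$spec`).
#' @param S observed covariance matrix used in the fit (defaults to `fit$S`).
#' @return data.frame with columns `param`, `op`, `est`, `se`, `est_std`,
#'   `se_std`, `p`, `sig` (significance at 0.05, unstandardized scale).
#' @export
standardize <- function(fit, spec = fit$spec, S = fit$S) {
  pt <- spec$pt
  vars <- c(spec$observed, spec$latents)
  li <- match(pt$lhs, vars); ri <- match(pt$rhs, vars)
  vals0 <- ifelse(pt$free, 0, pt$value)
  ti <- ifelse(pt$free, pt$theta_idx, NA_integer_)

  std_vec <- function(theta) {
    sig_all <- .implied_all(spec, theta)
    sd_all <- sqrt(pmax(diag(sig_all), 0))
    v <- vals0
    v[pt$free] <- theta[ti[pt$free]]
    num <- ifelse(pt$op == "=~", v * sd_all[li],
                  ifelse(pt$op == "~", v * sd_all[ri], v))
    den <- ifelse(pt$op == "=~", sd_all[ri],
                  ifelse(pt$op == "~", sd_all[li],
                         ifelse(li == ri, sd_all[li]^2, sd_all[li] * sd_all[ri])))
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }

  est_std <- std_vec(fit$theta)
  if (any(is.na(est_std)))
    warnf("standardization undefined for %d parameter(s) with zero variance",
          sum(is.na(est_std)))

  se_std <- rep(NA_real_, nrow(pt))
  if (!is.null(fit$vcov_theta)) {
    Jst <- matrix(0, nrow(pt), spec$q)
    for (i in seq_len(spec$q)) {
      h <- 1e-6 * max(1, abs(fit$theta[i]))
      tp <- fit$theta; tp[i] <- tp[i] + h
      tm <- fit$theta; tm[i] <- tm[i] - h
      Jst[, i] <- (std_vec(tp) - std_vec(tm)) / (2 * h)
    }
    vst <- Jst %*% fit$vcov_theta %*% t(Jst)
    se_std <- sqrt(pmax(diag(vst), 0))
    se_std[is.na(est_std)] <- NA_real_
  }

  est <- vapply(seq_len(nrow(pt)), function(r)
    if (pt$free[r]) fit$theta[pt$theta_idx[r]] else pt$value[r], numeric(1))
  se <- rep(NA_real_, nrow(pt))
  if (!is.null(fit$se)) se[pt$free] <- fit$se[pt$theta_idx[pt$free]]
  pz <- ifelse(is.na(se) | se == 0, NA_real_, 2 * stats::pnorm(-abs(est / se)))
  data.frame(param = pt$name, op = pt$op, free = pt$free,
             est = est, se = se, est_std = est_std, se_std = se_std,
             p = pz, sig = !is.na(pz) & pz < 0.05,
             stringsAsFactors = FALSE)
}
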