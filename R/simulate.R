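# Summary-level simulator with known ground truth.
#
# z-statistics are generated directly at the summary level under the same
# second-moment model that LD score regression assumes: for variant j the
# k-vector of z-statistics is multivariate normal with covariance
#   C_j = (l_j / M) * D_N Sigma_g D_N + I0,
# D_N = diag(sqrt(N)), Sigma_g the true genetic covariance matrix, and I0
# the intercept matrix (1 + confounding on the diagonal, sample-overlap
# terms off-diagonal). No individual-level genotypes are involved; this is
# the key idealization and exactly matches the regression expectations the
# estimators target.

#' Simulate an LD-score reference
#'
#' LD scores are drawn from a shifted gamma (right-skewed, minimum
#' `l_shift`), variants are split into contiguous equal-count jackknife
#' blocks, and biallelic alleles are sampled excluding strand-ambiguous
#' pairs except for a configurable fraction.
#'
#' @param M number of variants (must be at least `10 * n_blocks`).
#' @param n_blocks number of jackknife blocks.
#' @param seed integer seed (generation is a pure function of the arguments).
#' @param mean_l2 mean LD score (default 40).
#' @param l_shift lower bound of the LD-score distribution (default 1).
#' @param ambiguous_frac fraction of variants given strand-ambiguous (A/T or
#'   C/G) allele pairs (default 0).
#' @return `ld_reference` data.frame.
#' @export
simulate_ld_reference <- function(M, n_blocks, seed = 1, mean_l2 = 40,
                                  l_shift = 1, ambiguous_frac = 0) {
  if (M < 10 * n_blocks) stopf("need M >= 10 * n_blocks")
  with_seed(seed, {
    shape <- 1.5
    l2 <- l_shift + stats::rgamma(M, shape = shape,
                                  scale = (mean_l2 - l_shift) / shape)
    block <- as.integer(ceiling(seq_len(M) / (M / n_blocks)))
    block <- pmin(block, n_blocks)
    pairs_ok <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                      c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
    pairs_amb <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    amb <- stats::runif(M) < ambiguous_frac
    pick_ok <- sample.int(nrow(pairs_ok), M, replace = TRUE)
    pick_amb <- sample.int(nrow(pairs_amb), M, replace = TRUE)
    a1 <- ifelse(amb, pairs_amb[pick_amb, 1], pairs_ok[pick_ok, 1])
    a2 <- ifelse(amb, pairs_amb[pick_amb, 2], pairs_ok[pick_ok, 2])
    as_ld_reference(data.frame(
      SNP = sprintf("rs%07d", seq_len(M)), A1 = a1, A2 = a2,
      MAF = stats::runif(M, 0.01, 0.5), L2 = l2, BLOCK = block,
      stringsAsFactors = FALSE))
  })
}

#' Write an LD-score reference to a tab-delimited file
#'
#' @param ref `ld_reference`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ld_reference <- function(ref, path) {
  utils::write.table(as.data.frame(ref), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a ground-truth configuration for the simulator
#'
#' The truth is a latent factor model on the genetic (liability) scale:
#' standardized loadings `Lambda_std` on unit-variance factors with
#' correlation matrix `Phi`, per-trait heritabilities `h2` scaling the
#' implied genetic correlation matrix to the covariance `Sigma_g`
#' (`diag(Sigma_g) = h2`). The intercept matrix `I0` carries confounding
#' (diagonal) and sample-overlap (off-diagonal) terms.
#'
#' @param traits character vector of trait names.
#' @param h2 per-trait SNP heritabilities (diagonal of `Sigma_g`).
#' @param N per-trait (effective) sample sizes.
#' @param Lambda_std k x f matrix of standardized loadings.
#' @param Phi f x f factor correlation matrix.
#' @param I0 k x k intercept matrix (default identity: no confounding, no
#'   overlap).
#' @param M,n_blocks,seed simulation dimensions and seed.
#' @param binary named logical (which traits are case-control).
#' @param mean_l2 mean simulated LD score.
#' @return `truth_config` list with the implied `Sigma_g` attached.
#' @export
truth_config <- function(traits, h2, N, Lambda_std, Phi,
                         I0 = diag(length(traits)), M = 20000, n_blocks = 50,
                         seed = 1, binary = NULL, mean_l2 = 40) {
  k <- length(traits)
  stopifnot(length(h2) == k, length(N) == k, nrow(Lambda_std) == k,
            nrow(Phi) == ncol(Phi), ncol(Lambda_std) == nrow(Phi))
  if (any(h2 < 0 | h2 > 1)) stopf("per-trait h2 must lie in [0,1]")
  tc <- list(traits = traits, h2 = h2, N = N, Lambda_std = Lambda_std,
             Phi = Phi, I0 = I0, M = M, n_blocks = n_blocks, seed = seed,
             binary = binary, mean_l2 = mean_l2)
  class(tc) <- "truth_config"
  tc$Sigma_g <- implied_sigma_g(tc)
  tc
}

#' True genetic covariance matrix implied by a truth configuration
#'
#' `R = Lambda_std Phi Lambda_std' + Theta_std` with `Theta_std` diagonal
#' completing unit variances, then `Sigma_g = D R D`, `D = diag(sqrt(h2))`.
#'
#' @param truth `truth_config` (the `Sigma_g` field may be absent).
#' @return k x k positive semi-definite matrix with `h2` on the diagonal.
#' @export
implied_sigma_g <- function(truth) {
  L <- truth$Lambda_std
  comm <- diag(L %*% truth$Phi %*% t(L))
  if (any(comm > 1 + 1e-8))
    stopf("standardized communalities exceed 1 (max %.3f)", max(comm))
  R <- L %*% truth$Phi %*% t(L) + diag(pmax(1 - comm, 0))
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stopf("implied genetic correlation matrix is not PSD (min eigenvalue %.3g)", ev)
  D <- diag(sqrt(truth$h2), nrow = length(truth$h2))
  Sg <- D %*% R %*% D
  dimnames(Sg) <- list(truth$traits, truth$traits)
  Sg
}

# Symmetric square root with eigenvalue clipping at zero (inputs may be
# PSD to numerical tolerance).
.mat_sqrt <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Simulate multi-trait GWAS z-statistics
#'
#' Draws, for every reference variant, the k-vector of z-statistics from the
#' multivariate normal with covariance
#' `(l_j/M) D_N Sigma_g D_N + I0`; p-values are two-sided normal tails.
#'
#' @param truth `truth_config`.
#' @param ref `ld_reference` of length `truth$M` (defaults to a fresh
#'   simulated reference under the truth's seed).
#' @param seed overrides `truth$seed`.
#' @param n_jitter relative half-width of optional per-variant uniform N
#'   jitter (default 0 = constant N).
#' @return named list of munge-ready `sumstats` tables (alleles taken from
#'   the reference, INFO = 1).
#' @export
simulate_sumstats <- function(truth, ref = NULL, seed = truth$seed,
                              n_jitter = 0) {
  if (is.null(ref))
    ref <- simulate_ld_reference(truth$M, truth$n_blocks, seed = seed,
                                 mean_l2 = truth$mean_l2)
  M <- nrow(ref)
  k <- length(truth$traits)
  Lg <- .mat_sqrt(truth$Sigma_g)
  ev0 <- min(eigen(truth$I0, symmetric = TRUE, only.values = TRUE)$values)
  if (ev0 < -1e-10) stopf("intercept matrix I0 is not PSD")
  L0 <- .mat_sqrt(truth$I0)
  with_seed(seed + 1L, {
    Nmat <- matrix(rep(truth$N, each = M), M, k)
    if (n_jitter > 0)
      Nmat <- Nmat * stats::runif(M * k, 1 - n_jitter, 1 + n_jitter)
    U <- matrix(stats::rnorm(M * k), M, k)
    E <- matrix(stats::rnorm(M * k), M, k)
    # genetic part scales with sqrt(N_a l_j / M); intercept part is constant
    Z <- (U %*% Lg) * sqrt(Nmat) * sqrt(ref$L2 / M) + E %*% t(L0)
    out <- lapply(seq_len(k), function(a) {
      as_sumstats(data.frame(SNP = ref$SNP, A1 = ref$A1, A2 = ref$A2,
                             Z = Z[, a], P = p_from_z(Z[, a]),
                             N = Nmat[, a], INFO = 1, FRQ = ref$MAF,
                             stringsAsFactors = FALSE),
                  trait_name = truth$traits[a],
                  is_binary = isTRUE(truth$binary[[truth$traits[a]]]))
    })
    names(out) <- truth$traits
    out
  })
}

#' Simulate an exposure/outcome pair with known causal effect
#'
#' Standardized per-allele exposure effects are zero except at
#' `n_instruments` planted, evenly spaced instrument positions with effect
#' `instrument_b` (alternating sign); the outcome effect at every variant is
#' `beta * b_zx + d` with independent direct effects `d ~ N(0, direct_sd)`
#' at non-instrument positions. Observed z-statistics are
#' `sqrt(N) * b + e` with `e ~ N(0,1)` when `noise = TRUE` and exact
#' otherwise.
#'
#' @param ref `ld_reference`.
#' @param beta true causal effect of the exposure on the outcome.
#' @param n_instruments number of planted instruments.
#' @param instrument_b standardized instrument effect size (default 0.05;
#'   with the default N this puts instrument p-values far below 5e-7).
#' @param direct_sd SD of per-variant direct effects on the outcome.
#' @param N_exposure,N_outcome GWAS sample sizes.
#' @param noise add sampling noise to the z-statistics.
#' @param seed integer seed.
#' @return list with `exposure` and `outcome` `sumstats`; attributes
#'   `instrument_idx`, `beta`, `direct` (true direct effects).
#' @export
simulate_causal_pair <- function(ref, beta = 0.3, n_instruments = 50,
                                 instrument_b = 0.05, direct_sd = 0.005,
                                 N_exposure = 1e5, N_outcome = 1e5,
                                 noise = TRUE, seed = 1) {
  M <- nrow(ref)
  idx <- round(seq(1, M, length.out = n_instruments + 2))[2:(n_instruments + 1)]
  with_seed(seed, {
    b_zx <- numeric(M)
    b_zx[idx] <- instrument_b * rep_len(c(1, -1), n_instruments)
    d <- stats::rnorm(M, 0, direct_sd)
    d[idx] <- 0
    b_zy <- beta * b_zx + d
    zx <- sqrt(N_exposure) * b_zx
    zy <- sqrt(N_outcome) * b_zy
    if (noise) {
      zx <- zx + stats::rnorm(M)
      zy <- zy + stats::rnorm(M)
    }
    mk <- function(z, N, nm) as_sumstats(
      data.frame(SNP = ref$SNP, A1 = ref$A1, A2 = ref$A2, Z = z,
                 P = p_from_z(z), N = N, stringsAsFactors = FALSE),
      trait_name = nm)
    out <- list(exposure = mk(zx, N_exposure, "exposure"),
                outcome = mk(zy, N_outcome, "outcome"))
    attr(out, "instrument_idx") <- idx
    attr(out, "beta") <- beta
    attr(out, "direct") <- d
    out
  })
}

#' Canonical ground-truth configuration
#'
#' The default end-to-end scenario: 12 traits (five alcohol/suicide
#' measures, seven impulsivity measures) whose heritabilities and sample
#' sizes mirror the real GWAS inputs, a common alcohol/suicide factor with
#' standardized loadings (0.93, 0.97, 0.84, 0.65, 0.27), five impulsivity
#' factors with the single-indicator / equated-pair conventions, and factor
#' correlations placing the common factor closest to lack of premeditation.
#' Desk-scale dimensions: M = 20,000 variants in 50 jackknife blocks.
#'
#' @param seed integer seed stored in the configuration.
#' @param M,n_blocks override the desk-scale dimensions.
#' @return `truth_config`.
#' @export
canonical_truth <- function(seed = 1, M = 20000, n_blocks = 50) {
  traits <- trait_registry()
  h2 <- c(ALC = 0.0729, ALP = 0.0372, DEP = 0.1175, DPW = 0.0492,
          SA = 0.0399, NEG = 0.0799, POS = 0.0682, MED = 0.0402,
          BIS = 0.0617, SEN = 0.0836, EXT = 0.0508, PER = 0.0774)
  N <- c(ALC = 160824, ALP = 160824, DEP = 26853, DPW = 537349,
         SA = 74887, NEG = 22795, POS = 22738, MED = 22774,
         BIS = 21495, SEN = 22745, EXT = 63030, PER = 22861)
  factors <- c("Cg", .imp_factors)
  L <- matrix(0, 12, 6, dimnames = list(traits, factors))
  L["ALC", "Cg"] <- 0.93; L["DPW", "Cg"] <- 0.97
  L["ALP", "Cg"] <- 0.84; L["DEP", "Cg"] <- 0.65; L["SA", "Cg"] <- 0.27
  L["NEG", "F_NEG"] <- 1; L["POS", "F_POS"] <- 1
  # two-indicator factors: equal loadings on the covariance scale, so the
  # standardized pair differs by sqrt(h2_1 / h2_2)
  L["MED", "F_PRE"] <- 0.85
  L["BIS", "F_PRE"] <- 0.85 * sqrt(h2[["MED"]] / h2[["BIS"]])
  L["SEN", "F_SEN"] <- 0.55
  L["EXT", "F_SEN"] <- 0.55 * sqrt(h2[["SEN"]] / h2[["EXT"]])
  L["PER", "F_PER"] <- 1
  Phi <- diag(6); dimnames(Phi) <- list(factors, factors)
  set_phi <- function(a, b, v) { Phi[a, b] <<- v; Phi[b, a] <<- v }
  # common-factor row: reported correlations with the five impulsivity factors
  set_phi("Cg", "F_NEG", 0.24); set_phi("Cg", "F_POS", 0.39)
  set_phi("Cg", "F_PRE", 0.53); set_phi("Cg", "F_SEN", 0.26)
  set_phi("Cg", "F_PER", 0.30)
  # impulsivity inter-factor correlations: plausible moderate values
  set_phi("F_NEG", "F_POS", 0.60); set_phi("F_NEG", "F_PRE", 0.35)
  set_phi("F_NEG", "F_SEN", 0.00); set_phi("F_NEG", "F_PER", 0.40)
  set_phi("F_POS", "F_PRE", 0.45); set_phi("F_POS", "F_SEN", 0.25)
  set_phi("F_POS", "F_PER", 0.35); set_phi("F_PRE", "F_SEN", 0.20)
  set_phi("F_PRE", "F_PER", 0.45); set_phi("F_SEN", "F_PER", 0.05)
  truth_config(traits, h2, N, L, Phi, M = M, n_blocks = n_blocks,
               seed = seed)
}

#' True parameter values of the combined correlational model
#'
#' Translates a canonical-layout `truth_config` into the values the combined
#' model's free parameters take when the model is exactly true, on the
#' genetic covariance scale: loadings `sqrt(h2_indicator) * lambda_std` for
#' unit-variance factors (equated pairs share one value), factor covariances
#' `Phi[a,b] * s_a * s_b` with `s = 1` for unit-variance factors and
#' `s = sqrt(h2)` of the indicator for single-indicator factors, factor
#' variances `h2` for single-indicator factors, and indicator residuals
#' `h2 * (1 - lambda_std^2)`. Names match the fitted parameter names of
#' [spec_combined()]. Standardized loadings and the factor correlation
#' matrix are returned alongside for checks on the standardized solution.
#'
#' @param truth `truth_config` with the canonical factor layout.
#' @return list with `theta` (named truth values for the free parameters),
#'   `loadings_std` (named standardized loadings), `Phi` (factor
#'   correlations).
#' @export
truth_combined_params <- function(truth) {
  L <- truth$Lambda_std
  h2 <- truth$h2
  factors <- colnames(L)
  single <- vapply(factors, function(f) {
    ind <- rownames(L)[L[, f] != 0]
    length(ind) == 1 && L[ind, f] == 1
  }, logical(1))
  sfac <- ifelse(single,
                 sqrt(h2[vapply(factors, function(f)
                   rownames(L)[L[, f] != 0][1], character(1))]),
                 1)
  names(sfac) <- factors

  theta <- c()
  for (f in factors) {
    ind <- rownames(L)[L[, f] != 0]
    if (single[[f]]) {
      v <- h2[[ind]]
      names(v) <- paste0(f, "~~", f)
      theta <- c(theta, v)
    } else {
      lam <- sqrt(h2[ind]) * L[ind, f]
      names(lam) <- paste0(f, "=~", ind)
      if (length(unique(round(lam, 10))) == 1 && length(lam) > 1) {
        lam <- lam[1]  # equated group: one free parameter, named by first row
      }
      theta <- c(theta, lam)
      resid <- h2[ind] * (1 - L[ind, f]^2)
      names(resid) <- paste0(ind, "~~", ind)
      theta <- c(theta, resid)
    }
  }
  pairs <- utils::combn(factors, 2)
  phi <- truth$Phi[cbind(pairs[1, ], pairs[2, ])] *
    sfac[pairs[1, ]] * sfac[pairs[2, ]]
  names(phi) <- paste0(pairs[1, ], "~~", pairs[2, ])
  theta <- c(theta, phi)
  ls <- c()
  for (f in factors) {
    ind <- rownames(L)[L[, f] != 0]
    v <- L[ind, f]
    names(v) <- paste0(f, "=~", ind)
    ls <- c(ls, v)
  }
  list(theta = theta, loadings_std = ls, Phi = truth$Phi)
}
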