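# Conditioning one trait's summary statistics on an exposure trait via
# instrument-based estimation of the exposure -> outcome effect (mtCOJO-style,
# simplified: position-window pruning instead of LD clumping, no HEIDI
# outlier step; an instrument-heterogeneity Q statistic is reported instead).

# Standardized per-allele effects from z and n: b = z/sqrt(n), se = 1/sqrt(n).
# Puts binary (effective-N) and continuous traits on a common scale.
.std_effects <- function(ss) {
  list(b = ss$Z / sqrt(ss$N), se = 1 / sqrt(ss$N))
}

#' Select independent instruments for an exposure trait
#'
#' Retains variants with exposure p-value below `p_max` and prunes them
#' greedily: instruments are visited best-p-first and any candidate within
#' `prune_window` positions (in reference order) of an already kept
#' instrument is removed. Position-window pruning stands in for LD-matrix
#' clumping since no genotype panel is carried.
#'
#' @param exposure munged `sumstats` for the exposure, in reference order.
#' @param outcome munged `sumstats` for the outcome (instruments must also be
#'   present here to contribute to the causal-effect estimate).
#' @param p_max inclusion threshold on the exposure p-value (default 5e-7).
#' @param prune_window pruning window in variant positions (default 100).
#' @return `instrument_set`: data.frame with `SNP`, `b_zx`, `se_zx`, `b_zy`,
#'   `se_zy`, `p_exposure`; attribute `n_candidates`.
#' @export
select_instruments <- function(exposure, outcome, p_max = 5e-7,
                               prune_window = 100) {
  pos <- seq_len(nrow(exposure))
  cand <- which(exposure$P < p_max)
  if (!length(cand))
    stopf("no instruments: no exposure variant with p < %g", p_max)
  cand <- cand[order(exposure$P[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(pos[i] - pos[kept]) > prune_window))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  ex <- .std_effects(exposure)
  j <- match(exposure$SNP[kept], outcome$SNP)
  if (all(is.na(j))) stopf("no selected instrument is present in the outcome")
  kept <- kept[!is.na(j)]; j <- j[!is.na(j)]
  ou <- .std_effects(outcome)
  out <- data.frame(SNP = exposure$SNP[kept],
                    b_zx = ex$b[kept], se_zx = ex$se[kept],
                    b_zy = ou$b[j], se_zy = ou$se[j],
                    p_exposure = exposure$P[kept],
                    stringsAsFactors = FALSE)
  structure(out, class = c("instrument_set", "data.frame"),
            n_candidates = length(cand))
}

#' Estimate the exposure-on-outcome effect from instruments
#'
#' Inverse-variance-weighted mean of per-instrument Wald ratios
#' `b_zy / b_zx`, with first-order delta-method variances
#' `(se_zy^2 + r^2 se_zx^2) / b_zx^2`. Also reports Cochran's Q for
#' instrument heterogeneity.
#'
#' @param instruments `instrument_set` from [select_instruments()].
#' @return `causal_estimate`: list with `b_xy`, `se_xy`, `n_instruments`,
#'   `Q`, `Q_df`, `Q_p`.
#' @export
estimate_bxy <- function(instruments) {
  ins <- as.data.frame(instruments)
  zero <- ins$b_zx == 0
  if (any(zero)) {
    warnf("dropping %d instrument(s) with zero exposure effect", sum(zero))
    ins <- ins[!zero, , drop = FALSE]
  }
  if (!nrow(ins)) stopf("no usable instruments remain")
  r <- ins$b_zy / ins$b_zx
  vr <- (ins$se_zy^2 + r^2 * ins$se_zx^2) / ins$b_zx^2
  w <- 1 / vr
  b_xy <- sum(w * r) / sum(w)
  se_xy <- sqrt(1 / sum(w))
  Q <- sum(w * (r - b_xy)^2)
  Q_df <- nrow(ins) - 1L
  structure(list(b_xy = b_xy, se_xy = se_xy, n_instruments = nrow(ins),
                 Q = Q, Q_df = Q_df,
                 Q_p = if (Q_df > 0) stats::pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("<causal_estimate> b_xy = %.4f (se %.4f), %d instruments, Q = %.2f (df %d, p %.3g)\n",
              x$b_xy, x$se_xy, x$n_instruments, x$Q, x$Q_df, x$Q_p))
  invisible(x)
}

#' Condition outcome summary statistics on an exposure
#'
#' For every variant present in both tables (harmonized to common effect
#' alleles), removes the component of the outcome effect mediated by the
#' exposure: on the standardized-effect scale,
#' `b_c = b_zy - b_xy * b_zx` with variance
#' `se_c^2 = se_zy^2 + b_xy^2 se_zx^2 + b_zx^2 se_xy^2`; z and p are
#' recomputed from `b_c / se_c`. Variants absent from the exposure pass
#' through unchanged and are flagged in the `CONDITIONED` column. The
#' conditional standardized effect and its standard error are kept in the
#' `BETA` / `SE` columns.
#'
#' @param outcome,exposure munged `sumstats` tables on the same reference.
#' @param est `causal_estimate` from [estimate_bxy()].
#' @return conditioned `sumstats` with an extra logical column `CONDITIONED`.
#' @export
condition_sumstats <- function(outcome, exposure, est) {
  ou <- .std_effects(outcome)
  j <- match(outcome$SNP, exposure$SNP)
  shared <- !is.na(j)
  mismatch <- shared &
    (outcome$A1 != exposure$A1[j] | outcome$A2 != exposure$A2[j])
  if (any(mismatch, na.rm = TRUE)) {
    warnf("dropping %d variant(s) with unresolvable allele mismatch",
          sum(mismatch))
    keep <- !mismatch
    outcome <- outcome[keep, , drop = FALSE]
    ou <- lapply(ou, `[`, keep)
    j <- j[keep]; shared <- shared[keep]
  }

  b_c <- ou$b
  var_c <- ou$se^2
  js <- j[shared]
  ex <- .std_effects(exposure)
  b_zx <- ex$b[js]; se_zx <- ex$se[js]
  b_c[shared] <- ou$b[shared] - est$b_xy * b_zx
  var_c[shared] <- ou$se[shared]^2 + est$b_xy^2 * se_zx^2 +
    b_zx^2 * est$se_xy^2
  z_c <- b_c / sqrt(var_c)

  out <- data.frame(SNP = outcome$SNP, A1 = outcome$A1, A2 = outcome$A2,
                    Z = z_c, P = p_from_z(z_c), N = outcome$N,
                    BETA = b_c, SE = sqrt(var_c),
                    CONDITIONED = shared, stringsAsFactors = FALSE)
  res <- as_sumstats(out,
                     trait_name = paste0(attr(outcome, "trait_name"), "_cond"),
                     is_binary = attr(outcome, "is_binary"))
  attr(res, "causal_estimate") <- est
  res
}
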