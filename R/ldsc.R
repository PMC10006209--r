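# LD score regression: SNP heritability, genetic covariance, intercepts, and
# the block-jackknife sampling covariance of the genetic covariance matrix.

#' Read an LD-score reference file
#'
#' Expects a tab/whitespace-delimited file with header columns SNP, A1, A2,
#' MAF, L2, BLOCK (per-chromosome partitioned files may simply be
#' concatenated; `BLOCK` labels contiguous jackknife blocks in variant
#' order).
#'
#' @param path file path (or vector of paths, concatenated in order).
#' @return `ld_reference` data.frame with columns `SNP`, `A1`, `A2`, `MAF`,
#'   `L2`, `BLOCK`.
#' @export
read_ld_reference <- function(path) {
  parts <- lapply(path, function(p) {
    if (!file.exists(p)) stopf("LD reference file not found: %s", p)
    con <- if (grepl("\\.gz$", p)) gzfile(p) else file(p)
    utils::read.table(con, header = TRUE, stringsAsFactors = FALSE)
  })
  ref <- do.call(rbind, parts)
  as_ld_reference(ref)
}

#' Validate and class an LD-score reference table
#'
#' @param ref data.frame with columns `SNP`, `A1`, `A2`, `MAF`, `L2`, `BLOCK`.
#' @return `ld_reference` data.frame.
#' @export
as_ld_reference <- function(ref) {
  need <- c("SNP", "A1", "A2", "MAF", "L2", "BLOCK")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stopf("LD reference missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(ref$L2 < 0)) stopf("LD scores must be non-negative")
  if (anyDuplicated(ref$SNP)) stopf("duplicate variant ids in LD reference")
  b <- ref$BLOCK
  if (is.unsorted(b)) stopf("jackknife blocks must be contiguous in variant order")
  rownames(ref) <- NULL
  structure(ref, class = c("ld_reference", "data.frame"))
}

# Weighted least squares of y on x with intercept, returning per-block
# sufficient statistics so delete-one-block coefficients come out in closed
# form. block is an integer label vector aligned with x/y/w.
.wls_block_stats <- function(x, y, w, block) {
  agg <- function(v) as.numeric(rowsum(v, block, reorder = TRUE))
  list(sw = agg(w), swx = agg(w * x), swx2 = agg(w * x * x),
       swy = agg(w * y), swxy = agg(w * x * y))
}

# Full-sample and delete-one-block (slope, intercept) from block stats.
.wls_coefs <- function(st) {
  tot <- vapply(st, sum, numeric(1))
  slope_from <- function(sw, swx, swx2, swy, swxy) {
    den <- sw * swx2 - swx^2
    slope <- (sw * swxy - swx * swy) / den
    intercept <- (swy - slope * swx) / sw
    cbind(slope, intercept)
  }
  full <- slope_from(tot[["sw"]], tot[["swx"]], tot[["swx2"]], tot[["swy"]],
                     tot[["swxy"]])
  del <- slope_from(tot[["sw"]] - st$sw, tot[["swx"]] - st$swx,
                    tot[["swx2"]] - st$swx2, tot[["swy"]] - st$swy,
                    tot[["swxy"]] - st$swxy)
  colnames(del) <- NULL
  list(full = unname(drop(full)), delete_one = del)
}

.jackknife_se <- function(delete_one) {
  B <- nrow(delete_one)
  ctr <- sweep(delete_one, 2, colMeans(delete_one))
  sqrt((B - 1) / B * colSums(ctr^2))
}

# Align a munged sumstats table with the reference; returns merged columns.
.align_to_ref <- function(ss, ref) {
  j <- match(ref$SNP, ss$SNP)
  keep <- !is.na(j)
  list(z = ss$Z[j[keep]], n = ss$N[j[keep]], block = ref$BLOCK[keep],
       l2 = ref$L2[keep], keep = keep)
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics `z^2` on `N * l / M` (LD score
#' `l`, per-variant sample size `N`, `M` polymorphic variants) with a free
#' intercept. Under a polygenic model the slope estimates the observed-scale
#' SNP heritability and the intercept captures uncontrolled confounding
#' (expected 1 in its absence). Standard errors come from a
#' delete-one-block jackknife. Heritability is computed as the self-pair of
#' [estimate_gcov()] under one shared two-pass heteroskedasticity weighting,
#' so `estimate_gcov(ss, ss)` reproduces `estimate_h2(ss)` exactly.
#'
#' @param ss munged `sumstats` table.
#' @param ref `ld_reference`.
#' @param M number of polymorphic variants the heritability is spread over
#'   (default: number of reference variants).
#' @param n_blocks number of jackknife blocks (default 200; capped at the
#'   number of blocks present in `ref`).
#' @return list with `h2_obs`, `intercept`, `se_h2`, `se_intercept`,
#'   `mean_chi2`, `n_variants`, and `delete_one` (B x 2 matrix of
#'   delete-one-block (slope, intercept) estimates).
#' @export
estimate_h2 <- function(ss, ref, M = nrow(ref), n_blocks = 200) {
  al <- .align_to_ref(ss, ref)
  if (length(al$z) < 200) stopf("need >= 200 variants overlapping the reference")
  block <- .regroup_blocks(al$block, n_blocks)
  if (length(unique(block)) < 2) stopf("need at least 2 jackknife blocks")
  if (stats::var(al$l2) == 0) stopf("degenerate design: all LD scores equal")
  .h2_core(al$z, al$n, al$l2, block, M)
}

# Heritability is estimated as the self-pair of the covariance core, so the
# self-covariance identity estimate_gcov(ss, ss) == estimate_h2(ss) holds
# exactly (one shared weighting scheme).
.h2_core <- function(z, n, l2, block, M, h1 = NULL) {
  est <- .gcov_core(z, n, z, n, l2, block, M, h1 = h1, h2 = h1)
  list(h2_obs = est$gcov, intercept = est$intercept,
       se_h2 = est$se_gcov, se_intercept = est$se_intercept,
       mean_chi2 = mean(z^2), n_variants = length(z),
       delete_one = est$delete_one)
}

#' Estimate genetic covariance between two traits by LD score regression
#'
#' Regresses the per-variant product `z1 * z2` on `sqrt(N1 N2) * l / M` with
#' a free intercept; the slope estimates the genetic covariance and the
#' intercept absorbs sample overlap between the two GWAS. Both tables must be
#' harmonized to the same reference effect alleles.
#'
#' @inheritParams estimate_h2
#' @param ss1,ss2 munged `sumstats` tables.
#' @return list with `gcov`, `intercept`, `se_gcov`, `se_intercept`,
#'   `n_variants`, `delete_one`.
#' @export
estimate_gcov <- function(ss1, ss2, ref, M = nrow(ref), n_blocks = 200) {
  j1 <- match(ref$SNP, ss1$SNP)
  j2 <- match(ref$SNP, ss2$SNP)
  keep <- !is.na(j1) & !is.na(j2)
  if (sum(keep) == 0) stopf("no shared variants between the two traits")
  if (sum(keep) < 200) stopf("need >= 200 shared variants; have %d", sum(keep))
  z1 <- ss1$Z[j1[keep]]; n1 <- ss1$N[j1[keep]]
  z2 <- ss2$Z[j2[keep]]; n2 <- ss2$N[j2[keep]]
  l2 <- ref$L2[keep]
  block <- .regroup_blocks(ref$BLOCK[keep], n_blocks)
  if (length(unique(block)) < 2) stopf("need at least 2 jackknife blocks")
  .gcov_core(z1, n1, z2, n2, l2, block, M)
}

.gcov_core <- function(z1, n1, z2, n2, l2, block, M, h1 = NULL, h2 = NULL) {
  x <- sqrt(n1 * n2) * l2 / M
  y <- z1 * z2
  l <- pmax(l2, 1)
  # pass 1 on unit-LD weights for slope/intercept and per-trait h2 proxies
  st1 <- .wls_block_stats(x, y, 1 / l, block)
  co1 <- .wls_coefs(st1)$full
  if (is.null(h1))
    h1 <- .wls_coefs(.wls_block_stats(n1 * l2 / M, z1^2, 1 / l, block))$full[1]
  if (is.null(h2))
    h2 <- .wls_coefs(.wls_block_stats(n2 * l2 / M, z2^2, 1 / l, block))$full[1]
  a1 <- 1 + n1 * max(h1, 0) * l2 / M
  a2 <- 1 + n2 * max(h2, 0) * l2 / M
  cc <- co1[1] * x + co1[2]
  w <- 1 / (l * (a1 * a2 + cc^2))
  st <- .wls_block_stats(x, y, w, block)
  co <- .wls_coefs(st)
  se <- .jackknife_se(co$delete_one)
  list(gcov = co$full[1], intercept = co$full[2],
       se_gcov = se[1], se_intercept = se[2],
       n_variants = length(y), delete_one = co$delete_one)
}

# Collapse the reference's contiguous block labels into ~n_blocks contiguous
# equal-count groups (variant order), so callers can ask for fewer blocks
# than the reference provides. Returns an integer label per variant.
.regroup_blocks <- function(block, n_blocks) {
  ub <- unique(block)
  if (length(ub) <= n_blocks) return(match(block, ub))
  grp <- ceiling(seq_along(block) / (length(block) / n_blocks))
  as.integer(pmin(grp, n_blocks))
}

#' Liability-scale conversion factor and heritability
#'
#' Converts an observed-scale heritability of a binary trait to the liability
#' scale of a thresholded standard-normal liability:
#' `h2_liab = h2_obs * K^2 (1-K)^2 / (P (1-P) * phi(t)^2)` with `t` the
#' upper-`K` quantile of the standard normal and `phi` its density; `P` is
#' the sample case fraction and `K` the population prevalence. When summary
#' statistics carry effective sample sizes, `P = 0.5` is the standard
#' convention.
#'
#' @param h2_obs observed-scale heritability.
#' @param P sample prevalence in (0,1).
#' @param K population prevalence in (0,1).
#' @return liability-scale heritability.
#' @export
liability_scale <- function(h2_obs, P, K) {
  h2_obs * liability_factor(P, K)
}

#' @rdname liability_scale
#' @export
liability_factor <- function(P, K) {
  if (!is.finite(P) || P <= 0 || P >= 1) stopf("P must be in (0,1)")
  if (!is.finite(K) || K <= 0 || K >= 1) stopf("K must be in (0,1)")
  t <- stats::qnorm(1 - K)
  K^2 * (1 - K)^2 / (P * (1 - P) * stats::dnorm(t)^2)
}

#' Genetic correlation from a genetic covariance matrix
#'
#' @param S genetic covariance matrix.
#' @param i,j trait indices (or names).
#' @return `S[i,j] / sqrt(S[i,i] * S[j,j])`.
#' @export
rg_from_S <- function(S, i, j) {
  if (S[i, i] <= 0 || S[j, j] <= 0)
    stopf("genetic correlation undefined: non-positive heritability on the diagonal")
  S[i, j] / sqrt(S[i, i] * S[j, j])
}

#' Build the multivariate genetic covariance structures (S, V)
#'
#' Assembles the k x k genetic covariance matrix `S` (heritabilities on the
#' diagonal via [estimate_h2()], covariances off-diagonal via
#' [estimate_gcov()]) on the intersection variant set of all traits, together
#' with the p* x p* (p* = k(k+1)/2) block-jackknife sampling covariance `V`
#' of the half-vectorized `S`:
#' `V = (B-1)/B * sum_b (theta_(b) - theta_bar)(theta_(b) - theta_bar)'`
#' over the delete-one-block estimate vectors. Binary traits are rescaled to
#' the liability scale: the trait's rows/columns of `S` are multiplied by the
#' square root of the conversion factor (so its heritability scales by the
#' factor) and `V` by the matching products.
#'
#' Half-vectorization order is the lower triangle in column-major order (see
#' [vech()]).
#'
#' @param tables named list of munged `sumstats` tables (names become trait
#'   names).
#' @param ref `ld_reference`.
#' @param M polymorphic variant count (default `nrow(ref)`).
#' @param n_blocks jackknife blocks (default 200).
#' @param prevalences optional named list, per binary trait, of
#'   `list(P = sample prevalence, K = population prevalence)`; traits not
#'   listed stay on the observed scale. With effective sample sizes use
#'   `P = 0.5`.
#' @return `covstruct` object: list with `S`, `V`, `intercepts`,
#'   `trait_names`, `scale` (per-trait "observed"/"liability"),
#'   `vech_order = "lower-column-major"`, `M`, `n_blocks`, `n_variants`.
#' @export
build_S_V <- function(tables, ref, M = nrow(ref), n_blocks = 200,
                      prevalences = NULL) {
  k <- length(tables)
  if (k < 2) stopf("need at least two traits")
  traits <- names(tables) %||% vapply(tables, attr, "", "trait_name")
  if (is.null(names(tables))) names(tables) <- traits

  # intersect variant sets (in reference order)
  keep <- rep(TRUE, nrow(ref))
  for (t in tables) keep <- keep & !is.na(match(ref$SNP, t$SNP))
  if (sum(keep) < 200)
    stopf("fewer than 200 variants shared by all traits and the reference")
  ref_i <- as_ld_reference(as.data.frame(ref)[keep, , drop = FALSE])

  idx <- vech_index(k)
  p_star <- nrow(idx)
  B <- min(n_blocks, length(unique(ref_i$BLOCK)))
  theta_full <- numeric(p_star)
  theta_del <- NULL
  intercepts <- matrix(NA_real_, k, k, dimnames = list(traits, traits))

  # align all traits once (intersection set, reference order)
  jm <- vapply(tables, function(t) match(ref_i$SNP, t$SNP), integer(nrow(ref_i)))
  Zm <- vapply(seq_len(k), function(a) tables[[a]]$Z[jm[, a]],
               numeric(nrow(ref_i)))
  Nm <- vapply(seq_len(k), function(a) tables[[a]]$N[jm[, a]],
               numeric(nrow(ref_i)))
  l2 <- ref_i$L2
  block <- .regroup_blocks(ref_i$BLOCK, n_blocks)
  l <- pmax(l2, 1)
  # pass-1 heritability proxies shared by all pairwise regressions
  h_pass1 <- vapply(seq_len(k), function(a)
    .wls_coefs(.wls_block_stats(Nm[, a] * l2 / M, Zm[, a]^2, 1 / l,
                                block))$full[1], numeric(1))

  for (r in seq_len(p_star)) {
    i <- idx$row[r]; j <- idx$col[r]
    if (i == j) {
      est <- .h2_core(Zm[, i], Nm[, i], l2, block, M, h1 = h_pass1[i])
      theta_full[r] <- est$h2_obs
      intercepts[i, i] <- est$intercept
    } else {
      est <- .gcov_core(Zm[, j], Nm[, j], Zm[, i], Nm[, i], l2, block, M,
                        h1 = h_pass1[j], h2 = h_pass1[i])
      theta_full[r] <- est$gcov
      intercepts[i, j] <- intercepts[j, i] <- est$intercept
    }
    if (is.null(theta_del))
      theta_del <- matrix(NA_real_, nrow(est$delete_one), p_star)
    theta_del[, r] <- est$delete_one[, 1]
  }

  ctr <- sweep(theta_del, 2, colMeans(theta_del))
  V <- (B - 1) / B * crossprod(ctr)

  scale <- rep("observed", k); names(scale) <- traits
  d <- rep(1, k)
  for (t in names(prevalences %||% list())) {
    ti <- match(t, traits)
    if (is.na(ti)) stopf("prevalence given for unknown trait '%s'", t)
    fac <- liability_factor(prevalences[[t]]$P %||% 0.5, prevalences[[t]]$K)
    d[ti] <- sqrt(fac)
    scale[ti] <- "liability"
  }
  if (any(d != 1)) {
    elem_scale <- d[idx$row] * d[idx$col]
    theta_full <- theta_full * elem_scale
    V <- V * tcrossprod(elem_scale)
  }

  S <- unvech(theta_full)
  dimnames(S) <- list(traits, traits)
  if (any(diag(S) <= 0))
    warnf("non-positive heritability estimate(s) on diag(S) for: %s",
          paste(traits[diag(S) <= 0], collapse = ", "))

  structure(list(S = S, V = V, intercepts = intercepts,
                 trait_names = traits, scale = scale,
                 vech_order = "lower-column-major",
                 M = M, n_blocks = B, n_variants = nrow(ref_i)),
            class = "covstruct")
}

#' @export
print.covstruct <- function(x, ...) {
  cat(sprintf("<covstruct> %d traits, %d variants, %d jackknife blocks\n",
              length(x$trait_names), x$n_variants, x$n_blocks))
  cat("S (genetic covariance):\n")
  print(round(x$S, 4))
  invisible(x)
}

#' Serialize / restore genetic covariance structures
#'
#' Writes `S`, `V`, intercepts, trait names, per-trait scale flags, and the
#' half-vectorization order stamp to a single JSON file.
#'
#' @param gs `covstruct` object.
#' @param path output path.
#' @return `path` invisibly; `read_covstruct()` returns the `covstruct`.
#' @export
write_covstruct <- function(gs, path) {
  obj <- list(trait_names = gs$trait_names, scale = as.list(gs$scale),
              vech_order = gs$vech_order, M = gs$M, n_blocks = gs$n_blocks,
              n_variants = gs$n_variants,
              S = gs$S, V = gs$V, intercepts = gs$intercepts)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_covstruct
#' @export
read_covstruct <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  traits <- obj$trait_names
  S <- matrix(unlist(obj$S), length(traits), byrow = TRUE,
              dimnames = list(traits, traits))
  p_star <- length(traits) * (length(traits) + 1) / 2
  V <- matrix(unlist(obj$V), p_star, byrow = TRUE)
  intercepts <- matrix(unlist(obj$intercepts), length(traits), byrow = TRUE,
                       dimnames = list(traits, traits))
  structure(list(S = S, V = V, intercepts = intercepts,
                 trait_names = traits, scale = unlist(obj$scale),
                 vech_order = obj$vech_order, M = obj$M,
                 n_blocks = obj$n_blocks, n_variants = obj$n_variants),
            class = "covstruct")
}
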