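# Declarative structural model specification and its parameter table.
#
# A model is a set of parameter records (lhs, op, rhs, status) over observed
# traits and latent factors:
#   op "=~"  loading            lhs = factor, rhs = indicator
#   op "~"   regression         lhs ~ rhs (lhs regressed on rhs)
#   op "~~"  (co)variance       lhs == rhs gives a variance
# status is one of "free", "fixed:<value>", "equal:<label>" (records sharing
# a label estimate one parameter). Internally the model is held in RAM form:
# v = A v + u, Cov(u) = S_ram, Sigma_all = (I-A)^-1 S_ram (I-A)^-T.

#' Build loading / regression / covariance / variance records
#'
#' Convenience constructors for the parameter records accepted by
#' [model_spec()].
#'
#' @param factor,indicators factor name and indicator names (one record per
#'   indicator; `status` recycled).
#' @param status `"free"`, `"fixed:<value>"`, or `"equal:<label>"`.
#' @return data.frame of parameter records.
#' @export
loading <- function(factor, indicators, status = "free") {
  data.frame(lhs = factor, op = "=~", rhs = indicators, status = status,
             stringsAsFactors = FALSE)
}

#' @rdname loading
#' @param outcome,predictors outcome and predictor names.
#' @export
regression <- function(outcome, predictors, status = "free") {
  data.frame(lhs = outcome, op = "~", rhs = predictors, status = status,
             stringsAsFactors = FALSE)
}

#' @rdname loading
#' @param v1,v2 variable names (vectors are paired elementwise).
#' @export
covariance <- function(v1, v2, status = "free") {
  data.frame(lhs = v1, op = "~~", rhs = v2, status = status,
             stringsAsFactors = FALSE)
}

#' @rdname loading
#' @param v variable name(s).
#' @export
variance <- function(v, status = "free") {
  covariance(v, v, status)
}

.parse_status <- function(status) {
  out <- data.frame(free = FALSE, value = NA_real_, label = NA_character_)
  out <- out[rep(1, length(status)), , drop = FALSE]
  for (i in seq_along(status)) {
    s <- status[i]
    if (s == "free") {
      out$free[i] <- TRUE
    } else if (startsWith(s, "fixed:")) {
      out$value[i] <- as.numeric(sub("^fixed:", "", s))
      if (is.na(out$value[i])) stopf("bad fixed value in status '%s'", s)
    } else if (startsWith(s, "equal:")) {
      out$free[i] <- TRUE
      out$label[i] <- sub("^equal:", "", s)
    } else stopf("unknown parameter status '%s'", s)
  }
  out
}

#' Construct a structural model specification
#'
#' @param observed ordered character vector of observed trait names.
#' @param latents character vector of latent factor names (disjoint from
#'   `observed`).
#' @param params data.frame of parameter records, typically built by
#'   concatenating [loading()], [regression()], [covariance()], [variance()]
#'   calls with `rbind()`.
#' @param auto_var if `TRUE` (default), a free residual variance is added for
#'   every observed variable that has no `~~` self-record. Latent variances
#'   must always be given explicitly.
#' @param name model label.
#' @return `model_spec` object. Identification rules enforced: every latent
#'   needs a fixed loading or a fixed variance; equality groups need at least
#'   two members; duplicate records are an error.
#' @export
model_spec <- function(observed, latents = character(0), params,
                       auto_var = TRUE, name = "model") {
  if (length(intersect(observed, latents)))
    stopf("observed and latent names overlap: %s",
          paste(intersect(observed, latents), collapse = ", "))
  vars <- c(observed, latents)
  pt <- as.data.frame(params, stringsAsFactors = FALSE)
  need <- c("lhs", "op", "rhs", "status")
  if (!all(need %in% names(pt))) stopf("params needs columns lhs, op, rhs, status")

  bad <- setdiff(unique(c(pt$lhs, pt$rhs)), vars)
  if (length(bad)) stopf("unknown variable(s) in model: %s",
                         paste(bad, collapse = ", "))
  if (any(pt$op == "=~" & !(pt$lhs %in% latents)))
    stopf("loading lhs must be a latent factor")

  # canonicalize ~~ pairs so duplicates are caught regardless of order
  sw <- pt$op == "~~" & match(pt$lhs, vars) > match(pt$rhs, vars)
  tmp <- pt$lhs[sw]; pt$lhs[sw] <- pt$rhs[sw]; pt$rhs[sw] <- tmp
  key <- paste(pt$lhs, pt$op, pt$rhs)
  if (anyDuplicated(key)) stopf("duplicate parameter record(s): %s",
                                paste(unique(key[duplicated(key)]), collapse = "; "))

  if (auto_var) {
    have_var <- pt$lhs[pt$op == "~~" & pt$lhs == pt$rhs]
    add <- setdiff(observed, have_var)
    if (length(add)) pt <- rbind(pt, variance(add, "free"))
  }

  st <- .parse_status(pt$status)
  pt <- cbind(pt, st)

  # equality groups: >= 2 members, none crossing fixed records
  if (any(!is.na(pt$label))) {
    tab <- table(pt$label)
    if (any(tab < 2)) stopf("equality group(s) with fewer than 2 members: %s",
                            paste(names(tab)[tab < 2], collapse = ", "))
  }

  # free-parameter indices (shared within an equality group)
  pt$theta_idx <- NA_integer_
  nxt <- 0L
  seen <- list()
  for (i in seq_len(nrow(pt))) {
    if (!pt$free[i]) next
    lb <- pt$label[i]
    if (!is.na(lb) && !is.null(seen[[lb]])) {
      pt$theta_idx[i] <- seen[[lb]]
    } else {
      nxt <- nxt + 1L
      pt$theta_idx[i] <- nxt
      if (!is.na(lb)) seen[[lb]] <- nxt
    }
  }

  # identification: each latent needs a fixed loading or fixed variance
  for (f in latents) {
    fixed_load <- any(pt$op == "=~" & pt$lhs == f & !pt$free)
    var_row <- pt$op == "~~" & pt$lhs == f & pt$rhs == f
    if (!any(var_row))
      stopf("latent '%s' has no variance record; fix it (unit variance) or free it with a fixed loading", f)
    fixed_var <- any(var_row & !pt$free)
    has_load <- any(pt$op == "=~" & pt$lhs == f)
    if (!has_load && !any(pt$op %in% c("~", "~~") & (pt$lhs == f | pt$rhs == f)))
      stopf("latent '%s' is unused", f)
    if (!fixed_load && !fixed_var)
      stopf("latent '%s' not identified: needs a fixed loading or fixed variance", f)
  }

  pt$name <- paste0(pt$lhs, pt$op, pt$rhs)
  spec <- structure(list(observed = observed, latents = latents, pt = pt,
                         q = nxt, name = name),
                    class = "model_spec")
  spec$ram <- .ram_indices(spec)
  spec
}

# Precompute RAM matrix templates and fill indices for fast implied-sigma.
.ram_indices <- function(spec) {
  vars <- c(spec$observed, spec$latents)
  n <- length(vars)
  A0 <- matrix(0, n, n, dimnames = list(vars, vars))
  S0 <- matrix(0, n, n, dimnames = list(vars, vars))
  pt <- spec$pt
  iA <- integer(0); tA <- integer(0)    # linear index into A, theta index
  iS <- integer(0); tS <- integer(0)
  for (r in seq_len(nrow(pt))) {
    li <- match(pt$lhs[r], vars); ri <- match(pt$rhs[r], vars)
    if (pt$op[r] == "=~") { dst <- (li - 1L) * n + ri }        # A[ri, li]
    else if (pt$op[r] == "~") { dst <- (ri - 1L) * n + li }    # A[li, ri]
    else dst <- NA_integer_
    if (pt$op[r] != "~~") {
      if (pt$free[r]) { iA <- c(iA, dst); tA <- c(tA, pt$theta_idx[r]) }
      else A0[dst] <- pt$value[r]
    } else {
      d1 <- (ri - 1L) * n + li; d2 <- (li - 1L) * n + ri
      dst <- if (d1 == d2) d1 else c(d1, d2)
      if (pt$free[r]) { iS <- c(iS, dst); tS <- c(tS, rep(pt$theta_idx[r], length(dst))) }
      else S0[dst] <- pt$value[r]
    }
  }
  # decoded (row, col) positions of every free entry, for analytic
  # derivatives of the implied covariance
  decode <- function(lin) cbind(row = (lin - 1L) %% n + 1L,
                                col = (lin - 1L) %/% n + 1L)
  list(A0 = A0, S0 = S0, iA = iA, tA = tA, iS = iS, tS = tS, n = n,
       obs_idx = seq_along(spec$observed),
       posA = decode(iA), posS = decode(iS))
}

# Model-implied covariance of all variables (observed + latent).
.implied_all <- function(spec, theta) {
  r <- spec$ram
  A <- r$A0; S <- r$S0
  if (length(r$iA)) A[r$iA] <- theta[r$tA]
  if (length(r$iS)) S[r$iS] <- theta[r$tS]
  ImA <- diag(r$n) - A
  Fi <- tryCatch(solve(ImA), error = function(e)
    stopf("non-recursive model: (I - B) is singular"))
  Fi %*% S %*% t(Fi)
}

#' Model-implied covariance matrix of the observed variables
#'
#' Evaluates the structural model at a parameter vector `theta` (ordered by
#' the free-parameter indices of the spec) and returns the implied
#' covariance matrix of the observed traits.
#'
#' @param spec `model_spec`.
#' @param theta numeric vector of length `spec$q`.
#' @return `k x k` matrix in the order of `spec$observed`.
#' @export
implied_sigma <- function(spec, theta) {
  if (length(theta) != spec$q)
    stopf("theta has length %d; model has %d free parameters",
          length(theta), spec$q)
  sig <- .implied_all(spec, theta)
  sig[spec$ram$obs_idx, spec$ram$obs_idx, drop = FALSE]
}

#' Free-parameter count and model degrees of freedom
#'
#' @param spec `model_spec`.
#' @param k number of observed variables (default taken from the spec).
#' @return list with `q` (distinct free parameters; an equality group counts
#'   once), `p_star = k(k+1)/2`, and `df = p_star - q`.
#' @export
count_params_df <- function(spec, k = length(spec$observed)) {
  q <- spec$q
  p_star <- k * (k + 1) / 2
  df <- p_star - q
  if (df < 0) stopf("model under-identified: %d free parameters for %d moments",
                    q, p_star)
  list(q = q, p_star = p_star, df = df)
}

#' @export
print.model_spec <- function(x, ...) {
  cdf <- count_params_df(x)
  cat(sprintf("<model_spec> '%s': %d observed, %d latent, q = %d, df = %d\n",
              x$name, length(x$observed), length(x$latents), cdf$q, cdf$df))
  print(x$pt[, c("lhs", "op", "rhs", "status")], ...)
  invisible(x)
}

#' Serialize / restore a model specification
#'
#' Round-trip stable YAML (or JSON by extension) with records holding
#' `lhs`, `op`, `rhs`, `status` strings.
#'
#' @param spec `model_spec`.
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path` invisibly; `read_model_spec()` returns the `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  obj <- list(name = spec$name, observed = spec$observed,
              latents = spec$latents,
              params = lapply(seq_len(nrow(spec$pt)), function(i)
                list(lhs = spec$pt$lhs[i], op = spec$pt$op[i],
                     rhs = spec$pt$rhs[i], status = spec$pt$status[i])))
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  params <- do.call(rbind, lapply(obj$params, function(p)
    data.frame(lhs = p$lhs, op = p$op, rhs = p$rhs, status = p$status,
               stringsAsFactors = FALSE)))
  model_spec(unlist(obj$observed), unlist(obj$latents) %||% character(0),
             params, auto_var = FALSE, name = obj$name %||% "model")
}
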