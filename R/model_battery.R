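# The analysis battery: structural models linking a common genetic factor
# for alcohol consumption/problems and suicide attempt to five latent
# impulsivity factors, two alternative factorizations, and multivariable
# genetic regressions.
#
# Trait registry (fixed abbreviations):
#   ALC  AUDIT-C alcohol consumption        DPW  drinks per week
#   ALP  AUDIT-P alcohol problems           DEP  alcohol dependence
#   SA   suicide attempt
#   NEG/POS  negative/positive urgency      MED  lack of premeditation
#   BIS  Barratt total score                SEN  sensation-seeking
#   EXT  extraversion                       PER  lack of perseverance
#
# Identification conventions: multi-indicator latents have unit variance and
# free loadings (equated for two-indicator factors); single-indicator latents
# have the loading fixed to 1, the indicator residual fixed to 0, and a free
# factor variance.

#' @rdname run_battery
#' @export
trait_registry <- function() {
  c("ALC", "ALP", "DEP", "DPW", "SA",
    "NEG", "POS", "MED", "BIS", "SEN", "EXT", "PER")
}

.alc_sa <- c("ALC", "DPW", "ALP", "DEP", "SA")
.imp_obs <- c("NEG", "POS", "MED", "BIS", "SEN", "EXT", "PER")
.imp_factors <- c("F_NEG", "F_POS", "F_PRE", "F_SEN", "F_PER")

# Parameter records for the five impulsivity factors over the 7 observed
# impulsivity measures (single-indicator and equated-pair conventions).
.imp_factor_params <- function() {
  rbind(
    loading("F_NEG", "NEG", "fixed:1"),
    loading("F_POS", "POS", "fixed:1"),
    loading("F_PRE", c("MED", "BIS"), "equal:l_pre"),
    loading("F_SEN", c("SEN", "EXT"), "equal:l_sen"),
    loading("F_PER", "PER", "fixed:1"),
    variance(c("F_NEG", "F_POS", "F_PER"), "free"),
    variance(c("F_PRE", "F_SEN"), "fixed:1"),
    variance(c("NEG", "POS", "PER"), "fixed:0"),
    variance(c("MED", "BIS", "SEN", "EXT"), "free")
  )
}

.all_covariances <- function(factors, status = "free") {
  pairs <- utils::combn(factors, 2)
  covariance(pairs[1, ], pairs[2, ], status)
}

#' Common factor model for alcohol consumption, problems, and suicide attempt
#'
#' One unit-variance latent factor (`Cg`) with ALC, DPW, ALP, DEP, SA as
#' indicators (free loadings, free residuals); q = 10, df = 5.
#'
#' @return `model_spec`.
#' @export
spec_common_factor <- function() {
  model_spec(
    observed = .alc_sa, latents = "Cg",
    params = rbind(loading("Cg", .alc_sa, "free"),
                   variance("Cg", "fixed:1"),
                   variance(.alc_sa, "free")),
    auto_var = FALSE, name = "common_factor")
}

#' Five-factor confirmatory model of impulsivity
#'
#' Latent factors for negative urgency, positive urgency, lack of
#' premeditation (MED + BIS, equated loadings), sensation-seeking (SEN +
#' EXT, equated loadings), and lack of perseverance, with all 10 factor
#' covariances free; q = 19, df = 9.
#'
#' @return `model_spec`.
#' @export
spec_five_factor_impulsivity <- function() {
  model_spec(
    observed = .imp_obs, latents = .imp_factors,
    params = rbind(.imp_factor_params(),
                   .all_covariances(.imp_factors)),
    auto_var = FALSE, name = "five_factor_impulsivity")
}

#' Combined correlational model
#'
#' The `primary` variant correlates the common alcohol/suicide factor `Cg`
#' (5 indicators) with the five impulsivity factors (12 observed, q = 34,
#' df = 44). The `problems_only` variant restricts the common factor to
#' ALP, DEP, SA (10 observed, q = 30, df = 25).
#'
#' @param cg_variant `"primary"` or `"problems_only"`.
#' @return `model_spec`.
#' @export
spec_combined <- function(cg_variant = c("primary", "problems_only")) {
  cg_variant <- match.arg(cg_variant)
  cg_ind <- if (cg_variant == "primary") .alc_sa else c("ALP", "DEP", "SA")
  model_spec(
    observed = c(cg_ind, .imp_obs), latents = c("Cg", .imp_factors),
    params = rbind(loading("Cg", cg_ind, "free"),
                   variance("Cg", "fixed:1"),
                   variance(cg_ind, "free"),
                   .imp_factor_params(),
                   .all_covariances(c("Cg", .imp_factors))),
    auto_var = FALSE,
    name = paste0("combined_", cg_variant))
}

#' Two-factor alternative model
#'
#' Replaces `Cg` by an alcohol-specific factor (`ACPg`: ALC, DPW, ALP, DEP)
#' and a suicide-specific single-indicator factor (`SUICg`: SA), correlated
#' with the five impulsivity factors; q = 39, df = 39.
#'
#' @return `model_spec`.
#' @export
spec_two_factor_alternative <- function() {
  acp_ind <- c("ALC", "DPW", "ALP", "DEP")
  model_spec(
    observed = c(acp_ind, "SA", .imp_obs),
    latents = c("ACPg", "SUICg", .imp_factors),
    params = rbind(loading("ACPg", acp_ind, "free"),
                   variance("ACPg", "fixed:1"),
                   variance(acp_ind, "free"),
                   loading("SUICg", "SA", "fixed:1"),
                   variance("SUICg", "free"),
                   variance("SA", "fixed:0"),
                   .imp_factor_params(),
                   .all_covariances(c("ACPg", "SUICg", .imp_factors))),
    auto_var = FALSE, name = "two_factor_alternative")
}

#' Genetic multivariable regression model
#'
#' Regresses one impulsivity-related trait simultaneously on a latent
#' alcohol-consumption factor (ALC + DPW indicators), ALP, DEP, and SA, with
#' free covariances among the four predictors.
#'
#' @param outcome one of NEG, POS, MED, BIS, SEN, EXT, PER.
#' @return `model_spec`.
#' @export
spec_multivariable_regression <- function(outcome) {
  valid <- .imp_obs
  if (!is.character(outcome) || length(outcome) != 1 || !(outcome %in% valid))
    stopf("outcome must be one of %s", paste(valid, collapse = ", "))
  preds <- c("CONS", "ALP", "DEP", "SA")
  pairs <- utils::combn(preds, 2)
  model_spec(
    observed = c("ALC", "DPW", "ALP", "DEP", "SA", outcome),
    latents = "CONS",
    params = rbind(loading("CONS", c("ALC", "DPW"), "free"),
                   variance("CONS", "fixed:1"),
                   variance(c("ALC", "DPW"), "free"),
                   variance(c("ALP", "DEP", "SA"), "free"),
                   covariance(pairs[1, ], pairs[2, ], "free"),
                   regression(outcome, preds, "free"),
                   variance(outcome, "free")),
    auto_var = FALSE,
    name = paste0("regression_", outcome))
}

#' Run the full model battery on genetic covariance structures
#'
#' Fits the five structural models (common factor, five-factor impulsivity,
#' combined primary, two-factor alternative, problems-only) and the seven
#' multivariable regressions on one shared `covstruct`; each model is fitted
#' independently and a failure is recorded without aborting the others.
#'
#' @param gs `covstruct` whose traits cover [trait_registry()].
#' @param models `"all"` or a subset of `c("common", "five_factor",
#'   "combined", "alternative", "problems", "regression")`.
#' @param n_restarts restarts passed to [fit_dwls()].
#' @return `battery_result`: list with `fits` (named `fit_result`s or error
#'   messages), `correlations` (factor-correlation table from the combined
#'   model), `regressions` (standardized coefficient table with 95% CIs).
#' @export
run_battery <- function(gs, models = "all", n_restarts = 5) {
  need <- trait_registry()
  miss <- setdiff(need, gs$trait_names)
  if (length(miss)) stopf("covstruct missing required trait(s): %s",
                          paste(miss, collapse = ", "))
  all_models <- c("common", "five_factor", "combined", "alternative",
                  "problems", "regression")
  if (identical(models, "all")) models <- all_models
  bad <- setdiff(models, all_models)
  if (length(bad)) stopf("unknown model selection: %s", paste(bad, collapse = ", "))

  specs <- list()
  if ("common" %in% models) specs$common_factor <- spec_common_factor()
  if ("five_factor" %in% models)
    specs$five_factor_impulsivity <- spec_five_factor_impulsivity()
  if ("combined" %in% models) specs$combined_primary <- spec_combined("primary")
  if ("alternative" %in% models)
    specs$two_factor_alternative <- spec_two_factor_alternative()
  if ("problems" %in% models)
    specs$combined_problems_only <- spec_combined("problems_only")
  if ("regression" %in% models)
    for (o in .imp_obs) specs[[paste0("regression_", o)]] <-
      spec_multivariable_regression(o)

  fits <- lapply(specs, function(sp)
    tryCatch(fit_dwls(sp, gs, n_restarts = n_restarts),
             error = function(e) structure(conditionMessage(e),
                                           class = "battery_error")))

  correlations <- NULL
  if (!is.null(fits$combined_primary) &&
      inherits(fits$combined_primary, "fit_result") &&
      !is.null(fits$combined_primary$standardized)) {
    std <- fits$combined_primary$standardized
    rows <- std$op == "~~" & std$param != "Cg~~Cg" &
      (startsWith(std$param, "Cg~~") | endsWith(std$param, "~~Cg"))
    correlations <- std[rows, c("param", "est_std", "se_std", "p", "sig")]
    names(correlations)[2:3] <- c("rg", "se")
    rownames(correlations) <- NULL
  }

  regressions <- NULL
  reg_fits <- fits[startsWith(names(fits), "regression_")]
  if (length(reg_fits)) {
    tabs <- lapply(names(reg_fits), function(nm) {
      f <- reg_fits[[nm]]
      if (!inherits(f, "fit_result") || is.null(f$standardized)) return(NULL)
      std <- f$standardized
      rows <- std$op == "~"
      data.frame(outcome = sub("^regression_", "", nm),
                 predictor = sub("^.*~", "", std$param[rows]),
                 beta_std = std$est_std[rows], se = std$se_std[rows],
                 ci_lo = std$est_std[rows] - 1.96 * std$se_std[rows],
                 ci_hi = std$est_std[rows] + 1.96 * std$se_std[rows],
                 sig = std$sig[rows], stringsAsFactors = FALSE)
    })
    regressions <- do.call(rbind, tabs)
    rownames(regressions) <- NULL
  }

  structure(list(fits = fits, correlations = correlations,
                 regressions = regressions),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat(sprintf("<battery_result> %d model(s)\n", length(x$fits)))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    if (inherits(f, "fit_result"))
      cat(sprintf("  %-26s chi2(%d) = %7.2f  AIC = %7.2f  CFI = %.3f  SRMR = %.3f\n",
                  nm, f$df, f$chi2 %||% NA, f$aic %||% NA, f$cfi %||% NA,
                  f$srmr %||% NA))
    else cat(sprintf("  %-26s FAILED: %s\n", nm, unclass(f)))
  }
  invisible(x)
}
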