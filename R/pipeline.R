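# End-to-end orchestration: munge -> condition -> covariance structures ->
# model battery, from a single declarative configuration.

#' Validate a pipeline configuration
#'
#' The configuration (a list, or a YAML/JSON file path) has the shape:
#' \preformatted{
#' ld_reference: path or list of paths
#' traits:
#'   ALC: {file: alc.sumstats.gz}
#'   DEP: {file: dep.sumstats.gz, binary: true, K: 0.12,
#'         cohorts: [{v: 0.25, n: 20000}, ...]}
#'   ...
#' conditioning:          # optional
#'   - {outcome: SA, exposure: MDD, p_max: 5.0e-7}
#' ldsc: {M: 20000, n_blocks: 200}
#' munge: {info_min: 0.90, maf_min: 0.01}
#' battery: all
#' out_dir: results/
#' seed: 1
#' }
#' Traits with a `cohorts` list get their per-variant N replaced by the
#' summed effective sample size; binary traits with a population prevalence
#' `K` are converted to the liability scale in the covariance structures.
#'
#' @param cfg list or path to a YAML/JSON config file.
#' @return normalized config list (errors name the offending entry).
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) stopf("config file not found: %s", cfg)
    cfg <- if (grepl("\\.json$", cfg)) jsonlite::read_json(cfg, simplifyVector = TRUE)
    else yaml::read_yaml(cfg)
  }
  if (is.null(cfg$traits) || !length(cfg$traits)) stopf("config has no traits")
  if (anyDuplicated(names(cfg$traits))) stopf("duplicate trait names in config")
  for (nm in names(cfg$traits)) {
    t <- cfg$traits[[nm]]
    if (is.null(t$file)) stopf("trait '%s': no input file given", nm)
    if (!file.exists(t$file)) stopf("trait '%s': file not found: %s", nm, t$file)
  }
  for (p in unlist(cfg$ld_reference))
    if (!file.exists(p)) stopf("LD reference file not found: %s", p)
  for (cd in cfg$conditioning %||% list()) {
    if (is.null(cd$outcome) || is.null(cd$exposure))
      stopf("conditioning request needs 'outcome' and 'exposure'")
    if (!cd$outcome %in% names(cfg$traits))
      stopf("conditioning outcome '%s' is not a configured trait", cd$outcome)
    if (!cd$exposure %in% names(cfg$traits))
      stopf("conditioning exposure '%s' is not a configured trait", cd$exposure)
  }
  cfg$ldsc <- cfg$ldsc %||% list()
  cfg$munge <- cfg$munge %||% list()
  cfg$battery <- cfg$battery %||% "all"
  cfg$out_dir <- cfg$out_dir %||% "ldsem_results"
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read + munge each trait against the LD-score
#' reference; conditioning of requested outcome traits on exposure traits;
#' construction of the genetic covariance structures (S, V, intercepts);
#' the model battery. Intermediate artifacts (harmonized summary statistics,
#' conditioning reports, `covstruct.json`, per-model fit JSON, summary
#' tables) and a run manifest with input hashes and per-stage counts are
#' persisted under `out_dir`. A failure in any stage aborts with the stage
#' name; artifacts written so far are left in place.
#'
#' @param cfg config list or file path (see [validate_pipeline_config()]).
#' @param verbose log stage progress.
#' @return `battery_result` invisibly (`battery: none` stops after the
#'   covariance structures and returns the `covstruct`); side effect: files
#'   under `out_dir`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, started = format(Sys.time(), "%F %T"),
                   inputs = list(), stages = list())
  log_line <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%T"), sprintf(...))
    if (verbose) message(line)
    cat(line, "\n", file = file.path(cfg$out_dir, "pipeline.log"),
        append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    log_line("stage %s: done", name)
    out
  }

  for (nm in names(cfg$traits))
    manifest$inputs[[nm]] <- unname(tools::md5sum(cfg$traits[[nm]]$file))

  ref <- stage("ld_reference", read_ld_reference(unlist(cfg$ld_reference)))

  tables <- stage("munge", {
    out <- list()
    for (nm in names(cfg$traits)) {
      t <- cfg$traits[[nm]]
      neff <- if (!is.null(t$cohorts))
        effective_sample_size(lapply(t$cohorts, as.list)) else NULL
      raw <- read_sumstats(t$file, trait_name = nm,
                           n = neff %||% t$n, is_binary = isTRUE(t$binary),
                           verbose = verbose)
      if (!is.null(neff)) raw$N <- neff
      m <- munge(raw, ref,
                 info_min = cfg$munge$info_min %||% 0.90,
                 maf_min = cfg$munge$maf_min %||% 0.01, verbose = verbose)
      write_sumstats(m, file.path(cfg$out_dir, paste0(nm, ".sumstats.gz")))
      out[[nm]] <- m
    }
    out
  })
  manifest$stages$munge <- lapply(tables, nrow)

  exclude <- character(0)
  if (length(cfg$conditioning %||% list())) {
    tables <- stage("condition", {
      for (cd in cfg$conditioning) {
        ins <- select_instruments(tables[[cd$exposure]], tables[[cd$outcome]],
                                  p_max = cd$p_max %||% 5e-7,
                                  prune_window = cd$prune_window %||% 100)
        est <- estimate_bxy(ins)
        log_line("condition %s on %s: %d instruments, b_xy = %.4f (se %.4f), Q = %.2f",
                 cd$outcome, cd$exposure, est$n_instruments, est$b_xy,
                 est$se_xy, est$Q)
        cond <- condition_sumstats(tables[[cd$outcome]], tables[[cd$exposure]], est)
        write_sumstats(cond, file.path(cfg$out_dir,
                                       paste0(cd$outcome, "_cond.sumstats.gz")))
        jsonlite::write_json(
          list(outcome = cd$outcome, exposure = cd$exposure,
               n_instruments = est$n_instruments, b_xy = est$b_xy,
               se_xy = est$se_xy, Q = est$Q, Q_df = est$Q_df, Q_p = est$Q_p),
          file.path(cfg$out_dir, paste0(cd$outcome, "_conditioning.json")),
          auto_unbox = TRUE, digits = NA)
        tables[[cd$outcome]] <- cond
        if (isTRUE(cd$drop_exposure %||% TRUE))
          exclude <- c(exclude, cd$exposure)
      }
      tables
    })
  }
  tables <- tables[setdiff(names(tables), exclude)]

  gs <- stage("covstruct", {
    prev <- list()
    for (nm in names(cfg$traits)) {
      t <- cfg$traits[[nm]]
      if (isTRUE(t$binary) && !is.null(t$K) && nm %in% names(tables))
        prev[[nm]] <- list(P = t$P %||% 0.5, K = t$K)
    }
    g <- build_S_V(tables, ref,
                   M = cfg$ldsc$M %||% nrow(ref),
                   n_blocks = cfg$ldsc$n_blocks %||% 200,
                   prevalences = if (length(prev)) prev else NULL)
    write_covstruct(g, file.path(cfg$out_dir, "covstruct.json"))
    g
  })
  manifest$stages$covstruct <- list(n_variants = gs$n_variants,
                                    n_blocks = gs$n_blocks)

  if (identical(cfg$battery, "none")) {
    manifest$finished <- format(Sys.time(), "%F %T")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(gs))
  }

  res <- stage("battery", {
    b <- run_battery(gs, models = cfg$battery)
    for (nm in names(b$fits)) {
      f <- b$fits[[nm]]
      if (!inherits(f, "fit_result")) next
      jsonlite::write_json(
        list(model = nm, chi2 = f$chi2, df = f$df, p = f$p_model,
             aic = f$aic, cfi = f$cfi, srmr = f$srmr,
             converged = f$converged,
             smoothing = as.list(f$smoothing_report),
             parameters = f$standardized),
        file.path(cfg$out_dir, paste0(nm, "_fit.json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    if (!is.null(b$correlations))
      utils::write.table(b$correlations,
                         file.path(cfg$out_dir, "factor_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(b$regressions))
      utils::write.table(b$regressions,
                         file.path(cfg$out_dir, "regressions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    b
  })
  manifest$stages$battery <- lapply(res$fits, function(f)
    if (inherits(f, "fit_result")) "ok" else "failed")

  manifest$finished <- format(Sys.time(), "%F %T")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
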