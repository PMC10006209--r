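# Reading, harmonizing and quality-filtering GWAS summary statistics.

# Default header aliases recognised by read_sumstats(); keys are canonical
# column names, values are accepted (case-insensitive) header spellings.
.default_aliases <- list(
  snp  = c("SNP", "RSID", "RS_ID", "MARKERNAME", "VARIANT_ID", "ID"),
  a1   = c("A1", "EA", "EFFECT_ALLELE", "ALLELE1"),
  a2   = c("A2", "OA", "OTHER_ALLELE", "NEA", "ALLELE2"),
  beta = c("BETA", "B", "EFFECT"),
  or   = c("OR", "ODDS_RATIO"),
  se   = c("SE", "STDERR", "STDERRLOGOR"),
  z    = c("Z", "ZSCORE", "Z_SCORE", "ZSTAT"),
  p    = c("P", "PVAL", "PVALUE", "P_VALUE"),
  n    = c("N", "NEFF", "N_EFF", "TOTALSAMPLESIZE"),
  info = c("INFO", "IMPINFO", "RSQ"),
  frq  = c("FRQ", "MAF", "EAF", "FREQ", "AF")
)

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a plain or gz-compressed whitespace/tab-delimited summary-statistics
#' file with a header, maps column names through configurable aliases, and
#' returns a harmonizable per-variant table. The signed statistic `z` is taken
#' directly when a Z column is present, otherwise reconstructed as `beta/se`
#' or `log(OR)/se`. Rows with unparseable mandatory fields (missing variant
#' id, allele, or signed statistic) are dropped and counted.
#'
#' @param path file path (".gz" handled transparently).
#' @param column_map optional named list overriding the default header
#'   aliases; names are canonical fields (`snp`, `a1`, `a2`, `beta`, `or`,
#'   `se`, `z`, `p`, `n`, `info`, `frq`), values are header names in the file.
#' @param trait_name label stored on the table (defaults to the file name).
#' @param n trait-level sample size used to fill a missing N column.
#' @param is_binary logical flag recorded on the table.
#' @param verbose emit a message with drop counts.
#' @return A `sumstats` data.frame with columns `SNP`, `A1`, `A2`, `Z`, `P`,
#'   `N`, and where available `INFO` and `FRQ`; attributes `trait_name`,
#'   `is_binary`, `n_dropped`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NULL,
                          n = NULL, is_binary = FALSE, verbose = TRUE) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  if (nrow(raw) == 0L) stopf("summary-statistics file is empty: %s", path)

  hdr <- toupper(names(raw))
  find_col <- function(field) {
    if (!is.null(column_map[[field]])) {
      j <- match(toupper(column_map[[field]]), hdr)
      if (is.na(j))
        stopf("mapped column '%s' for field '%s' not present in %s",
              column_map[[field]], field, path)
      return(j)
    }
    j <- match(.default_aliases[[field]], hdr)
    j <- j[!is.na(j)]
    if (length(j)) j[1] else NA_integer_
  }
  cols <- vapply(names(.default_aliases), find_col, integer(1))

  for (field in c("snp", "a1", "a2")) {
    if (is.na(cols[[field]]))
      stopf("mandatory column '%s' not found in %s (aliases tried: %s)",
            field, path, paste(.default_aliases[[field]], collapse = ", "))
  }

  get <- function(field) if (is.na(cols[[field]])) NULL else raw[[cols[[field]]]]
  num <- function(field) {
    v <- get(field)
    if (is.null(v)) NULL else suppressWarnings(as.numeric(v))
  }
  snp <- as.character(get("snp"))
  a1 <- toupper(as.character(get("a1")))
  a2 <- toupper(as.character(get("a2")))
  beta <- num("beta")
  or_ <- num("or")
  se <- num("se")
  z <- num("z")
  p <- num("p")
  nn <- num("n")
  info <- num("info")
  frq <- num("frq")

  if (is.null(beta) && !is.null(or_)) beta <- log(or_)
  z_ratio <- if (!is.null(beta) && !is.null(se)) beta / se else NULL
  if (is.null(z)) {
    if (is.null(z_ratio))
      stopf("no signed statistic in %s: need Z, or BETA/OR with SE", path)
    z <- z_ratio
  } else if (!is.null(z_ratio)) {
    dz <- max(abs(z - z_ratio), na.rm = TRUE)
    if (is.finite(dz) && dz > 1e-6)
      warnf("Z and beta/se disagree (max |diff| = %.3g); using beta/se", dz)
    z <- ifelse(is.finite(z_ratio), z_ratio, z)
  }

  if (is.null(nn)) {
    if (is.null(n)) nn <- rep(NA_real_, length(snp)) else nn <- rep(n, length(snp))
  }

  ok <- !is.na(snp) & snp != "" &
    a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T") &
    is.finite(z)
  n_dropped <- sum(!ok)

  out <- data.frame(SNP = snp[ok], A1 = a1[ok], A2 = a2[ok],
                    Z = z[ok], stringsAsFactors = FALSE)
  out$P <- if (!is.null(p)) p[ok] else p_from_z(out$Z)
  out$N <- nn[ok]
  if (!is.null(info)) out$INFO <- info[ok]
  if (!is.null(frq)) out$FRQ <- frq[ok]

  msgf(verbose, "read %d variants from %s (%d rows dropped as unparseable)",
       nrow(out), basename(path), n_dropped)
  as_sumstats(out, trait_name = trait_name %||% basename(path),
              is_binary = is_binary, n_dropped = n_dropped)
}

#' Construct a summary-statistics table from columns in memory
#'
#' @param df data.frame with at least `SNP`, `A1`, `A2`, `Z`, `N`; `P`,
#'   `INFO`, `FRQ` optional (`P` filled from `Z` when absent).
#' @param trait_name,is_binary,n_dropped metadata stored as attributes.
#' @return `sumstats` data.frame.
#' @export
as_sumstats <- function(df, trait_name = "trait", is_binary = FALSE,
                        n_dropped = 0L) {
  need <- c("SNP", "A1", "A2", "Z", "N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sumstats missing columns: %s", paste(miss, collapse = ", "))
  if (is.null(df$P)) df$P <- p_from_z(df$Z)
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            trait_name = trait_name, is_binary = is_binary,
            n_dropped = n_dropped)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s'%s: %d variants\n",
              attr(x, "trait_name"),
              if (isTRUE(attr(x, "is_binary"))) " (binary)" else "",
              nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Harmonize and quality-filter summary statistics against a reference
#'
#' Mirrors standard munging of GWAS summary statistics: variants are kept
#' only if they are present in the LD-score reference with a matching allele
#' pair (direct, allele-swapped, strand-flipped, or both; the sign of `Z` is
#' flipped when the effect allele is swapped relative to the reference),
#' imputation INFO is at least `info_min` (when an INFO column is present),
#' and minor allele frequency is at least `maf_min`. Strand-ambiguous (A/T,
#' C/G) variants and duplicated variant ids are removed; variants with
#' per-variant N below `0.67 x` the 90th percentile of N are removed.
#' The output is ordered as in the reference, with `A1`/`A2` set to the
#' reference alleles.
#'
#' @param raw `sumstats` table.
#' @param ref `ld_reference` table (see [read_ld_reference()]).
#' @param info_min minimum imputation quality (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param verbose emit a per-filter exclusion report.
#' @return Harmonized `sumstats` table with columns `SNP`, `A1`, `A2`, `Z`,
#'   `P`, `N`; attribute `exclusions` holds per-filter counts.
#' @export
munge <- function(raw, ref, info_min = 0.90, maf_min = 0.01, verbose = TRUE) {
  stopifnot(inherits(raw, "sumstats"))
  excl <- c(duplicate = 0L, missing_n = 0L, low_n = 0L, info = 0L, maf = 0L,
            ambiguous = 0L, not_in_ref = 0L, allele_mismatch = 0L)
  x <- as.data.frame(raw)

  dup <- x$SNP[duplicated(x$SNP)]
  if (length(dup)) {
    drop <- x$SNP %in% dup
    excl[["duplicate"]] <- sum(drop)
    x <- x[!drop, , drop = FALSE]
  }

  if (anyNA(x$N)) {
    excl[["missing_n"]] <- 0L  # filled, not dropped; kept for the report shape
    x$N[is.na(x$N)] <- stats::median(x$N, na.rm = TRUE)
  }
  n_floor <- 0.67 * stats::quantile(x$N, 0.9, names = FALSE, na.rm = TRUE)
  drop <- x$N < n_floor
  excl[["low_n"]] <- sum(drop)
  x <- x[!drop, , drop = FALSE]

  if (!is.null(x$INFO)) {
    drop <- !is.na(x$INFO) & x$INFO < info_min
    excl[["info"]] <- sum(drop)
    x <- x[!drop, , drop = FALSE]
  }
  if (!is.null(x$FRQ)) {
    maf <- pmin(x$FRQ, 1 - x$FRQ)
    drop <- !is.na(maf) & maf < maf_min
    excl[["maf"]] <- sum(drop)
    x <- x[!drop, , drop = FALSE]
  }

  drop <- is_ambiguous_pair(x$A1, x$A2)
  excl[["ambiguous"]] <- sum(drop)
  x <- x[!drop, , drop = FALSE]

  j <- match(x$SNP, ref$SNP)
  excl[["not_in_ref"]] <- sum(is.na(j))
  x <- x[!is.na(j), , drop = FALSE]
  j <- j[!is.na(j)]
  rA1 <- ref$A1[j]; rA2 <- ref$A2[j]

  direct <- x$A1 == rA1 & x$A2 == rA2
  swapped <- x$A1 == rA2 & x$A2 == rA1
  fA1 <- flip_strand(x$A1); fA2 <- flip_strand(x$A2)
  flip_direct <- !direct & !swapped & fA1 == rA1 & fA2 == rA2
  flip_swapped <- !direct & !swapped & fA1 == rA2 & fA2 == rA1
  keep <- direct | swapped | flip_direct | flip_swapped
  excl[["allele_mismatch"]] <- sum(!keep)

  sign <- ifelse(swapped | flip_swapped, -1, 1)[keep]
  x <- x[keep, , drop = FALSE]
  j <- j[keep]
  out <- data.frame(SNP = x$SNP, A1 = ref$A1[j], A2 = ref$A2[j],
                    Z = sign * x$Z, P = x$P, N = x$N,
                    stringsAsFactors = FALSE)
  out <- out[order(j), , drop = FALSE]

  if (nrow(out) == 0L) stopf("munge: no variants retained against reference")
  if (nrow(out) < 0.10 * nrow(ref))
    warnf("munge: only %d of %d reference variants retained (<10%%)",
          nrow(out), nrow(ref))
  if (verbose) {
    rep <- paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")
    message(sprintf("munge '%s': retained %d variants; excluded: %s",
                    attr(raw, "trait_name"), nrow(out), rep))
  }
  res <- as_sumstats(out, trait_name = attr(raw, "trait_name"),
                     is_binary = attr(raw, "is_binary"))
  attr(res, "exclusions") <- excl
  attr(res, "munged") <- TRUE
  res
}

#' Effective sample size for case-control cohorts
#'
#' For a case-control cohort with case fraction (sample prevalence) `v` and
#' total size `n`, the effective sample size is `4 v (1 - v) n`; cohorts are
#' summed. This equalizes information across ascertainment schemes so binary
#' traits can be analysed alongside quantitative ones.
#'
#' @param cohorts list of cohorts, each a list/vector with elements `v`
#'   (sample prevalence, in (0,1)) and `n` (original sample size).
#' @return total effective sample size (scalar).
#' @examples
#' effective_sample_size(list(list(v = 0.5, n = 1000)))  # 1000
#' @export
effective_sample_size <- function(cohorts) {
  if (!length(cohorts)) stopf("cohort list is empty")
  vals <- vapply(cohorts, function(c) {
    v <- c[["v"]]; n <- c[["n"]]
    if (!is.finite(v) || v <= 0 || v >= 1)
      stopf("sample prevalence must be in (0,1); got %s", format(v))
    if (!is.finite(n) || n < 2) stopf("cohort n must be >= 2; got %s", format(n))
    4 * v * (1 - v) * n
  }, numeric(1))
  sum(vals)
}

#' Write harmonized summary statistics to a tab-delimited file
#'
#' @param ss `sumstats` table.
#' @param path output path (".gz" compresses).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- as.data.frame(ss)[, c("SNP", "A1", "A2", "Z", "N")]
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  open(con, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
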