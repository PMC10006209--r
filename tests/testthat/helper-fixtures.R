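# Shared fixtures, built in code at test time.

# Small three-trait one-factor truth for fast end-to-end runs.
small_truth <- function(M = 4000, n_blocks = 40, seed = 1,
                        h2 = c(T1 = 0.3, T2 = 0.2, T3 = 0.4),
                        lambda = c(0.9, 0.7, 0.5),
                        N = c(T1 = 50000, T2 = 80000, T3 = 30000)) {
  L <- matrix(lambda, 3, 1, dimnames = list(names(h2), "F1"))
  truth_config(names(h2), h2, N, L, matrix(1, 1, 1),
               M = M, n_blocks = n_blocks, seed = seed)
}

# Five-trait truth exactly matching the alcohol/SA common factor model.
common_factor_truth <- function(M = 20000, n_blocks = 500, seed = 1) {
  h2 <- c(ALC = 0.0729, ALP = 0.0372, DEP = 0.1175, DPW = 0.0492, SA = 0.0399)
  N <- c(ALC = 160824, ALP = 160824, DEP = 26853, DPW = 537349, SA = 74887)
  L <- matrix(c(0.93, 0.84, 0.65, 0.97, 0.27), 5, 1,
              dimnames = list(names(h2), "Cg"))
  truth_config(names(h2), h2, N, L, matrix(1, 1, 1),
               M = M, n_blocks = n_blocks, seed = seed)
}

# Wrap an (S, V) pair as a covstruct without running LDSC.
make_covstruct <- function(S, V, traits = rownames(S)) {
  if (is.null(traits)) traits <- paste0("T", seq_len(nrow(S)))
  dimnames(S) <- list(traits, traits)
  structure(list(S = S, V = V, intercepts = diag(nrow(S)),
                 trait_names = traits,
                 scale = stats::setNames(rep("observed", nrow(S)), traits),
                 vech_order = "lower-column-major",
                 M = NA, n_blocks = NA, n_variants = NA),
            class = "covstruct")
}

# In-memory sumstats table.
mk_ss <- function(snp, a1, a2, z, n = 10000, p = NULL, info = NULL,
                  frq = NULL, trait = "T") {
  df <- data.frame(SNP = snp, A1 = a1, A2 = a2, Z = z, N = n,
                   stringsAsFactors = FALSE)
  if (!is.null(p)) df$P <- p
  if (!is.null(info)) df$INFO <- info
  if (!is.null(frq)) df$FRQ <- frq
  as_sumstats(df, trait_name = trait)
}

# Minimal LD reference with constant-free fields.
mk_ref <- function(n, a1 = "A", a2 = "G", l2 = NULL, n_blocks = 4) {
  data.frame(SNP = sprintf("rs%05d", seq_len(n)),
             A1 = rep_len(a1, n), A2 = rep_len(a2, n),
             MAF = 0.3,
             L2 = l2 %||% stats::runif(n, 1, 80),
             BLOCK = as.integer(ceiling(seq_len(n) / (n / n_blocks))),
             stringsAsFactors = FALSE) |> as_ld_reference()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
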