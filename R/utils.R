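# Internal helpers shared across modules.

# 95% normal quantile used for all confidence intervals.
Z95 <- 1.959964

# Two-sided normal p-value from an estimate and its standard error.
z_pvalue <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[se <= 0 | !is.finite(beta / se)] <- NA_real_
  p
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(DNA_COMPLEMENT[toupper(x)])

# A/T and C/G pairs cannot be oriented from allele letters alone.
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
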