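# Independent oracles and fixture builders shared across tests.
# These deliberately reimplement the checked computations through a different
# route (explicit matrix algebra, plain loops) than the package code.

# Generic weighted least squares via explicit normal equations.
# Returns coefficients and both unscaled and residual-scaled SEs.
wls_oracle <- function(bx, by, sy, intercept = FALSE) {
  W <- diag(1 / sy^2, length(sy))
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  xtwx_inv <- solve(t(X) %*% W %*% X)
  coefs <- as.vector(xtwx_inv %*% t(X) %*% W %*% by)
  res <- by - as.vector(X %*% coefs)
  dfres <- length(by) - ncol(X)
  sigma <- sqrt(sum(res^2 / sy^2) / dfres)
  se_unscaled <- unname(sqrt(diag(xtwx_inv)))
  list(coef = coefs, se_unscaled = se_unscaled,
       se_scaled = se_unscaled * max(1, sigma), sigma = sigma)
}

# Brute-force greedy clumping: same rule as clump(), written as a plain
# while-loop over a candidate table with explicit LD lookups.
brute_clump <- function(cand, ld, r2_max, window_kb) {
  picked <- character(0)
  pool <- cand
  while (nrow(pool) > 0) {
    o <- order(pool$pvalue, pool$chrom, pool$pos, pool$variant_id)
    pool <- pool[o, , drop = FALSE]
    idx <- pool[1, ]
    picked <- c(picked, idx$variant_id)
    pool <- pool[-1, , drop = FALSE]
    if (nrow(pool) == 0) break
    drop <- rep(FALSE, nrow(pool))
    for (j in seq_len(nrow(pool))) {
      if (is.na(idx$chrom) || is.na(pool$chrom[j]) || idx$chrom != pool$chrom[j]) next
      if (is.na(idx$pos) || is.na(pool$pos[j])) next
      if (abs(idx$pos - pool$pos[j]) > window_kb * 1000) next
      i1 <- match(idx$variant_id, ld$variant_ids)
      i2 <- match(pool$variant_id[j], ld$variant_ids)
      r2 <- if (is.na(i1) || is.na(i2)) 0 else ld$r2[i1, i2]
      if (r2 >= r2_max) drop[j] <- TRUE
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  picked
}

# Harmonised pairs straight from paired effect vectors (bypasses allele
# bookkeeping when it is not under study).
make_pairs <- function(bx, by, sy, sx = rep(0.02, length(bx)),
                       ids = sprintf("rs%03d", seq_along(bx))) {
  data.frame(variant_id = ids, beta_exposure = bx, se_exposure = sx,
             beta_outcome = by, se_outcome = sy, stringsAsFactors = FALSE)
}

# Random, valid symmetric LD matrix with unit diagonal for small instances.
random_ld <- function(ids, pos, chrom) {
  k <- length(ids)
  r2 <- matrix(runif(k * k), k, k)
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  ld_matrix(r2, pos = pos, chrom = chrom, variant_ids = ids)
}

# One summary-stat record as a data.frame row.
record <- function(id, ea, oa, beta, se, eaf = NA_real_, chrom = "1",
                   pos = 1e6, pvalue = NA_real_, n = 10000) {
  data.frame(variant_id = id, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}
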