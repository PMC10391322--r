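# Causal-effect estimators and sensitivity statistics for two-sample MR.
#
# All estimators operate on harmonised exposure-outcome pairs: per-variant
# SNP-exposure effects beta_x (SD units) with se_x, and SNP-outcome effects
# beta_y (log odds for binary outcomes) with se_y. Weights are first-order
# inverse-variance weights 1/se_y^2 throughout; the uncertainty in beta_x is
# ignored in the weights (the usual approximation, accurate for strong
# instruments, F >> 10).

mr_estimate_row <- function(method, beta, se, n_snps,
                            q = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
                            egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_) {
  out <- data.frame(method = method, n_snps = as.integer(n_snps),
                    beta = beta, se = se,
                    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                    pvalue = z_pvalue(beta, se),
                    q = q, q_df = q_df, q_pvalue = q_pvalue,
                    egger_intercept = egger_intercept,
                    egger_intercept_se = egger_intercept_se,
                    egger_intercept_p = egger_intercept_p,
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

pairs_matrix <- function(pairs) {
  if (inherits(pairs, "harmonised_set")) pairs <- retained(pairs)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(setdiff(need, c("se_exposure")), names(pairs))
  if (length(miss)) stop("pairs lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(pairs$se_exposure)) pairs$se_exposure <- NA_real_
  if (is.null(pairs$variant_id)) pairs$variant_id <- paste0("v", seq_len(nrow(pairs)))
  pairs
}

#' Wald ratio estimate from a single variant
#'
#' The causal effect identified by one instrument:
#' \code{beta = beta_outcome / beta_exposure}, with the first-order delta-method
#' standard error \code{se = se_outcome / |beta_exposure|} (exposure-side
#' uncertainty neglected, appropriate for F >> 10) and a two-sided normal
#' p-value.
#'
#' @param pairs A harmonised set (or compatible data.frame) with exactly one
#'   retained pair.
#' @return An \code{mr_estimate} row (method \code{"wald_ratio"}).
#' @export
wald_ratio <- function(pairs) {
  p <- pairs_matrix(pairs)
  if (nrow(p) != 1) stop("wald_ratio expects exactly one pair", call. = FALSE)
  if (p$beta_exposure == 0) stop("undefined estimate: beta_exposure is zero", call. = FALSE)
  beta <- p$beta_outcome / p$beta_exposure
  se <- p$se_outcome / abs(p$beta_exposure)
  mr_estimate_row("wald_ratio", beta, se, 1L)
}

#' Cochran's Q heterogeneity statistic
#'
#' \code{Q = sum(w_j * (ratio_j - beta_ref)^2)} over per-variant ratio
#' estimates \code{ratio_j = beta_outcome/beta_exposure}, with first-order
#' weights \code{w_j = beta_exposure^2 / se_outcome^2}; \code{df = J - 1};
#' p-value from the upper tail of chi-square(df). Large Q signals that the
#' per-variant causal estimates disagree, i.e. that some instruments may be
#' invalid.
#'
#' @param pairs Harmonised pairs (J >= 2).
#' @param beta_ref Reference causal effect, usually the IVW estimate.
#' @return List with \code{q}, \code{df}, \code{pvalue}.
#' @export
cochran_q <- function(pairs, beta_ref) {
  p <- pairs_matrix(pairs)
  if (nrow(p) < 2) stop("cochran_q needs at least two pairs", call. = FALSE)
  w <- p$beta_exposure^2 / p$se_outcome^2
  ratio <- p$beta_outcome / p$beta_exposure
  q <- sum(w * (ratio - beta_ref)^2)
  df <- nrow(p) - 1L
  list(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted regression of SNP-outcome effects on SNP-exposure effects with the
#' intercept constrained to zero and weights \code{1/se_outcome^2}:
#' \code{beta = sum(bx*by/sy^2) / sum(bx^2/sy^2)}, fixed-effect
#' \code{se = 1/sqrt(sum(bx^2/sy^2))}. Under the multiplicative random-effects
#' model (the default) the variance is inflated by
#' \code{phi = max(1, Q/(J-1))}, which leaves the point estimate unchanged but
#' widens the interval under heterogeneity. Cochran's Q about the IVW estimate
#' is attached. With a single pair the call collapses to [wald_ratio()].
#'
#' @param pairs Harmonised pairs (J >= 1).
#' @param effects_model \code{"multiplicative_random"} (default) or
#'   \code{"fixed"}.
#' @return An \code{mr_estimate} row (method \code{"ivw_mre"} or
#'   \code{"ivw_fixed"}; \code{"wald_ratio"} when J = 1).
#' @export
ivw <- function(pairs, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  p <- pairs_matrix(pairs)
  if (nrow(p) == 0) stop("no pairs to estimate from", call. = FALSE)
  if (nrow(p) == 1) return(wald_ratio(p))
  if (all(p$beta_exposure == 0)) stop("undefined estimate: all beta_exposure zero", call. = FALSE)
  w <- 1 / p$se_outcome^2
  sxx <- sum(w * p$beta_exposure^2)
  beta <- sum(w * p$beta_exposure * p$beta_outcome) / sxx
  se_fixed <- 1 / sqrt(sxx)
  qq <- cochran_q(p, beta)
  phi <- max(1, qq$q / (nrow(p) - 1))
  se <- if (effects_model == "fixed") se_fixed else se_fixed * sqrt(phi)
  mr_estimate_row(if (effects_model == "fixed") "ivw_fixed" else "ivw_mre",
                  beta, se, nrow(p), q = qq$q, q_df = qq$df, q_pvalue = qq$pvalue)
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with a free
#' intercept (weights \code{1/se_outcome^2}). The slope is a causal estimate
#' robust to directional pleiotropy under the InSIDE assumption; the intercept
#' estimates the average direct (pleiotropic) effect, and its test is the
#' directional-pleiotropy test. Pairs are first oriented so every
#' \code{beta_exposure >= 0} (a joint sign flip of a pair, which leaves causal
#' quantities unchanged). Standard errors of slope and intercept are scaled by
#' \code{max(1, sqrt(RSS_w/(J-2)))} (multiplicative residual heterogeneity,
#' never deflating below the fixed-effect SE); p-values use the normal
#' reference.
#'
#' @param pairs Harmonised pairs; requires J >= 3 (with fewer the regression
#'   is saturated and the method is not estimable).
#' @return An \code{mr_estimate} row (method \code{"egger"}) with intercept
#'   fields, or \code{NULL} with a warning when J < 3.
#' @export
mr_egger <- function(pairs) {
  p <- pairs_matrix(pairs)
  if (nrow(p) < 3) {
    warning("MR-Egger not estimable with fewer than 3 variants", call. = FALSE)
    return(NULL)
  }
  flip <- sign(p$beta_exposure)
  flip[flip == 0] <- 1
  bx <- p$beta_exposure * flip
  by <- p$beta_outcome * flip
  w <- 1 / p$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  se_unscaled <- sqrt(diag(sm$cov.unscaled))
  scale <- max(1, sm$sigma)
  se <- se_unscaled * scale
  qq <- cochran_q(p, coefs[["bx"]])
  mr_estimate_row("egger", beta = coefs[["bx"]], se = se[["bx"]], n_snps = nrow(p),
                  q = qq$q, q_df = qq$df, q_pvalue = qq$pvalue,
                  egger_intercept = coefs[["(Intercept)"]],
                  egger_intercept_se = se[["(Intercept)"]],
                  egger_intercept_p = z_pvalue(coefs[["(Intercept)"]], se[["(Intercept)"]]))
}

# Weighted-median point estimate of ratio estimates with weights w
# (normalised internally): linear interpolation of the ordered ratios at
# cumulative weight midpoint 0.5.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- w[ord] / sum(w)
  pj <- cumsum(wn) - wn / 2
  if (0.5 <= pj[1]) return(r[1])
  if (0.5 >= pj[length(pj)]) return(r[length(r)])
  stats::approx(pj, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median of the per-variant ratio estimates, with weights
#' \code{w_j = beta_exposure^2/se_outcome^2} normalised to sum to one: the
#' ordered ratios are interpolated at cumulative-weight midpoint 0.5. The
#' estimate is consistent when instruments carrying less than half the total
#' weight are invalid. Its standard error has no closed form and is obtained
#' by a seeded parametric bootstrap: \code{beta_exposure} and
#' \code{beta_outcome} are resampled from their normal sampling distributions
#' and the point estimate recomputed \code{n_boot} times.
#'
#' @param pairs Harmonised pairs; requires J >= 3.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @return An \code{mr_estimate} row (method \code{"weighted_median"}), or
#'   \code{NULL} with a warning when J < 3.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed) {
  p <- pairs_matrix(pairs)
  if (nrow(p) < 3) {
    warning("weighted median not estimable with fewer than 3 variants", call. = FALSE)
    return(NULL)
  }
  if (missing(seed)) stop("weighted_median requires an explicit `seed`", call. = FALSE)
  ratio <- p$beta_outcome / p$beta_exposure
  w <- p$beta_exposure^2 / p$se_outcome^2
  est <- weighted_median_point(ratio, w)
  se <- with_seed(seed, {
    boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bx <- stats::rnorm(nrow(p), p$beta_exposure, p$se_exposure)
      by <- stats::rnorm(nrow(p), p$beta_outcome, p$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      boot[b] <- weighted_median_point(by / bx, bx^2 / p$se_outcome^2)
    }
    stats::sd(boot)
  })
  mr_estimate_row("weighted_median", est, se, nrow(p))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect with each variant removed in turn; a single
#' influential (possibly pleiotropic) variant shows up as a large deviation of
#' one leave-one-out estimate from the full-set estimate.
#'
#' @param pairs Harmonised pairs; requires J >= 3 (so every reduced set keeps
#'   at least two variants).
#' @param effects_model Passed to [ivw()].
#' @return A data.frame of class \code{mr_loo} with one row per excluded
#'   variant (\code{excluded_variant, beta, se, ci_low, ci_high, pvalue,
#'   n_snps}) and attributes \code{full_beta} and \code{max_abs_deviation};
#'   \code{NULL} with a warning when J < 3.
#' @export
leave_one_out <- function(pairs, effects_model = "multiplicative_random") {
  p <- pairs_matrix(pairs)
  if (nrow(p) < 3) {
    warning("leave-one-out not estimable with fewer than 3 variants", call. = FALSE)
    return(NULL)
  }
  full <- ivw(p, effects_model)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    est <- ivw(p[-i, , drop = FALSE], effects_model)
    data.frame(excluded_variant = p$variant_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
               n_snps = est$n_snps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_beta") <- full$beta
  attr(out, "max_abs_deviation") <- max(abs(out$beta - full$beta))
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(x$method, ": beta = ", formatC(x$beta, digits = digits, format = "g"),
      " (se ", formatC(x$se, digits = digits, format = "g"),
      "), 95% CI [", formatC(x$ci_low, digits = digits, format = "g"), ", ",
      formatC(x$ci_high, digits = digits, format = "g"),
      "], p = ", formatC(x$pvalue, digits = digits, format = "g"),
      ", J = ", x$n_snps, "\n", sep = "")
  invisible(x)
}
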