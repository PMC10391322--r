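# The central model-fitting interface: one call running the full estimator
# battery on a harmonised set, returning a classed fit with the usual methods.

#' Fit two-sample Mendelian randomization estimators to harmonised pairs
#'
#' Runs the estimator battery on a harmonised exposure-outcome set: Wald ratio
#' (single variant) or IVW (several variants) always; MR-Egger, weighted
#' median and leave-one-out when at least three variants are available (with
#' fewer the extra methods are not estimable and are flagged, not errors).
#' Cochran's Q accompanies the IVW fit.
#'
#' @param pairs A \code{harmonised_set} from [harmonise()], or a data.frame
#'   with columns \code{beta_exposure, se_exposure, beta_outcome, se_outcome}
#'   (and optionally \code{variant_id}).
#' @param methods Which estimators to run; default all feasible.
#' @param effects_model IVW variance model, see [ivw()].
#' @param outcome_type \code{"binary"} (effects are log odds ratios; summaries
#'   report OR = exp(beta)) or \code{"continuous"} (SD units).
#' @param n_boot,seed Bootstrap control for [weighted_median()]. \code{seed}
#'   is required if the weighted median is requested with J >= 3.
#' @param exposure,outcome Labels carried into reports.
#' @return An object of class \code{mr_fit}: list with \code{estimates} (one
#'   \code{mr_estimate} row per method), \code{data} (the retained pairs),
#'   \code{loo} (leave-one-out table or NULL), \code{infeasible} (character
#'   vector of methods skipped for J < 3) and the labels. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{confint}, \code{plot},
#'   \code{residuals}.
#' @examples
#' h <- data.frame(beta_exposure = c(0.2, 0.3, 0.5, 0.4),
#'                 se_exposure = rep(0.02, 4),
#'                 beta_outcome = c(0.021, 0.031, 0.049, 0.042),
#'                 se_outcome = rep(0.01, 4))
#' fit <- mr_fit(h, seed = 1)
#' coef(fit)
#' @export
mr_fit <- function(pairs,
                   methods = c("ivw", "egger", "weighted_median", "wald_ratio"),
                   effects_model = c("multiplicative_random", "fixed"),
                   outcome_type = c("binary", "continuous"),
                   n_boot = 1000, seed = NULL,
                   exposure = "exposure", outcome = "outcome") {
  effects_model <- match.arg(effects_model)
  outcome_type <- match.arg(outcome_type)
  p <- pairs_matrix(pairs)
  if (nrow(p) == 0) stop("no retained pairs to fit", call. = FALSE)

  est <- list()
  infeasible <- character(0)
  if (nrow(p) == 1) {
    est$wald <- wald_ratio(p)
    infeasible <- c("egger", "weighted_median", "leave_one_out")
    loo <- NULL
  } else {
    if ("ivw" %in% methods) est$ivw <- ivw(p, effects_model)
    if (nrow(p) >= 3) {
      if ("egger" %in% methods) est$egger <- mr_egger(p)
      if ("weighted_median" %in% methods) {
        if (is.null(seed)) stop("`seed` required for the weighted-median bootstrap", call. = FALSE)
        est$wm <- weighted_median(p, n_boot = n_boot, seed = seed)
      }
      loo <- leave_one_out(p, effects_model)
    } else {
      infeasible <- intersect(c("egger", "weighted_median"), methods)
      infeasible <- c(infeasible, "leave_one_out")
      loo <- NULL
    }
  }
  estimates <- do.call(rbind, unname(est))
  structure(list(estimates = estimates, data = p, loo = loo,
                 infeasible = infeasible, effects_model = effects_model,
                 outcome_type = outcome_type,
                 exposure = exposure, outcome = outcome),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit: ", x$exposure, " -> ", x$outcome,
      " (", nrow(x$data), " variants)\n", sep = "")
  e <- x$estimates
  for (i in seq_len(nrow(e))) print(e[i, ], digits = digits)
  if (length(x$infeasible))
    cat("not estimable with", nrow(x$data), "variant(s):",
        paste(x$infeasible, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  e <- object$estimates
  e$or <- exp(e$beta)
  e$or_ci_low <- exp(e$ci_low)
  e$or_ci_high <- exp(e$ci_high)
  out <- list(estimates = e, outcome_type = object$outcome_type,
              exposure = object$exposure, outcome = object$outcome,
              n_snps = nrow(object$data),
              max_loo_deviation = if (!is.null(object$loo)) attr(object$loo, "max_abs_deviation") else NA_real_,
              infeasible = object$infeasible)
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR: ", x$exposure, " -> ", x$outcome,
      " (", x$n_snps, " variants, ", x$outcome_type, " outcome)\n\n", sep = "")
  e <- x$estimates
  cols <- c("method", "n_snps", "beta", "se", "pvalue",
            if (x$outcome_type == "binary") c("or", "or_ci_low", "or_ci_high"),
            "q", "q_pvalue", "egger_intercept", "egger_intercept_p")
  print(format(e[, cols], digits = digits), row.names = FALSE)
  if (!is.na(x$max_loo_deviation))
    cat("\nmax |leave-one-out deviation| from full IVW:",
        formatC(x$max_loo_deviation, digits = 3, format = "g"), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  e <- object$estimates
  out <- cbind(e$beta - z * e$se, e$beta + z * e$se)
  dimnames(out) <- list(e$method,
                        paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Residuals of an MR fit
#'
#' Weighted residuals of the SNP-outcome effects about the chosen method's
#' fitted line: \code{(beta_outcome - fitted) / se_outcome}, where fitted is
#' \code{beta * beta_exposure} (plus the intercept for MR-Egger, on
#' exposure-oriented pairs). Under valid instruments these are approximately
#' standard normal; their squared sum about the IVW line is Cochran's Q.
#'
#' @param object An \code{mr_fit}.
#' @param method Which fitted line to residualise about.
#' @param ... Unused.
#' @export
residuals.mr_fit <- function(object, method = c("ivw", "egger"), ...) {
  method <- match.arg(method)
  p <- object$data
  e <- object$estimates
  if (method == "ivw") {
    row <- e[e$method %in% c("ivw_mre", "ivw_fixed", "wald_ratio"), ][1, ]
    fitted <- row$beta * p$beta_exposure
  } else {
    row <- e[e$method == "egger", ]
    if (!nrow(row)) stop("no Egger fit in this object", call. = FALSE)
    flip <- ifelse(p$beta_exposure < 0, -1, 1)
    fitted <- flip * (row$egger_intercept + row$beta * (flip * p$beta_exposure))
  }
  stats::setNames((p$beta_outcome - fitted) / p$se_outcome, p$variant_id)
}

#' Scatter plot of an MR fit
#'
#' SNP-outcome against SNP-exposure effects with +/- 1 SE error bars and the
#' fitted lines of each estimator (IVW through the origin, Egger with its
#' intercept, weighted median through the origin).
#'
#' @param x An \code{mr_fit}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$data
  flip <- ifelse(p$beta_exposure < 0, -1, 1)
  bx <- p$beta_exposure * flip
  by <- p$beta_outcome * flip
  graphics::plot(bx, by,
                 xlim = range(0, bx + p$se_exposure, bx - p$se_exposure),
                 ylim = range(0, by + p$se_outcome, by - p$se_outcome),
                 xlab = "SNP effect on exposure (SD)",
                 ylab = "SNP effect on outcome",
                 main = paste(x$exposure, "->", x$outcome), pch = 19, ...)
  # error bars; arrows() warns on segments shorter than device resolution
  suppressWarnings({
    graphics::arrows(bx, by - p$se_outcome, bx, by + p$se_outcome,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
    graphics::arrows(bx - p$se_exposure, by, bx + p$se_exposure, by,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  })
  e <- x$estimates
  lty <- 1
  for (i in seq_len(nrow(e))) {
    icpt <- if (e$method[i] == "egger") e$egger_intercept[i] else 0
    graphics::abline(icpt, e$beta[i], lty = lty, col = i + 1)
    lty <- lty + 1
  }
  graphics::legend("topleft", legend = e$method, lty = seq_len(nrow(e)),
                   col = seq_len(nrow(e)) + 1, bty = "n", cex = 0.8)
  invisible(x)
}
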