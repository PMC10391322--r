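# Grid orchestration: many exposures x many outcomes, with logging.

#' Define an exposure-by-outcome analysis grid
#'
#' Collects the inputs of a full analysis: named exposure and outcome
#' summary-statistic sources (file paths or in-memory data.frames), an LD
#' matrix, analysis options, and optional gene annotations for cis-MR.
#'
#' @param exposures Named list of summary-stat sources (paths or data.frames).
#' @param outcomes Named list of summary-stat sources.
#' @param outcome_types Character vector (recycled) of \code{"binary"} /
#'   \code{"continuous"}, one per outcome; ORs are reported for binary and
#'   score outcomes alike, with the scale labelled.
#' @param ld An [ld_matrix()] (or path readable by [read_ld_matrix()]).
#' @param cis_annotations Optional data.frame from [read_gene_annotations()];
#'   \code{gene_symbol} must match exposure names for cis-MR.
#' @param options Named list overriding analysis defaults: \code{primary_p}
#'   (5e-8), \code{fallback_p} (5e-7), \code{clump_r2} (0.01), \code{clump_kb}
#'   (10000), \code{proxy_r2} (0.8), \code{cis_flank_kb} (100),
#'   \code{palindromic_eaf_window} (c(0.42, 0.58)), \code{effects_model},
#'   \code{n_boot} (1000).
#' @param seed Integer seed for the weighted-median bootstrap.
#' @return An object of class \code{analysis_grid}.
#' @export
analysis_grid <- function(exposures, outcomes, outcome_types = "binary",
                          ld, cis_annotations = NULL, options = list(), seed = 1L) {
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(outcomes)) == length(outcomes))
  if (anyDuplicated(names(exposures)) || anyDuplicated(names(outcomes)))
    stop("exposure and outcome names must be unique", call. = FALSE)
  for (src in c(exposures, outcomes))
    if (is.character(src) && !file.exists(src))
      stop("source file does not exist: ", src, call. = FALSE)
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  defaults <- list(primary_p = 5e-8, fallback_p = 5e-7, clump_r2 = 0.01,
                   clump_kb = 10000, proxy_r2 = 0.8, cis_flank_kb = 100,
                   palindromic_eaf_window = c(0.42, 0.58),
                   effects_model = "multiplicative_random", n_boot = 1000)
  defaults[names(options)] <- options
  structure(list(exposures = exposures, outcomes = outcomes,
                 outcome_types = rep_len(outcome_types, length(outcomes)),
                 ld = ld, cis_annotations = cis_annotations,
                 options = defaults, seed = as.integer(seed)),
            class = "analysis_grid")
}

load_source <- function(src) if (is.character(src)) read_summary_stats(src) else src

grid_log_entry <- function(exposure, outcome, event, detail) {
  data.frame(exposure = exposure, outcome = outcome, event = event,
             detail = detail, stringsAsFactors = FALSE)
}

#' Run the full exposure-by-outcome MR grid
#'
#' For every exposure: select instruments ([select_instruments()], with the
#' relaxed fallback threshold). For every exposure-outcome pair: substitute
#' proxies for instruments missing from the outcome ([find_proxy()]),
#' harmonise alleles ([harmonise()]), and fit the estimator battery
#' ([mr_fit()]): Wald ratio or IVW always, MR-Egger / weighted median /
#' leave-one-out / Cochran's Q when at least three variants survive. Every
#' decision (relaxed threshold, proxy substitution, dropped variant,
#' infeasible method, uninstrumentable exposure) is appended to a
#' machine-readable log. A failing source fails only its own rows.
#'
#' @param grid An [analysis_grid()].
#' @param cis Run in cis-restricted mode (used by [run_cis_grid()]).
#' @return A \code{grid_result}: list with \code{estimates} (one row per
#'   exposure x outcome x method, schema of [write_results_table()] plus
#'   \code{q_df} and intercept SE), \code{flags}, \code{log},
#'   \code{leave_one_out} (named list), \code{instruments} (named list of
#'   instrument sets) and \code{forest} (plot-ready OR table).
#' @export
run_grid <- function(grid, cis = FALSE) {
  stopifnot(inherits(grid, "analysis_grid"))
  opt <- grid$options
  logs <- list(); flags <- list(); est_rows <- list(); loo_list <- list()
  instr_list <- list()

  for (ex_name in names(grid$exposures)) {
    ex <- tryCatch(load_source(grid$exposures[[ex_name]]), error = function(e) e)
    if (inherits(ex, "error")) {
      flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, NA, "source_error", conditionMessage(ex))
      next
    }
    instr <- select_instruments(ex, grid$ld, primary_p = opt$primary_p,
                                fallback_p = opt$fallback_p, r2_max = opt$clump_r2,
                                window_kb = opt$clump_kb, exposure_name = ex_name)
    if (!instr$uninstrumentable && instr$threshold_used == opt$fallback_p)
      logs[[length(logs) + 1L]] <- grid_log_entry(ex_name, NA, "threshold_relaxed",
                                                  format(opt$fallback_p))
    if (cis) {
      gene <- grid$cis_annotations[grid$cis_annotations$gene_symbol == ex_name, , drop = FALSE]
      if (nrow(gene) == 0) {
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, NA, "no_cis_annotation", "")
        next
      }
      instr <- cis_filter(instr, gene[1, ], flank_kb = opt$cis_flank_kb)
      if (instr$uninstrumentable) {
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, NA, "uninstrumentable_cis", "")
        instr_list[[ex_name]] <- instr
        next
      }
    }
    instr_list[[ex_name]] <- instr
    if (instr$uninstrumentable) {
      flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, NA, "uninstrumentable", "")
      next
    }

    for (ou_i in seq_along(grid$outcomes)) {
      ou_name <- names(grid$outcomes)[ou_i]
      ou_type <- grid$outcome_types[ou_i]
      ou <- tryCatch(load_source(grid$outcomes[[ou_i]]), error = function(e) e)
      if (inherits(ou, "error")) {
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, ou_name, "source_error",
                                                      conditionMessage(ou))
        next
      }
      # proxy substitution, per outcome
      rec <- instr$records
      missing_ids <- setdiff(rec$variant_id, ou$variant_id)
      for (mid in missing_ids) {
        proxy <- suppressWarnings(
          find_proxy(mid, intersect(ou$variant_id, ex$variant_id), grid$ld,
                     r2_min = opt$proxy_r2))
        rec <- rec[rec$variant_id != mid, , drop = FALSE]
        if (!is.null(proxy) && !(proxy %in% rec$variant_id)) {
          rec <- rbind(rec, ex[ex$variant_id == proxy, names(rec), drop = FALSE])
          logs[[length(logs) + 1L]] <- grid_log_entry(ex_name, ou_name, "proxy_substituted",
                                                      paste(mid, "->", proxy))
        } else {
          logs[[length(logs) + 1L]] <- grid_log_entry(ex_name, ou_name, "variant_unavailable", mid)
        }
      }
      if (nrow(rec) == 0) {
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, ou_name, "no_variants_in_outcome", "")
        next
      }
      h <- harmonise(rec, ou, palindromic_eaf_window = opt$palindromic_eaf_window)
      dropped <- attr(h, "dropped")
      for (k in seq_len(nrow(dropped)))
        logs[[length(logs) + 1L]] <- grid_log_entry(ex_name, ou_name,
                                                    dropped$action[k], dropped$variant_id[k])
      hk <- retained(h)
      if (nrow(hk) == 0) {
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, ou_name, "no_harmonised_variants", "")
        next
      }
      fit <- suppressWarnings(
        mr_fit(hk, effects_model = opt$effects_model, outcome_type = ou_type,
               n_boot = opt$n_boot, seed = grid$seed,
               exposure = ex_name, outcome = ou_name))
      if (length(fit$infeasible))
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, ou_name, "methods_infeasible",
                                                      paste(fit$infeasible, collapse = ","))
      if (instr$threshold_used == opt$fallback_p)
        flags[[length(flags) + 1L]] <- grid_log_entry(ex_name, ou_name, "threshold_relaxed", "")
      rows <- fit$estimates
      rows$exposure <- ex_name; rows$outcome <- ou_name
      rows$outcome_scale <- if (ou_type == "binary") "log_odds" else "sd_score"
      rows$or <- exp(rows$beta)
      est_rows[[length(est_rows) + 1L]] <- rows
      if (!is.null(fit$loo)) loo_list[[paste(ex_name, ou_name, sep = ".")]] <- fit$loo
    }
  }

  estimates <- if (length(est_rows)) do.call(rbind, est_rows) else NULL
  forest <- NULL
  if (!is.null(estimates)) {
    forest <- data.frame(exposure = estimates$exposure, outcome = estimates$outcome,
                         method = estimates$method, or = exp(estimates$beta),
                         ci_low = exp(estimates$ci_low), ci_high = exp(estimates$ci_high),
                         outcome_scale = estimates$outcome_scale, stringsAsFactors = FALSE)
  }
  structure(list(estimates = estimates,
                 flags = if (length(flags)) do.call(rbind, flags) else
                   grid_log_entry(character(0), character(0), character(0), character(0))[0, ],
                 log = if (length(logs)) do.call(rbind, logs) else
                   grid_log_entry(character(0), character(0), character(0), character(0))[0, ],
                 leave_one_out = loo_list, instruments = instr_list,
                 forest = forest),
            class = "grid_result")
}

#' Run the grid restricted to cis instruments
#'
#' As [run_grid()], but instruments are first passed through [cis_filter()]
#' using the grid's gene annotations (matched to exposures by
#' \code{gene_symbol}); exposures losing all instruments are flagged
#' \code{uninstrumentable_cis}.
#'
#' @param grid An [analysis_grid()] with \code{cis_annotations}.
#' @return A \code{grid_result}.
#' @export
run_cis_grid <- function(grid) {
  if (is.null(grid$cis_annotations))
    stop("cis analysis requires gene annotations", call. = FALSE)
  run_grid(grid, cis = TRUE)
}

#' @export
print.grid_result <- function(x, ...) {
  n_pairs <- if (is.null(x$estimates)) 0 else
    nrow(unique(x$estimates[, c("exposure", "outcome")]))
  cat("Grid result:", n_pairs, "exposure-outcome pairs,",
      NROW(x$estimates), "estimate rows,", nrow(x$flags), "flags\n")
  invisible(x)
}

#' Side-by-side sensitivity report
#'
#' One row per exposure-outcome pair comparing the IVW, MR-Egger and
#' weighted-median estimates: their betas, whether all available methods agree
#' in sign (the concordance reading applied to multi-method MR), the
#' heterogeneity Q p-value, the Egger intercept p (directional pleiotropy
#' test), and the largest leave-one-out deviation. A Bonferroni significance
#' threshold across the grid's pairs is included as a reader aid (no
#' correction is applied to the p-values themselves).
#'
#' @param result A \code{grid_result} from [run_grid()].
#' @return data.frame, empty when the grid produced no estimates.
#' @export
sensitivity_report <- function(result) {
  empty <- data.frame(exposure = character(0), outcome = character(0),
                      beta_ivw = numeric(0), beta_egger = numeric(0),
                      beta_weighted_median = numeric(0), sign_agreement = logical(0),
                      q_pvalue = numeric(0), egger_intercept_p = numeric(0),
                      max_loo_deviation = numeric(0), bonferroni_p = numeric(0))
  if (is.null(result$estimates) || !nrow(result$estimates)) return(empty)
  e <- result$estimates
  pairs <- unique(e[, c("exposure", "outcome")])
  bonf <- 0.05 / nrow(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- e[e$exposure == pairs$exposure[i] & e$outcome == pairs$outcome[i], ]
    get <- function(m) if (any(sub$method %in% m)) sub$beta[sub$method %in% m][1] else NA_real_
    b_ivw <- get(c("ivw_mre", "ivw_fixed", "wald_ratio"))
    b_egg <- get("egger")
    b_wm <- get("weighted_median")
    betas <- c(b_ivw, b_egg, b_wm)
    betas <- betas[!is.na(betas)]
    loo <- result$leave_one_out[[paste(pairs$exposure[i], pairs$outcome[i], sep = ".")]]
    data.frame(exposure = pairs$exposure[i], outcome = pairs$outcome[i],
               beta_ivw = b_ivw, beta_egger = b_egg, beta_weighted_median = b_wm,
               sign_agreement = length(unique(sign(betas))) == 1,
               q_pvalue = sub$q_pvalue[!is.na(sub$q_pvalue)][1] %||% NA_real_,
               egger_intercept_p = if (any(sub$method == "egger"))
                 sub$egger_intercept_p[sub$method == "egger"] else NA_real_,
               max_loo_deviation = if (!is.null(loo)) attr(loo, "max_abs_deviation") else NA_real_,
               bonferroni_p = bonf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
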