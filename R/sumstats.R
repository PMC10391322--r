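# Reading, validating and writing GWAS summary statistics.

SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pvalue", "n")

# Column-name synonyms accepted without an explicit column_map
# (GWAS-SSF-like conventions; matching is case-insensitive).
COLUMN_SYNONYMS <- list(
  variant_id    = c("variant_id", "snp", "rsid", "rs_id", "markername", "id"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele  = c("other_allele", "oa", "a2", "allele2", "non_effect_allele"),
  eaf           = c("eaf", "freq", "af", "effect_allele_frequency", "maf"),
  beta          = c("beta", "b", "effect"),
  se            = c("se", "standard_error", "stderr"),
  pvalue        = c("pvalue", "p", "pval", "p_value"),
  n             = c("n", "samplesize", "n_total", "sample_size")
)

resolve_columns <- function(header, column_map = NULL) {
  out <- stats::setNames(rep(NA_character_, length(SUMSTAT_COLS)), SUMSTAT_COLS)
  lower <- tolower(header)
  for (canon in SUMSTAT_COLS) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      hit <- match(tolower(column_map[[canon]]), lower)
    } else {
      hit <- match(COLUMN_SYNONYMS[[canon]], lower)
      hit <- hit[!is.na(hit)][1]
    }
    if (length(hit) == 1 && !is.na(hit)) out[canon] <- header[hit]
  }
  out
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited summary-statistic file with a header row,
#' maps its columns onto the canonical schema (\code{variant_id}, \code{chrom},
#' \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#' \code{beta}, \code{se}, \code{pvalue}, \code{n}), and validates every row.
#' Rows violating basic invariants (non-positive standard error, identical or
#' non-ACGT alleles, allele frequency outside (0,1)) are dropped with a
#' recorded reason; missing p-values are recomputed as two-sided normal
#' p-values from \code{beta}/\code{se}; duplicated variant IDs keep the row
#' with the smallest p-value. A p-value inconsistent with \code{beta}/\code{se}
#' by more than a factor of two triggers a warning, not a drop.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. \code{c(variant_id = "SNP")}.
#'   Columns not named are matched against common synonyms.
#' @return A \code{data.frame} of validated records with the canonical columns,
#'   with attributes \code{drops} (a data.frame of dropped variant IDs and
#'   reasons) and \code{source} (the file path).
#' @seealso [validate_summary_stats()], [write_results_table()]
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cannot read summary statistics: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  cols <- resolve_columns(names(raw), column_map)
  if (all(is.na(cols))) stop("no recognisable summary-statistic columns in ", path, call. = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_req <- required[is.na(cols[required])]
  if (length(missing_req))
    stop("required column(s) not resolvable: ", paste(missing_req, collapse = ", "), call. = FALSE)

  df <- data.frame(variant_id = as.character(raw[[cols["variant_id"]]]),
                   stringsAsFactors = FALSE)
  df$chrom <- if (!is.na(cols["chrom"])) as.character(raw[[cols["chrom"]]]) else NA_character_
  df$pos <- if (!is.na(cols["pos"])) as.integer(raw[[cols["pos"]]]) else NA_integer_
  df$effect_allele <- toupper(as.character(raw[[cols["effect_allele"]]]))
  df$other_allele <- toupper(as.character(raw[[cols["other_allele"]]]))
  df$eaf <- if (!is.na(cols["eaf"])) as.numeric(raw[[cols["eaf"]]]) else NA_real_
  df$beta <- as.numeric(raw[[cols["beta"]]])
  df$se <- as.numeric(raw[[cols["se"]]])
  df$pvalue <- if (!is.na(cols["pvalue"])) as.numeric(raw[[cols["pvalue"]]]) else NA_real_
  df$n <- if (!is.na(cols["n"])) as.numeric(raw[[cols["n"]]]) else NA_real_

  validate_summary_stats(df, source = path)
}

#' Validate summary-statistic records
#'
#' Applies the record invariants to an in-memory table: alleles must be single
#' distinct A/C/G/T codes, \code{se > 0}, \code{eaf} (when present) in (0,1),
#' finite \code{beta}. Missing p-values are recomputed from \code{beta/se}
#' under a two-sided normal test; grossly inconsistent p-values (off by more
#' than a factor of 2) produce a warning. Duplicate \code{variant_id}s keep
#' the smallest-p row.
#'
#' @param df A data.frame carrying the canonical summary-statistic columns.
#' @param source Label used in messages.
#' @return The validated data.frame with a \code{drops} attribute.
#' @export
validate_summary_stats <- function(df, source = "summary stats") {
  for (col in SUMSTAT_COLS) if (is.null(df[[col]])) df[[col]] <- NA
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  reason <- rep(NA_character_, nrow(df))
  bad_allele <- !(df$effect_allele %in% names(DNA_COMPLEMENT)) |
    !(df$other_allele %in% names(DNA_COMPLEMENT)) |
    df$effect_allele == df$other_allele
  reason[bad_allele] <- "invalid_alleles"
  bad_se <- is.na(df$se) | df$se <= 0
  reason[is.na(reason) & bad_se] <- "nonpositive_se"
  bad_beta <- is.na(df$beta) | !is.finite(df$beta)
  reason[is.na(reason) & bad_beta] <- "missing_beta"
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  reason[is.na(reason) & bad_eaf] <- "eaf_out_of_range"

  drops <- data.frame(variant_id = df$variant_id[!is.na(reason)],
                      reason = reason[!is.na(reason)],
                      stringsAsFactors = FALSE)
  df <- df[is.na(reason), , drop = FALSE]

  if (nrow(df)) {
    recompute <- is.na(df$pvalue)
    df$pvalue[recompute] <- z_pvalue(df$beta[recompute], df$se[recompute])
    # consistency check: stated p within a factor of 2 of the normal p
    pz <- z_pvalue(df$beta, df$se)
    ok <- is.na(pz) | recompute | (df$pvalue > pz / 2 & df$pvalue < pmin(1, pz * 2)) |
      (pz < 1e-300)  # underflow regime: ratios meaningless
    if (any(!ok))
      warning(sum(!ok), " record(s) in ", source,
              " have p-values inconsistent with beta/se (factor > 2)", call. = FALSE)
    # duplicates: keep the strongest (smallest p), deterministic order
    if (anyDuplicated(df$variant_id)) {
      ord <- order(df$variant_id, df$pvalue)
      df <- df[ord, , drop = FALSE]
      dup <- duplicated(df$variant_id)
      drops <- rbind(drops, data.frame(variant_id = df$variant_id[dup],
                                       reason = "duplicate_id",
                                       stringsAsFactors = FALSE))
      df <- df[!dup, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  attr(df, "drops") <- drops
  attr(df, "source") <- source
  df
}

RESULT_COLS <- c("exposure", "outcome", "method", "n_snps", "beta", "se", "or",
                 "ci_low", "ci_high", "pvalue", "q", "q_pvalue",
                 "egger_intercept", "egger_intercept_p")

#' Write MR estimates to a tab-delimited results table
#'
#' Serialises a set of MR estimates with the fixed column schema
#' \code{exposure, outcome, method, n_snps, beta, se, or, ci_low, ci_high,
#' pvalue, q, q_pvalue, egger_intercept, egger_intercept_p}. The \code{or}
#' column is \code{exp(beta)}, the odds ratio per SD of exposure for binary
#' outcomes. Numeric fields are written with 15 significant digits so a
#' read-back reproduces the values to full double precision.
#'
#' @param rows A data.frame of estimates (e.g. rbound [mr_estimate] rows or the
#'   \code{estimates} element of a [run_grid()] result). Missing schema columns
#'   are filled with \code{NA}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(rows, path) {
  out <- data.frame(matrix(nrow = NROW(rows), ncol = 0))
  if (NROW(rows) > 0 && is.null(rows$or) && !is.null(rows$beta)) rows$or <- exp(rows$beta)
  for (col in RESULT_COLS)
    out[[col]] <- if (!is.null(rows[[col]])) rows[[col]] else rep(NA, NROW(rows))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  out[num] <- lapply(out[num], function(x) ifelse(x %in% c("NA", " NA"), NA, x))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results table to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to a tab-delimited results table.
#' @return A data.frame with the schema of [write_results_table()].
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("cannot read results table: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", colClasses = NA)
}
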