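# Instrument selection: thresholds, clumping, proxies, strength, cis filter.

#' Greedy LD clumping
#'
#' Prunes correlated variants by p-value: repeatedly takes the remaining
#' variant with the smallest p-value as an index variant and removes all
#' remaining variants on the same chromosome within \code{window_kb} of it
#' whose r2 with it is at least \code{r2_max}. Variants absent from the LD
#' matrix are treated as unlinked (r2 = 0). Ties in p-value are broken by
#' chromosome, position, then variant ID, so the result is invariant to the
#' input row order.
#'
#' @param candidates Summary-statistic data.frame (needs \code{variant_id},
#'   \code{pvalue}; \code{chrom}/\code{pos} used for the distance window).
#' @param ld An [ld_matrix()].
#' @param r2_max LD threshold; default 0.01.
#' @param window_kb Distance window in kilobases; default 10000 (10 Mb).
#' @return The index variants, a subset of \code{candidates} in selection order.
#' @export
clump <- function(candidates, ld, r2_max = 0.01, window_kb = 10000) {
  if (NROW(candidates) == 0) return(candidates)
  cand <- candidates
  # coordinates may live on the records or on the LD matrix
  m <- match(cand$variant_id, ld$variant_ids)
  if (is.null(cand$chrom)) cand$chrom <- NA_character_
  if (is.null(cand$pos)) cand$pos <- NA_real_
  fill <- is.na(cand$chrom) & !is.na(m)
  cand$chrom[fill] <- ld$chrom[m[fill]]
  fill <- is.na(cand$pos) & !is.na(m)
  cand$pos[fill] <- ld$pos[m[fill]]
  ord <- order(cand$pvalue, cand$chrom, cand$pos, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  orig <- candidates[ord, , drop = FALSE]
  keep <- integer(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (i == nrow(cand)) break
    for (j in seq(i + 1L, nrow(cand))) {
      if (!alive[j]) next
      same_chr <- !is.na(cand$chrom[i]) && !is.na(cand$chrom[j]) &&
        cand$chrom[i] == cand$chrom[j]
      if (!same_chr) next
      within <- !is.na(cand$pos[i]) && !is.na(cand$pos[j]) &&
        abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      if (!within) next
      if (ld_r2(ld, cand$variant_id[i], cand$variant_id[j]) >= r2_max)
        alive[j] <- FALSE
    }
  }
  out <- orig[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find a proxy variant in high LD with a missing target
#'
#' Used when an instrument is absent from an outcome dataset: returns the
#' available variant with the highest r2 to the target, provided that r2
#' reaches \code{r2_min}. Ties are broken by smaller base-pair distance to the
#' target, then lexicographic ID.
#'
#' @param target Variant ID missing from \code{available}.
#' @param available Character vector of variant IDs present in the outcome.
#' @param ld An [ld_matrix()] covering target and candidates.
#' @param r2_min Minimum acceptable r2 (default 0.8, the community standard
#'   for proxy instruments).
#' @return The proxy variant ID, or \code{NULL} if none qualifies.
#' @export
find_proxy <- function(target, available, ld, r2_min = 0.8) {
  ti <- match(target, ld$variant_ids)
  if (is.na(ti)) {
    warning("proxy target ", target, " not present in LD matrix", call. = FALSE)
    return(NULL)
  }
  cand <- setdiff(intersect(available, ld$variant_ids), target)
  if (!length(cand)) return(NULL)
  ci <- match(cand, ld$variant_ids)
  r2 <- ld$r2[ti, ci]
  dist <- abs(ld$pos[ci] - ld$pos[ti])
  dist[is.na(dist)] <- Inf
  ord <- order(-r2, dist, cand)
  best <- ord[1]
  if (r2[best] >= r2_min) cand[best] else NULL
}

#' Per-variant instrument strength
#'
#' The F-statistic of a single instrument is \code{(beta/se)^2}. The variance
#' in the (SD-scaled) exposure explained by the variant is
#' \code{2 * beta^2 * eaf * (1 - eaf)}; when the allele frequency is missing it
#' falls back to \code{f / (f + n - 2)}, the R2 implied by the F-statistic of
#' a simple regression on \code{n} samples.
#'
#' @param beta,se,eaf,n Effect size (SD units), standard error, effect-allele
#'   frequency (may be \code{NA}) and sample size.
#' @return A list with elements \code{f} and \code{r2} (vectorised).
#' @export
per_snp_strength <- function(beta, se, eaf = NA_real_, n = NA_real_) {
  if (any(se <= 0, na.rm = TRUE)) stop("se must be positive", call. = FALSE)
  f <- (beta / se)^2
  r2 <- ifelse(!is.na(eaf), 2 * beta^2 * eaf * (1 - eaf), NA_real_)
  fb <- is.na(r2)
  if (any(fb)) {
    nn <- rep_len(n, length(f))
    bad <- fb & (is.na(nn) | nn <= 2)
    r2[fb] <- f[fb] / (f[fb] + rep_len(nn, length(f))[fb] - 2)
    if (any(bad)) {
      r2[bad] <- NA_real_
      warning("r2 undefined for ", sum(bad), " variant(s): eaf missing and n <= 2",
              call. = FALSE)
    }
  }
  list(f = f, r2 = r2)
}

#' Cumulative instrument strength
#'
#' Joint F-statistic of \code{k} approximately independent instruments
#' explaining a total variance \code{R2 = sum(per-SNP r2)} (capped at 0.99) in
#' an exposure GWAS of \code{n} samples:
#' \code{F = (R2 / (1 - R2)) * ((n - k - 1) / k)}.
#'
#' @param per_snp_r2 Numeric vector of per-variant variance explained.
#' @param n Exposure GWAS sample size.
#' @return The cumulative F-statistic (NA with a warning when \code{n <= k+1}).
#' @export
cumulative_strength <- function(per_snp_r2, n) {
  k <- length(per_snp_r2)
  if (k == 0) return(NA_real_)
  if (is.na(n) || n <= k + 1) {
    warning("cumulative F undefined: n <= k + 1", call. = FALSE)
    return(NA_real_)
  }
  r2 <- min(sum(per_snp_r2, na.rm = TRUE), 0.99)
  (r2 / (1 - r2)) * ((n - k - 1) / k)
}

#' Select genetic instruments for an exposure
#'
#' Takes all variants with p below \code{primary_p} (default genome-wide
#' significance, 5e-8) and clumps them ([clump()]); if no variant reaches the
#' primary threshold, the procedure is repeated at the relaxed
#' \code{fallback_p} (default 5e-7). Per-variant and cumulative F-statistics
#' and variance explained are attached ([per_snp_strength()],
#' [cumulative_strength()]). Exposures with no variant below the fallback
#' threshold are flagged uninstrumentable.
#'
#' @param stats Summary-statistic data.frame for the exposure.
#' @param ld An [ld_matrix()]; variants missing from it are treated as
#'   unlinked, with a warning.
#' @param primary_p,fallback_p Significance thresholds (p strictly below).
#' @param r2_max,window_kb Clumping parameters, see [clump()].
#' @param exposure_name Label carried through to reports.
#' @return An \code{instrument_set}: list with \code{exposure_name},
#'   \code{records} (the index variants), \code{threshold_used}, \code{k},
#'   \code{per_snp_f}, \code{per_snp_r2}, \code{cumulative_f} and
#'   \code{uninstrumentable} flag.
#' @export
select_instruments <- function(stats, ld, primary_p = 5e-8, fallback_p = 5e-7,
                               r2_max = 0.01, window_kb = 10000,
                               exposure_name = "exposure") {
  empty <- function(threshold) structure(
    list(exposure_name = exposure_name, records = stats[0, , drop = FALSE],
         threshold_used = threshold, k = 0L, per_snp_f = numeric(0),
         per_snp_r2 = numeric(0), cumulative_f = NA_real_,
         uninstrumentable = TRUE),
    class = "instrument_set")
  if (NROW(stats) == 0) return(empty(NA_real_))

  pass1 <- stats[!is.na(stats$pvalue) & stats$pvalue < primary_p, , drop = FALSE]
  if (nrow(pass1) > 0) {
    cand <- pass1; threshold <- primary_p
  } else {
    cand <- stats[!is.na(stats$pvalue) & stats$pvalue < fallback_p, , drop = FALSE]
    threshold <- fallback_p
  }
  if (nrow(cand) == 0) return(empty(NA_real_))
  missing_ld <- setdiff(cand$variant_id, ld$variant_ids)
  if (length(missing_ld))
    warning(length(missing_ld), " candidate variant(s) absent from LD matrix; treated as unlinked",
            call. = FALSE)
  idx <- clump(cand, ld, r2_max = r2_max, window_kb = window_kb)
  st <- per_snp_strength(idx$beta, idx$se, idx$eaf, idx$n)
  n_gwas <- suppressWarnings(max(idx$n, na.rm = TRUE))
  if (!is.finite(n_gwas)) n_gwas <- NA_real_
  structure(
    list(exposure_name = exposure_name, records = idx, threshold_used = threshold,
         k = nrow(idx), per_snp_f = st$f, per_snp_r2 = st$r2,
         cumulative_f = suppressWarnings(cumulative_strength(st$r2, n_gwas)),
         uninstrumentable = FALSE),
    class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  if (x$uninstrumentable) {
    cat("Instrument set for", x$exposure_name, ": uninstrumentable\n")
    return(invisible(x))
  }
  cat("Instrument set for ", x$exposure_name, ": k = ", x$k,
      " (p < ", format(x$threshold_used), ")\n", sep = "")
  cat("  per-SNP F: ", paste(formatC(x$per_snp_f, digits = 4, format = "g"), collapse = ", "),
      "\n  cumulative F: ", formatC(x$cumulative_f, digits = 5, format = "g"), "\n", sep = "")
  invisible(x)
}

#' Restrict instruments to the cis region of the encoding gene
#'
#' Retains only instruments on the gene's chromosome whose position lies in
#' \code{[start - flank, end + flank]} (bounds inclusive). Cis variants lie
#' near the gene encoding the measured protein and are less prone to
#' horizontal pleiotropy than distal (trans) variants. The result may be
#' empty, in which case the exposure is uninstrumentable for cis-MR.
#'
#' @param instruments An \code{instrument_set} from [select_instruments()].
#' @param gene A list/row with \code{gene_symbol}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), e.g. one row of [read_gene_annotations()].
#' @param flank_kb Flanking window in kilobases (default 100).
#' @return An \code{instrument_set} with strength statistics recomputed on the
#'   retained variants.
#' @export
cis_filter <- function(instruments, gene, flank_kb = 100) {
  rec <- instruments$records
  lo <- gene$start - flank_kb * 1000
  hi <- gene$end + flank_kb * 1000
  keep <- !is.na(rec$chrom) & rec$chrom == gene$chrom &
    !is.na(rec$pos) & rec$pos >= lo & rec$pos <= hi
  rec <- rec[keep, , drop = FALSE]
  st <- per_snp_strength(rec$beta, rec$se, rec$eaf, rec$n)
  n_gwas <- suppressWarnings(max(rec$n, na.rm = TRUE))
  if (!is.finite(n_gwas)) n_gwas <- NA_real_
  structure(
    list(exposure_name = instruments$exposure_name, records = rec,
         threshold_used = instruments$threshold_used, k = nrow(rec),
         per_snp_f = st$f, per_snp_r2 = st$r2,
         cumulative_f = if (nrow(rec)) suppressWarnings(cumulative_strength(st$r2, n_gwas)) else NA_real_,
         uninstrumentable = nrow(rec) == 0),
    class = "instrument_set")
}

#' Read gene annotations for cis-restriction
#'
#' Reads a BED-like tab-delimited file with columns chrom, start, end,
#' gene_symbol. Coordinates are interpreted 1-based inclusive by default; set
#' \code{zero_based = TRUE} for the 0-based half-open BED dialect (start is
#' then incremented by one).
#'
#' @param path File path (no header required; a header line starting with
#'   "chrom" or "#" is skipped).
#' @param zero_based Interpret as BED 0-based half-open.
#' @return data.frame with columns gene_symbol, chrom, start, end.
#' @export
read_gene_annotations <- function(path, zero_based = FALSE) {
  if (!file.exists(path)) stop("cannot read gene annotations: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) && grepl("^chrom\\b", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  tab <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(gene_symbol = as.character(tab[[4]]),
                    chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]) + if (zero_based) 1 else 0,
                    end = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  bad <- out$start > out$end
  if (any(bad)) stop("gene annotation with start > end: ", out$gene_symbol[bad][1], call. = FALSE)
  out
}
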