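# Exposure-outcome allele harmonisation.

HARMONISE_ACTIONS <- c("aligned", "sign_flipped", "strand_flipped",
                       "strand_flipped_and_sign_flipped",
                       "dropped_palindromic", "dropped_incompatible")

#' Harmonise exposure and outcome summary statistics to a common effect allele
#'
#' Matches variants by ID and re-expresses the outcome association on the
#' exposure's effect allele. For non-palindromic variants the orientation is
#' decided from the allele letters alone: identical coding is kept
#' (\code{aligned}); swapped effect/other alleles negate the outcome beta and
#' complement its allele frequency (\code{sign_flipped}); allele pairs that
#' match only after A<->T / C<->G complementation are treated as reported on
#' the opposite strand, then aligned or sign-flipped as before
#' (\code{strand_flipped}, \code{strand_flipped_and_sign_flipped}).
#'
#' Palindromic variants (A/T or C/G pairs) carry no strand information in
#' their letters, so orientation is resolved from the effect-allele frequency:
#' when both sides' frequencies are available and fall outside
#' \code{palindromic_eaf_window}, frequencies on the same side of 0.5 keep the
#' sign and opposite sides flip it. Frequencies inside the window (or missing)
#' leave the orientation ambiguous and the variant is dropped
#' (\code{dropped_palindromic}) when \code{drop_palindromic_ambiguous} is
#' \code{TRUE} (the default, the conservative standard for two-sample MR).
#' Allele sets that cannot be reconciled at all are dropped as
#' \code{dropped_incompatible}.
#'
#' @param exposure,outcome Summary-statistic data.frames (canonical columns,
#'   see [read_summary_stats()]).
#' @param palindromic_eaf_window Numeric length-2: frequencies in this open
#'   interval around 0.5 are considered too close to 0.5 to orient a
#'   palindromic variant. Default \code{c(0.42, 0.58)}.
#' @param drop_palindromic_ambiguous Drop palindromic variants whose
#'   orientation cannot be resolved (default \code{TRUE}). If \code{FALSE},
#'   ambiguous palindromic variants are retained as-coded (\code{aligned}) —
#'   use only when both datasets are known to share strand conventions.
#' @return A \code{harmonised_set}: a data.frame with one row per shared
#'   variant and columns \code{variant_id, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, eaf_exposure, eaf_outcome, chrom, pos, action},
#'   plus a \code{dropped} attribute listing excluded variants and reasons.
#'   Only retained rows (\code{attr(x, "retained")} or \code{x[x$kept, ]})
#'   enter downstream estimation; the \code{kept} column marks them.
#' @export
harmonise <- function(exposure, outcome,
                      palindromic_eaf_window = c(0.42, 0.58),
                      drop_palindromic_ambiguous = TRUE) {
  req <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  for (d in list(exposure, outcome))
    if (!all(req %in% names(d)))
      stop("exposure/outcome must carry columns: ", paste(req, collapse = ", "), call. = FALSE)

  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  beta_out <- as.numeric(ou$beta)
  eaf_out <- if (!is.null(ou$eaf)) as.numeric(ou$eaf) else rep(NA_real_, n)
  eaf_exp <- if (!is.null(ex$eaf)) as.numeric(ex$eaf) else rep(NA_real_, n)

  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(ou$effect_allele); oa_y <- toupper(ou$other_allele)
  lo <- min(palindromic_eaf_window); hi <- max(palindromic_eaf_window)

  for (i in seq_len(n)) {
    pal_x <- is_palindromic(ea_x[i], oa_x[i])
    pal_y <- is_palindromic(ea_y[i], oa_y[i])
    if (pal_x || pal_y) {
      if (!(pal_x && pal_y) || !setequal(c(ea_x[i], oa_x[i]), c(ea_y[i], oa_y[i]))) {
        action[i] <- "dropped_incompatible"
        next
      }
      fx <- eaf_exp[i]; fy <- eaf_out[i]
      ambiguous <- is.na(fx) || is.na(fy) ||
        (fx > lo && fx < hi) || (fy > lo && fy < hi)
      if (ambiguous) {
        if (drop_palindromic_ambiguous) {
          action[i] <- "dropped_palindromic"
        } else {
          action[i] <- "aligned"
        }
        next
      }
      same_side <- (fx - 0.5) * (fy - 0.5) > 0
      letters_match <- ea_y[i] == ea_x[i]
      if (same_side) {
        # effect alleles refer to the same physical allele
        action[i] <- if (letters_match) "aligned" else "strand_flipped"
        if (!letters_match) { ea_y[i] <- ea_x[i]; oa_y[i] <- oa_x[i] }
      } else {
        action[i] <- if (letters_match) "strand_flipped_and_sign_flipped" else "sign_flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      next
    }
    # non-palindromic: letters decide
    if (ea_y[i] == ea_x[i] && oa_y[i] == oa_x[i]) {
      action[i] <- "aligned"
    } else if (ea_y[i] == oa_x[i] && oa_y[i] == ea_x[i]) {
      action[i] <- "sign_flipped"
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    } else {
      cea <- complement_allele(ea_y[i]); coa <- complement_allele(oa_y[i])
      if (cea == ea_x[i] && coa == oa_x[i]) {
        action[i] <- "strand_flipped"
      } else if (cea == oa_x[i] && coa == ea_x[i]) {
        action[i] <- "strand_flipped_and_sign_flipped"
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else {
        action[i] <- "dropped_incompatible"
      }
    }
  }

  kept <- !startsWith(action, "dropped")
  res <- data.frame(
    variant_id = shared,
    beta_exposure = as.numeric(ex$beta),
    se_exposure = as.numeric(ex$se),
    beta_outcome = beta_out,
    se_outcome = as.numeric(ou$se),
    eaf_exposure = eaf_exp,
    eaf_outcome = eaf_out,
    chrom = if (!is.null(ex$chrom)) as.character(ex$chrom) else NA_character_,
    pos = if (!is.null(ex$pos)) as.integer(ex$pos) else NA_integer_,
    action = action,
    kept = kept,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "dropped") <- res[!kept, c("variant_id", "action")]
  class(res) <- c("harmonised_set", "data.frame")
  res
}

#' Retained pairs of a harmonised set
#'
#' @param h A \code{harmonised_set} from [harmonise()].
#' @return The subset of rows retained for estimation.
#' @export
retained <- function(h) {
  h2 <- h[h$kept, , drop = FALSE]
  rownames(h2) <- NULL
  h2
}

#' @export
print.harmonised_set <- function(x, ...) {
  tab <- table(factor(x$action, levels = HARMONISE_ACTIONS))
  cat("Harmonised set: ", sum(x$kept), " retained of ", nrow(x), " shared variants\n", sep = "")
  for (a in names(tab)) if (tab[[a]] > 0) cat("  ", a, ": ", tab[[a]], "\n", sep = "")
  invisible(x)
}

# Build a harmonised_set directly from paired effect vectors (used by the
# simulator and in tests where allele bookkeeping is not under study).
as_harmonised <- function(variant_id, beta_exposure, se_exposure,
                          beta_outcome, se_outcome,
                          eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                          chrom = NA_character_, pos = NA_integer_) {
  res <- data.frame(variant_id = as.character(variant_id),
                    beta_exposure = beta_exposure, se_exposure = se_exposure,
                    beta_outcome = beta_outcome, se_outcome = se_outcome,
                    eaf_exposure = eaf_exposure, eaf_outcome = eaf_outcome,
                    chrom = chrom, pos = pos,
                    action = "aligned", kept = TRUE, stringsAsFactors = FALSE)
  class(res) <- c("harmonised_set", "data.frame")
  res
}
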