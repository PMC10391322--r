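# LD matrices: construction and file formats.

#' Construct an LD matrix object
#'
#' Bundles a symmetric matrix of squared correlations (r2) between variants
#' with their genomic coordinates, as used by [clump()], [find_proxy()] and
#' [select_instruments()].
#'
#' @param r2 Square numeric matrix of pairwise r2 in [0,1]; row/column names
#'   are the variant IDs unless \code{variant_ids} is given.
#' @param pos Integer base-pair positions (1-based), one per variant.
#' @param chrom Chromosome labels, one per variant (recycled if length 1).
#' @param variant_ids Optional explicit variant IDs.
#' @return An object of class \code{ld_matrix}.
#' @export
ld_matrix <- function(r2, pos, chrom, variant_ids = NULL) {
  r2 <- as.matrix(r2)
  ids <- variant_ids %||% rownames(r2)
  if (is.null(ids)) stop("variant IDs required (names or `variant_ids`)", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(ids))
    stop("r2 must be square with one row per variant", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must be 1", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric", call. = FALSE)
  if (length(chrom) == 1) chrom <- rep(chrom, length(ids))
  stopifnot(length(pos) == length(ids), length(chrom) == length(ids))
  dimnames(r2) <- list(ids, ids)
  structure(list(variant_ids = as.character(ids), r2 = r2,
                 pos = as.numeric(pos), chrom = as.character(chrom)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD matrix:", length(x$variant_ids), "variants on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

# r2 between two variant IDs; 0 (unlinked) when either is absent.
ld_r2 <- function(ld, id1, id2) {
  i <- match(id1, ld$variant_ids); j <- match(id2, ld$variant_ids)
  if (is.na(i) || is.na(j)) return(0)
  ld$r2[i, j]
}

#' Read an LD matrix from a file
#'
#' Accepts either a square tab-delimited matrix whose first column and header
#' row hold variant IDs, or a long-format triplet file with columns
#' \code{id1, id2, r2} (unlisted pairs are taken as r2 = 0). Positions and
#' chromosomes are supplied via \code{coords}, a data.frame with columns
#' \code{variant_id, chrom, pos}; variants without coordinates get position
#' \code{NA} and are treated as unlinked by distance-window logic.
#'
#' @param path File path.
#' @param coords Optional coordinate table (variant_id, chrom, pos).
#' @param format \code{"auto"}, \code{"matrix"} or \code{"triplet"}.
#' @return An \code{ld_matrix}.
#' @export
read_ld_matrix <- function(path, coords = NULL, format = c("auto", "matrix", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read LD matrix: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "auto")
    format <- if (ncol(tab) == 3 && !all(vapply(tab[-1], is.numeric, logical(1))) ||
                  identical(tolower(names(tab))[1:2], c("id1", "id2"))) "triplet" else "matrix"
  if (format == "triplet") {
    ids <- sort(unique(c(tab[[1]], tab[[2]])))
    r2 <- diag(length(ids)); dimnames(r2) <- list(ids, ids)
    for (k in seq_len(nrow(tab))) {
      i <- match(tab[[1]][k], ids); j <- match(tab[[2]][k], ids)
      r2[i, j] <- r2[j, i] <- as.numeric(tab[[3]][k])
    }
    diag(r2) <- 1
  } else {
    ids <- as.character(tab[[1]])
    r2 <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(r2) <- list(ids, colnames(r2))
    r2 <- r2[, ids, drop = FALSE]
  }
  pos <- rep(NA_real_, length(ids)); chrom <- rep(NA_character_, length(ids))
  if (!is.null(coords)) {
    m <- match(ids, coords$variant_id)
    pos <- as.numeric(coords$pos[m]); chrom <- as.character(coords$chrom[m])
  }
  ld_matrix(r2, pos = pos, chrom = chrom, variant_ids = ids)
}
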