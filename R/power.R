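# Closed-form power for two-sample MR with a binary outcome.

#' Power of a two-sample MR test with a binary outcome
#'
#' Normal-approximation power for detecting an odds ratio \code{or_alt} per SD
#' of exposure at two-sided level \code{alpha}, given an outcome GWAS of
#' \code{n_total} samples with \code{n_cases} cases and instruments explaining
#' a fraction \code{r2} of exposure variance. With case fraction
#' \code{p = n_cases/n_total} and \code{b = log(or_alt)}, the non-centrality of
#' the instrumented log-odds test is \code{sqrt(n_total * r2 * p * (1-p)) * |b|}
#' and
#' \deqn{power = \Phi(ncp - z_{1-\alpha/2}) + \Phi(-ncp - z_{1-\alpha/2}).}
#' The function is strictly increasing in \code{n_total}, \code{r2} and
#' \code{|log(or_alt)|}, symmetric under \code{or_alt -> 1/or_alt}, and equals
#' \code{alpha} at the null \code{or_alt = 1}.
#'
#' @param n_total Total outcome-GWAS sample size.
#' @param n_cases Number of cases (0 < n_cases < n_total).
#' @param or_alt Odds ratio per SD of exposure under the alternative (> 0).
#' @param r2 Variance in the exposure explained by the instruments, in (0,1).
#' @param alpha Two-sided significance level, in (0,1); default 0.05.
#' @return Power in [0,1] (vectorised over the arguments).
#' @examples
#' # phase-one Alzheimer's GWAS scenario: 24,087 cases / 79,145 total
#' binary_outcome_power(79145, 24087, or_alt = 1.1, r2 = 0.06)
#' @export
binary_outcome_power <- function(n_total, n_cases, or_alt, r2, alpha = 0.05) {
  if (any(n_cases <= 0 | n_cases >= n_total))
    stop("need 0 < n_cases < n_total", call. = FALSE)
  if (any(or_alt <= 0)) stop("or_alt must be positive", call. = FALSE)
  if (any(r2 <= 0 | r2 >= 1)) stop("r2 must lie in (0,1)", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0,1)", call. = FALSE)
  p <- n_cases / n_total
  b <- log(or_alt)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- sqrt(n_total * r2 * p * (1 - p)) * abs(b)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Power grid over study scenarios
#'
#' Evaluates [binary_outcome_power()] over the Cartesian grid of \code{r2} and
#' \code{or_alt} values for one outcome-GWAS configuration, returning a table
#' ordered by (r2, or_alt).
#'
#' @param n_total,n_cases,alpha As in [binary_outcome_power()].
#' @param r2,or_alt Numeric vectors swept over.
#' @return data.frame with columns \code{r2, or_alt, power}, ordered by
#'   \code{r2} then \code{or_alt}; empty input gives an empty table.
#' @export
power_grid <- function(n_total, n_cases, or_alt, r2, alpha = 0.05) {
  grid <- expand.grid(or_alt = or_alt, r2 = r2)[, 2:1, drop = FALSE]
  if (nrow(grid) == 0)
    return(data.frame(r2 = numeric(0), or_alt = numeric(0), power = numeric(0)))
  grid <- grid[order(grid$r2, grid$or_alt), , drop = FALSE]
  grid$power <- binary_outcome_power(n_total, n_cases, grid$or_alt, grid$r2, alpha)
  rownames(grid) <- NULL
  grid
}
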