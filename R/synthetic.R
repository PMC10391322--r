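# Seeded synthetic GWAS summary statistics with known causal structure.
#
# The generator emulates the study design the package targets: an exposure
# GWAS of a SD-scaled continuous trait (a circulating cytokine concentration)
# and a disjoint outcome GWAS (binary, log-odds scale, or continuous),
# connected by a known causal effect theta, with optional horizontal
# pleiotropy and allele-coding corruption for harmonisation stress tests.

NON_PALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                              c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulation configuration
#'
#' Bundles and validates the generating parameters for
#' [simulate_summary_level()] and [simulate_individual_level()].
#'
#' Defaults describe a realistic cytokine-GWAS scenario: 8,000 exposure
#' samples (the largest cytokine cohorts), an outcome GWAS of 79,145 with case
#' fraction 24,087/79,145 when binary, SNP-exposure effects gamma_j ~
#' N(0.15, 0.05) SD per allele (per-SNP F of genome-wide-significant
#' instruments roughly 40-130), and minor allele frequencies uniform on
#' (0.05, 0.5).
#'
#' @param n_snps Number of instruments to generate.
#' @param theta True causal effect (log odds per SD for binary outcomes).
#' @param n_exposure,n_outcome GWAS sample sizes (two disjoint samples).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param gamma_mean,gamma_sd Normal distribution of true SNP-exposure effects.
#' @param pleiotropy One of \code{"none"}, \code{"balanced"} (direct effects
#'   alpha_j ~ N(0, sd)), \code{"directional"} (alpha_j ~ N(mean, sd), InSIDE
#'   holding), \code{"inside_violating"} (alpha_j correlated with gamma_j).
#' @param pleiotropy_mean,pleiotropy_sd,pleiotropy_cor Parameters of the
#'   pleiotropy regime (cor used only by \code{inside_violating}).
#' @param invalid_fraction Fraction of SNPs given pleiotropic effects.
#' @param outcome_type \code{"continuous"} or \code{"binary"}.
#' @param case_fraction Case fraction of the binary outcome GWAS.
#' @param confounder_strength Coefficient of the shared confounder
#'   (individual-level path only).
#' @param seed Integer seed; mandatory, the whole draw is reproducible.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_snps = 30, theta = 0,
                       n_exposure = 8000, n_outcome = 79145,
                       maf_range = c(0.05, 0.5),
                       gamma_mean = 0.15, gamma_sd = 0.05,
                       pleiotropy = c("none", "balanced", "directional", "inside_violating"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0.05, pleiotropy_cor = 0.5,
                       invalid_fraction = 0, outcome_type = c("continuous", "binary"),
                       case_fraction = 24087 / 79145,
                       confounder_strength = 0, seed) {
  pleiotropy <- match.arg(pleiotropy)
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop("sim_config requires an explicit `seed`", call. = FALSE)
  if (n_snps < 0 || n_snps != round(n_snps)) stop("n_snps must be a non-negative integer", call. = FALSE)
  if (invalid_fraction < 0 || invalid_fraction > 1)
    stop("invalid_fraction must lie in [0,1]", call. = FALSE)
  if (min(maf_range) <= 0 || max(maf_range) > 0.5)
    stop("maf_range must lie in (0, 0.5]", call. = FALSE)
  if (outcome_type == "binary" && (case_fraction <= 0 || case_fraction >= 1))
    stop("case_fraction must lie in (0,1)", call. = FALSE)
  if (n_exposure < 3 || n_outcome < 3) stop("sample sizes too small", call. = FALSE)
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 maf_range = maf_range, gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleiotropy = pleiotropy, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd, pleiotropy_cor = pleiotropy_cor,
                 invalid_fraction = invalid_fraction, outcome_type = outcome_type,
                 case_fraction = case_fraction,
                 confounder_strength = confounder_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw the latent genetic architecture shared by both generator paths.
draw_truth <- function(cfg) {
  J <- cfg$n_snps
  maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
  gamma <- stats::rnorm(J, cfg$gamma_mean, cfg$gamma_sd)
  invalid <- rep(FALSE, J)
  n_invalid <- round(cfg$invalid_fraction * J)
  if (n_invalid > 0) invalid[sample.int(J, n_invalid)] <- TRUE
  alpha <- numeric(J)
  if (n_invalid > 0 && cfg$pleiotropy != "none") {
    idx <- which(invalid)
    alpha[idx] <- switch(cfg$pleiotropy,
      balanced = stats::rnorm(n_invalid, 0, cfg$pleiotropy_sd),
      directional = stats::rnorm(n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      inside_violating = {
        rho <- cfg$pleiotropy_cor
        gz <- (gamma[idx] - cfg$gamma_mean) / cfg$gamma_sd
        cfg$pleiotropy_mean + cfg$pleiotropy_sd *
          (rho * gz + sqrt(1 - rho^2) * stats::rnorm(n_invalid))
      })
  }
  structure(list(theta = cfg$theta, gamma = gamma, alpha = alpha, maf = maf,
                 invalid = invalid, seed = cfg$seed),
            class = "sim_truth")
}

# Variant metadata: IDs, far-apart positions (independent post-clumping
# instruments), non-palindromic allele pairs, eaf = maf on both sides.
variant_frame <- function(J, maf) {
  pair_idx <- sample.int(length(NON_PALINDROMIC_PAIRS), J, replace = TRUE)
  ea <- vapply(NON_PALINDROMIC_PAIRS[pair_idx], `[`, "", 1L)
  oa <- vapply(NON_PALINDROMIC_PAIRS[pair_idx], `[`, "", 2L)
  data.frame(variant_id = sprintf("rs%06d", seq_len(J)),
             chrom = as.character(rep_len(1:22, J)),
             pos = 1000000L + (seq_len(J) - 1L) %/% 22L * 20000000L,
             effect_allele = ea, other_allele = oa, eaf = maf,
             stringsAsFactors = FALSE)
}

#' Simulate summary-level GWAS statistics with known causal structure
#'
#' Draws true SNP-exposure effects gamma_j and pleiotropic direct effects
#' alpha_j per the configured regime, computes the standard GWAS standard
#' errors implied by sample size and allele frequency,
#' \code{se_x = 1/sqrt(2 n_exposure maf (1-maf))} (outcome analogously;
#' binary outcomes inflate by \code{1/sqrt(p(1-p))} with p the case fraction),
#' and emits estimated effects \code{beta_x ~ N(gamma_j, se_x)} and
#' \code{beta_y ~ N(theta gamma_j + alpha_j, se_y)} with two-sided normal
#' p-values. Output is bit-identical for identical configurations.
#'
#' @param cfg A [sim_config()].
#' @return List with \code{exposure} and \code{outcome} summary-statistic
#'   data.frames (canonical columns, shared variant IDs and alleles) and
#'   \code{truth}, a \code{sim_truth} holding theta, gamma, alpha, maf and
#'   the invalid flags.
#' @export
simulate_summary_level <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    truth <- draw_truth(cfg)
    J <- cfg$n_snps
    if (J == 0) {
      empty <- validate_summary_stats(data.frame(
        variant_id = character(0), chrom = character(0), pos = integer(0),
        effect_allele = character(0), other_allele = character(0),
        eaf = numeric(0), beta = numeric(0), se = numeric(0),
        pvalue = numeric(0), n = numeric(0)))
      return(list(exposure = empty, outcome = empty, truth = truth))
    }
    vf <- variant_frame(J, truth$maf)
    se_x <- 1 / sqrt(2 * cfg$n_exposure * truth$maf * (1 - truth$maf))
    se_y <- 1 / sqrt(2 * cfg$n_outcome * truth$maf * (1 - truth$maf))
    if (cfg$outcome_type == "binary")
      se_y <- se_y / sqrt(cfg$case_fraction * (1 - cfg$case_fraction))
    beta_x <- stats::rnorm(J, truth$gamma, se_x)
    beta_y <- stats::rnorm(J, cfg$theta * truth$gamma + truth$alpha, se_y)
    exposure <- cbind(vf, data.frame(beta = beta_x, se = se_x,
                                     pvalue = z_pvalue(beta_x, se_x),
                                     n = cfg$n_exposure))
    outcome <- cbind(vf, data.frame(beta = beta_y, se = se_y,
                                    pvalue = z_pvalue(beta_y, se_y),
                                    n = cfg$n_outcome))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate individual-level data and reduce to summary statistics
#'
#' Generates genotypes \code{G_j ~ Binomial(2, maf_j)} in two disjoint
#' samples, builds the exposure \code{X = sum(gamma_j G_j) + c U + e} with the
#' residual variance of \code{e} set to \code{1 - var(genetic) - c^2} so that
#' \code{Var(X) = 1} by construction (X is SD-scaled and \code{gamma_j} stays
#' in SD units, matching [simulate_summary_level()]), and the outcome
#' (continuous: \code{Y = theta X' + sum(alpha_j G_j) + c U' + e'} with the
#' outcome sample's own latent exposure X'; binary: Bernoulli via a logistic
#' model whose intercept is solved to hit \code{case_fraction}). Summary
#' statistics come from per-SNP simple linear regression (continuous traits)
#' or the logistic score test (binary outcome). Configurations whose genetic
#' plus confounder variance reaches the unit trait variance are rejected.
#'
#' A guard refuses configurations needing more than 1e8 genotype draws; use
#' [simulate_summary_level()] for large designs.
#'
#' @param cfg A [sim_config()].
#' @return Same structure as [simulate_summary_level()].
#' @export
simulate_individual_level <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps * (cfg$n_exposure + cfg$n_outcome) > 1e8)
    stop("individual-level simulation would need > 1e8 genotype draws; ",
         "use simulate_summary_level()", call. = FALSE)
  with_seed(cfg$seed, {
    truth <- draw_truth(cfg)
    J <- cfg$n_snps
    if (J == 0) {
      empty <- validate_summary_stats(data.frame(
        variant_id = character(0), chrom = character(0), pos = integer(0),
        effect_allele = character(0), other_allele = character(0),
        eaf = numeric(0), beta = numeric(0), se = numeric(0),
        pvalue = numeric(0), n = numeric(0)))
      return(list(exposure = empty, outcome = empty, truth = truth))
    }
    vf <- variant_frame(J, truth$maf)
    h2 <- sum(truth$gamma^2 * 2 * truth$maf * (1 - truth$maf))
    resid_var <- 1 - h2 - cfg$confounder_strength^2
    if (resid_var <= 0.05)
      stop("genetic + confounder variance (", round(h2 + cfg$confounder_strength^2, 3),
           ") leaves no residual variance for a unit-variance exposure; ",
           "reduce gamma or n_snps", call. = FALSE)

    make_exposure <- function(n) {
      G <- matrix(stats::rbinom(n * J, 2L, rep(truth$maf, each = n)), nrow = n)
      U <- stats::rnorm(n)
      X <- as.vector(G %*% truth$gamma) + cfg$confounder_strength * U +
        stats::rnorm(n, sd = sqrt(resid_var))
      list(G = G, U = U, X = X)
    }

    # per-SNP simple linear regression, vectorised across SNPs
    linear_scan <- function(G, y, n_label) {
      n <- length(y)
      gbar <- colMeans(G)
      sgg <- colSums(G^2) - n * gbar^2
      sgy <- as.vector(crossprod(G, y)) - n * gbar * mean(y)
      beta <- sgy / sgg
      rss <- (sum(y^2) - n * mean(y)^2) - beta * sgy  # per-SNP residual SS
      se <- sqrt(pmax(rss, 0) / (n - 2) / sgg)
      data.frame(beta = beta, se = se, pvalue = z_pvalue(beta, se), n = n_label)
    }

    ex <- make_exposure(cfg$n_exposure)
    exp_stats <- linear_scan(ex$G, ex$X, cfg$n_exposure)

    ou <- make_exposure(cfg$n_outcome)
    direct <- as.vector(ou$G %*% truth$alpha)
    if (cfg$outcome_type == "continuous") {
      Y <- cfg$theta * ou$X + direct + cfg$confounder_strength * ou$U + stats::rnorm(cfg$n_outcome)
      out_stats <- linear_scan(ou$G, Y, cfg$n_outcome)
    } else {
      eta0 <- cfg$theta * ou$X + direct + cfg$confounder_strength * ou$U
      icpt <- stats::uniroot(function(c0) mean(stats::plogis(eta0 + c0)) - cfg$case_fraction,
                             c(-30, 30))$root
      Y <- stats::rbinom(cfg$n_outcome, 1L, stats::plogis(eta0 + icpt))
      # logistic score test per SNP: U = sum g (y - ybar), V = ybar(1-ybar) s_gg
      n <- cfg$n_outcome
      gbar <- colMeans(ou$G)
      sgg <- colSums(ou$G^2) - n * gbar^2
      ybar <- mean(Y)
      sc <- as.vector(crossprod(ou$G, Y - ybar))
      V <- ybar * (1 - ybar) * sgg
      beta <- sc / V
      se <- 1 / sqrt(V)
      out_stats <- data.frame(beta = beta, se = se, pvalue = z_pvalue(beta, se), n = n)
    }
    list(exposure = cbind(vf, exp_stats), outcome = cbind(vf, out_stats), truth = truth)
  })
}

#' Corrupt allele coding for harmonisation stress tests
#'
#' Independently per record: with probability \code{swap_prob} exchanges
#' effect and other alleles (negating beta and complementing eaf — a pure
#' recoding); with probability \code{strand_prob} complements both alleles
#' (reporting the opposite strand — numerically a no-op). Before corruption, a
#' fraction \code{palindromic_fraction} of variants is redesignated as A/T or
#' C/G pairs, the case allele letters cannot orient.
#'
#' The palindromic designation is drawn from the seed \emph{before} the
#' swap/strand draws, so calling \code{scramble_alleles(x, 0, 0,
#' palindromic_fraction, seed)} on the matching exposure table reproduces the
#' identical designation — that keeps the two sides letter-compatible in
#' round-trip experiments.
#'
#' @param records Summary-statistic data.frame (canonical columns).
#' @param swap_prob,strand_prob Corruption probabilities.
#' @param palindromic_fraction Fraction of variants redesignated palindromic.
#' @param seed Integer seed.
#' @return The corrupted records with a \code{corruption} attribute: a
#'   data.frame with per-variant logical columns \code{palindromic},
#'   \code{swapped}, \code{strand_flipped}.
#' @export
scramble_alleles <- function(records, swap_prob, strand_prob,
                             palindromic_fraction = 0, seed) {
  if (missing(seed)) stop("scramble_alleles requires an explicit `seed`", call. = FALSE)
  with_seed(seed, {
    n <- nrow(records)
    out <- records
    pal <- rep(FALSE, n)
    n_pal <- round(palindromic_fraction * n)
    if (n_pal > 0) {
      idx <- sample.int(n, n_pal)
      pal[idx] <- TRUE
      pal_first <- sample(c("A", "C"), n_pal, replace = TRUE)
      out$effect_allele[idx] <- pal_first
      out$other_allele[idx] <- complement_allele(pal_first)
    }
    swapped <- stats::runif(n) < swap_prob
    stranded <- stats::runif(n) < strand_prob
    if (any(swapped)) {
      ea <- out$effect_allele[swapped]
      out$effect_allele[swapped] <- out$other_allele[swapped]
      out$other_allele[swapped] <- ea
      out$beta[swapped] <- -out$beta[swapped]
      out$eaf[swapped] <- 1 - out$eaf[swapped]
    }
    if (any(stranded)) {
      out$effect_allele[stranded] <- complement_allele(out$effect_allele[stranded])
      out$other_allele[stranded] <- complement_allele(out$other_allele[stranded])
    }
    attr(out, "corruption") <- data.frame(variant_id = records$variant_id,
                                          palindromic = pal, swapped = swapped,
                                          strand_flipped = stranded,
                                          stringsAsFactors = FALSE)
    out
  })
}

#' Block-diagonal LD matrix fixture
#'
#' Builds an [ld_matrix()] whose r2 is \code{within_r2} inside consecutive
#' blocks of the given sizes and 0 between blocks, with all variants placed on
#' one chromosome at 10 kb spacing so every block sits inside the default
#' clumping window. Greedy clumping at \code{r2_max <= within_r2} then keeps
#' exactly one index variant per block.
#'
#' @param n_snps Total number of variants.
#' @param block_sizes Integer partition of \code{n_snps}.
#' @param within_r2 Within-block r2, in [0,1).
#' @param variant_ids Optional IDs; default \code{rs000001...}.
#' @return An \code{ld_matrix}.
#' @export
make_ld_blocks <- function(n_snps, block_sizes, within_r2, variant_ids = NULL) {
  if (sum(block_sizes) != n_snps) stop("block_sizes must sum to n_snps", call. = FALSE)
  if (within_r2 < 0 || within_r2 >= 1) stop("within_r2 must lie in [0,1)", call. = FALSE)
  ids <- variant_ids %||% sprintf("rs%06d", seq_len(n_snps))
  r2 <- matrix(0, n_snps, n_snps)
  start <- 1L
  for (b in block_sizes) {
    idx <- start:(start + b - 1L)
    r2[idx, idx] <- within_r2
    start <- start + b
  }
  diag(r2) <- 1
  ld_matrix(r2, pos = 1000000 + (seq_len(n_snps) - 1) * 10000,
            chrom = "1", variant_ids = ids)
}
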