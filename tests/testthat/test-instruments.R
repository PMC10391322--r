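# Instrument selection: thresholds, clumping, proxies, strength, cis filter.

test_that("a single genome-wide-significant variant is selected at 5e-8", {
  stats <- record("rs1", "A", "G", 0.15, 0.02, eaf = 0.3, pvalue = 1e-10)
  ld <- make_ld_blocks(1, 1, 0, variant_ids = "rs1")
  inst <- select_instruments(stats, ld)
  expect_equal(inst$k, 1L)
  expect_equal(inst$threshold_used, 5e-8)
  expect_false(inst$uninstrumentable)
})

test_that("the threshold relaxes to 5e-7 when nothing passes 5e-8", {
  stats <- rbind(record("rs1", "A", "G", 0.15, 0.028, eaf = 0.3, pvalue = 1e-7, pos = 1e6),
                 record("rs2", "A", "G", 0.14, 0.027, eaf = 0.3, pvalue = 3e-7, pos = 3e7))
  ld <- make_ld_blocks(2, c(1, 1), 0, variant_ids = c("rs1", "rs2"))
  inst <- select_instruments(stats, ld)
  expect_equal(inst$threshold_used, 5e-7)
  expect_equal(inst$k, 2L)
})

test_that("exposures with no variant below the fallback are uninstrumentable", {
  stats <- record("rs1", "A", "G", 0.05, 0.02, eaf = 0.3, pvalue = 1e-5)
  ld <- make_ld_blocks(1, 1, 0, variant_ids = "rs1")
  inst <- select_instruments(stats, ld)
  expect_true(inst$uninstrumentable)
  expect_equal(inst$k, 0L)
  expect_true(select_instruments(stats[0, ], ld)$uninstrumentable)
})

test_that("clumping removes linked neighbours of the index variant", {
  # r2(rs1, rs2) = 0.5 excludes rs2; rs3 unlinked and kept
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.5
  ld <- ld_matrix(r2, pos = c(1e6, 1.1e6, 1.2e6), chrom = "1",
                  variant_ids = c("rs1", "rs2", "rs3"))
  cand <- rbind(record("rs1", "A", "G", 0.2, 0.02, pvalue = 1e-12, pos = 1e6),
                record("rs2", "A", "G", 0.2, 0.02, pvalue = 1e-10, pos = 1.1e6),
                record("rs3", "A", "G", 0.2, 0.02, pvalue = 1e-9, pos = 1.2e6))
  out <- clump(cand, ld, r2_max = 0.01, window_kb = 10000)
  expect_setequal(out$variant_id, c("rs1", "rs3"))
})

test_that("variants outside the distance window are retained despite LD", {
  r2 <- diag(2); r2[1, 2] <- r2[2, 1] <- 0.5
  ld <- ld_matrix(r2, pos = c(1e6, 2.1e7), chrom = "1",
                  variant_ids = c("rs1", "rs2"))
  cand <- rbind(record("rs1", "A", "G", 0.2, 0.02, pvalue = 1e-12, pos = 1e6),
                record("rs2", "A", "G", 0.2, 0.02, pvalue = 1e-10, pos = 2.1e7))
  out <- clump(cand, ld, r2_max = 0.01, window_kb = 10000)
  expect_equal(nrow(out), 2)
})

test_that("clumping matches the brute-force oracle on random instances", {
  set.seed(401)
  for (rep in 1:60) {
    k <- sample(2:12, 1)
    ids <- sprintf("rs%03d", sample(1:999, k))
    chrom <- sample(c("1", "2"), k, replace = TRUE)
    pos <- sample(1e6:2e7, k)
    ld <- random_ld(ids, pos, chrom)
    cand <- do.call(rbind, lapply(seq_len(k), function(i)
      record(ids[i], "A", "G", 0.2, 0.02, chrom = chrom[i], pos = pos[i],
             pvalue = runif(1, 1e-12, 1e-8))))
    cand <- cand[sample(k), ]  # row order must not matter
    got <- clump(cand, ld, r2_max = 0.1, window_kb = 5000)
    expect_equal(got$variant_id, brute_clump(cand, ld, 0.1, 5000))
  }
})

test_that("clumped instruments within a window are pairwise below r2_max", {
  set.seed(402)
  ids <- sprintf("rs%03d", 1:10)
  pos <- seq(1e6, by = 5e5, length.out = 10)
  r2 <- matrix(runif(100, 0, 0.4), 10, 10)
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  ld <- ld_matrix(r2, pos = pos, chrom = rep("1", 10), variant_ids = ids)
  cand <- do.call(rbind, lapply(1:10, function(i)
    record(ids[i], "A", "G", 0.2, 0.02, pos = pos[i], pvalue = runif(1, 1e-12, 1e-8))))
  out <- clump(cand, ld, r2_max = 0.2, window_kb = 10000)
  idx <- match(out$variant_id, ld$variant_ids)
  expect_gte(length(idx), 2)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j) next
    if (abs(ld$pos[idx[i]] - ld$pos[idx[j]]) <= 1e7)
      expect_lt(ld$r2[idx[i], idx[j]], 0.2)
  }
})

test_that("proxy search returns the highest-r2 variant above threshold", {
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.95
  r2[1, 3] <- r2[3, 1] <- 0.85
  ld <- ld_matrix(r2, pos = c(1e6, 1.01e6, 1.02e6), chrom = "1",
                  variant_ids = c("target", "rsA", "rsB"))
  expect_equal(find_proxy("target", c("rsA", "rsB"), ld, r2_min = 0.8), "rsA")
  # below threshold -> none
  r2[1, 2] <- r2[2, 1] <- 0.5; r2[1, 3] <- r2[3, 1] <- 0.4
  ld2 <- ld_matrix(r2, pos = c(1e6, 1.01e6, 1.02e6), chrom = "1",
                   variant_ids = c("target", "rsA", "rsB"))
  expect_null(find_proxy("target", c("rsA", "rsB"), ld2, r2_min = 0.8))
})

test_that("proxy ties break by distance then ID", {
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.9
  r2[1, 3] <- r2[3, 1] <- 0.9
  ld <- ld_matrix(r2, pos = c(1e6, 1e6 + 50000, 1e6 + 5000), chrom = "1",
                  variant_ids = c("target", "far", "near"))
  expect_equal(find_proxy("target", c("far", "near"), ld, 0.8), "near")
  expect_warning(out <- find_proxy("absent", c("far"), ld, 0.8), "not present")
  expect_null(out)
})

test_that("per-variant strength follows the closed forms", {
  st <- per_snp_strength(beta = 0.1, se = 0.01, eaf = 0.5)
  expect_equal(st$f, 100)
  expect_equal(st$r2, 0.005)
  # eaf missing: r2 from the F-statistic fallback f/(f + n - 2)
  st2 <- per_snp_strength(beta = 0.1, se = 0.02, eaf = NA, n = 1000)
  expect_equal(st2$f, 25)
  expect_equal(st2$r2, 25 / (25 + 998), tolerance = 1e-12)
  expect_warning(per_snp_strength(0.1, 0.02, eaf = NA, n = 2), "undefined")
})

test_that("the F >= 10 rule is equivalent to |beta/se| >= sqrt(10)", {
  set.seed(403)
  beta <- rnorm(50); se <- runif(50, 0.01, 1)
  f <- per_snp_strength(beta, se, eaf = rep(0.3, 50))$f
  expect_equal(f >= 10, abs(beta / se) >= sqrt(10))
})

test_that("cumulative strength follows the joint-R2 formula", {
  expect_equal(cumulative_strength(0.02, n = 1000), (0.02 / 0.98) * 998,
               tolerance = 1e-12)
  expect_equal(cumulative_strength(c(0.01, 0.01), n = 1000),
               (0.02 / 0.98) * (997 / 2), tolerance = 1e-12)
  expect_warning(out <- cumulative_strength(c(0.01, 0.01), n = 3), "undefined")
  expect_true(is.na(out))
})

test_that("cumulative F approximates the joint-regression F on simulated data", {
  # one individual-level dataset; package route = per-SNP summaries ->
  # cumulative_strength, oracle route = joint multiple regression on the
  # same data
  set.seed(31)
  n <- 4000; k <- 6
  maf <- runif(k, 0.1, 0.5)
  gamma <- rnorm(k, 0.08, 0.01)
  G <- matrix(rbinom(n * k, 2, rep(maf, each = n)), nrow = n)
  X <- as.vector(G %*% gamma) +
    rnorm(n, sd = sqrt(1 - sum(gamma^2 * 2 * maf * (1 - maf))))
  per_snp <- lapply(seq_len(k), function(j) {
    fit <- summary(lm(X ~ G[, j]))
    c(beta = fit$coefficients[2, 1], se = fit$coefficients[2, 2])
  })
  per_snp <- do.call(rbind, per_snp)
  st <- per_snp_strength(per_snp[, "beta"], per_snp[, "se"],
                         eaf = colMeans(G) / 2, n = n)
  f_pkg <- cumulative_strength(st$r2, n = n)
  f_joint <- summary(lm(X ~ G))$fstatistic[["value"]]
  expect_lt(abs(f_pkg - f_joint) / f_joint, 0.15)
})

test_that("cis filtering keeps only variants near the encoding gene", {
  gene <- list(gene_symbol = "IL6", chrom = "1", start = 1000000, end = 1010000)
  stats <- rbind(
    record("in_flank", "A", "G", 0.2, 0.02, eaf = 0.3, chrom = "1", pos = 950000, pvalue = 1e-10),
    record("wrong_chr", "A", "G", 0.2, 0.02, eaf = 0.3, chrom = "2", pos = 1000000, pvalue = 1e-10),
    record("past_boundary", "A", "G", 0.2, 0.02, eaf = 0.3, chrom = "1", pos = 1110001, pvalue = 1e-10),
    record("at_boundary", "A", "G", 0.2, 0.02, eaf = 0.3, chrom = "1", pos = 1110000, pvalue = 1e-10))
  ld <- make_ld_blocks(4, rep(1, 4), 0, variant_ids = stats$variant_id)
  inst <- select_instruments(stats, ld)
  cis <- cis_filter(inst, gene, flank_kb = 100)
  expect_setequal(cis$records$variant_id, c("in_flank", "at_boundary"))
  # an infinite flank restricts to the gene's chromosome only
  cis_inf <- cis_filter(inst, gene, flank_kb = Inf)
  expect_setequal(cis_inf$records$variant_id,
                  c("in_flank", "at_boundary", "past_boundary"))
  # losing every variant flags the exposure uninstrumentable for cis-MR
  gene2 <- list(gene_symbol = "X", chrom = "9", start = 1, end = 2)
  expect_true(cis_filter(inst, gene2)$uninstrumentable)
})

test_that("gene annotations read 1-based inclusive with a BED dialect flag", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "1\t999999\t1010000\tIL6"), path)
  g0 <- read_gene_annotations(path, zero_based = TRUE)
  expect_equal(g0$start, 1000000)
  g1 <- read_gene_annotations(path, zero_based = FALSE)
  expect_equal(g1$start, 999999)
  writeLines("1\t10\t5\tBAD", path)
  expect_error(read_gene_annotations(path), "start > end")
})

test_that("LD matrices read from square and triplet files agree", {
  ids <- c("rs1", "rs2", "rs3")
  sq <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("id", ids), collapse = "\t"),
               "rs1\t1\t0.5\t0", "rs2\t0.5\t1\t0.2", "rs3\t0\t0.2\t1"), sq)
  tri <- tempfile(fileext = ".tsv")
  writeLines(c("id1\tid2\tr2", "rs1\trs2\t0.5", "rs2\trs3\t0.2"), tri)
  coords <- data.frame(variant_id = ids, chrom = "1", pos = c(1e6, 2e6, 3e6))
  m1 <- read_ld_matrix(sq, coords)
  m2 <- read_ld_matrix(tri, coords)
  expect_equal(m1$r2, m2$r2)
  expect_equal(m1$pos, c(1e6, 2e6, 3e6))
  # validity checks on construction
  bad <- diag(2); bad[1, 2] <- 1.5; bad[2, 1] <- 1.5
  expect_error(ld_matrix(bad, pos = c(1, 2), chrom = "1", variant_ids = c("a", "b")),
               "\\[0,1\\]")
})
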