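test_that("BH-FDR matches hand-applied step-up and brute force", {
  # classic worked example: [0.01, 0.02, 0.03, 0.04] -> all 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(1.0), 1.0)
  # families are adjusted independently
  p <- c(0.01, 0.04, 0.02, 0.5)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_fdr(p, fam), c(bh_fdr(p[1:2]), bh_fdr(p[3:4])))
  # NA propagates without touching the rest
  q <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_fdr(c(0.01, 0.04)))
  set.seed(61)
  for (i in 1:20) {
    pv <- runif(sample(1:10, 1))
    expect_equal(bh_fdr(pv), brute_bh(pv))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

test_that("global burden OLS matches the normal-equations oracle", {
  set.seed(2)
  n <- 50
  dat <- data.frame(trait = rnorm(n), burden = rpois(n, 1),
                    PC1 = rnorm(n), PC2 = rnorm(n))
  r <- global_burden(dat, "trait", "burden", c("PC1", "PC2"))
  X <- cbind(1, dat$burden, dat$PC1, dat$PC2)
  beta <- brute_ols(X, dat$trait)
  expect_equal(r$estimate, beta[2, 1], tolerance = 1e-8)
  # rank-deficient design errors with the collinear column named
  dat$PC1b <- dat$PC1
  expect_error(global_burden(dat, "trait", "burden",
                             c("PC1", "PC1b")), "collinear")
})

test_that("global burden adjusts away a planted confounder", {
  set.seed(9)
  n <- 3000
  conf <- rnorm(n)
  burden <- rpois(n, exp(0.5 * conf))
  trait <- 0 * burden + 1 * conf + rnorm(n)
  dat <- data.frame(trait = trait, burden = burden, conf = conf)
  adj <- global_burden(dat, "trait", "burden", "conf")
  raw <- global_burden(dat, "trait", "burden")
  expect_true(adj$ci_low < 0 && 0 < adj$ci_high)   # unbiased when adjusted
  expect_gt(raw$estimate, adj$ci_high)             # biased when not
})

test_that("gene-set burden separates a causal set under global correction", {
  set.seed(77)
  n <- 3000
  ids <- sprintf("P%05d", 1:n)
  genes <- data.frame(symbol = sprintf("G%03d", 1:60),
                      chrom = "chr1", start = (0:59) * 1e5,
                      end = (0:59) * 1e5 + 5e4, strand = "+")
  sets <- list(causal = genes$symbol[1:15],
               control = genes$symbol[16:30])
  # sparse random rare deletions over the gene array
  k <- rpois(n, 1.2)
  calls <- data.frame(
    participant_id = rep(ids, k),
    chrom = "chr1",
    start = (sample.int(60, sum(k), replace = TRUE) - 1) * 1e5,
    type = "DEL", stratum = "rare")
  calls$end <- calls$start + 6e4
  bm <- build_burden_matrix(calls, genes, sets, ids)
  # set-specific causal effect plus nonspecific inflation from total load
  pheno <- data.frame(participant_id = ids,
                      trait = 0.4 * bm$counts$set.causal_DEL_rare +
                        0.15 * bm$counts$global_gene_count + rnorm(n))
  out <- geneset_burden(bm, pheno, "trait")
  causal <- out[out$gene_set == "causal", ]
  control <- out[out$gene_set == "control", ]
  expect_true(causal$ci_low < 0.4 && 0.4 < causal$ci_high)
  expect_lt(causal$q, 0.05)
  expect_equal(which.min(out$q), which(out$gene_set == "causal"))
  expect_lt(abs(control$beta), 0.2)
  expect_true(all(out$q >= out$p, na.rm = TRUE))
  # without the global correction the nonspecific load leaks into every
  # set: the negative control turns falsely significant
  off <- geneset_burden(bm, pheno, "trait", global_correction = FALSE)
  expect_lt(off$p[off$gene_set == "control"], 0.05)
})

test_that("gene-set burden skips zero-carrier sets with a record", {
  ids <- sprintf("P%d", 1:8)
  genes <- data.frame(symbol = c("G1", "G2"), chrom = "chr1",
                      start = c(0, 1e5), end = c(5e4, 1.5e5), strand = "+")
  calls <- data.frame(participant_id = c("P1", "P2", "P3", "P3"),
                      chrom = "chr1", start = c(0, 1e5, 0, 1e5),
                      end = c(4e4, 1.4e5, 4e4, 1.4e5),
                      type = c("DEL", "DUP", "DEL", "DUP"),
                      stratum = "rare")
  bm <- build_burden_matrix(calls, genes, list(hit = "G1", unhit = "G2"),
                            ids)
  set.seed(1)
  pheno <- data.frame(participant_id = ids, trait = rnorm(8))
  out <- geneset_burden(bm, pheno, "trait")
  expect_equal(out$note[out$gene_set == "unhit"], "skipped_zero_carriers")
})

test_that("locus burden excludes thin genes and flags a strong planted locus", {
  set.seed(55)
  n <- 2000
  ids <- sprintf("P%04d", 1:n)
  G <- 30
  X <- matrix(0L, n, G, dimnames = list(ids, sprintf("G%02d", 1:G)))
  for (j in 1:G) X[sample.int(n, 12), j] <- 1L
  # a gene with only 2 carriers must be excluded
  X[, 1] <- 0L; X[sample.int(n, 2), 1] <- 1L
  pheno <- data.frame(participant_id = ids, PC1 = rnorm(n))
  pheno$trait <- 2.0 * X[, 5] + 0.1 * pheno$PC1 + rnorm(n)
  out <- locus_burden(X, pheno, "trait", covariates = "PC1",
                      min_carriers = 3, n_perm = 500, seed = 42)
  expect_false("G01" %in% out$gene)
  top <- out[out$gene == "G05", ]
  expect_lt(top$fwer_p, 0.05)
  expect_true(top$significant_fwer)
  # observed t matches a direct lm fit
  fit <- lm(trait ~ X[, 5] + PC1, data = pheno)
  expect_equal(top$t, summary(fit)$coefficients[2, "t value"],
               tolerance = 1e-8)
  expect_equal(top$beta, unname(coef(fit)[2]), tolerance = 1e-8)
  # permutation path is deterministic given the seed
  out2 <- locus_burden(X, pheno, "trait", covariates = "PC1",
                       min_carriers = 3, n_perm = 500, seed = 42)
  expect_equal(out, out2)
})

test_that("locus burden reports a reason when screening removes everything", {
  X <- matrix(0L, 10, 2, dimnames = list(sprintf("P%d", 1:10),
                                         c("G1", "G2")))
  pheno <- data.frame(participant_id = sprintf("P%d", 1:10),
                      trait = rnorm(10))
  gs_res <- data.frame(gene_set = "s1", p = 0.9, q = 0.9)
  out <- locus_burden(X, pheno, "trait", geneset_results = gs_res,
                      gene_sets = list(s1 = c("G1", "G2")), n_perm = 10)
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "reason"), "screening")
})

test_that("sex LRT is non-negative, detects a planted difference, skips single sex", {
  set.seed(66)
  n <- 2000
  ids <- sprintf("P%04d", 1:n)
  sexes <- sample(c("M", "F"), n, TRUE)
  counts <- data.frame(
    participant_id = ids,
    gene_count_DEL_rare = 0, gene_count_DEL_less_rare = 0,
    gene_count_DUP_rare = 0, gene_count_DUP_less_rare = 0,
    total_length_DEL = rgamma(n, 2, 1e-5) * ifelse(sexes == "M", 1.25, 1),
    total_length_DUP = rgamma(n, 2, 1e-5),
    total_gene_count_DEL = rpois(n, 2 + (sexes == "M")),
    total_gene_count_DUP = rpois(n, 2),
    global_gene_count = 0)
  bm <- structure(list(counts = counts, gene_carriers = list(),
                       metadata = list(), n = n), class = "burden_matrix")
  pheno <- data.frame(participant_id = ids, sex = sexes, PC1 = rnorm(n))
  out <- sex_burden_lrt(bm, pheno, "PC1")
  expect_true(all(out$statistic >= 0))
  expect_lt(out$p[out$outcome == "total_length_DEL"], 0.05)
  expect_lt(out$p[out$outcome == "total_gene_count_DEL"], 0.05)
  expect_gt(out$p[out$outcome == "total_length_DUP"], 0.001)
  pheno$sex <- "M"
  out1 <- sex_burden_lrt(bm, pheno, "PC1")
  expect_true(all(grepl("skipped", out1$note)))
})

test_that("quasi-Poisson sex model recovers a multiplicative rate effect", {
  set.seed(70)
  n <- 4000
  sexes <- sample(c("F", "M"), n, TRUE)
  mult <- 1.3
  ncnv <- rpois(n, 1.5 * ifelse(sexes == "M", mult, 1))
  counts <- vapply(ncnv, function(k) sum(rpois(k, 1.5)), numeric(1))
  r <- sex_burden_glm(counts, sexes)
  expect_true(r$ci_low < log(mult) && log(mult) < r$ci_high)
})
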