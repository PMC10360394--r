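# Burden machinery: global and gene-set burden regression with
# global-burden correction, BH-FDR, locus-level tests with max-T
# permutation FWER, and sex-difference tests.

# OLS fit returning the focal coefficient row; errors on rank deficiency
ols_term <- function(dat, term, analysis) {
  fit <- stats::lm(y ~ ., data = dat)
  al <- stats::alias(fit)
  if (!is.null(al$Complete)) {
    stop_input("rank-deficient design; collinear column(s): %s",
               paste(rownames(al$Complete), collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  association_result(analysis, term, cf[term, "Estimate"], ci[term, 1],
                     ci[term, 2], cf[term, "t value"], cf[term, "Pr(>|t|)"],
                     n = nrow(dat), method = "ols")
}

#' Global CNV burden regression
#'
#' Linear regression of a trait on a burden predictor (e.g. the count of
#' genes impacted by rare deletions), adjusting covariates (principal
#' components, genotyping batch and platform; stimulant medication for
#' SSRT/RTV). Ancestry strata should be analyzed separately by subsetting
#' the input.
#'
#' @param data data.frame containing outcome, predictor and covariates.
#' @param outcome name of the trait column.
#' @param predictor name of the burden column.
#' @param covariates character vector of covariate column names.
#' @return one-row association result with the burden beta, 95% CI and p.
#' @export
global_burden <- function(data, outcome, predictor,
                          covariates = character()) {
  check_columns(data, c(outcome, predictor, covariates), "burden data")
  dat <- data.frame(y = data[[outcome]], data[, c(predictor, covariates),
                                              drop = FALSE])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  res <- ols_term(dat, predictor, "global_burden")
  res$term <- predictor
  res
}

#' Benjamini-Hochberg FDR within families
#'
#' Step-up BH adjustment applied separately within each family of tests.
#' Missing p-values propagate as missing and do not affect other tests in
#' the family.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param family optional vector of family labels; `NULL` treats all
#'   p-values as one family.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_input("p-values must lie in [0, 1]")
  }
  if (is.null(family)) family <- rep(1L, length(p))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    idx <- which(family == f & !is.na(p))
    if (length(idx) > 0L) q[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  q
}

#' Gene-set burden regression with global-burden correction
#'
#' For each gene-set column of the requested CNV type and stratum, fits
#' trait ~ set-specific gene count + global gene count (+ covariates) by
#' OLS, so that set effects are specific rather than a reflection of
#' overall CNV load. BH-FDR is applied across the sets of the family
#' (one trait x type x stratum). Sets with zero carriers are skipped and
#' recorded.
#'
#' @param bm a `burden_matrix` from [build_burden_matrix()].
#' @param phenotypes data.frame aligned to the cohort with the outcome and
#'   covariate columns; must contain `participant_id`.
#' @param outcome trait column name in `phenotypes`.
#' @param type CNV type, `"DEL"` or `"DUP"`.
#' @param stratum frequency stratum, `"rare"` or `"less_rare"`.
#' @param covariates covariate column names in `phenotypes`.
#' @param global_correction include the combined global gene count as a
#'   covariate (default `TRUE`).
#' @return data.frame with one row per gene-set: `gene_set`, `beta`,
#'   `ci_low`, `ci_high`, `p`, `q`, `n_carriers`, `stratum`, `type`,
#'   `note`.
#' @export
geneset_burden <- function(bm, phenotypes, outcome, type = "DEL",
                           stratum = "rare", covariates = character(),
                           global_correction = TRUE) {
  stopifnot(inherits(bm, "burden_matrix"))
  check_columns(phenotypes, c("participant_id", outcome, covariates),
                "phenotype table")
  counts <- bm$counts
  m <- match(counts$participant_id, phenotypes$participant_id)
  if (any(is.na(m))) stop_input("phenotypes missing for some participants")
  ph <- phenotypes[m, , drop = FALSE]
  set_cols <- names(bm$metadata)[vapply(bm$metadata, function(x) {
    identical(x$kind, "gene_set_count") && identical(x$type, type) &&
      identical(x$stratum, stratum)
  }, logical(1))]
  rows <- list()
  for (col in set_cols) {
    set_name <- bm$metadata[[col]]$set
    x <- counts[[col]]
    n_car <- sum(x > 0)
    if (n_car == 0L) {
      rows[[col]] <- data.frame(gene_set = set_name, beta = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                p = NA_real_, q = NA_real_, n_carriers = 0L,
                                stratum = stratum, type = type,
                                note = "skipped_zero_carriers")
      next
    }
    dat <- data.frame(y = ph[[outcome]], set_count = x)
    if (global_correction) dat$global_count <- counts$global_gene_count
    if (length(covariates) > 0L) {
      dat <- cbind(dat, ph[, covariates, drop = FALSE])
    }
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    res <- tryCatch(ols_term(dat, "set_count", "geneset_burden"),
                    error = function(e) NULL)
    if (is.null(res)) {
      rows[[col]] <- data.frame(gene_set = set_name, beta = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                p = NA_real_, q = NA_real_,
                                n_carriers = n_car, stratum = stratum,
                                type = type, note = "skipped_collinear")
      next
    }
    rows[[col]] <- data.frame(gene_set = set_name, beta = res$estimate,
                              ci_low = res$ci_low, ci_high = res$ci_high,
                              p = res$p, q = NA_real_, n_carriers = n_car,
                              stratum = stratum, type = type, note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out
}

# residualize columns of X (and y) on covariate design; returns list
residualize <- function(y, X, covariates) {
  C <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrC <- qr(C)
  list(y = qr.resid(qrC, y),
       X = qr.resid(qrC, X),
       rank = qrC$rank)
}

#' Locus-level burden tests with permutation FWER control
#'
#' Tests each candidate gene's carrier indicator against a trait by OLS
#' (adjusting covariates), restricted to genes belonging to gene-sets that
#' passed the screening thresholds (p < 0.05 and FDR q < 0.2 by default)
#' and carried by at least `min_carriers` participants. Family-wise error
#' is controlled by max-T permutation: outcome residuals (after covariate
#' adjustment) are permuted and the maximum absolute t-statistic across
#' genes is recorded; each gene's FWER-adjusted p is the proportion of
#' permutations whose max |t| reaches its observed |t|.
#'
#' @param gene_carriers participant x gene 0/1 matrix for one CNV type
#'   (from `burden_matrix$gene_carriers`).
#' @param phenotypes data.frame aligned to the matrix rows (same order),
#'   containing the outcome and covariates.
#' @param outcome trait column name.
#' @param covariates covariate column names.
#' @param geneset_results optional [geneset_burden()] table used to select
#'   the screening gene-sets.
#' @param gene_sets named list of gene symbol vectors (required when
#'   `geneset_results` is supplied).
#' @param screen_p,screen_q screening thresholds on the gene-set results.
#' @param min_carriers minimum carrier count per gene, default 3.
#' @param n_perm number of permutations, default 10000.
#' @param seed RNG seed for the permutations.
#' @return data.frame with one row per tested gene: `gene`, `n_carriers`,
#'   `beta`, `t`, `p`, `fwer_p`, `significant_fwer`; the 5% max-T critical
#'   value is attached as attribute `"fwer_critical_t"`. When no gene-set
#'   passes screening, an empty table with attribute `"reason"` is
#'   returned.
#' @export
locus_burden <- function(gene_carriers, phenotypes, outcome,
                         covariates = character(),
                         geneset_results = NULL, gene_sets = NULL,
                         screen_p = 0.05, screen_q = 0.2,
                         min_carriers = 3, n_perm = 10000, seed = 1L) {
  empty <- function(reason) {
    out <- data.frame(gene = character(0), n_carriers = integer(0),
                      beta = numeric(0), t = numeric(0), p = numeric(0),
                      fwer_p = numeric(0), significant_fwer = logical(0))
    attr(out, "reason") <- reason
    out
  }
  universe <- colnames(gene_carriers)
  if (!is.null(geneset_results)) {
    if (is.null(gene_sets)) {
      stop_input("gene_sets must be supplied with geneset_results")
    }
    passing <- geneset_results$gene_set[
      !is.na(geneset_results$p) & geneset_results$p < screen_p &
        !is.na(geneset_results$q) & geneset_results$q < screen_q]
    if (length(passing) == 0L) {
      return(empty("no gene-set passed screening thresholds"))
    }
    universe <- intersect(universe,
                          unique(unlist(gene_sets[passing], use.names = FALSE)))
  }
  y <- phenotypes[[outcome]]
  keep <- !is.na(y)
  if (length(covariates) > 0L) {
    keep <- keep & stats::complete.cases(phenotypes[, covariates,
                                                    drop = FALSE])
  }
  X <- gene_carriers[keep, universe, drop = FALSE]
  y <- y[keep]
  carriers <- colSums(X)
  tested <- carriers >= min_carriers & carriers < nrow(X)
  if (!any(tested)) return(empty("no gene with enough carriers"))
  X <- X[, tested, drop = FALSE]
  carriers <- carriers[tested]

  covs <- if (length(covariates) > 0L) {
    stats::model.matrix(~ . - 1, data = phenotypes[keep, covariates,
                                                   drop = FALSE])
  } else {
    matrix(numeric(0), nrow = sum(keep), ncol = 0)
  }
  res <- residualize(y, X, covs)
  n <- length(res$y)
  df <- n - res$rank - 1L   # intercept+covariates, plus the gene term
  xs <- sqrt(colSums(res$X^2))
  degenerate <- xs < 1e-10
  if (any(degenerate)) {
    X <- X[, !degenerate, drop = FALSE]
    res$X <- res$X[, !degenerate, drop = FALSE]
    carriers <- carriers[!degenerate]
    xs <- xs[!degenerate]
  }
  if (ncol(res$X) == 0L) return(empty("all candidate genes collinear with covariates"))

  t_stats <- function(yr) {
    # t for the gene coefficient in the full model, via FWL on residuals
    ys <- sqrt(sum(yr^2))
    r <- as.vector(crossprod(res$X, yr)) / (xs * ys)
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r * sqrt(df) / sqrt(1 - r^2)
  }
  t_obs <- t_stats(res$y)
  beta <- as.vector(crossprod(res$X, res$y)) / xs^2
  p_obs <- 2 * stats::pt(-abs(t_obs), df)

  set.seed(seed)
  max_t <- vapply(seq_len(n_perm), function(b) {
    max(abs(t_stats(res$y[sample.int(n)])))
  }, numeric(1))
  fwer_p <- vapply(abs(t_obs), function(t0) {
    (1 + sum(max_t >= t0)) / (n_perm + 1)
  }, numeric(1))
  crit <- stats::quantile(max_t, 0.95, names = FALSE)

  out <- data.frame(gene = colnames(res$X), n_carriers = as.integer(carriers),
                    beta = beta, t = t_obs, p = p_obs, fwer_p = fwer_p,
                    significant_fwer = fwer_p < 0.05,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fwer_critical_t") <- crit
  attr(out, "n_perm") <- n_perm
  out
}

#' Sex-difference likelihood-ratio tests on CNV totals
#'
#' For each of the four burden totals (total deletion/duplication length
#' and deletion/duplication gene count), compares a covariate-only linear
#' model against one adding sex by a likelihood-ratio test (chi-square,
#' 1 df).
#'
#' @param bm a `burden_matrix`.
#' @param phenotypes data.frame with `participant_id`, `sex` and the
#'   covariate columns.
#' @param covariates covariate column names (e.g. PC1-PC3, plate, phase).
#' @return data.frame with one row per outcome: `outcome`, `statistic`,
#'   `df`, `p`, `note`.
#' @export
sex_burden_lrt <- function(bm, phenotypes, covariates = character()) {
  stopifnot(inherits(bm, "burden_matrix"))
  check_columns(phenotypes, c("participant_id", "sex", covariates),
                "phenotype table")
  m <- match(bm$counts$participant_id, phenotypes$participant_id)
  ph <- phenotypes[m, , drop = FALSE]
  outcomes <- c("total_length_DEL", "total_length_DUP",
                "total_gene_count_DEL", "total_gene_count_DUP")
  if (length(unique(ph$sex[!is.na(ph$sex)])) < 2L) {
    return(data.frame(outcome = outcomes, statistic = NA_real_,
                      df = NA_real_, p = NA_real_,
                      note = "single-sex cohort; skipped"))
  }
  rows <- lapply(outcomes, function(oc) {
    dat <- data.frame(y = bm$counts[[oc]], sex = factor(ph$sex))
    if (length(covariates) > 0L) {
      dat <- cbind(dat, ph[, covariates, drop = FALSE])
    }
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    full <- stats::lm(y ~ ., data = dat)
    red <- stats::lm(y ~ . - sex, data = dat)
    lt <- lmtest::lrtest(red, full)
    data.frame(outcome = oc, statistic = lt$Chisq[2], df = lt$Df[2],
               p = lt$`Pr(>Chisq)`[2], note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sex effect on a burden count (quasi-Poisson companion model)
#'
#' Gene counts per participant are compound-Poisson (a Poisson number of
#' CNVs each hitting a random number of genes) and hence overdispersed; a
#' quasi-Poisson log-link regression gives a calibrated interval for a
#' multiplicative sex effect on the expected count. This complements
#' [sex_burden_lrt()] (the hypothesis test on totals) when the estimand is
#' the rate ratio itself.
#'
#' @param counts non-negative count outcome (e.g. rare-deletion gene count).
#' @param sex factor/character sex; the coefficient reported is for the
#'   second level relative to the first.
#' @param covariates optional data.frame of covariates.
#' @return one-row association result: `estimate` is the log rate ratio
#'   with its 95% Wald CI.
#' @export
sex_burden_glm <- function(counts, sex, covariates = NULL) {
  sex <- factor(sex)
  if (nlevels(droplevels(sex)) < 2L) stop_input("need both sexes")
  dat <- data.frame(y = counts, sex = sex)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::glm(y ~ ., data = dat, family = quasipoisson())
  cf <- summary(fit)$coefficients
  term <- grep("^sex", rownames(cf), value = TRUE)[1]
  est <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  z <- stats::qnorm(0.975)
  association_result("sex_burden_glm", term, est, est - z * se,
                     est + z * se, cf[term, "t value"],
                     cf[term, "Pr(>|t|)"], n = nrow(dat),
                     method = "quasipoisson")
}
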