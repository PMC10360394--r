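# Carrier-phenotype association: 2x2 odds ratios with Woolf intervals,
# chi-square enrichment, per-disorder logistic models, carrier trait
# regressions and carrier demographic comparisons.

association_result <- function(analysis, term, estimate, ci_low, ci_high,
                               statistic, p, n, method, note = "") {
  data.frame(analysis = analysis, term = term, estimate = estimate,
             ci_low = ci_low, ci_high = ci_high, statistic = statistic,
             p = p, q = NA_real_, n = n, method = method, note = note,
             stringsAsFactors = FALSE)
}

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' The table is (a, b; c, d) = (carrier & outcome, carrier & no outcome;
#' non-carrier & outcome, non-carrier & no outcome). OR = ad / bc; the CI
#' is log-OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d) (Woolf). If any cell is
#' zero, 0.5 is added to every cell (Haldane-Anscombe) and the result is
#' flagged in `note`.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param alpha two-sided error level for the CI, default 0.05.
#' @return one-row association result data.frame with the OR as `estimate`,
#'   the Wald z as `statistic` and its two-sided p.
#' @export
odds_ratio_ci <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_input("2x2 cells must be non-negative counts")
  }
  if (sum(cells) == 0) stop_input("empty 2x2 table")
  note <- ""
  if (any(cells == 0)) {
    cells <- cells + 0.5
    note <- "continuity-corrected (0.5 added to all cells)"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  stat <- log(or) / se
  p <- 2 * stats::pnorm(-abs(stat))
  association_result("odds_ratio", "carrier", or, lo, hi, stat, p,
                     n = sum(c(a, b, c, d)), method = "woolf", note = note)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b,c,d cell counts as in [odds_ratio_ci()], or a 2x2 matrix
#'   passed as `a`.
#' @param correction apply Yates continuity correction, default `FALSE`.
#' @return one-row association result with the chi-square statistic (df = 1).
#' @export
chi_square <- function(a, b = NULL, c = NULL, d = NULL, correction = FALSE) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_input("degenerate 2x2 table: zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correction))
  association_result("chi_square", "independence",
                     estimate = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_,
                     statistic = unname(ct$statistic), p = ct$p.value,
                     n = sum(m),
                     method = if (correction) "pearson_yates" else "pearson")
}

#' Per-disorder logistic regression on carrier status
#'
#' Fits `diagnosis ~ carrier (+ covariates)` by logistic regression, where
#' `carrier` is a logical/0-1 indicator (e.g. clinically significant or
#' susceptibility CNV vs neither). Reports the carrier odds ratio with
#' Wald CI and p. Separated fits are flagged with no estimate.
#'
#' @param diagnosis 0/1 outcome vector.
#' @param carrier logical or 0/1 carrier indicator.
#' @param covariates optional data.frame of covariates.
#' @param min_n minimum case count; below it the fit is skipped, default 20.
#' @return one-row association result (estimate = odds ratio).
#' @export
disorder_logistic <- function(diagnosis, carrier, covariates = NULL,
                              min_n = 20) {
  carrier <- as.numeric(carrier)
  if (length(unique(carrier[!is.na(carrier)])) < 2L) {
    stop_input("carrier indicator is constant; no contrast to estimate")
  }
  if (sum(diagnosis, na.rm = TRUE) < min_n) {
    return(association_result("disorder_logistic", "carrier", NA_real_,
                              NA_real_, NA_real_, NA_real_, NA_real_,
                              n = sum(!is.na(diagnosis)),
                              method = "logistic_wald",
                              note = "skipped_min_n"))
  }
  dat <- data.frame(y = diagnosis, carrier = carrier)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = binomial()))
  cf <- summary(fit)$coefficients
  if (!fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
      cf["carrier", "Std. Error"] > 10) {
    return(association_result("disorder_logistic", "carrier", NA_real_,
                              NA_real_, NA_real_, NA_real_, NA_real_,
                              n = nrow(dat), method = "logistic_wald",
                              note = "separation"))
  }
  est <- cf["carrier", "Estimate"]
  se <- cf["carrier", "Std. Error"]
  z <- stats::qnorm(0.975)
  association_result("disorder_logistic", "carrier", exp(est),
                     exp(est - z * se), exp(est + z * se),
                     cf["carrier", "z value"], cf["carrier", "Pr(>|z|)"],
                     n = nrow(dat), method = "logistic_wald")
}

#' Carrier-group trait regression
#'
#' Linear regression of a (T-scored) trait on carrier group with `neither`
#' as the reference, optionally adjusting covariates (SSRT/RTV models
#' should include the stimulant-medication flag). Groups with fewer than
#' `min_group_n` scored members are flagged and skipped.
#'
#' @param trait numeric trait vector.
#' @param carrier_group factor/character with levels including `neither`
#'   (reference) and carrier groups (e.g. `significant`, `susceptibility`).
#' @param covariates optional data.frame of covariates.
#' @param min_group_n minimum scored members per carrier group, default 10.
#' @return association result data.frame, one row per carrier group.
#' @export
trait_group_regression <- function(trait, carrier_group, covariates = NULL,
                                   min_group_n = 10) {
  grp <- factor(as.character(carrier_group))
  if (!"neither" %in% levels(grp)) {
    stop_input("carrier_group must contain the reference level 'neither'")
  }
  grp <- stats::relevel(grp, ref = "neither")
  scored <- !is.na(trait)
  sizes <- table(grp[scored])
  groups <- setdiff(levels(grp), "neither")
  if (length(groups) == 0L || sum(scored) == 0L) {
    return(association_result("trait_regression", "none", NA_real_,
                              NA_real_, NA_real_, NA_real_, NA_real_,
                              n = sum(scored), method = "ols",
                              note = "reference-only cohort; skipped"))
  }
  usable <- groups[sizes[groups] >= min_group_n]
  skipped <- setdiff(groups, usable)
  rows <- list()
  for (g in skipped) {
    rows[[g]] <- association_result("trait_regression", g, NA_real_,
                                    NA_real_, NA_real_, NA_real_, NA_real_,
                                    n = unname(sizes[g]), method = "ols",
                                    note = "skipped_min_group_n")
  }
  if (length(usable) > 0L) {
    keep <- scored & grp %in% c("neither", usable)
    dat <- data.frame(y = trait[keep], grp = droplevels(grp[keep]))
    if (!is.null(covariates)) {
      dat <- cbind(dat, covariates[keep, , drop = FALSE])
    }
    fit <- stats::lm(y ~ ., data = dat)
    cf <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    for (g in usable) {
      term <- paste0("grp", g)
      rows[[g]] <- association_result(
        "trait_regression", g, cf[term, "Estimate"], ci[term, 1],
        ci[term, 2], cf[term, "t value"], cf[term, "Pr(>|t|)"],
        n = nrow(dat), method = "ols")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Carrier demographic comparisons
#'
#' Compares carrier groups on age (one-way ANOVA), sex and respondent
#' (chi-square). With fewer than two groups present each test is skipped
#' with a note.
#'
#' @param tiers participant tier table with `carrier_group`.
#' @param age numeric age in years (aligned with `tiers` rows).
#' @param sex sex factor/character.
#' @param respondent respondent factor/character (e.g. parent/self).
#' @return data.frame with one row per comparison: `variable`, `test`,
#'   `statistic`, `df`, `p`, `note`.
#' @export
carrier_demographics <- function(tiers, age, sex, respondent) {
  grp <- factor(tiers$carrier_group)
  row <- function(variable, test, statistic, df, p, note = "") {
    data.frame(variable = variable, test = test, statistic = statistic,
               df = df, p = p, note = note, stringsAsFactors = FALSE)
  }
  if (nlevels(droplevels(grp)) < 2L) {
    return(rbind(
      row("age", "anova", NA, NA, NA, "single group present; skipped"),
      row("sex", "chi_square", NA, NA, NA, "single group present; skipped"),
      row("respondent", "chi_square", NA, NA, NA,
          "single group present; skipped")))
  }
  fit <- stats::aov(age ~ grp)
  an <- summary(fit)[[1]]
  out <- row("age", "anova", an[1, "F value"], an[1, "Df"],
             an[1, "Pr(>F)"])
  for (v in c("sex", "respondent")) {
    x <- if (v == "sex") sex else respondent
    tab <- table(x, grp)
    if (any(dim(tab) < 2L)) {
      out <- rbind(out, row(v, "chi_square", NA, NA, NA,
                            "degenerate table; skipped"))
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out <- rbind(out, row(v, "chi_square", unname(ct$statistic),
                            unname(ct$parameter), ct$p.value))
    }
  }
  rownames(out) <- NULL
  out
}

#' Enrichment table from pre-tabulated 2x2 counts
#'
#' Computes odds ratios (Woolf CI) and chi-square p-values for a table of
#' printed 2x2 counts, one row per carrier-group x outcome combination,
#' e.g. published contingency tables of diagnosis/high-trait enrichment
#' among CNV carriers.
#'
#' @param counts data.frame with columns `group`, `outcome`, `a`, `b`, `c`,
#'   `d` (cells as in [odds_ratio_ci()]).
#' @return data.frame with `group`, `outcome`, `or`, `ci_low`, `ci_high`,
#'   `chisq_p`.
#' @export
enrichment_from_counts <- function(counts) {
  check_columns(counts, c("group", "outcome", "a", "b", "c", "d"),
                "2x2 count table")
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    orr <- odds_ratio_ci(counts$a[i], counts$b[i], counts$c[i], counts$d[i])
    chi <- chi_square(counts$a[i], counts$b[i], counts$c[i], counts$d[i])
    data.frame(group = counts$group[i], outcome = counts$outcome[i],
               or = orr$estimate, ci_low = orr$ci_low,
               ci_high = orr$ci_high, chisq_p = chi$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
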