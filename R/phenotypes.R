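# Phenotype harmonization: gender-adjusted T-scores, extreme-decile trait
# flags, composite indicators, small-cell exclusion and demographic models.

#' Gender-adjusted T-scores
#'
#' Standardizes raw trait scores within groups (typically gender, or
#' gender x study phase) to mean 50 and SD 10. Missing values stay missing
#' and do not contribute to the group moments.
#'
#' @param raw numeric vector of raw scores.
#' @param group grouping factor/vector (recycled checks apply).
#' @return numeric vector of T-scores.
#' @export
t_score <- function(raw, group) {
  if (length(raw) != length(group)) {
    stop_input("raw scores and grouping must have equal length")
  }
  out <- rep(NA_real_, length(raw))
  for (g in unique(group[!is.na(group)])) {
    idx <- which(group == g & !is.na(raw))
    if (length(idx) < 2L) {
      stop_input("group '%s' has fewer than 2 non-missing scores", g)
    }
    s <- stats::sd(raw[idx])
    if (s == 0) {
      stop_input("group '%s' has zero variance; T-scores are undefined", g)
    }
    out[idx] <- 50 + 10 * (raw[idx] - mean(raw[idx])) / s
  }
  out
}

#' Flag the most extreme trait scores
#'
#' Flags scores at or above the empirical `1 - quantile` quantile (default:
#' top 10%). Ties at the cutoff are all flagged. All listed study traits,
#' including SSRT and RTV, are higher-is-worse, so "extreme" means high;
#' `direction = "low"` is available for reversed instruments.
#'
#' @param scores numeric vector (typically T-scores).
#' @param quantile proportion flagged, default 0.10.
#' @param direction `"high"` (default) or `"low"`.
#' @return logical vector; missing scores give missing flags.
#' @export
flag_high_traits <- function(scores, quantile = 0.10,
                             direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (all(is.na(scores))) return(rep(NA, length(scores)))
  if (direction == "high") {
    cutoff <- stats::quantile(scores, probs = 1 - quantile, na.rm = TRUE,
                              names = FALSE, type = 7)
    scores >= cutoff
  } else {
    cutoff <- stats::quantile(scores, probs = quantile, na.rm = TRUE,
                              names = FALSE, type = 7)
    scores <= cutoff
  }
}

#' Exclude disorders with too few cases
#'
#' Per-disorder association models are unstable below a minimum case
#' count; disorders with total n below `min_n` (default 20) are dropped
#' from per-disorder analyses (they remain part of composite indicators).
#'
#' @param diagnoses either a data.frame of 0/1 diagnosis columns or a named
#'   numeric vector of case counts.
#' @param min_n minimum total case count, default 20.
#' @return character vector of retained disorder names, with the excluded
#'   names in attribute `"excluded"`.
#' @export
exclude_small_disorders <- function(diagnoses, min_n = 20) {
  counts <- if (is.data.frame(diagnoses)) {
    colSums(diagnoses == 1, na.rm = TRUE)
  } else {
    diagnoses
  }
  retained <- names(counts)[counts >= min_n]
  structure(retained, excluded = names(counts)[counts < min_n])
}

#' Per-disorder demographic logistic models
#'
#' Fits `diagnosis ~ age_group * gender` (age dichotomized at 12 years) by
#' logistic regression for each retained disorder, reporting Wald
#' coefficients and p-values. Fits showing separation (non-convergence or
#' exploding estimates) are flagged and report no coefficients.
#'
#' @param diagnoses data.frame of 0/1 diagnosis columns.
#' @param age numeric age in years.
#' @param gender factor/character gender ("M"/"F").
#' @param min_n disorders below this case count are skipped, default 20.
#' @param age_cut dichotomization age, default 12 years.
#' @return data.frame: one row per disorder x term, with `estimate`
#'   (log-odds), `se`, `p` and a `flag` column (`ok`, `separation`,
#'   `skipped_min_n`).
#' @export
demographic_models <- function(diagnoses, age, gender, min_n = 20,
                               age_cut = 12) {
  retained <- exclude_small_disorders(diagnoses, min_n)
  age_group <- factor(ifelse(age >= age_cut, "12plus", "under12"),
                      levels = c("under12", "12plus"))
  gender <- factor(gender)
  rows <- list()
  for (d in names(diagnoses)) {
    if (!d %in% retained) {
      rows[[d]] <- data.frame(disorder = d, term = NA_character_,
                              estimate = NA_real_, se = NA_real_,
                              p = NA_real_, flag = "skipped_min_n")
      next
    }
    fit <- suppressWarnings(
      stats::glm(diagnoses[[d]] ~ age_group * gender, family = binomial()))
    cf <- summary(fit)$coefficients
    separated <- !fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
      any(cf[, "Std. Error"] > 10)
    if (separated) {
      rows[[d]] <- data.frame(disorder = d, term = NA_character_,
                              estimate = NA_real_, se = NA_real_,
                              p = NA_real_, flag = "separation")
    } else {
      rows[[d]] <- data.frame(disorder = d, term = rownames(cf),
                              estimate = cf[, "Estimate"],
                              se = cf[, "Std. Error"],
                              p = cf[, "Pr(>|z|)"], flag = "ok")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score a phenotype table
#'
#' Convenience wrapper used by the pipeline: computes T-scores (within
#' gender, or gender x phase when a `phase` column is present) for every
#' `trait_*` column, top-decile high-trait flags, and composite indicators
#' `any_diagnosis` (over `dx_*` columns), `any_high_trait` and
#' `any_dx_or_high`.
#'
#' @param pheno data.frame with `participant_id`, `sex`, optional `phase`,
#'   diagnosis columns prefixed `dx_` and raw trait columns prefixed
#'   `trait_`.
#' @param quantile high-trait proportion, default 0.10.
#' @return `pheno` with added `tscore_*`, `high_*` and composite columns.
#' @export
score_phenotypes <- function(pheno, quantile = 0.10) {
  check_columns(pheno, c("participant_id", "sex"), "phenotype table")
  traits <- grep("^trait_", names(pheno), value = TRUE)
  dxs <- grep("^dx_", names(pheno), value = TRUE)
  grp <- if ("phase" %in% names(pheno)) {
    interaction(pheno$sex, pheno$phase, drop = TRUE)
  } else {
    pheno$sex
  }
  for (tr in traits) {
    t_col <- sub("^trait_", "tscore_", tr)
    h_col <- sub("^trait_", "high_", tr)
    pheno[[t_col]] <- t_score(pheno[[tr]], grp)
    pheno[[h_col]] <- flag_high_traits(pheno[[t_col]], quantile)
  }
  if (length(dxs) > 0L) {
    pheno$any_diagnosis <- rowSums(pheno[dxs] == 1, na.rm = TRUE) > 0
  } else {
    pheno$any_diagnosis <- FALSE
  }
  highs <- grep("^high_", names(pheno), value = TRUE)
  if (length(highs) > 0L) {
    pheno$any_high_trait <- rowSums(
      as.data.frame(lapply(pheno[highs], function(x) x %in% TRUE))) > 0
  } else {
    pheno$any_high_trait <- FALSE
  }
  pheno$any_dx_or_high <- pheno$any_diagnosis | pheno$any_high_trait
  pheno
}
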