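# Tiered clinical classification of consensus CNVs against a catalog of
# recurrent genomic-disorder loci, clinically significant genes and
# susceptibility genes.

#' Read a classification catalog
#'
#' The catalog is a TSV with columns `kind` (`recurrent_locus`,
#' `significant_gene`, `susceptibility_gene`), `name`, `chrom`, `start`,
#' `end` (loci only; 0-based half-open), `symbol` (gene entries only),
#' `required_type` (`DEL`, `DUP` or `any`) and `min_reciprocal_overlap`
#' (loci only; empty uses the default 0.5).
#'
#' @param path catalog TSV.
#' @return validated catalog data.frame.
#' @export
read_catalog <- function(path) {
  cat_df <- as.data.frame(fread(path, sep = "\t", na.strings = c("", "NA")))
  validate_catalog(cat_df)
}

validate_catalog <- function(cat_df) {
  check_columns(cat_df, c("kind", "name", "required_type"), "catalog")
  kinds <- c("recurrent_locus", "significant_gene", "susceptibility_gene")
  bad <- setdiff(unique(cat_df$kind), kinds)
  if (length(bad) > 0L) {
    stop_input("unknown catalog kind(s): %s", paste(bad, collapse = ", "))
  }
  if (!all(cat_df$required_type %in% c("DEL", "DUP", "any"))) {
    stop_input("catalog required_type must be DEL, DUP or any")
  }
  loci <- cat_df$kind == "recurrent_locus"
  if (any(loci)) {
    check_columns(cat_df, c("chrom", "start", "end"), "catalog")
    if (any(is.na(cat_df$start[loci])) || any(is.na(cat_df$end[loci]))) {
      stop_input("recurrent_locus catalog entries require coordinates")
    }
  }
  if (any(!loci)) {
    check_columns(cat_df, "symbol", "catalog")
    if (any(is.na(cat_df$symbol[!loci]))) {
      stop_input("gene catalog entries require a symbol")
    }
  }
  if (!"min_reciprocal_overlap" %in% names(cat_df)) {
    cat_df$min_reciprocal_overlap <- NA_real_
  }
  cat_df
}

#' Detect aneuploidies among CNV calls
#'
#' A call covering at least `span_fraction` (default 90%) of its chromosome
#' is labeled an aneuploidy; array calls rarely cover 100% of the assembly
#' length, hence the margin. Labels are karyotype-style where sex is known
#' (trisomy/monosomy for autosomes; 47,XXX / 45,X / 47,XYY / 47,XXY for
#' whole sex-chromosome events).
#'
#' @param calls call data.frame (`participant_id`, `chrom`, `start`, `end`,
#'   `type`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param sex optional named vector (participant id -> "M"/"F") used for
#'   sex-chromosome karyotype labels.
#' @param span_fraction minimum covered fraction of the chromosome.
#' @return input data.frame with logical `is_aneuploidy` and character
#'   `karyotype` columns.
#' @export
detect_aneuploidy <- function(calls, chrom_lengths, sex = NULL,
                              span_fraction = 0.9) {
  check_columns(calls, c("participant_id", "chrom", "start", "end", "type"),
                "call table")
  miss <- setdiff(unique(calls$chrom), names(chrom_lengths))
  if (length(miss) > 0L) {
    stop_input("missing chromosome length(s) for: %s",
               paste(miss, collapse = ", "))
  }
  clen <- chrom_lengths[as.character(calls$chrom)]
  frac <- (calls$end - calls$start) / clen
  calls$is_aneuploidy <- frac >= span_fraction
  kt <- rep(NA_character_, nrow(calls))
  idx <- which(calls$is_aneuploidy)
  for (i in idx) {
    chrom <- as.character(calls$chrom[i])
    ty <- calls$type[i]
    sx <- if (!is.null(sex)) {
      unname(sex[as.character(calls$participant_id[i])])
    } else NA_character_
    base <- sub("^chr", "", chrom)
    kt[i] <- if (base == "X") {
      if (ty == "DEL") "45,X"
      else if (identical(sx, "M")) "47,XXY" else "47,XXX"
    } else if (base == "Y") {
      if (ty == "DUP") "47,XYY" else "45,X"
    } else {
      if (ty == "DUP") paste0("trisomy ", base) else paste0("monosomy ", base)
    }
  }
  calls$karyotype <- kt
  calls
}

#' Classify consensus CNVs into clinical tiers
#'
#' Each call receives one tier by fixed precedence:
#' aneuploidy > recurrent (reciprocal overlap with a catalog locus at or
#' above the entry threshold, type matching) > non-recurrent clinically
#' significant (>= 1 bp overlap with a significant gene, type matching) >
#' susceptibility (overlap with a susceptibility gene, type matching) >
#' unclassified. Gene-symbol catalog entries are resolved to coordinates
#' through the gene annotation. Classification is idempotent and
#' deterministic.
#'
#' @param calls consensus, size-filtered call data.frame.
#' @param catalog catalog data.frame (see [read_catalog()]).
#' @param genes gene model data.frame used to resolve catalog gene symbols.
#' @param chrom_lengths named chromosome lengths (for aneuploidy detection).
#' @param sex optional participant sex lookup (see [detect_aneuploidy()]).
#' @param default_locus_ro default reciprocal-overlap threshold for locus
#'   entries without their own, default 0.5.
#' @return calls with `tier` (`aneuploidy`, `recurrent`, `non_recurrent`,
#'   `susceptibility`, `unclassified`), `clinically_significant` (logical),
#'   `matched_entry` and `karyotype` columns.
#' @export
classify_cnvs <- function(calls, catalog, genes, chrom_lengths, sex = NULL,
                          default_locus_ro = 0.5) {
  calls <- detect_aneuploidy(calls, chrom_lengths, sex = sex)
  catalog <- validate_catalog(catalog)
  n <- nrow(calls)
  tier <- ifelse(calls$is_aneuploidy, "aneuploidy", NA_character_)
  matched <- ifelse(calls$is_aneuploidy, calls$karyotype, NA_character_)

  type_ok <- function(req, ty) req == "any" | req == ty

  match_gene_entries <- function(entries, open) {
    hit_name <- rep(NA_character_, n)
    if (nrow(entries) == 0L || n == 0L) return(hit_name)
    sub <- merge(entries, genes, by = "symbol",
                 suffixes = c(".cat", ""))
    if (nrow(sub) == 0L) return(hit_name)
    for (j in seq_len(nrow(sub))) {
      ov <- calls$chrom == sub$chrom[j] &
        calls$start < sub$end[j] & sub$start[j] < calls$end &
        type_ok(sub$required_type[j], calls$type)
      new_hit <- open & ov & is.na(hit_name)
      hit_name[new_hit] <- sub$name[j]
    }
    hit_name
  }

  open <- is.na(tier)
  # recurrent genomic-disorder loci
  loci <- catalog[catalog$kind == "recurrent_locus", , drop = FALSE]
  if (nrow(loci) > 0L && any(open)) {
    for (j in seq_len(nrow(loci))) {
      thr <- loci$min_reciprocal_overlap[j]
      if (is.na(thr)) thr <- default_locus_ro
      same <- calls$chrom == loci$chrom[j] & type_ok(loci$required_type[j],
                                                    calls$type)
      if (!any(same & open)) next
      ro <- rep(0, n)
      idx <- which(same)
      ro[idx] <- reciprocal_overlap(calls$start[idx], calls$end[idx],
                                    loci$start[j], loci$end[j])
      hit <- open & ro >= thr
      tier[hit & is.na(tier)] <- "recurrent"
      matched[hit & is.na(matched)] <- loci$name[j]
    }
    open <- is.na(tier)
  }
  # non-recurrent clinically significant genes
  sig <- catalog[catalog$kind == "significant_gene", , drop = FALSE]
  hit <- match_gene_entries(sig, open)
  tier[open & !is.na(hit)] <- "non_recurrent"
  matched[is.na(matched) & !is.na(hit)] <- hit[is.na(matched) & !is.na(hit)]
  open <- is.na(tier)
  # susceptibility genes
  sus <- catalog[catalog$kind == "susceptibility_gene", , drop = FALSE]
  hit <- match_gene_entries(sus, open)
  tier[open & !is.na(hit)] <- "susceptibility"
  matched[is.na(matched) & !is.na(hit)] <- hit[is.na(matched) & !is.na(hit)]

  tier[is.na(tier)] <- "unclassified"
  calls$tier <- tier
  calls$clinically_significant <-
    tier %in% c("aneuploidy", "recurrent", "non_recurrent")
  calls$matched_entry <- matched
  calls
}

#' Summarize classified CNVs per participant
#'
#' Participants carrying at least one clinically significant CNV form the
#' `significant` group; of the rest, those carrying a susceptibility CNV
#' form the `susceptibility` group; everyone else is `neither`.
#' Participants carrying both kinds are counted under `significant`
#' (significant takes precedence), with both flags set so the overlap
#' remains auditable.
#'
#' @param classified_calls output of [classify_cnvs()].
#' @param cohort_ids all participant ids (non-carriers get `neither`).
#' @return data.frame with `participant_id`, `has_significant`,
#'   `has_susceptibility`, `carrier_group` and `n_classified_cnvs`.
#' @export
classify_participants <- function(classified_calls, cohort_ids) {
  check_columns(classified_calls, c("participant_id", "tier"),
                "classified call table")
  cohort_ids <- as.character(cohort_ids)
  dt <- as.data.table(classified_calls)
  per <- dt[, .(
    has_significant = any(tier %in% c("aneuploidy", "recurrent",
                                      "non_recurrent")),
    has_susceptibility = any(tier == "susceptibility"),
    n_classified_cnvs = sum(tier != "unclassified")
  ), by = participant_id]
  out <- data.table(participant_id = cohort_ids)
  m <- match(cohort_ids, per$participant_id)
  out$has_significant <- ifelse(is.na(m), FALSE, per$has_significant[m])
  out$has_susceptibility <- ifelse(is.na(m), FALSE,
                                   per$has_susceptibility[m])
  out$n_classified_cnvs <- ifelse(is.na(m), 0L, per$n_classified_cnvs[m])
  out$carrier_group <- ifelse(out$has_significant, "significant",
                       ifelse(out$has_susceptibility, "susceptibility",
                              "neither"))
  setDF(out)
}

#' Carrier prevalence summary
#'
#' Cohort-level rates of classified-CNV carriage, as percentages: either
#' group, clinically significant, susceptibility, and (optionally) the
#' share of carriers with a reported diagnosis or high trait.
#'
#' @param tiers participant tier table from [classify_participants()].
#' @param dx_or_high optional named logical vector (participant id ->
#'   any diagnosis or high trait).
#' @param digits rounding for the percentages, default 1.
#' @return named list of percentages and counts.
#' @export
prevalence_summary <- function(tiers, dx_or_high = NULL, digits = 1) {
  n <- nrow(tiers)
  carriers <- tiers$carrier_group != "neither"
  out <- list(
    n = n,
    n_carriers = sum(carriers),
    pct_carriers = round(100 * sum(carriers) / n, digits),
    n_significant = sum(tiers$carrier_group == "significant"),
    pct_significant = round(
      100 * sum(tiers$carrier_group == "significant") / n, digits),
    n_susceptibility = sum(tiers$carrier_group == "susceptibility"),
    pct_susceptibility = round(
      100 * sum(tiers$carrier_group == "susceptibility") / n, digits)
  )
  if (!is.null(dx_or_high)) {
    flag <- dx_or_high[as.character(tiers$participant_id[carriers])]
    out$n_carriers_dx_or_high <- sum(flag, na.rm = TRUE)
    out$pct_carriers_dx_or_high <- round(
      100 * sum(flag, na.rm = TRUE) / sum(carriers), digits)
  }
  out
}
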