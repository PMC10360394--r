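# End-to-end orchestration: simulate or load a cohort, run consensus ->
# classification -> phenotype scoring -> association -> burden, and write
# result tables, a JSON manifest and a markdown report.

#' Pipeline run configuration
#'
#' Either a simulation configuration or a set of input paths, plus all
#' analysis thresholds and the output directory.
#'
#' @param sim a [sim_config()] to generate the cohort, or `NULL` to read
#'   files from `paths`.
#' @param paths named list of input files (used when `sim` is `NULL`):
#'   `calls` (character vector of per-caller TSVs), `genes` (BED6 or GFF3),
#'   `gene_sets` (GMT), `catalog` (TSV), `chromosomes` (TSV with
#'   `chrom`/`length`), `phenotypes` (TSV), `covariates` (TSV).
#' @param min_callers,merge_ro,cluster_ro,size_floor consensus and
#'   frequency-annotation thresholds.
#' @param high_trait_quantile top-trait proportion, default 0.10.
#' @param min_n_disorder minimum case count for per-disorder models.
#' @param min_carriers minimum carriers per gene for locus tests.
#' @param n_perm permutations for the locus FWER, default 10000.
#' @param run_locus run the locus burden stage, default `TRUE`.
#' @param seed run seed (also seeds the permutations).
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, paths = NULL, min_callers = 2L,
                       merge_ro = 0.5, cluster_ro = 0.5,
                       size_floor = 10000, high_trait_quantile = 0.10,
                       min_n_disorder = 20, min_carriers = 3,
                       n_perm = 10000, run_locus = TRUE, seed = 1L,
                       out_dir = tempfile("cnvburden_run_")) {
  if (is.null(sim) && is.null(paths)) {
    stop_input("either a simulation config or input paths are required")
  }
  if (!is.null(paths)) {
    needed <- c("calls", "genes", "gene_sets", "catalog", "chromosomes",
                "phenotypes", "covariates")
    miss <- setdiff(needed, names(paths))
    if (length(miss) > 0L) {
      stop_input("paths is missing entries: %s", paste(miss, collapse = ", "))
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop_input("input file does not exist: %s", p)
    }
  }
  structure(list(sim = sim, paths = paths,
                 min_callers = as.integer(min_callers),
                 merge_ro = merge_ro, cluster_ro = cluster_ro,
                 size_floor = size_floor,
                 high_trait_quantile = high_trait_quantile,
                 min_n_disorder = min_n_disorder,
                 min_carriers = min_carriers, n_perm = as.integer(n_perm),
                 run_locus = run_locus, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    genome <- simulate_genome(config$sim)
    cohort <- simulate_cohort(config$sim, genome)
    list(genes = genome$genes, gene_sets = genome$gene_sets,
         catalog = genome$catalog,
         chrom_lengths = genome$chrom_lengths,
         calls = cohort$calls, phenotypes = cohort$phenotypes,
         causal_set = genome$causal_set)
  } else {
    p <- config$paths
    genes <- if (grepl("\\.gff3?$", p$genes)) {
      read_gff3_genes(p$genes)
    } else {
      read_bed_genes(p$genes)
    }
    chroms <- as.data.frame(fread(p$chromosomes, sep = "\t"))
    calls <- rbindlist(lapply(p$calls, fread, sep = "\t"))
    pheno <- as.data.frame(fread(p$phenotypes, sep = "\t"))
    covar <- as.data.frame(fread(p$covariates, sep = "\t"))
    pheno <- merge(pheno, covar, by = "participant_id", sort = TRUE)
    list(genes = genes, gene_sets = read_gmt(p$gene_sets),
         catalog = read_catalog(p$catalog),
         chrom_lengths = stats::setNames(chroms$length, chroms$chrom),
         calls = setDF(calls), phenotypes = pheno, causal_set = NULL)
  }
}

# 2x2 cells (a, b, c, d) for carrier group vs 'neither' on a logical outcome
group_2x2 <- function(group_flag, neither_flag, outcome) {
  ok <- !is.na(outcome)
  c(a = sum(group_flag & outcome & ok), b = sum(group_flag & !outcome & ok),
    c = sum(neither_flag & outcome & ok),
    d = sum(neither_flag & !outcome & ok))
}

#' Run the full CNV burden pipeline
#'
#' Executes simulate/load -> consensus merge -> size filter -> frequency
#' annotation and stratification -> tier classification -> phenotype
#' scoring -> carrier association -> burden analyses, writes one TSV per
#' result table plus `manifest.json` and `report.md` under the configured
#' output directory, and returns the result bundle invisibly. A fixed
#' seed yields byte-identical outputs across runs; stage failures abort
#' with the stage name, preserving earlier outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a `cnv_result_bundle` list of result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- with_stage("input", load_inputs(config))
  pheno <- inputs$phenotypes
  cohort_ids <- sort(unique(pheno$participant_id))
  n <- length(cohort_ids)

  consensus <- with_stage("consensus", {
    cons <- consensus_merge(inputs$calls,
                            consensus_policy(config$min_callers,
                                             config$merge_ro))
    cons <- size_filter(cons, config$size_floor)
    cons <- annotate_frequency(cons, n, config$cluster_ro)
    suppressWarnings(stratify_frequency(cons))
  })

  classified <- with_stage("classification", {
    sex_lookup <- stats::setNames(pheno$sex, pheno$participant_id)
    classify_cnvs(consensus, inputs$catalog, inputs$genes,
                  inputs$chrom_lengths, sex = sex_lookup)
  })
  tiers <- with_stage("classification",
                      classify_participants(classified, cohort_ids))

  scored <- with_stage("phenotype", {
    score_phenotypes(pheno, config$high_trait_quantile)
  })
  scored <- scored[match(cohort_ids, scored$participant_id), , drop = FALSE]
  tiers <- tiers[match(cohort_ids, tiers$participant_id), , drop = FALSE]

  prevalence <- prevalence_summary(
    tiers, stats::setNames(scored$any_dx_or_high, scored$participant_id))

  assoc <- with_stage("association", {
    grp <- tiers$carrier_group
    neither <- grp == "neither"
    outcomes <- list(reported_dx = scored$any_diagnosis,
                     high_traits = scored$any_high_trait,
                     dx_or_high = scored$any_dx_or_high)
    groups <- list(significant = grp == "significant",
                   susceptibility = grp == "susceptibility",
                   either = grp != "neither")
    enr <- list()
    for (gn in names(groups)) {
      for (on in names(outcomes)) {
        cells <- group_2x2(groups[[gn]], neither, outcomes[[on]])
        if (any(cells[c("a", "c")] + cells[c("b", "d")] == 0)) next
        orr <- odds_ratio_ci(cells["a"], cells["b"], cells["c"], cells["d"])
        chi <- tryCatch(
          chi_square(cells["a"], cells["b"], cells["c"], cells["d"]),
          error = function(e) NULL)
        enr[[paste(gn, on)]] <- data.frame(
          group = gn, outcome = on, a = cells["a"], b = cells["b"],
          c = cells["c"], d = cells["d"], or = orr$estimate,
          ci_low = orr$ci_low, ci_high = orr$ci_high,
          chisq_p = if (is.null(chi)) NA_real_ else chi$p)
      }
    }
    enrichment <- do.call(rbind, enr)
    rownames(enrichment) <- NULL

    dx_cols <- grep("^dx_", names(scored), value = TRUE)
    retained <- exclude_small_disorders(scored[dx_cols],
                                        config$min_n_disorder)
    either <- as.numeric(grp != "neither")
    dis <- lapply(dx_cols, function(d) {
      if (!d %in% retained) {
        return(data.frame(disorder = d, or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          note = "excluded_min_n"))
      }
      r <- disorder_logistic(scored[[d]], either,
                             min_n = config$min_n_disorder)
      data.frame(disorder = d, or = r$estimate, ci_low = r$ci_low,
                 ci_high = r$ci_high, p = r$p, note = r$note)
    })
    disorder_table <- do.call(rbind, dis)

    t_cols <- grep("^tscore_", names(scored), value = TRUE)
    tr <- lapply(t_cols, function(tc) {
      covs <- if (tc %in% c("tscore_ssrt", "tscore_rtv") &&
                  "stimulant" %in% names(scored)) {
        scored[, "stimulant", drop = FALSE]
      } else NULL
      r <- trait_group_regression(scored[[tc]], grp, covariates = covs)
      cbind(trait = tc, r)
    })
    trait_table <- do.call(rbind, tr)

    demo <- carrier_demographics(tiers, scored$age, scored$sex,
                                 scored$respondent)
    list(enrichment = enrichment, disorders = disorder_table,
         traits = trait_table, demographics = demo,
         retained_disorders = retained)
  })

  burden_res <- with_stage("burden", {
    bm <- build_burden_matrix(classified, inputs$genes, inputs$gene_sets,
                              cohort_ids)
    covs <- intersect(c("PC1", "PC2", "PC3", "batch", "platform"),
                      names(scored))
    glob <- list()
    gsets <- list()
    for (anc in unique(scored$ancestry)) {
      in_anc <- scored$ancestry == anc
      if (sum(in_anc) < 50) next
      dat <- cbind(scored[in_anc, , drop = FALSE],
                   bm$counts[in_anc, -1, drop = FALSE])
      for (tc in intersect(c("tscore_adhd", "tscore_inattention"),
                           names(dat))) {
        for (pred in c("gene_count_DEL_rare", "gene_count_DUP_rare",
                       "gene_count_DEL_less_rare",
                       "gene_count_DUP_less_rare")) {
          if (stats::var(dat[[pred]], na.rm = TRUE) == 0) next
          r <- tryCatch(global_burden(dat, tc, pred, covs),
                        error = function(e) NULL)
          if (is.null(r)) next
          glob[[paste(anc, tc, pred)]] <- cbind(ancestry = anc, trait = tc,
                                                r)
        }
      }
      bm_anc <- bm
      bm_anc$counts <- bm$counts[in_anc, , drop = FALSE]
      for (tc in intersect("tscore_adhd", names(scored))) {
        gs <- tryCatch(
          geneset_burden(bm_anc, scored[in_anc, , drop = FALSE], tc,
                         type = "DEL", stratum = "rare",
                         covariates = covs),
          error = function(e) NULL)
        if (is.null(gs)) next
        gsets[[paste(anc, tc)]] <- cbind(ancestry = anc, trait = tc, gs)
      }
    }
    global_table <- if (length(glob)) do.call(rbind, glob) else NULL
    geneset_table <- if (length(gsets)) do.call(rbind, gsets) else NULL

    sex_lrt <- sex_burden_lrt(bm, scored,
                              intersect(c("PC1", "PC2", "PC3", "batch",
                                          "phase"), names(scored)))

    locus <- NULL
    if (config$run_locus && !is.null(geneset_table)) {
      anc_main <- names(sort(table(scored$ancestry), decreasing = TRUE))[1]
      in_anc <- scored$ancestry == anc_main
      gs_main <- geneset_table[geneset_table$ancestry == anc_main, ]
      locus <- locus_burden(
        bm$gene_carriers$DEL[in_anc, , drop = FALSE],
        scored[in_anc, , drop = FALSE], "tscore_adhd",
        covariates = covs, geneset_results = gs_main,
        gene_sets = inputs$gene_sets,
        min_carriers = config$min_carriers, n_perm = config$n_perm,
        seed = config$seed)
    }
    list(matrix = bm, global = global_table, genesets = geneset_table,
         sex_lrt = sex_lrt, locus = locus)
  })

  bundle <- structure(list(
    config = config, n = n, consensus = consensus,
    classified = classified, tiers = tiers, prevalence = prevalence,
    phenotypes = scored, association = assoc, burden = burden_res
  ), class = "cnv_result_bundle")

  with_stage("output", {
    out <- config$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    fwrite(consensus, file.path(out, "consensus_calls.tsv"), sep = "\t")
    fwrite(classified, file.path(out, "classified_calls.tsv"), sep = "\t")
    fwrite(tiers, file.path(out, "participant_tiers.tsv"), sep = "\t")
    fwrite(assoc$enrichment, file.path(out, "enrichment.tsv"), sep = "\t")
    fwrite(assoc$disorders, file.path(out, "disorder_association.tsv"),
           sep = "\t")
    fwrite(assoc$traits, file.path(out, "trait_association.tsv"),
           sep = "\t")
    fwrite(assoc$demographics, file.path(out, "carrier_demographics.tsv"),
           sep = "\t")
    if (!is.null(burden_res$global)) {
      fwrite(burden_res$global, file.path(out, "global_burden.tsv"),
             sep = "\t")
    }
    if (!is.null(burden_res$genesets)) {
      fwrite(burden_res$genesets, file.path(out, "geneset_burden.tsv"),
             sep = "\t")
    }
    fwrite(burden_res$sex_lrt, file.path(out, "sex_burden_lrt.tsv"),
           sep = "\t")
    if (!is.null(burden_res$locus) && nrow(burden_res$locus) > 0) {
      fwrite(burden_res$locus, file.path(out, "locus_burden.tsv"),
             sep = "\t")
    }
    write_burden_matrix(burden_res$matrix,
                        file.path(out, "burden_matrix.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("cnvburden")),
      seed = config$seed,
      n_participants = n,
      thresholds = config[c("min_callers", "merge_ro", "cluster_ro",
                            "size_floor", "high_trait_quantile",
                            "min_n_disorder", "min_carriers", "n_perm")],
      simulated = !is.null(config$sim))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(make_report(bundle), file.path(out, "report.md"))
  })
  invisible(bundle)
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "-", formatC(x, digits = digits, format = "g"))
}

#' Render a markdown report for a pipeline result bundle
#'
#' Regeneration from the same bundle is idempotent (no timestamps).
#'
#' @param bundle a `cnv_result_bundle` from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "cnv_result_bundle"))
  lines <- c("# CNV burden pipeline report", "")
  if (bundle$n == 0) {
    return(c(lines, "Zero participants; no tables produced."))
  }
  pv <- bundle$prevalence
  lines <- c(lines, "## Cohort and carrier prevalence", "",
             sprintf("- Participants: %d", pv$n),
             sprintf("- Clinically significant carriers: %d (%.1f%%)",
                     pv$n_significant, pv$pct_significant),
             sprintf("- Susceptibility carriers: %d (%.1f%%)",
                     pv$n_susceptibility, pv$pct_susceptibility),
             sprintf("- Either: %d (%.1f%%)", pv$n_carriers,
                     pv$pct_carriers))
  if (!is.null(pv$pct_carriers_dx_or_high)) {
    lines <- c(lines, sprintf(
      "- Carriers with a diagnosis or high trait: %d (%.1f%%)",
      pv$n_carriers_dx_or_high, pv$pct_carriers_dx_or_high))
  }
  enr <- bundle$association$enrichment
  if (!is.null(enr) && nrow(enr) > 0) {
    lines <- c(lines, "", "## Diagnosis / high-trait enrichment", "",
               "| group | outcome | OR | 95% CI | chi-square p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.2f | %.2f-%.2f | %s |", enr$group,
                       enr$outcome, enr$or, enr$ci_low, enr$ci_high,
                       fmt_num(enr$chisq_p)))
  }
  dis <- bundle$association$disorders
  if (!is.null(dis) && nrow(dis) > 0) {
    lines <- c(lines, "", "## Per-disorder carrier association", "",
               "| disorder | OR | 95% CI | p | note |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s-%s | %s | %s |", dis$disorder,
                       fmt_num(dis$or), fmt_num(dis$ci_low),
                       fmt_num(dis$ci_high), fmt_num(dis$p), dis$note))
  }
  glob <- bundle$burden$global
  if (!is.null(glob) && nrow(glob) > 0) {
    lines <- c(lines, "", "## Global burden (per ancestry stratum)", "",
               "| ancestry | trait | predictor | beta | 95% CI | p |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s, %s | %s |",
                       glob$ancestry, glob$trait, glob$term,
                       fmt_num(glob$estimate), fmt_num(glob$ci_low),
                       fmt_num(glob$ci_high), fmt_num(glob$p)))
  }
  gs <- bundle$burden$genesets
  if (!is.null(gs) && nrow(gs) > 0) {
    top <- gs[order(gs$q), ][seq_len(min(10, nrow(gs))), ]
    lines <- c(lines, "", "## Gene-set burden (top sets by FDR)", "",
               "| ancestry | gene set | beta | p | q |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s |", top$ancestry,
                       top$gene_set, fmt_num(top$beta), fmt_num(top$p),
                       fmt_num(top$q)))
  }
  lines
}
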