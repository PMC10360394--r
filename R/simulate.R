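# Synthetic cohort generator: a fully specified genome, three pseudo-caller
# CNV tables, catalogs, phenotypes and covariates with known planted
# effects, so every downstream stage can be calibrated without restricted
# genotype data.

#' Simulation configuration
#'
#' Defaults emulate a two-ancestry pediatric community cohort: ~80/20
#' European/East Asian split, ~4% carriers of catalog-classified CNVs,
#' polymorphic CNV loci spanning the rare (<0.5%), less-rare (1-5%) and
#' common (>5%) frequency strata, CNV sizes log-uniform from the 10 kb
#' array resolution floor to 5 Mb, aneuploidies at 0.1%, and traits with
#' planted gene-burden effects. Identical configurations (including seed)
#' reproduce byte-identical cohorts.
#'
#' @param n_participants cohort size.
#' @param ancestry_fractions named proportions summing to 1.
#' @param n_genes number of genes placed on the synthetic genome (>= 10).
#' @param genome_length total genome length in bp, split over four
#'   autosomes and chromosome X.
#' @param cnv_rate mean background CNVs per participant (Poisson; split
#'   evenly between deletions and duplications).
#' @param size_range CNV length range in bp, log-uniform; minimum >= 10 kb.
#' @param polymorphic_loci data.frame (`chrom`, `start`, `end`, `type`,
#'   `frequency`) of recurrent polymorphic loci realized at their target
#'   population frequencies; `NULL` places three defaults spanning the
#'   rare/less-rare/common strata.
#' @param carrier_fraction_classified proportion of participants planted
#'   with a catalog-classified CNV.
#' @param planted_or odds ratio of diagnosis given classified-carrier
#'   status (> 0).
#' @param planted_beta per-gene trait effect of causal-set deletions
#'   (ADHD-trait analogue).
#' @param planted_beta_global per-gene trait effect of total rare-deletion
#'   burden (inattention analogue); separates the diffuse global estimand
#'   from the set-specific one.
#' @param caller_sensitivity named per-caller detection probabilities.
#' @param noise_sd residual SD of the continuous traits.
#' @param aneuploidy_rate probability of a whole-chromosome event.
#' @param sex_del_rate_multiplier multiplicative factor on the male
#'   deletion rate (1 = no sex difference).
#' @param n_gene_sets number of gene-sets emitted (including one designated
#'   causal set and organ-system negative-control sets).
#' @param causal_set_fraction fraction of genes in the causal set.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 7100,
                       ancestry_fractions = c(EUR = 0.8, EAS = 0.2),
                       n_genes = 800,
                       genome_length = 2.8e9,
                       cnv_rate = 3,
                       size_range = c(1e4, 5e6),
                       polymorphic_loci = NULL,
                       carrier_fraction_classified = 0.039,
                       planted_or = 1.9,
                       planted_beta = 0.15,
                       planted_beta_global = 0.15,
                       caller_sensitivity = c(penncnv = 0.85,
                                              quantisnp = 0.85,
                                              ipattern = 0.85),
                       noise_sd = 1,
                       aneuploidy_rate = 0.001,
                       sex_del_rate_multiplier = 1,
                       n_gene_sets = 10,
                       causal_set_fraction = 0.1,
                       seed = 1L) {
  if (n_participants <= 0 || n_genes <= 0 || genome_length <= 0) {
    stop_input("configuration error: counts must be positive")
  }
  if (abs(sum(ancestry_fractions) - 1) > 1e-8) {
    stop_input("configuration error: ancestry_fractions must sum to 1")
  }
  props <- c(carrier_fraction_classified, aneuploidy_rate,
             causal_set_fraction, caller_sensitivity)
  if (any(props < 0 | props > 1)) {
    stop_input("configuration error: proportions must lie in [0, 1]")
  }
  if (planted_or <= 0) stop_input("configuration error: planted_or must be > 0")
  if (size_range[1] < 1e4) {
    stop_input("configuration error: minimum CNV size must be >= 10 kb")
  }
  if (is.null(names(caller_sensitivity))) {
    stop_input("configuration error: caller_sensitivity must be named")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    ancestry_fractions = ancestry_fractions,
    n_genes = as.integer(n_genes),
    genome_length = genome_length,
    cnv_rate = cnv_rate,
    size_range = size_range,
    polymorphic_loci = polymorphic_loci,
    carrier_fraction_classified = carrier_fraction_classified,
    planted_or = planted_or,
    planted_beta = planted_beta,
    planted_beta_global = planted_beta_global,
    caller_sensitivity = caller_sensitivity,
    noise_sd = noise_sd,
    aneuploidy_rate = aneuploidy_rate,
    sex_del_rate_multiplier = sex_del_rate_multiplier,
    n_gene_sets = as.integer(n_gene_sets),
    causal_set_fraction = causal_set_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# log-uniform CNV lengths
runif_log <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Simulate the synthetic genome, gene-sets and catalogs
#'
#' Places non-overlapping genes on four autosomes plus chromosome X,
#' builds gene-sets (one designated causal set, organ-system negative
#' controls and random filler sets), default polymorphic loci and a
#' classification catalog (one recurrent genomic-disorder locus, one
#' clinically significant gene, one susceptibility gene).
#'
#' @param config a [sim_config()].
#' @return object of class `cnv_genome`: `chromosomes`, `chrom_lengths`,
#'   `genes`, `gene_sets` (with `causal_set` / `control_set` names),
#'   `catalog`, `polymorphic_loci`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 10L) stop_input("configuration error: n_genes must be >= 10")
  set.seed(config$seed)
  props <- c(chr1 = 0.27, chr2 = 0.23, chr3 = 0.18, chr4 = 0.14,
             chrX = 0.18)
  chrom_lengths <- round(config$genome_length * props)
  chromosomes <- data.frame(chrom = names(chrom_lengths),
                            length = unname(chrom_lengths),
                            stringsAsFactors = FALSE)

  # proportional allocation of genes, at least one per chromosome
  n_per <- pmax(1L, floor(config$n_genes * props))
  names(n_per) <- names(props)
  while (sum(n_per) < config$n_genes) {
    i <- which.max(chrom_lengths / n_per)
    n_per[i] <- n_per[i] + 1L
  }
  while (sum(n_per) > config$n_genes) {
    i <- which.max(n_per)
    n_per[i] <- n_per[i] - 1L
  }
  genes <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    k <- n_per[[ch]]
    slot <- floor(chrom_lengths[[ch]] / k)
    len <- round(pmin(stats::runif(k, 2e4, 2e5), 0.5 * slot))
    start <- (seq_len(k) - 1L) * slot +
      floor(stats::runif(k) * (slot - len - 1))
    data.table(chrom = ch, start = start, end = start + len,
               strand = sample(c("+", "-"), k, replace = TRUE))
  }))
  genes[, symbol := sprintf("G%04d", seq_len(nrow(genes)))]
  genes <- setDF(genes[, .(symbol, chrom, start, end, strand)])

  # gene-sets: one causal, negative-control organ-system sets, filler sets
  k_set <- max(3L, round(config$causal_set_fraction * config$n_genes))
  causal <- sort(sample(genes$symbol, k_set))
  control <- sort(sample(setdiff(genes$symbol, causal), k_set))
  set_names <- c("brain_expressed", "organ_system_cardiac",
                 "synaptic_pathway", "neuronal_behavior_mouse",
                 "nervous_system_mouse", "higher_mental_function",
                 "brain_protein_expression", "organ_system_renal",
                 "organ_system_immune", "organ_system_skeletal")
  if (config$n_gene_sets > length(set_names)) {
    set_names <- c(set_names,
                   sprintf("gene_set_%02d",
                           seq_len(config$n_gene_sets - length(set_names))))
  }
  set_names <- set_names[seq_len(max(2L, config$n_gene_sets))]
  gene_sets <- list()
  gene_sets[[set_names[1]]] <- causal
  gene_sets[[set_names[2]]] <- control
  for (nm in set_names[-(1:2)]) {
    gene_sets[[nm]] <- sort(sample(genes$symbol, k_set))
  }

  # catalog: recurrent locus on chr2 spanning two adjacent genes;
  # significant gene on chr1 (deletion-specific), susceptibility gene on
  # chr3 (type-agnostic); catalog genes kept out of the causal set so the
  # planted diagnosis and trait effects stay separable
  g2 <- which(genes$chrom == "chr2")
  ok_pair <- g2[!genes$symbol[g2] %in% causal &
                  !genes$symbol[pmin(g2 + 1L, max(g2))] %in% causal]
  i <- if (length(ok_pair) > 0L) {
    ok_pair[ceiling(length(ok_pair) / 2)]
  } else {
    g2[ceiling(length(g2) / 2)]
  }
  locus <- data.frame(kind = "recurrent_locus", name = "GD_chr2_locus",
                      chrom = "chr2", start = genes$start[i] - 1e4,
                      end = genes$end[min(i + 1L, max(g2))] + 1e4,
                      symbol = NA_character_, required_type = "any",
                      min_reciprocal_overlap = 0.5,
                      stringsAsFactors = FALSE)
  pick_gene <- function(ch) {
    cand <- genes$symbol[genes$chrom == ch & !genes$symbol %in% causal]
    if (length(cand) == 0L) cand <- genes$symbol[genes$chrom == ch]
    cand[ceiling(length(cand) / 2)]
  }
  sig_gene <- pick_gene("chr1")
  sus_gene <- pick_gene("chr3")
  gene_entry <- function(kind, name, sym, req) {
    data.frame(kind = kind, name = name, chrom = NA_character_,
               start = NA_real_, end = NA_real_, symbol = sym,
               required_type = req, min_reciprocal_overlap = NA_real_,
               stringsAsFactors = FALSE)
  }
  catalog <- rbind(locus,
                   gene_entry("significant_gene", sig_gene, sig_gene, "DEL"),
                   gene_entry("susceptibility_gene", sus_gene, sus_gene,
                              "any"))

  poly <- config$polymorphic_loci
  if (is.null(poly)) {
    # one locus per stratum: rare, less-rare, common
    pick_interval <- function(ch, width) {
      L <- chrom_lengths[[ch]]
      s <- floor(L * 0.7)
      data.frame(chrom = ch, start = s, end = s + width)
    }
    poly <- rbind(
      cbind(pick_interval("chr1", 8e4), type = "DEL", frequency = 0.002),
      cbind(pick_interval("chr3", 1.2e5), type = "DEL", frequency = 0.03),
      cbind(pick_interval("chr4", 6e4), type = "DUP", frequency = 0.08))
  }

  structure(list(chromosomes = chromosomes, chrom_lengths = chrom_lengths,
                 genes = genes, gene_sets = gene_sets,
                 causal_set = set_names[1], control_set = set_names[2],
                 catalog = catalog, polymorphic_loci = poly,
                 config = config),
            class = "cnv_genome")
}

#' Simulate a cohort: per-caller CNV tables, phenotypes and covariates
#'
#' Draws background CNVs (Poisson per participant, log-uniform sizes),
#' realizes polymorphic loci at their target frequencies, plants
#' catalog-classified CNVs in a `carrier_fraction_classified` share of
#' participants and whole-chromosome aneuploidies at `aneuploidy_rate`;
#' every true CNV is emitted independently by each pseudo-caller with its
#' configured sensitivity and small boundary jitter, so two-of-three
#' consensus recovers it. Traits carry the planted per-gene deletion
#' effects plus small PC1 and batch effects and Gaussian noise; diagnoses
#' are Bernoulli with the planted carrier odds ratio on the logit scale.
#'
#' @param config a [sim_config()] (the same one used for the genome).
#' @param genome output of [simulate_genome()].
#' @return object of class `cnv_cohort`: `calls` (per-caller long table),
#'   `true_cnvs`, `phenotypes` (diagnoses `dx_*`, raw traits `trait_*`,
#'   covariates), and `truth` (carrier flags and true burden counts).
#' @export
simulate_cohort <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "cnv_genome"))
  set.seed(config$seed + 1L)
  n <- config$n_participants
  ids <- sprintf("P%05d", seq_len(n))
  chrom_lengths <- genome$chrom_lengths
  autosomes <- setdiff(names(chrom_lengths), c("chrX", "chrY"))

  ancestry <- sample(names(config$ancestry_fractions), n, replace = TRUE,
                     prob = config$ancestry_fractions)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  pheno <- data.frame(
    participant_id = ids, ancestry = ancestry,
    PC1 = stats::rnorm(n) + 2 * (ancestry != names(config$ancestry_fractions)[1]),
    PC2 = stats::rnorm(n), PC3 = stats::rnorm(n),
    batch = sample(c("batch1", "batch2"), n, replace = TRUE),
    platform = sample(c("coreexome", "gsa"), n, replace = TRUE,
                      prob = c(0.735, 0.265)),
    phase = sample(c("phase1", "phase2"), n, replace = TRUE,
                   prob = c(0.7, 0.3)),
    age = round(stats::runif(n, 4, 18), 1), sex = sex,
    respondent = sample(c("parent", "self"), n, replace = TRUE,
                        prob = c(0.84, 0.16)),
    stringsAsFactors = FALSE
  )

  # --- background CNVs -------------------------------------------------
  lam_del <- config$cnv_rate / 2 *
    ifelse(sex == "M", config$sex_del_rate_multiplier, 1)
  lam_dup <- rep(config$cnv_rate / 2, n)
  draw_background <- function(counts, type) {
    total <- sum(counts)
    if (total == 0L) return(NULL)
    pid <- rep(ids, counts)
    chrom <- sample(names(chrom_lengths), total, replace = TRUE,
                    prob = chrom_lengths)
    len <- round(runif_log(total, config$size_range[1],
                           config$size_range[2]))
    len <- pmin(len, floor(0.5 * chrom_lengths[chrom]))
    start <- floor(stats::runif(total) * (chrom_lengths[chrom] - len))
    data.table(participant_id = pid, chrom = chrom, start = start,
               end = start + len, type = type, origin = "background",
               locus = NA_character_)
  }
  true_list <- list(
    draw_background(stats::rpois(n, lam_del), "DEL"),
    draw_background(stats::rpois(n, lam_dup), "DUP")
  )

  # --- polymorphic loci ------------------------------------------------
  poly <- genome$polymorphic_loci
  for (j in seq_len(nrow(poly))) {
    carr <- which(stats::rbinom(n, 1, poly$frequency[j]) == 1)
    if (length(carr) == 0L) next
    len <- poly$end[j] - poly$start[j]
    shift <- round(stats::runif(length(carr), -0.02, 0.02) * len)
    true_list[[length(true_list) + 1L]] <- data.table(
      participant_id = ids[carr], chrom = poly$chrom[j],
      start = poly$start[j] + shift, end = poly$end[j] + shift,
      type = poly$type[j], origin = "polymorphic",
      locus = sprintf("poly_%d", j))
  }

  # --- classified (catalog) CNVs --------------------------------------
  carrier <- stats::rbinom(n, 1, config$carrier_fraction_classified) == 1
  carr_idx <- which(carrier)
  if (length(carr_idx) > 0L) {
    cls <- sample(c("recurrent", "significant", "susceptibility"),
                  length(carr_idx), replace = TRUE,
                  prob = c(0.17, 0.13, 0.70))
    cat_df <- genome$catalog
    locus <- cat_df[cat_df$kind == "recurrent_locus", ][1, ]
    sig <- cat_df[cat_df$kind == "significant_gene", ][1, ]
    sus <- cat_df[cat_df$kind == "susceptibility_gene", ][1, ]
    g <- genome$genes
    sig_g <- g[g$symbol == sig$symbol, ]
    sus_g <- g[g$symbol == sus$symbol, ]
    rows <- lapply(seq_along(carr_idx), function(k) {
      i <- carr_idx[k]
      if (cls[k] == "recurrent") {
        len <- locus$end - locus$start
        shift <- round(stats::runif(1, -0.02, 0.02) * len)
        data.table(participant_id = ids[i], chrom = locus$chrom,
                   start = locus$start + shift, end = locus$end + shift,
                   type = sample(c("DEL", "DUP"), 1),
                   origin = "classified", locus = locus$name)
      } else {
        gg <- if (cls[k] == "significant") sig_g else sus_g
        ty <- if (cls[k] == "significant") "DEL" else sample(c("DEL", "DUP"), 1)
        ext_l <- round(stats::runif(1, 1e4, 6e4))
        ext_r <- round(stats::runif(1, 1e4, 6e4))
        data.table(participant_id = ids[i], chrom = gg$chrom,
                   start = max(0, gg$start - ext_l), end = gg$end + ext_r,
                   type = ty, origin = "classified", locus = gg$symbol)
      }
    })
    true_list[[length(true_list) + 1L]] <- rbindlist(rows)
  }

  # --- aneuploidies ----------------------------------------------------
  aneu <- which(stats::rbinom(n, 1, config$aneuploidy_rate) == 1)
  if (length(aneu) > 0L) {
    chroms <- sample(c(autosomes[length(autosomes)], "chrX"),
                     length(aneu), replace = TRUE)
    true_list[[length(true_list) + 1L]] <- data.table(
      participant_id = ids[aneu], chrom = chroms, start = 0,
      end = unname(chrom_lengths[chroms]),
      type = sample(c("DEL", "DUP"), length(aneu), replace = TRUE),
      origin = "aneuploidy", locus = chroms)
    carrier[aneu] <- TRUE  # aneuploidy is clinically significant
  }

  true_cnvs <- rbindlist(true_list, use.names = TRUE)
  setorder(true_cnvs, participant_id, chrom, start, end, type)

  # --- caller emission -------------------------------------------------
  callers <- names(config$caller_sensitivity)
  m <- nrow(true_cnvs)
  call_list <- lapply(callers, function(cl) {
    det <- stats::rbinom(m, 1, config$caller_sensitivity[[cl]]) == 1
    sub <- true_cnvs[det]
    if (nrow(sub) == 0L) return(NULL)
    len <- sub$end - sub$start
    js <- round(stats::runif(nrow(sub), -0.02, 0.02) * len)
    je <- round(stats::runif(nrow(sub), -0.02, 0.02) * len)
    start <- pmax(0, sub$start + js)
    end <- pmin(unname(chrom_lengths[sub$chrom]), sub$end + je)
    bad <- end <= start
    end[bad] <- start[bad] + len[bad]
    data.table(participant_id = sub$participant_id, chrom = sub$chrom,
               start = start, end = end, type = sub$type, caller = cl)
  })
  calls <- rbindlist(call_list)
  setorder(calls, participant_id, chrom, start, end, type, caller)

  # --- true burden counts used to generate traits ----------------------
  # Planted continuous effects act on a-priori rare deletions: background,
  # aneuploidy and polymorphic loci with target frequency < 0.5%.
  # Classified CNVs drive the diagnosis effect instead, so the two planted
  # estimands stay separable.
  rare_poly <- sprintf("poly_%d", which(poly$frequency < 0.005))
  qual <- true_cnvs[type == "DEL" &
                      (origin %in% c("background", "aneuploidy") |
                         (origin == "polymorphic" & locus %in% rare_poly))]
  ovq <- overlap_calls_genes(qual, genome$genes)
  causal_syms <- genome$gene_sets[[genome$causal_set]]
  count_distinct <- function(sub) {
    if (nrow(sub) == 0L) return(stats::setNames(integer(0), character(0)))
    tab <- unique(data.table(pid = qual$participant_id[sub$call_row],
                             symbol = sub$symbol))
    cnt <- tab[, .N, by = pid]
    stats::setNames(cnt$N, cnt$pid)
  }
  causal_n <- count_distinct(ovq[symbol %in% causal_syms])
  total_n <- count_distinct(ovq)
  causal_count <- unname(causal_n[ids]); causal_count[is.na(causal_count)] <- 0
  total_count <- unname(total_n[ids]); total_count[is.na(total_count)] <- 0

  # --- diagnoses and traits -------------------------------------------
  lo <- log(config$planted_or)
  dx_rate <- function(base, effect) {
    stats::rbinom(n, 1, stats::plogis(stats::qlogis(base) + effect * carrier))
  }
  pheno$dx_adhd <- dx_rate(0.067, lo)
  pheno$dx_anxiety <- dx_rate(0.045, 0.5 * lo)
  pheno$dx_asd <- dx_rate(0.02, lo)
  pheno$dx_learning <- dx_rate(0.091, 0.5 * lo)
  pheno$dx_mood <- dx_rate(0.014, 0)
  pheno$dx_ocd <- dx_rate(0.011, 0)
  pheno$dx_tics <- dx_rate(0.012, 0)
  pheno$dx_eating_disorder <- dx_rate(4e-4, 0)
  pheno$dx_language_disorder <- dx_rate(8e-4, 0)
  pheno$dx_schizophrenia <- dx_rate(9e-4, 0)
  pheno$stimulant <- stats::rbinom(n, 1,
                                   stats::plogis(-5 + 4 * pheno$dx_adhd))

  b_cov <- 0.1 * pheno$PC1 + 0.05 * (pheno$batch == "batch2")
  noise <- function(sd = config$noise_sd) stats::rnorm(n, 0, sd)
  pheno$trait_adhd <- config$planted_beta * causal_count + b_cov + noise()
  pheno$trait_inattention <- config$planted_beta_global * total_count +
    b_cov + noise()
  pheno$trait_hyperactivity <- 0.5 * config$planted_beta * causal_count +
    b_cov + noise()
  pheno$trait_ocd <- 0.05 * pheno$PC1 + noise()
  pheno$trait_anxiety <- 0.1 * pheno$PC1 + noise()
  pheno$trait_ssrt <- 250 + 10 * pheno$PC1 - 15 * pheno$stimulant +
    noise(40)
  pheno$trait_rtv <- 80 + 5 * pheno$PC1 - 5 * pheno$stimulant + noise(15)

  structure(list(
    calls = setDF(calls), true_cnvs = setDF(true_cnvs),
    phenotypes = pheno,
    truth = list(carrier = stats::setNames(carrier, ids),
                 causal_count = stats::setNames(causal_count, ids),
                 total_count = stats::setNames(total_count, ids),
                 planted_or = config$planted_or,
                 planted_beta = config$planted_beta,
                 planted_beta_global = config$planted_beta_global,
                 sex_del_rate_multiplier = config$sex_del_rate_multiplier)
  ), class = "cnv_cohort")
}

#' Write a simulated genome and cohort to plain-text files
#'
#' Emits genes as BED6 (0-based half-open), gene-sets as GMT, the catalog,
#' chromosome table and polymorphic loci as TSV, one CNV call table per
#' caller, and phenotype/covariate TSVs.
#'
#' @param genome a `cnv_genome`.
#' @param cohort a `cnv_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(genome, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- genome$genes
  bed <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                    name = g$symbol, score = 0L, strand = g$strand)
  fwrite(bed, file.path(dir, "genes.bed"), sep = "\t", col.names = FALSE)
  write_gmt(genome$gene_sets, file.path(dir, "gene_sets.gmt"))
  fwrite(genome$catalog, file.path(dir, "catalog.tsv"), sep = "\t")
  fwrite(genome$chromosomes, file.path(dir, "chromosomes.tsv"), sep = "\t")
  fwrite(genome$polymorphic_loci, file.path(dir, "polymorphic_loci.tsv"),
         sep = "\t")
  for (cl in unique(cohort$calls$caller)) {
    fwrite(cohort$calls[cohort$calls$caller == cl, ],
           file.path(dir, sprintf("calls_%s.tsv", cl)), sep = "\t")
  }
  ph <- cohort$phenotypes
  pheno_cols <- c("participant_id", grep("^dx_|^trait_|^stimulant$",
                                         names(ph), value = TRUE))
  cov_cols <- setdiff(names(ph), setdiff(pheno_cols, "participant_id"))
  fwrite(ph[pheno_cols], file.path(dir, "phenotypes.tsv"), sep = "\t")
  fwrite(ph[cov_cols], file.path(dir, "covariates.tsv"), sep = "\t")
  invisible(dir)
}
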