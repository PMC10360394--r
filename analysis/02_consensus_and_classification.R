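#!/usr/bin/env Rscript
# Step 2: consensus calling, frequency annotation and tier classification.
#
# Reads the per-caller tables from step 1, merges them into two-of-three
# consensus events (50% reciprocal overlap, union coordinates), applies
# the 10 kb size floor, annotates cohort frequency by cross-participant
# reciprocal-overlap clustering, stratifies by rarity and classifies each
# event against the catalog. Writes the consensus and classified call
# tables and the per-participant tier table.

suppressMessages(library(cnvburden))

dir_in <- "results/analysis/cohort"
dir_out <- "results/analysis"
stopifnot(dir.exists(dir_in))

calls <- do.call(rbind, lapply(
  list.files(dir_in, pattern = "^calls_", full.names = TRUE),
  read.delim))
genes <- read_bed_genes(file.path(dir_in, "genes.bed"))
catalog <- read_catalog(file.path(dir_in, "catalog.tsv"))
chroms <- read.delim(file.path(dir_in, "chromosomes.tsv"))
covar <- read.delim(file.path(dir_in, "covariates.tsv"))
n <- nrow(covar)

cons <- consensus_merge(calls)
cat(sprintf("consensus: %d caller calls -> %d events (>=2 callers)\n",
            nrow(calls), nrow(cons)))
cons <- size_filter(cons)
cons <- annotate_frequency(cons, n)
cons <- stratify_frequency(cons)
print(table(cons$stratum))

classified <- classify_cnvs(cons, catalog, genes,
                            setNames(chroms$length, chroms$chrom),
                            sex = setNames(covar$sex,
                                           covar$participant_id))
cat("tiers among consensus events:\n")
print(table(classified$tier))

tiers <- classify_participants(classified, covar$participant_id)
pv <- prevalence_summary(tiers)
cat(sprintf(
  "carriers: %.1f%% either (%.1f%% clinically significant, %.1f%% susceptibility)\n",
  pv$pct_carriers, pv$pct_significant, pv$pct_susceptibility))

write.table(cons, file.path(dir_out, "consensus_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(classified, file.path(dir_out, "classified_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tiers, file.path(dir_out, "participant_tiers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
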