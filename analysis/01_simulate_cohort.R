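#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Emulates a two-ancestry (80/20) pediatric community cohort with ~4%
# carriers of catalog-classified CNVs, polymorphic CNV loci spanning the
# rare / less-rare / common frequency strata, three pseudo-callers at 85%
# sensitivity each, and planted effects: a carrier-diagnosis odds ratio
# of 1.9 and per-gene deletion effects of 0.15 on the ADHD-trait and
# inattention analogues. Writes the plain-text cohort (BED/GMT/TSV) that
# the later steps consume.

suppressMessages(library(cnvburden))

out_dir <- "results/analysis/cohort"
cfg <- sim_config(n_participants = 2000, seed = 101L)
genome <- simulate_genome(cfg)
cohort <- simulate_cohort(cfg, genome)
write_cohort(genome, cohort, out_dir)

cat(sprintf("cohort: %d participants, %d true CNVs, %d caller calls\n",
            cfg$n_participants, nrow(cohort$true_cnvs),
            nrow(cohort$calls)))
cat(sprintf("planted: carrier OR %.2f, set beta %.2f, global beta %.2f\n",
            cfg$planted_or, cfg$planted_beta, cfg$planted_beta_global))
cat(sprintf("true classified-carrier fraction: %.3f\n",
            mean(cohort$truth$carrier)))
cat("files written to", out_dir, "\n")
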