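genes <- tiny_genes()

test_that("genes_hit uses >= 1 bp overlap with half-open boundaries", {
  expect_equal(genes_hit(list(chrom = "chr1", start = 0, end = 10000), genes),
               "GA")
  # touching at the boundary shares no base
  expect_equal(genes_hit(list(chrom = "chr1", start = 10000, end = 20000),
                         genes), character(0))
  # spanning call hits all three chr1 genes
  expect_equal(genes_hit(list(chrom = "chr1", start = 0, end = 60000), genes),
               c("GA", "GB", "GC"))
})

strat_calls <- function(...) {
  df <- make_calls(...)
  df$caller <- NULL
  df$stratum <- "rare"
  df
}

test_that("burden matrix counts distinct genes per participant", {
  calls <- strat_calls(
    list("P1", "chr1", 0, 25000, "DEL"),     # GA, GB
    list("P1", "chr1", 25000, 60000, "DEL"), # GB, GC -> distinct {GA,GB,GC}
    list("P2", "chr2", 0, 10000, "DUP"))     # GD
  bm <- build_burden_matrix(calls, genes, list(), c("P1", "P2", "P3"))
  cnt <- bm$counts
  expect_equal(cnt$gene_count_DEL_rare[cnt$participant_id == "P1"], 3)
  expect_equal(cnt$gene_count_DUP_rare[cnt$participant_id == "P2"], 1)
  # non-carrier row is all zero
  p3 <- cnt[cnt$participant_id == "P3", -1]
  expect_true(all(p3 == 0))
  # per-gene indicators are binary and match
  expect_equal(unname(bm$gene_carriers$DEL["P1", c("GA", "GB", "GC")]),
               c(1L, 1L, 1L))
  expect_equal(sum(bm$gene_carriers$DUP), 1L)
})

test_that("common-stratum calls are excluded and unknown participants error", {
  calls <- strat_calls(list("P1", "chr1", 0, 25000, "DEL"))
  calls$stratum <- "common"
  bm <- build_burden_matrix(calls, genes, list(), c("P1"))
  expect_true(all(bm$counts[, -1] == 0))
  bad <- strat_calls(list("P9", "chr1", 0, 25000, "DEL"))
  expect_error(build_burden_matrix(bad, genes, list(), c("P1")),
               "not in cohort ids")
})

test_that("gene-set counts respect membership and the set-sum bound", {
  calls <- strat_calls(
    list("P1", "chr1", 0, 60000, "DEL"),  # GA GB GC
    list("P1", "chr2", 0, 70000, "DEL"))  # GD GE
  sets <- list(sA = c("GA", "GB"), sB = c("GC", "GD", "GE"),
               sX = c("GX1", "GX2"))
  bm <- build_burden_matrix(calls, genes, sets, "P1")
  cnt <- bm$counts
  expect_equal(cnt$set.sA_DEL_rare, 2)
  expect_equal(cnt$set.sB_DEL_rare, 3)
  expect_equal(cnt$set.sX_DEL_rare, 0)
  # sA, sB, sX partition the annotation: per-set counts sum to the total
  expect_equal(cnt$set.sA_DEL_rare + cnt$set.sB_DEL_rare +
                 cnt$set.sX_DEL_rare, cnt$total_gene_count_DEL)
  # set counts never exceed the matching global count
  expect_true(all(cnt$set.sB_DEL_rare <= cnt$gene_count_DEL_rare))
})

test_that("burden matrix matches exhaustive brute-force recount", {
  set.seed(21)
  ids <- sprintf("P%d", 1:6)
  calls <- do.call(rbind, lapply(1:20, function(i) {
    ch <- sample(c("chr1", "chr2", "chrX"), 1)
    s <- sample.int(6e4, 1)
    data.frame(participant_id = sample(ids, 1), chrom = ch, start = s,
               end = s + sample.int(4e4, 1),
               type = sample(c("DEL", "DUP"), 1),
               stratum = sample(c("rare", "less_rare"), 1))
  }))
  bm <- build_burden_matrix(calls, genes, list(), ids)
  for (ty in c("DEL", "DUP")) {
    for (st in c("rare", "less_rare")) {
      want <- brute_gene_counts(calls, genes, ids, ty, st)
      col <- sprintf("gene_count_%s_%s", ty, st)
      expect_equal(setNames(bm$counts[[col]], bm$counts$participant_id),
                   want)
    }
  }
  # total lengths match direct summation
  for (ty in c("DEL", "DUP")) {
    want <- vapply(ids, function(pid) {
      sub <- calls[calls$participant_id == pid & calls$type == ty, ]
      sum(sub$end - sub$start)
    }, numeric(1))
    expect_equal(setNames(bm$counts[[paste0("total_length_", ty)]],
                          bm$counts$participant_id), want)
  }
})

test_that("adding a call never decreases any burden entry", {
  set.seed(33)
  ids <- sprintf("P%d", 1:4)
  base <- strat_calls(
    list("P1", "chr1", 0, 30000, "DEL"),
    list("P2", "chr2", 0, 60000, "DUP"))
  extra <- strat_calls(list("P1", "chr2", 40000, 71000, "DEL"))
  bm0 <- build_burden_matrix(base, genes, list(sA = c("GA", "GE")), ids)
  bm1 <- build_burden_matrix(rbind(base, extra), genes,
                             list(sA = c("GA", "GE")), ids)
  num0 <- as.matrix(bm0$counts[, -1]); num1 <- as.matrix(bm1$counts[, -1])
  expect_true(all(num1 >= num0))
})

test_that("X-subset counts only X-linked genes and is bounded by the global", {
  calls <- strat_calls(
    list("P1", "chrX", 0, 35000, "DEL"),   # GX1, GX2
    list("P1", "chr1", 0, 30000, "DEL"))   # GA, GB (not X)
  bmx <- subset_chromosome_x(calls, genes, list(), c("P1", "P2"))
  bm <- build_burden_matrix(calls, genes, list(), c("P1", "P2"))
  expect_equal(bmx$counts$gene_count_DEL_rare, c(2, 0))
  expect_true(all(bmx$counts$gene_count_DEL_rare <=
                    bm$counts$gene_count_DEL_rare))
  # all-autosomal annotation gives zero gene counts throughout
  bmx0 <- subset_chromosome_x(calls, genes[genes$chrom != "chrX", ],
                              list(), c("P1", "P2"))
  gc_cols <- grep("gene_count", names(bmx0$counts), value = TRUE)
  expect_true(all(bmx0$counts[gc_cols] == 0))
})

test_that("GMT and BED round-trips preserve content", {
  sets <- list(alpha = c("GA", "GB"), beta = c("GC"))
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_equal(read_gmt(gmt), sets)

  bed <- tempfile(fileext = ".bed")
  g <- tiny_genes()
  write.table(data.frame(g$chrom, g$start, g$end, g$symbol, 0, g$strand),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- read_bed_genes(bed)
  expect_equal(back[c("symbol", "chrom", "start", "end")],
               g[c("symbol", "chrom", "start", "end")])
})
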