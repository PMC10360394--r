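chrom_lengths <- c(chr1 = 1e6, chr2 = 8e5, chr21 = 4.7e7, chrX = 6e5,
                   chrY = 2e5)

toy_catalog <- function() {
  data.frame(
    kind = c("recurrent_locus", "significant_gene", "susceptibility_gene"),
    name = c("locus_chr2", "SIGGENE", "SUSGENE"),
    chrom = c("chr2", NA, NA),
    start = c(1e5, NA, NA), end = c(3e5, NA, NA),
    symbol = c(NA, "SIGGENE", "SUSGENE"),
    required_type = c("any", "DEL", "any"),
    min_reciprocal_overlap = c(0.5, NA, NA),
    stringsAsFactors = FALSE)
}

toy_genes <- function() {
  data.frame(symbol = c("SIGGENE", "SUSGENE", "OTHER"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(1e5, 5e5, 6e5), end = c(2e5, 6e5, 7e5),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("whole-chromosome events get karyotype-style aneuploidy labels", {
  sex <- c(P1 = "F", P2 = "F", P3 = "M", P4 = "M")
  calls <- make_calls(
    list("P1", "chr21", 0, 4.6e7, "DUP"),  # trisomy 21 in a female
    list("P2", "chrX", 0, 5.8e5, "DEL"),   # 45,X
    list("P3", "chrY", 0, 2e5, "DUP"),     # 47,XYY
    list("P4", "chr21", 10000, 510000, "DEL"))  # 500 kb, not aneuploidy
  calls$caller <- NULL
  out <- detect_aneuploidy(calls, chrom_lengths, sex = sex)
  expect_equal(out$is_aneuploidy, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$karyotype[1:3], c("trisomy 21", "45,X", "47,XYY"))
  expect_error(detect_aneuploidy(calls, c(chr1 = 1e6)),
               "missing chromosome length")
})

test_that("tier precedence is aneuploidy > recurrent > significant gene > susceptibility", {
  calls <- make_calls(
    list("P1", "chr2", 9e4, 3.1e5, "DEL"),   # RO with locus ~0.91 -> recurrent
    list("P2", "chr1", 1.5e5, 2.6e5, "DEL"), # overlaps SIGGENE -> non_recurrent
    list("P3", "chr1", 1.5e5, 2.6e5, "DUP"), # DUP does not match required DEL
    list("P4", "chr1", 5.5e5, 6.6e5, "DUP"), # overlaps SUSGENE (any)
    list("P5", "chrX", 0, 6e5, "DUP"),       # aneuploidy
    list("P6", "chr2", 6.1e5, 6.9e5, "DEL")) # OTHER gene: not in catalog
  calls$caller <- NULL
  out <- classify_cnvs(calls, toy_catalog(), toy_genes(), chrom_lengths)
  expect_equal(out$tier, c("recurrent", "non_recurrent", "unclassified",
                           "susceptibility", "aneuploidy", "unclassified"))
  expect_equal(out$clinically_significant,
               c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$matched_entry[c(1, 2, 4)],
               c("locus_chr2", "SIGGENE", "SUSGENE"))
  # idempotent: reclassifying the labeled calls changes nothing
  again <- classify_cnvs(out[names(calls)], toy_catalog(), toy_genes(),
                         chrom_lengths)
  expect_equal(again$tier, out$tier)
})

test_that("locus match requires reciprocal overlap at the entry threshold", {
  # small call inside the locus: overlap full for the call but RO vs the
  # 200 kb locus is 50k/200k = 0.25 < 0.5 -> no recurrent match
  calls <- make_calls(list("P1", "chr2", 1e5, 1.5e5, "DEL"))
  calls$caller <- NULL
  out <- classify_cnvs(calls, toy_catalog(), toy_genes(), chrom_lengths)
  expect_equal(out$tier, "unclassified")
})

test_that("participant grouping gives significant precedence over susceptibility", {
  calls <- make_calls(
    list("P1", "chr1", 5.5e5, 6.6e5, "DUP"),  # susceptibility only
    list("P2", "chr1", 1.5e5, 2.6e5, "DEL"),  # significant
    list("P2", "chr1", 5.5e5, 6.6e5, "DUP"))  # plus susceptibility
  calls$caller <- NULL
  cl <- classify_cnvs(calls, toy_catalog(), toy_genes(), chrom_lengths)
  tiers <- classify_participants(cl, c("P1", "P2", "P3"))
  expect_equal(tiers$carrier_group,
               c("susceptibility", "significant", "neither"))
  expect_equal(tiers$n_classified_cnvs, c(1L, 2L, 0L))
  expect_true(tiers$has_susceptibility[2])
  # group sizes partition the cohort
  expect_equal(sum(table(tiers$carrier_group)), 3L)
})

test_that("empty catalog leaves all calls unclassified, everyone 'neither'", {
  calls <- make_calls(list("P1", "chr1", 1.5e5, 2.6e5, "DEL"))
  calls$caller <- NULL
  empty <- toy_catalog()[0, ]
  cl <- classify_cnvs(calls, empty, toy_genes(), chrom_lengths)
  expect_equal(cl$tier, "unclassified")
  tiers <- classify_participants(cl, c("P1", "P2"))
  expect_true(all(tiers$carrier_group == "neither"))
})

test_that("prevalence summary reproduces printed cohort bookkeeping", {
  # mirror of the published carrier structure: 85 significant, 194
  # susceptibility, 6821 neither; 130 of the 279 carriers with a
  # diagnosis or high trait
  tiers <- data.frame(
    participant_id = sprintf("P%04d", 1:7100),
    carrier_group = c(rep("significant", 85), rep("susceptibility", 194),
                      rep("neither", 6821)))
  flag <- setNames(c(rep(TRUE, 130), rep(FALSE, 7100 - 130)),
                   tiers$participant_id)
  pv <- prevalence_summary(tiers, flag)
  expect_equal(pv$pct_carriers, 3.9)
  expect_equal(pv$pct_significant, 1.2)
  expect_equal(pv$pct_susceptibility, 2.7)
  expect_equal(pv$pct_carriers_dx_or_high, 46.6)
})

test_that("catalog reader validates kinds and required fields", {
  path <- tempfile(fileext = ".tsv")
  cat_df <- toy_catalog()
  write.table(cat_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_catalog(path)
  expect_equal(back$kind, cat_df$kind)
  bad <- cat_df; bad$kind[1] <- "mystery"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_catalog(path), "unknown catalog kind")
})
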