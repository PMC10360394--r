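test_that("reciprocal overlap matches hand-computed values and is symmetric", {
  expect_equal(reciprocal_overlap(0, 100, 0, 100), 1.0)
  expect_equal(reciprocal_overlap(0, 100, 50, 150), 0.5)
  expect_equal(reciprocal_overlap(0, 100, 200, 300), 0.0)
  expect_equal(
    reciprocal_overlap(0, 100, 0, 100, a_chrom = "chr1", b_chrom = "chr2"),
    0.0)
  expect_error(reciprocal_overlap(10, 10, 0, 5), "end > start")

  set.seed(42)
  for (i in 1:50) {
    a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1
    if (b[1] == b[2]) b[2] <- b[2] + 1
    expect_equal(reciprocal_overlap(a[1], a[2], b[1], b[2]),
                 reciprocal_overlap(b[1], b[2], a[1], a[2]))
    expect_equal(reciprocal_overlap(a[1], a[2], b[1], b[2]),
                 brute_ro(a[1], a[2], b[1], b[2]))
  }
})

test_that("consensus merge keeps two-caller events and drops singletons", {
  calls <- make_calls(
    list("P1", "chr1", 0, 100000, "DEL", "callerA"),
    list("P1", "chr1", 0, 100000, "DEL", "callerB"),
    list("P2", "chr1", 0, 100000, "DEL", "callerA"))
  out <- consensus_merge(calls)
  expect_equal(nrow(out), 1L)
  expect_equal(out$participant_id, "P1")
  expect_equal(out$callers, "callerA,callerB")
  expect_equal(out$n_callers, 2L)
})

test_that("consensus merge takes union coordinates at RO >= threshold", {
  # RO([0,100k), [40k,140k)) = 60k/100k = 0.6 >= 0.5 -> merged [0,140k)
  calls <- make_calls(
    list("P1", "chr1", 0, 100000, "DEL", "callerA"),
    list("P1", "chr1", 40000, 140000, "DEL", "callerB"))
  out <- consensus_merge(calls)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 0)
  expect_equal(out$end, 140000)
  expect_equal(out$length, 140000)

  # below threshold: two singleton events, both dropped at min_callers = 2
  far <- make_calls(
    list("P1", "chr1", 0, 100000, "DEL", "callerA"),
    list("P1", "chr1", 60000, 160000, "DEL", "callerB"))
  expect_equal(nrow(consensus_merge(far)), 0L)
  # retained at min_callers = 1
  expect_equal(nrow(consensus_merge(far, consensus_policy(min_callers = 1))),
               2L)
})

test_that("calls of different participants, chromosomes or types never merge", {
  calls <- make_calls(
    list("P1", "chr1", 0, 100000, "DEL", "callerA"),
    list("P2", "chr1", 0, 100000, "DEL", "callerB"),
    list("P1", "chr2", 0, 100000, "DEL", "callerB"),
    list("P1", "chr1", 0, 100000, "DUP", "callerB"))
  out <- consensus_merge(calls, consensus_policy(min_callers = 1))
  expect_equal(nrow(out), 4L)
  expect_true(all(out$n_callers == 1L))
})

test_that("consensus merge is invariant to input row order", {
  set.seed(7)
  base <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample.int(5e5, 1)
    make_calls(list(sprintf("P%d", sample.int(4, 1)), "chr1", s,
                    s + sample(c(2e4, 5e4, 1e5), 1),
                    sample(c("DEL", "DUP"), 1),
                    sample(c("callerA", "callerB", "callerC"), 1)))
  }))
  ref <- consensus_merge(base)
  for (k in 1:5) {
    perm <- base[sample.int(nrow(base)), ]
    expect_equal(consensus_merge(perm), ref)
  }
})

test_that("unknown CNV type is an input-format error", {
  bad <- make_calls(list("P1", "chr1", 0, 100000, "INV", "callerA"))
  expect_error(consensus_merge(bad), "unknown CNV type")
})

test_that("RO clustering matches brute-force connected components", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    key <- sample(c("k1", "k2"), n, replace = TRUE)
    start <- sample.int(2e5, n)
    end <- start + sample(c(1e4, 3e4, 8e4), n, replace = TRUE)
    got <- cnvburden:::cluster_by_ro(key, start, end, 0.5)
    want <- brute_cluster(key, start, end, 0.5)
    # same partition (cluster labels may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("size filter is boundary-inclusive at the 10 kb floor", {
  calls <- data.frame(participant_id = c("P1", "P2", "P3"), chrom = "chr1",
                      start = 0, end = c(8000, 10000, 20000),
                      type = "DEL")
  expect_message(out <- size_filter(calls), "removed 1")
  expect_equal(out$end, c(10000, 20000))
  expect_equal(nrow(size_filter(calls[0, ])), 0L)
})

test_that("frequency annotation counts distinct carriers per RO cluster", {
  # unique call in a cohort of 200 -> f = 1/200
  one <- data.frame(participant_id = "P1", chrom = "chr1", start = 0,
                    end = 50000, type = "DEL")
  expect_equal(annotate_frequency(one, 200)$frequency, 0.005)

  # 120 carriers of one locus among 1000 -> f = 0.12 for every member
  many <- data.frame(participant_id = sprintf("P%03d", 1:120),
                     chrom = "chr1", start = 1e5, end = 2e5, type = "DEL")
  out <- annotate_frequency(many, 1000)
  expect_true(all(out$frequency == 0.12))
  expect_true(all(out$n_carriers == 120))

  # two disjoint singletons -> two clusters, each f = 1/n
  two <- data.frame(participant_id = c("P1", "P2"), chrom = "chr1",
                    start = c(0, 5e5), end = c(5e4, 5.5e5), type = "DEL")
  out2 <- annotate_frequency(two, 100)
  expect_equal(out2$frequency, c(0.01, 0.01))
  expect_equal(length(unique(out2$cluster_id)), 2L)

  expect_error(annotate_frequency(one, 0), "positive cohort size")
})

test_that("frequency conservation: carrier sums match incidences, f <= 1", {
  set.seed(13)
  calls <- do.call(rbind, lapply(1:60, function(i) {
    s <- sample(c(0, 4e4, 2e5, 6e5), 1)
    data.frame(participant_id = sprintf("P%02d", sample.int(15, 1)),
               chrom = sample(c("chr1", "chr2"), 1), start = s,
               end = s + 3e4, type = sample(c("DEL", "DUP"), 1))
  }))
  out <- annotate_frequency(calls, 15)
  expect_true(all(out$frequency <= 1))
  incid <- aggregate(participant_id ~ cluster_id, out,
                     function(v) length(unique(v)))
  carr <- aggregate(n_carriers ~ cluster_id, out, unique)
  m <- merge(incid, carr)
  expect_equal(m$participant_id, m$n_carriers)
})

test_that("rarity strata follow the frequency cutoffs, gap folds to rare", {
  calls <- data.frame(frequency = c(0.003, 0.02, 0.06, 0.007, 0.05, 0.01))
  expect_warning(out <- stratify_frequency(calls), "0.5%")
  expect_equal(out$stratum,
               c("rare", "less_rare", "common", "rare", "less_rare",
                 "less_rare"))
  expect_error(stratify_frequency(data.frame(frequency = NA_real_)),
               "frequency")
})
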