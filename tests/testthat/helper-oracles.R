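# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: nested
# loops and textbook formulas only.

# reciprocal overlap of two intervals, scalar
brute_ro <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  min(inter / (e1 - s1), inter / (e2 - s2))
}

# single-linkage clustering by all-pairs RO + union-find
brute_cluster <- function(key, start, end, thr) {
  n <- length(start)
  parent <- seq_len(n)
  find2 <- function(i, p) {
    while (p[i] != i) i <- p[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && key[i] == key[j] &&
          brute_ro(start[i], end[i], start[j], end[j]) >= thr) {
        ri <- find2(i, parent); rj <- find2(j, parent)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find2, integer(1), p = parent)
  match(roots, unique(roots))
}

# per-participant distinct-gene recount by exhaustive nested loops
brute_gene_counts <- function(calls, genes, ids, type, stratum) {
  out <- setNames(integer(length(ids)), ids)
  for (pid in ids) {
    hit <- character(0)
    for (i in seq_len(nrow(calls))) {
      if (calls$participant_id[i] != pid) next
      if (calls$type[i] != type || calls$stratum[i] != stratum) next
      for (j in seq_len(nrow(genes))) {
        if (genes$chrom[j] == calls$chrom[i] &&
            genes$start[j] < calls$end[i] &&
            calls$start[i] < genes$end[j]) {
          hit <- union(hit, genes$symbol[j])
        }
      }
    }
    out[pid] <- length(hit)
  }
  out
}

# textbook BH step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) {
    if (m == 1) break
    q[ord[i]] <- min(q[ord[i]], q[ord[i + 1]])
  }
  pmin(q, 1)
}

# OLS by normal equations
brute_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# textbook Pearson chi-square on a 2x2, no correction
brute_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# quick call-table constructor
make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(participant_id = r[[1]], chrom = r[[2]],
               start = as.numeric(r[[3]]), end = as.numeric(r[[4]]),
               type = r[[5]],
               caller = if (length(r) >= 6) r[[6]] else "callerA",
               stringsAsFactors = FALSE)
  }))
}

# small deterministic gene annotation on two autosomes + X
tiny_genes <- function() {
  data.frame(
    symbol = c("GA", "GB", "GC", "GD", "GE", "GX1", "GX2"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chrX", "chrX"),
    start = c(0, 20000, 40000, 0, 50000, 0, 30000),
    end = c(10000, 30000, 55000, 15000, 70000, 20000, 45000),
    strand = "+",
    stringsAsFactors = FALSE
  )
}
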