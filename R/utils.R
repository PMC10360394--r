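# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom data.table data.table as.data.table setDT setDF setorder
#' @importFrom data.table setnames setcolorder rbindlist copy fwrite fread :=
#' @import stats
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "..keep", "participant_id", "chrom", "start", "end",
  "type", "caller", "callers", "n_callers", "cluster_id", "frequency",
  "stratum", "tier", "length_bp", "symbol", "gstart", "gend", "n_carriers",
  "pre", "anycomp", "pos", "p1", "p2", "i.pos", "i.start", "i.end",
  "caller_bit", "mask", "pid", "origin", "locus", "call_row"
))

stop_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

# required-column check for call tables
check_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_input("%s is missing required column(s): %s", what,
               paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

check_call_types <- function(type) {
  bad <- setdiff(unique(as.character(type)), c("DEL", "DUP"))
  if (length(bad) > 0L) {
    stop_input("unknown CNV type value(s): %s (expected DEL or DUP)",
               paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Intervals are 0-based half-open throughout. GRanges is 1-based closed, so
# shift on the way in; any pair of half-open intervals [s1,e1) [s2,e2) with
# e > s maps to a closed [s1+1, e1] that overlaps iff the half-open ones do.
ranges_from_intervals <- function(key, start, end) {
  GenomicRanges::GRanges(
    seqnames = key,
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
}

# connected components over an edge list on 1..n vertices
components_from_edges <- function(n, from, to) {
  if (n == 0L) return(integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  as.integer(igraph::components(g)$membership)
}
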