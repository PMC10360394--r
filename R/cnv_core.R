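# Consensus CNV handling: reciprocal overlap, multi-caller merging,
# cohort frequency annotation and rarity stratification.

#' Reciprocal overlap between two genomic intervals
#'
#' The standard CNV equivalence metric: the length of the intersection
#' divided by the length of each interval, taking the minimum, so that
#' `reciprocal_overlap(a, b) == reciprocal_overlap(b, a)`. Intervals are
#' 0-based half-open. Intervals on different chromosomes have reciprocal
#' overlap 0 (this is not an error).
#'
#' All arguments are vectorized and recycled.
#'
#' @param a_start,a_end,b_start,b_end interval coordinates in bp
#'   (0-based half-open, `end > start`).
#' @param a_chrom,b_chrom optional chromosome names; when supplied, pairs on
#'   different chromosomes return 0.
#' @return numeric vector of reciprocal-overlap proportions in \[0, 1\].
#' @examples
#' reciprocal_overlap(0, 100, 50, 150)   # 0.5
#' reciprocal_overlap(0, 100, 200, 300)  # 0
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               a_chrom = NULL, b_chrom = NULL) {
  if (any(a_end <= a_start) || any(b_end <= b_start)) {
    stop_input("intervals must satisfy end > start")
  }
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ro <- pmin(inter / (a_end - a_start), inter / (b_end - b_start))
  if (!is.null(a_chrom) && !is.null(b_chrom)) {
    ro[as.character(a_chrom) != as.character(b_chrom)] <- 0
  }
  ro
}

#' Consensus policy for multi-caller CNV merging
#'
#' @param min_callers minimum number of distinct supporting callers for a
#'   merged event to be retained (default 2, i.e. "at least two of three").
#' @param merge_reciprocal_overlap reciprocal-overlap threshold in (0, 1\]
#'   used for single-linkage merging of calls within a participant.
#' @param merge_mode `"union"` (default) reports the maximal extent of the
#'   merged calls; `"intersection"` reports the shared core.
#' @return a `consensus_policy` list.
#' @export
consensus_policy <- function(min_callers = 2L,
                             merge_reciprocal_overlap = 0.5,
                             merge_mode = c("union", "intersection")) {
  merge_mode <- match.arg(merge_mode)
  if (min_callers < 1L) stop_input("min_callers must be >= 1")
  if (merge_reciprocal_overlap <= 0 || merge_reciprocal_overlap > 1) {
    stop_input("merge_reciprocal_overlap must be in (0, 1]")
  }
  structure(list(min_callers = as.integer(min_callers),
                 merge_reciprocal_overlap = merge_reciprocal_overlap,
                 merge_mode = merge_mode),
            class = "consensus_policy")
}

# Single-linkage clustering of intervals by reciprocal overlap within groups.
# `key` is a group identifier (calls are only compared within a key); returns
# an integer cluster id per row, globally unique.
#
# Two-stage sweep: a sorted cummax pass finds any-overlap components (a
# superset of the RO clusters, since RO > 0 requires overlap), then exact
# pairwise RO edges within each multi-member component are resolved to
# connected components.
cluster_by_ro <- function(key, start, end, ro_threshold) {
  n <- length(start)
  if (n == 0L) return(integer(0))
  dt <- data.table(grp = key, start = start, end = end, idx = seq_len(n))
  data.table::setkey(dt, grp, start, end)
  ov <- data.table::foverlaps(dt, dt, which = TRUE)
  ov <- ov[ov$xid < ov$yid]
  from <- dt$idx[ov$xid]
  to <- dt$idx[ov$yid]
  if (length(from) > 0L) {
    ro <- reciprocal_overlap(start[from], end[from], start[to], end[to])
    keep <- ro >= ro_threshold
    from <- from[keep]; to <- to[keep]
  }
  memb <- components_from_edges(n, from, to)
  match(memb, unique(memb))
}

#' Merge per-caller CNV calls into consensus events
#'
#' Calls from the same participant, chromosome and CNV type whose pairwise
#' reciprocal overlap reaches the policy threshold are merged by single
#' linkage into one event carrying the union of supporting callers;
#' coordinates are the union extent (or intersection, per policy). Only
#' events supported by at least `min_callers` distinct callers are retained.
#' The result is invariant to the row order of the input.
#'
#' @param calls data.frame with columns `participant_id`, `chrom`, `start`,
#'   `end`, `type` (DEL/DUP) and `caller`.
#' @param policy a [consensus_policy()].
#' @return data.frame of consensus calls with columns `participant_id`,
#'   `chrom`, `start`, `end`, `type`, `callers` (comma-separated),
#'   `n_callers` and `length`.
#' @export
consensus_merge <- function(calls, policy = consensus_policy()) {
  check_columns(calls, c("participant_id", "chrom", "start", "end",
                         "type", "caller"), "caller CNV table")
  check_call_types(calls$type)
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) {
    out <- dt[, .(participant_id, chrom, start, end, type)]
    out[, `:=`(callers = character(0), n_callers = integer(0),
               length = integer(0))]
    return(setDF(out))
  }
  if (any(dt$end <= dt$start)) stop_input("calls must satisfy end > start")
  key <- paste(dt$participant_id, dt$chrom, dt$type, sep = "\r")
  dt[, cluster_id := cluster_by_ro(key, start, end,
                                   policy$merge_reciprocal_overlap)]
  # caller sets as bitmasks so the per-cluster aggregation stays vectorized
  caller_levels <- sort(unique(as.character(dt$caller)))
  dt[, caller_bit := 2^(match(as.character(caller), caller_levels) - 1L)]
  masks <- unique(dt[, .(cluster_id, caller_bit)])[
    , .(mask = sum(caller_bit), n_callers = .N), by = cluster_id]
  agg <- if (policy$merge_mode == "union") {
    dt[, .(participant_id = participant_id[1L], chrom = chrom[1L],
           start = min(start), end = max(end), type = type[1L]),
       by = cluster_id]
  } else {
    dt[, .(participant_id = participant_id[1L], chrom = chrom[1L],
           start = max(start), end = min(end), type = type[1L]),
       by = cluster_id]
  }
  agg <- masks[agg, on = "cluster_id"]
  agg <- agg[n_callers >= policy$min_callers]
  mask_labels <- vapply(seq_len(2^length(caller_levels) - 1L), function(m) {
    paste(caller_levels[bitwAnd(m, 2^(seq_along(caller_levels) - 1L)) > 0],
          collapse = ",")
  }, character(1))
  agg[, callers := mask_labels[mask]]
  agg[, c("cluster_id", "mask") := NULL]
  agg[, length := end - start]
  setcolorder(agg, c("participant_id", "chrom", "start", "end", "type",
                     "callers", "n_callers", "length"))
  setorder(agg, participant_id, chrom, start, end, type)
  setDF(agg)
}

#' Filter consensus calls by minimum size
#'
#' Retains calls with `length >= min_length` (boundary inclusive; the
#' default reflects the 10 kb resolution floor of array-based CNV calls).
#' The number of removed calls is reported via [message()].
#'
#' @param calls consensus call data.frame with `start`/`end` (a `length`
#'   column is computed if absent).
#' @param min_length minimum length in bp, default 10000.
#' @return filtered data.frame.
#' @export
size_filter <- function(calls, min_length = 10000) {
  check_columns(calls, c("start", "end"), "call table")
  len <- calls$end - calls$start
  keep <- len >= min_length
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(sprintf("size_filter: removed %d call(s) shorter than %d bp",
                    n_removed, as.integer(min_length)))
  }
  out <- calls[keep, , drop = FALSE]
  if (!"length" %in% names(out)) out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Annotate cohort frequency of consensus CNV calls
#'
#' Calls are clustered across participants by single linkage on (same
#' chromosome, same type, reciprocal overlap at or above the threshold);
#' the frequency of every call in a cluster is the number of distinct
#' carrier participants in the cluster divided by the cohort size.
#'
#' @param calls consensus call data.frame (`participant_id`, `chrom`,
#'   `start`, `end`, `type`).
#' @param n_participants cohort size used as the frequency denominator.
#' @param cluster_reciprocal_overlap reciprocal-overlap threshold, default 0.5.
#' @return input data.frame with added `cluster_id`, `n_carriers` and
#'   `frequency` columns.
#' @export
annotate_frequency <- function(calls, n_participants,
                               cluster_reciprocal_overlap = 0.5) {
  if (missing(n_participants) || n_participants <= 0) {
    stop_input("n_participants must be a positive cohort size")
  }
  check_columns(calls, c("participant_id", "chrom", "start", "end", "type"),
                "consensus call table")
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) {
    dt[, `:=`(cluster_id = integer(0), n_carriers = integer(0),
              frequency = numeric(0))]
    return(setDF(dt))
  }
  key <- paste(dt$chrom, dt$type, sep = "\r")
  dt[, cluster_id := cluster_by_ro(key, start, end,
                                   cluster_reciprocal_overlap)]
  dt[, n_carriers := length(unique(participant_id)), by = cluster_id]
  dt[, frequency := n_carriers / n_participants]
  setDF(dt)
}

#' Assign rarity strata from cohort frequencies
#'
#' Frequency strata: rare (< 0.5%), less-rare (1–5%) and common (> 5%,
#' excluded from burden analyses). Frequencies falling in the 0.5–1% gap
#' between the rare and less-rare definitions are folded into `rare`
#' (conservative; keeps the strata exhaustive) with a warning listing the
#' affected calls.
#'
#' @param calls call data.frame with a `frequency` column.
#' @return data.frame with added `stratum` column
#'   (`rare` / `less_rare` / `common`).
#' @export
stratify_frequency <- function(calls) {
  check_columns(calls, "frequency", "call table")
  f <- calls$frequency
  if (any(is.na(f))) stop_input("all calls must have an annotated frequency")
  stratum <- ifelse(f > 0.05, "common",
             ifelse(f >= 0.01, "less_rare", "rare"))
  gap <- which(f >= 0.005 & f < 0.01)
  if (length(gap) > 0L) {
    warning(sprintf(
      "%d call(s) with frequency in [0.5%%, 1%%) assigned to 'rare' (rows: %s)",
      length(gap), paste(utils::head(gap, 20L), collapse = ", ")),
      call. = FALSE)
  }
  calls$stratum <- stratum
  calls
}
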