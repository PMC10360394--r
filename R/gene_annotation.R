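# Gene models, CNV-gene intersection and per-participant burden matrices.

#' Read gene models from a BED6 file
#'
#' BED is 0-based half-open, matching the package's internal convention.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    symbol = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_genes(df)
}

#' Read gene models from a GFF3 file
#'
#' GFF3 is 1-based inclusive; coordinates are converted to 0-based
#' half-open on ingest. Only records of type `gene` are kept; the symbol is
#' taken from the `Name` attribute, falling back to `ID`.
#'
#' @param path GFF3 file.
#' @return data.frame as in [read_bed_genes()].
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  sym <- as.character(gr$Name)
  if (all(is.na(sym)) && !is.null(gr$ID)) sym <- as.character(gr$ID)
  df <- data.frame(
    symbol = sym,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_genes(df)
}

validate_genes <- function(genes) {
  check_columns(genes, c("symbol", "chrom", "start", "end"), "gene table")
  if (any(genes$end <= genes$start)) stop_input("genes must satisfy end > start")
  if (anyDuplicated(genes$symbol)) {
    stop_input("gene symbols must be unique within an annotation")
  }
  genes
}

#' Read gene-sets from a GMT file
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene-sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Genes impacted by a single CNV call
#'
#' A gene is impacted when its span overlaps the call by at least 1 bp
#' (half-open coordinates: touching intervals do not overlap). Gene-body
#' overlap is the appropriate resolution for array-scale (>= 10 kb) calls.
#'
#' @param call one-row data.frame or list with `chrom`, `start`, `end`.
#' @param genes gene model data.frame.
#' @return character vector of impacted gene symbols.
#' @export
genes_hit <- function(call, genes) {
  hit <- genes$chrom == call$chrom &
    genes$start < call$end & call$start < genes$end
  genes$symbol[hit]
}

# all call-gene overlaps at once: returns data.table(call_row, symbol, gchrom)
overlap_calls_genes <- function(calls, genes) {
  if (nrow(calls) == 0L || nrow(genes) == 0L) {
    return(data.table(call_row = integer(0), symbol = character(0)))
  }
  gr_c <- ranges_from_intervals(calls$chrom, calls$start, calls$end)
  gr_g <- ranges_from_intervals(genes$chrom, genes$start, genes$end)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_g)
  data.table(call_row = S4Vectors::queryHits(hits),
             symbol = genes$symbol[S4Vectors::subjectHits(hits)])
}

#' Build per-participant CNV burden matrices
#'
#' Produces, per participant: distinct-gene counts by CNV type and rarity
#' stratum, total CNV length by type, a combined global gene count
#' (distinct genes impacted by deletions or duplications, used as the
#' global-burden correction covariate), per-gene-set distinct-gene counts
#' by type and stratum, and per-gene binary carrier indicators by type.
#' Common-stratum calls (frequency > 5%) are excluded. Non-carriers get
#' all-zero rows. A gene hit by two calls of the same participant counts
#' once.
#'
#' @param calls frequency-stratified consensus calls (`participant_id`,
#'   `chrom`, `start`, `end`, `type`, `stratum`).
#' @param genes gene model data.frame.
#' @param gene_sets named list of gene symbol vectors; symbols absent from
#'   `genes` are ignored (a count is reported via [message()]).
#' @param cohort_ids character vector of all participant ids (row universe).
#' @return object of class `burden_matrix`: a list with `counts` (data.frame,
#'   one row per participant), `gene_carriers` (list of participant x gene
#'   0/1 matrices for DEL and DUP), `metadata` (column definitions) and `n`.
#' @export
build_burden_matrix <- function(calls, genes, gene_sets = list(),
                                cohort_ids) {
  check_columns(calls, c("participant_id", "chrom", "start", "end",
                         "type", "stratum"), "stratified call table")
  validate_genes(genes)
  cohort_ids <- as.character(cohort_ids)
  extra <- setdiff(unique(as.character(calls$participant_id)), cohort_ids)
  if (length(extra) > 0L) {
    stop_input("calls contain participant(s) not in cohort ids: %s",
               paste(utils::head(extra, 5L), collapse = ", "))
  }
  dt <- as.data.table(calls)
  dt <- dt[stratum != "common"]
  n <- length(cohort_ids)
  n_genes <- nrow(genes)

  # clean gene-sets against the annotation
  gene_sets <- lapply(gene_sets, as.character)
  unknown <- sum(vapply(gene_sets, function(s) sum(!s %in% genes$symbol),
                        integer(1)))
  if (unknown > 0L) {
    message(sprintf(
      "build_burden_matrix: ignored %d gene-set member(s) absent from the annotation",
      unknown))
  }
  gene_sets <- lapply(gene_sets, function(s) intersect(s, genes$symbol))

  counts <- data.table(participant_id = cohort_ids)
  strata <- c("rare", "less_rare")
  types <- c("DEL", "DUP")
  meta <- list()
  zero_fill <- function(col_dt, col) {
    v <- col_dt[[col]][match(cohort_ids, col_dt$participant_id)]
    v[is.na(v)] <- 0
    v
  }

  ov <- overlap_calls_genes(dt, genes)
  if (nrow(ov) > 0L) {
    ov <- cbind(ov,
                dt[ov$call_row, .(participant_id, type, stratum)])
  } else {
    ov <- data.table(call_row = integer(0), symbol = character(0),
                     participant_id = character(0), type = character(0),
                     stratum = character(0))
  }
  pg <- unique(ov[, .(participant_id, type, stratum, symbol)])

  for (ty in types) {
    for (st in strata) {
      col <- sprintf("gene_count_%s_%s", ty, st)
      tab <- pg[type == ty & stratum == st,
                .(cnt = length(unique(symbol))), by = participant_id]
      counts[[col]] <- zero_fill(
        setnames(tab, "cnt", col), col)
      meta[[col]] <- list(kind = "gene_count", type = ty, stratum = st)
    }
    lcol <- sprintf("total_length_%s", ty)
    ltab <- dt[type == ty,
               .(len = sum(as.numeric(end - start))), by = participant_id]
    counts[[lcol]] <- zero_fill(setnames(ltab, "len", lcol), lcol)
    meta[[lcol]] <- list(kind = "total_length", type = ty)
    gcol <- sprintf("total_gene_count_%s", ty)
    gtab <- pg[type == ty, .(cnt = length(unique(symbol))),
               by = participant_id]
    counts[[gcol]] <- zero_fill(setnames(gtab, "cnt", gcol), gcol)
    meta[[gcol]] <- list(kind = "total_gene_count", type = ty)
  }
  # combined global burden: distinct genes impacted by DEL or DUP
  gall <- pg[, .(cnt = length(unique(symbol))), by = participant_id]
  counts[["global_gene_count"]] <- zero_fill(
    setnames(gall, "cnt", "global_gene_count"), "global_gene_count")
  meta[["global_gene_count"]] <- list(kind = "global_gene_count")

  for (set_name in names(gene_sets)) {
    members <- gene_sets[[set_name]]
    for (ty in types) {
      for (st in strata) {
        col <- sprintf("set.%s_%s_%s", set_name, ty, st)
        tab <- pg[type == ty & stratum == st & symbol %in% members,
                  .(cnt = length(unique(symbol))), by = participant_id]
        counts[[col]] <- zero_fill(setnames(tab, "cnt", col), col)
        meta[[col]] <- list(kind = "gene_set_count", set = set_name,
                            type = ty, stratum = st)
      }
    }
  }

  gene_carriers <- lapply(types, function(ty) {
    m <- matrix(0L, nrow = n, ncol = n_genes,
                dimnames = list(cohort_ids, genes$symbol))
    sub <- unique(pg[type == ty, .(participant_id, symbol)])
    if (nrow(sub) > 0L) {
      m[cbind(match(sub$participant_id, cohort_ids),
              match(sub$symbol, genes$symbol))] <- 1L
    }
    m
  })
  names(gene_carriers) <- types

  structure(list(counts = setDF(counts), gene_carriers = gene_carriers,
                 metadata = meta, n = n),
            class = "burden_matrix")
}

#' Chromosome-X restricted burden matrices
#'
#' Rebuilds the burden matrices using only genes on chromosome X (gene-set
#' membership is intersected with the X-linked annotation).
#'
#' @inheritParams build_burden_matrix
#' @param x_chrom chromosome name, default `"chrX"` (`"X"` also recognized).
#' @return a `burden_matrix` restricted to X-linked genes.
#' @export
subset_chromosome_x <- function(calls, genes, gene_sets = list(), cohort_ids,
                                x_chrom = c("chrX", "X")) {
  gx <- genes[genes$chrom %in% x_chrom, , drop = FALSE]
  if (nrow(gx) == 0L) {
    # no X-linked genes: all-zero matrices over an empty gene universe
    gx <- genes[0, , drop = FALSE]
  }
  build_burden_matrix(calls, gx, gene_sets, cohort_ids)
}

#' Write a burden matrix and its column metadata
#'
#' @param bm a `burden_matrix`.
#' @param path output TSV for the counts table; a sidecar
#'   `<path>.columns.json` records column definitions.
#' @export
write_burden_matrix <- function(bm, path) {
  fwrite(bm$counts, path, sep = "\t")
  jsonlite::write_json(bm$metadata, paste0(path, ".columns.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
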