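# Internal helpers shared across modules.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Convert a 0-based half-open interval table to a GRanges (1-based inclusive).
# Strand is dropped everywhere: eccDNA junctions are unstranded observations.
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# findOverlaps with the "no sequence levels in common" warning silenced:
# inputs with disjoint chromosome sets are legitimate (e.g. circles on a
# chromosome without annotated genes) and simply have no overlaps.
.overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

.empty_calls <- function() {
  data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    split_reads = numeric(0), sample_id = character(0),
    stringsAsFactors = FALSE
  )
}

# Validate a circle-call data frame; `where` names the offending input in
# error messages.
.check_calls <- function(calls, where = "calls") {
  need <- c("chrom", "start", "end", "split_reads", "sample_id")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(calls) > 0) {
    if (any(calls$end <= calls$start)) {
      stop(sprintf("%s contains interval(s) with end <= start", where),
           call. = FALSE)
    }
    if (any(calls$split_reads < 0)) {
      stop(sprintf("%s contains negative split-read count(s)", where),
           call. = FALSE)
    }
  }
  invisible(calls)
}

# Accept a gene_annotation object or a bare gene table.
.gene_table <- function(genes) {
  if (inherits(genes, "gene_annotation")) genes$genes else genes
}

.exon_table <- function(genes) {
  if (inherits(genes, "gene_annotation")) genes$exons else NULL
}

.check_genes <- function(genes) {
  gt <- .gene_table(genes)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(gt))
  if (length(miss) > 0) {
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(gt) > 0 && any(gt$end <= gt$start)) {
    stop("gene table contains gene(s) with end <= start", call. = FALSE)
  }
  invisible(gt)
}

.check_sample_sheet <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "group") %in% names(samples))) {
    stop("sample sheet must be a data frame with columns sample_id and group",
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample sheet contains duplicated sample_id(s)", call. = FALSE)
  }
  invisible(samples)
}

# Group labels in order of first appearance in the sheet (group A first).
.group_levels <- function(samples, groups = NULL) {
  seen <- unique(as.character(samples$group))
  if (is.null(groups)) {
    if (length(seen) != 2) {
      stop("exactly two groups are required; sample sheet has: ",
           paste(seen, collapse = ", "), call. = FALSE)
    }
    return(seen)
  }
  if (length(groups) != 2 || !all(groups %in% seen)) {
    stop("`groups` must name two group labels present in the sample sheet",
         call. = FALSE)
  }
  as.character(groups)
}
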