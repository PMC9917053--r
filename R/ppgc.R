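# Produced-per-Gene Circles (PpGC) quantification: circle-to-gene
# annotation, the genes x samples split-read matrix, gene-length scaling,
# and log2 equalization.

#' Annotate circles with overlapping genes
#'
#' Emits one (circle, gene) pair for every circle/gene-body overlap of at
#' least 1 bp (half-open adjacency does not count). Overlap is against the
#' gene body, not exons, because an eccDNA carrying any fragment of a gene
#' counts toward that gene. A circle overlapping several genes yields one
#' pair per gene; circles overlapping no gene yield none.
#'
#' @param calls Processed circle-call data frame.
#' @param genes A `gene_annotation` or gene table.
#' @return Data frame: the call columns plus `gene_id`.
#' @export
annotate_circles <- function(calls, genes) {
  .check_calls(calls)
  gt <- .check_genes(genes)
  empty <- cbind(.empty_calls(),
                 data.frame(gene_id = character(0),
                            stringsAsFactors = FALSE))
  if (nrow(calls) == 0 || nrow(gt) == 0) return(empty)
  hits <- .overlaps(.as_granges(calls), .as_granges(gt))
  if (length(hits) == 0) return(empty)
  out <- calls[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- gt$gene_id[S4Vectors::subjectHits(hits)]
  rownames(out) <- NULL
  out
}

#' Build the raw PpGC matrix
#'
#' Unifies circles by gene: cell (gene, sample) is the sum of split reads
#' of all of that sample's circles overlapping the gene. A circle
#' overlapping k genes contributes its full split-read count to each of the
#' k genes (no apportioning). Genes with zero totals across all samples are
#' dropped; every sample of the sheet gets a column, even without calls.
#'
#' @param pairs Annotated pairs from [annotate_circles()].
#' @param samples Sample sheet data frame (`sample_id`, `group`).
#' @param genes A `gene_annotation` or gene table supplying gene lengths.
#' @return A `ppgc_table` with `stage = "raw"`.
#' @export
compute_ppgc <- function(pairs, samples, genes) {
  .check_sample_sheet(samples)
  gt <- .check_genes(genes)
  unknown <- setdiff(unique(pairs$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    stop("sample_id(s) not in the sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gene_ids <- sort(unique(pairs$gene_id))
  sample_ids <- samples$sample_id
  values <- matrix(0, nrow = length(gene_ids), ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  if (nrow(pairs) > 0) {
    agg <- stats::aggregate(split_reads ~ gene_id + sample_id, data = pairs,
                            FUN = sum)
    values[cbind(agg$gene_id, agg$sample_id)] <- agg$split_reads
  }
  keep <- rowSums(values) > 0
  values <- values[keep, , drop = FALSE]
  lens <- gt$length
  if (is.null(lens)) lens <- gt$end - gt$start
  names(lens) <- gt$gene_id
  miss <- setdiff(rownames(values), names(lens))
  if (length(miss) > 0) {
    stop("gene_id(s) missing from the annotation: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ppgc_table(values, gene_lengths = lens[rownames(values)], stage = "raw",
             annotation_lengths = lens)
}

#' Construct a PpGC table
#'
#' @param values Numeric genes x samples matrix with dimnames.
#' @param gene_lengths Named vector of gene-body lengths (bp) covering the
#'   matrix rows.
#' @param stage `"raw"`, `"scaled"`, or `"equalized"`.
#' @param l_max_gene The scaling numerator (longest gene length, bp), once
#'   scaling has been applied.
#' @param annotation_lengths Optional named length vector over the full
#'   annotation (for scaling with the annotation-wide longest gene).
#' @return A `ppgc_table` object.
#' @export
ppgc_table <- function(values, gene_lengths,
                       stage = c("raw", "scaled", "equalized"),
                       l_max_gene = NULL, annotation_lengths = NULL) {
  stage <- match.arg(stage)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  }
  if (!all(rownames(values) %in% names(gene_lengths))) {
    stop("gene_lengths must cover all matrix rows", call. = FALSE)
  }
  obj <- list(values = values,
              gene_lengths = gene_lengths[rownames(values)],
              stage = stage, l_max_gene = l_max_gene,
              annotation_lengths = annotation_lengths)
  class(obj) <- "ppgc_table"
  obj
}

#' @export
print.ppgc_table <- function(x, ...) {
  cat(sprintf("ppgc_table (%s): %d gene(s) x %d sample(s)\n",
              x$stage, nrow(x$values), ncol(x$values)))
  if (!is.null(x$l_max_gene)) {
    cat(sprintf("  scaled with longest gene = %g bp\n", x$l_max_gene))
  }
  invisible(x)
}

#' @export
dim.ppgc_table <- function(x) dim(x$values)

#' @export
as.data.frame.ppgc_table <- function(x, ...) {
  data.frame(gene_id = rownames(x$values),
             gene_length = unname(x$gene_lengths),
             as.data.frame(x$values), check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scale PpGCs by gene length
#'
#' Multiplies each gene's row by the scale factor L_Max / L_i, where L_i is
#' the gene-body length and L_Max the length of the longest gene found in
#' the dataset. Short genes are scaled up so that production per gene is
#' comparable across gene sizes; the longest gene is left unchanged. By
#' default L_Max is taken over the genes retained in the table; with
#' `l_max_from = "annotation"` the longest gene of the whole annotation is
#' used instead.
#'
#' @param table A raw `ppgc_table`.
#' @param l_max_from `"table"` or `"annotation"`.
#' @return A `ppgc_table` with `stage = "scaled"`.
#' @export
scale_by_gene_length <- function(table, l_max_from = c("table", "annotation")) {
  l_max_from <- match.arg(l_max_from)
  stopifnot(inherits(table, "ppgc_table"))
  if (table$stage != "raw") {
    stop("scale_by_gene_length expects a raw table", call. = FALSE)
  }
  lens <- table$gene_lengths
  if (any(lens <= 0)) stop("non-positive gene length(s)", call. = FALSE)
  l_max_gene <- if (l_max_from == "annotation" &&
                    !is.null(table$annotation_lengths)) {
    max(table$annotation_lengths)
  } else {
    max(lens)
  }
  values <- table$values * (l_max_gene / lens)
  ppgc_table(values, gene_lengths = lens, stage = "scaled",
             l_max_gene = l_max_gene,
             annotation_lengths = table$annotation_lengths)
}

#' Log2 equalization of a PpGC table
#'
#' Applies the variance-stabilising log2(x + 1) transform cellwise, mapping
#' the skewed split-read scale onto the log scale on which group means and
#' fold changes are computed.
#'
#' @param table A raw or scaled `ppgc_table`.
#' @return A `ppgc_table` with `stage = "equalized"`.
#' @export
equalize <- function(table) {
  stopifnot(inherits(table, "ppgc_table"))
  if (table$stage == "equalized") {
    stop("table is already equalized", call. = FALSE)
  }
  if (any(table$values < 0)) {
    stop("negative values cannot be equalized", call. = FALSE)
  }
  out <- ppgc_table(log2(table$values + 1),
                    gene_lengths = table$gene_lengths, stage = "equalized",
                    l_max_gene = table$l_max_gene,
                    annotation_lengths = table$annotation_lengths)
  out
}
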