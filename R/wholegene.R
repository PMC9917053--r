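# Detection of eccDNA carrying whole genes: circles whose interval fully
# contains a gene body, summarised by recurrence across samples.

#' Find eccDNA carrying whole genes
#'
#' A gene is hit in a sample when any of the sample's processed circles
#' contains the entire gene body: same chromosome, circle start <= gene
#' start, and circle end >= gene end (inclusive at both ends on the
#' half-open convention, so a circle with exactly the gene's coordinates
#' carries the full gene). Genes hit in at least `min_samples` samples are
#' reported with the set of carrying samples, alongside a Boolean
#' gene x sample presence matrix (1 = an eccDNA carrying the whole gene is
#' present in that sample).
#'
#' @param calls Processed circle calls: a data frame with a `sample_id`
#'   column, or a named list of per-sample call data frames.
#' @param genes A `gene_annotation` or gene table.
#' @param min_samples Minimum number of samples carrying the whole gene
#'   (default 2).
#' @param sample_ids Optional sample ids defining the presence-matrix
#'   columns (defaults to the samples seen in `calls`).
#' @return List with `hits` (data frame `gene_id`, `gene_length`,
#'   `n_samples`, `samples`; sorted by `n_samples` descending then gene id)
#'   and `presence` (0/1 matrix over the hit genes).
#' @export
find_whole_gene_circles <- function(calls, genes, min_samples = 2,
                                    sample_ids = NULL) {
  if (!is.data.frame(calls)) {
    calls <- do.call(rbind, c(calls, make.row.names = FALSE))
  }
  .check_calls(calls)
  gt <- .check_genes(genes)
  if (is.null(sample_ids)) sample_ids <- sort(unique(calls$sample_id))

  hit_pairs <- if (nrow(calls) == 0 || nrow(gt) == 0) {
    data.frame(gene_id = character(0), sample_id = character(0))
  } else {
    # Genes contained in circles: gene "within" circle.
    ov <- .overlaps(.as_granges(gt), .as_granges(calls), type = "within")
    unique(data.frame(
      gene_id = gt$gene_id[S4Vectors::queryHits(ov)],
      sample_id = calls$sample_id[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE
    ))
  }

  by_gene <- split(hit_pairs$sample_id, hit_pairs$gene_id)
  n_hit <- vapply(by_gene, function(s) length(unique(s)), integer(1))
  keep <- names(by_gene)[n_hit >= min_samples]

  lens <- gt$length
  if (is.null(lens)) lens <- gt$end - gt$start
  names(lens) <- gt$gene_id

  hits <- data.frame(
    gene_id = keep,
    gene_length = unname(lens[keep]),
    n_samples = unname(n_hit[keep]),
    samples = vapply(by_gene[keep],
                     function(s) paste(sort(unique(s)), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(-hits$n_samples, hits$gene_id), , drop = FALSE]
  rownames(hits) <- NULL

  presence <- matrix(0L, nrow = nrow(hits), ncol = length(sample_ids),
                     dimnames = list(hits$gene_id, sample_ids))
  for (g in hits$gene_id) {
    presence[g, intersect(unique(by_gene[[g]]), sample_ids)] <- 1L
  }
  list(hits = hits, presence = presence)
}
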