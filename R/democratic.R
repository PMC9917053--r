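# Democratic voting for Common PpGCs (CPpGCs) within one group: a sample
# votes for a gene when its equalized PpGC reaches a data-derived
# threshold; genes with a vote quorum are the group's common producers.

#' Data-derived vote threshold for the democratic method
#'
#' Pools all nonzero equalized PpGC values of the group, estimates their
#' empirical distribution with a fixed-width histogram smoothed by a
#' centered triangular-weighted moving average, and returns the floor of
#' the center of the highest smoothed bin (the mode location; leftmost bin
#' on ties). The triangular kernel keeps an isolated single-bin mode at its
#' own bin instead of flattening it into a plateau. Zeros are excluded: a
#' zero-inflated mode would pin the threshold at 0 and make voting vacuous.
#'
#' @param table An equalized `ppgc_table` or numeric matrix.
#' @param group_samples Sample ids forming the group.
#' @param bin_width Histogram bin width on the equalized scale.
#' @param smooth_bins Centered moving-average window in bins (odd).
#' @return The threshold (a non-negative integer-valued number).
#' @export
vote_threshold <- function(table, group_samples, bin_width = 0.5,
                           smooth_bins = 3) {
  values <- if (inherits(table, "ppgc_table")) table$values else table
  miss <- setdiff(group_samples, colnames(values))
  if (length(miss) > 0) {
    stop("sample(s) absent from the table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (smooth_bins %% 2 != 1) stop("smooth_bins must be odd", call. = FALSE)
  v <- as.vector(values[, group_samples, drop = FALSE])
  v <- v[v > 0]
  if (length(v) == 0) {
    stop("all group values are zero; no distribution to threshold",
         call. = FALSE)
  }
  n_bins <- floor(max(v) / bin_width) + 1L          # [a, a + bw) bins
  counts <- tabulate(floor(v / bin_width) + 1L, nbins = n_bins)
  smoothed <- .moving_average(counts, smooth_bins)
  top <- which.max(smoothed)                         # leftmost on ties
  center <- (top - 0.5) * bin_width
  floor(center)
}

#' Democratic vote for common PpGCs
#'
#' Each sample of the group casts a vote for every gene whose equalized
#' PpGC value reaches the threshold (inclusive by default). Genes with at
#' least `min_votes` votes are flagged as CPpGCs -- consistently
#' circle-producing genes within the group, irrespective of any
#' between-group comparison.
#'
#' @param table An equalized `ppgc_table` or numeric matrix.
#' @param group_samples Sample ids forming the group.
#' @param threshold Vote threshold, typically from [vote_threshold()].
#' @param min_votes Vote quorum (default 4).
#' @param inclusive Count values equal to the threshold as votes
#'   (default `TRUE`); set `FALSE` for a strict comparison.
#' @return Data frame (`gene_id`, `votes`, `threshold`, `is_cppgc`), sorted
#'   by votes descending then gene id.
#' @export
vote_cppgc <- function(table, group_samples, threshold, min_votes = 4,
                       inclusive = TRUE) {
  values <- if (inherits(table, "ppgc_table")) table$values else table
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (min_votes < 1) stop("min_votes must be >= 1", call. = FALSE)
  miss <- setdiff(group_samples, colnames(values))
  if (length(miss) > 0) {
    stop("sample(s) absent from the table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  g <- values[, group_samples, drop = FALSE]
  votes <- if (inclusive) rowSums(g >= threshold) else rowSums(g > threshold)
  out <- data.frame(gene_id = rownames(values), votes = as.integer(votes),
                    threshold = threshold,
                    is_cppgc = votes >= min_votes,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$votes, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect CPpGC sets of two groups
#'
#' Partitions the CPpGC gene ids of two vote results into group-specific
#' and shared sets.
#'
#' @param results_a,results_b Vote-result data frames from [vote_cppgc()].
#' @return List with `only_a`, `only_b`, `common` (character vectors,
#'   sorted).
#' @export
cppgc_overlap <- function(results_a, results_b) {
  set_a <- results_a$gene_id[results_a$is_cppgc]
  set_b <- results_b$gene_id[results_b$is_cppgc]
  list(only_a = sort(setdiff(set_a, set_b)),
       only_b = sort(setdiff(set_b, set_a)),
       common = sort(intersect(set_a, set_b)))
}
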