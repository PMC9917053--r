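# Per-sample circle processing: mitochondrial and length filters, junction
# cluster merging with split-read summation, minimum split-read filter, and
# the descriptive statistics of the processed circles.

#' Processing parameters
#'
#' Bundles the circle-level filter settings. Defaults follow the standard
#' Circle-Seq post-mapping cascade: circles longer than `l_max` = 100 kb are
#' discarded (the short-eccDNA size cutoff), clusters of junctions whose
#' endpoints both lie within `d_min` = 10 bp are merged with their split
#' reads added up, and merged circles supported by fewer than `jt_min` = 2
#' split reads are dropped.
#'
#' @param l_max Maximum circle length in bp (circles with length strictly
#'   greater are removed).
#' @param d_min Merge distance in bp (strict: endpoints at distance exactly
#'   `d_min` are not linked).
#' @param jt_min Minimum junction split-read count (inclusive).
#' @param mito_names Chromosome names treated as mitochondrial.
#' @return A list of class `processing_params`.
#' @export
processing_params <- function(l_max = 100000, d_min = 10, jt_min = 2,
                              mito_names = c("chrM", "MT", "chrMT")) {
  if (l_max <= 0) stop("l_max must be > 0", call. = FALSE)
  if (d_min < 0) stop("d_min must be >= 0", call. = FALSE)
  if (jt_min < 1) stop("jt_min must be >= 1", call. = FALSE)
  structure(list(l_max = l_max, d_min = d_min, jt_min = jt_min,
                 mito_names = mito_names),
            class = "processing_params")
}

#' Filter circles by chromosome and length
#'
#' Splits raw calls into autosomal/nuclear circles passing the length cutoff
#' and mitochondrial circles, which are retained separately because the
#' mitochondrial "copy number" proxy is counted from the raw (pre-merge)
#' split reads. Circles of length exactly `l_max` are kept: the filter
#' removes lengths strictly greater than the cutoff.
#'
#' @param calls Circle-call data frame.
#' @param params A [processing_params()] object.
#' @return List with elements `kept` and `mito`, both in input order.
#' @export
filter_circles <- function(calls, params = processing_params()) {
  .check_calls(calls)
  is_mito <- calls$chrom %in% params$mito_names
  len_ok <- (calls$end - calls$start) <= params$l_max
  list(
    kept = calls[!is_mito & len_ok, , drop = FALSE],
    mito = calls[is_mito, , drop = FALSE]
  )
}

#' Merge clusters of near-identical circle junctions
#'
#' Two calls are linked when they share a chromosome and both their start
#' and end coordinates differ by strictly less than `d_min`; clusters are
#' the connected components of this relation (transitive closure). Each
#' cluster collapses to one call spanning min(start)..max(end) with the
#' member split reads added up. Linkage uses both endpoints rather than
#' interval overlap because the merged entities are circular junctions:
#' overlap-based merging would collapse distinct circles sharing a single
#' breakpoint.
#'
#' @param calls Circle-call data frame from one sample.
#' @param d_min Linking distance in bp (strict inequality).
#' @return Merged calls sorted by (chrom, start, end).
#' @export
merge_circles <- function(calls, d_min = 10) {
  .check_calls(calls)
  if (length(unique(calls$sample_id)) > 1) {
    stop("merge_circles expects calls from a single sample", call. = FALSE)
  }
  if (nrow(calls) == 0) return(calls)

  # Union-find with path halving.
  parent <- seq_len(nrow(calls))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  ord <- order(calls$chrom, calls$start, calls$end)
  ch <- calls$chrom[ord]; st <- calls$start[ord]; en <- calls$end[ord]
  n <- length(ord)
  # Sorted by start within chromosome, so only a forward window with
  # start difference < d_min needs checking.
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && ch[j] == ch[i] && st[j] - st[i] < d_min) {
      if (abs(en[j] - en[i]) < d_min) union(ord[i], ord[j])
      j <- j + 1L
    }
  }

  comp <- vapply(seq_len(nrow(calls)), find, integer(1))
  idx <- split(seq_len(nrow(calls)), comp)
  first <- vapply(idx, `[[`, integer(1), 1L)
  merged <- data.frame(
    chrom = calls$chrom[first],
    start = vapply(idx, function(i) min(calls$start[i]), numeric(1)),
    end = vapply(idx, function(i) max(calls$end[i]), numeric(1)),
    split_reads = vapply(idx, function(i) sum(calls$split_reads[i]),
                         numeric(1)),
    sample_id = calls$sample_id[first],
    stringsAsFactors = FALSE
  )
  merged <- merged[order(merged$chrom, merged$start, merged$end), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Remove circles with too few split reads
#'
#' Retains circles supported by at least `jt_min` split reads (inclusive
#' boundary). Applied after merging, so a cluster of weakly supported
#' duplicates can survive through its summed support.
#'
#' @param calls Merged circle-call data frame.
#' @param jt_min Minimum split-read count.
#' @return Filtered calls, order preserved.
#' @export
filter_min_split_reads <- function(calls, jt_min = 2) {
  .check_calls(calls)
  calls[calls$split_reads >= jt_min, , drop = FALSE]
}

#' Run the full per-sample processing cascade
#'
#' Convenience wrapper: [filter_circles()], then [merge_circles()] per
#' sample, then [filter_min_split_reads()]. Accepts calls from several
#' samples at once (merging is done within each sample).
#'
#' @param calls Circle-call data frame (one or more samples).
#' @param params A [processing_params()] object.
#' @return List with `kept` (processed calls), `mito` (raw mitochondrial
#'   calls), and `log` (records surviving each stage).
#' @export
process_circles <- function(calls, params = processing_params()) {
  .check_calls(calls)
  f <- filter_circles(calls, params)
  by_sample <- split(f$kept, f$kept$sample_id)
  merged <- do.call(rbind, c(lapply(by_sample, merge_circles,
                                    d_min = params$d_min),
                             make.row.names = FALSE))
  if (is.null(merged)) merged <- .empty_calls()
  kept <- filter_min_split_reads(merged, params$jt_min)
  rownames(kept) <- NULL
  list(
    kept = kept,
    mito = f$mito,
    log = c(input = nrow(calls), after_filter = nrow(f$kept),
            after_merge = nrow(merged), after_jt = nrow(kept))
  )
}

#' Count unique eccDNA per sample
#'
#' Counts processed (merged + filtered) circles per sample -- the
#' cross-chromosomal load of unique eccDNA.
#'
#' @param calls Processed circle-call data frame, or a named list of
#'   per-sample call data frames.
#' @param sample_ids Optional vector of sample ids to report (zero counts
#'   for samples without calls).
#' @return Named integer vector of per-sample counts.
#' @export
count_unique_eccdna <- function(calls, sample_ids = NULL) {
  if (is.data.frame(calls)) {
    tab <- table(factor(calls$sample_id,
                        levels = if (is.null(sample_ids))
                          sort(unique(calls$sample_id)) else sample_ids))
  } else {
    counts <- vapply(calls, nrow, integer(1))
    if (!is.null(sample_ids)) {
      counts <- counts[sample_ids]
      counts[is.na(counts)] <- 0L
      names(counts) <- sample_ids
    }
    return(counts)
  }
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Count mitochondrial split reads
#'
#' Sums split reads over all raw mitochondrial calls (taken before merging
#' and before the minimum split-read filter), a per-sample proxy for
#' mitochondrial DNA content that is robust to the interval merging which
#' otherwise collapses the whole ~16 kb mitochondrial genome into a single
#' unique circle.
#'
#' @param mito_calls Mitochondrial circle calls of one sample.
#' @return Total split-read count (0 for no calls).
#' @export
count_mt_split_reads <- function(mito_calls) {
  .check_calls(mito_calls, "mito_calls")
  sum(mito_calls$split_reads)
}

#' Length histogram, periodicity, and cumulative distribution
#'
#' Histograms circle lengths over `[0, range_max]` bp, smooths the counts
#' with a centered moving average, and reports the local maxima of the
#' smoothed histogram -- the nucleosome-periodic enrichment peaks (~160 bp
#' and multiples) typical of eccDNA -- together with the cumulative length
#' distribution over the same range.
#'
#' @param calls Circle-call data frame.
#' @param bin_width Histogram bin width in bp (>= 1).
#' @param smooth_window Centered moving-average window in bins (odd).
#' @param range_max Upper end of the analysed length range in bp.
#' @return List of class `length_stats`: `breaks`, `mids`, `counts`,
#'   `smoothed`, `maxima` (bin centers of strict local maxima),
#'   `cumulative` (non-decreasing, ending at 1), `n` (circles in range).
#' @export
length_periodicity <- function(calls, bin_width = 10, smooth_window = 3,
                               range_max = 1000) {
  .check_calls(calls)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  if (smooth_window %% 2 != 1) {
    stop("smooth_window must be odd", call. = FALSE)
  }
  len <- calls$end - calls$start
  len <- len[len <= range_max]
  n_bins <- ceiling(range_max / bin_width)
  idx <- pmin(floor(len / bin_width), n_bins - 1) + 1L   # [a, a+bw) bins
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (seq_len(n_bins) - 0.5) * bin_width
  smoothed <- .moving_average(counts, smooth_window)
  interior <- which(diff(sign(diff(smoothed))) == -2) + 1L
  maxima <- mids[interior]
  cumulative <- if (sum(counts) > 0) cumsum(counts) / sum(counts)
                else rep(0, n_bins)
  structure(list(breaks = seq(0, n_bins * bin_width, by = bin_width),
                 mids = mids, counts = counts, smoothed = smoothed,
                 maxima = maxima, cumulative = cumulative,
                 n = length(len)),
            class = "length_stats")
}

# Centered triangular-weighted moving average with zero padding at the
# edges. The triangular kernel (e.g. 1-2-1 for a 3-bin window) smooths
# noisy histograms without flattening an isolated single-bin mode into a
# plateau, which a uniform window would.
.moving_average <- function(x, window) {
  half <- (window - 1) / 2
  w <- c(seq_len(half), half + 1, rev(seq_len(half)))
  w <- w / sum(w)
  padded <- c(rep(0, half), x, rep(0, half))
  vapply(seq_along(x), function(i) {
    sum(padded[i:(i + window - 1)] * w)
  }, numeric(1))
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("length_stats: %d circle(s) in range; local maxima at %s bp\n",
              x$n,
              if (length(x$maxima) > 0) paste(x$maxima, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Classify a circle as exonic, intronic, or intergenic
#'
#' A circle is `exonic` if it overlaps at least 1 bp of any exon (exon
#' overlap takes precedence), else `intronic` if it overlaps any gene body,
#' else `intergenic`. The three labels are exhaustive and exclusive.
#'
#' @param calls Circle-call data frame.
#' @param genes A `gene_annotation` (exons needed for the exon/intron
#'   distinction; with no exons every genic circle is intronic).
#' @return Character vector, one label per call.
#' @export
classify_circle_region <- function(calls, genes) {
  .check_calls(calls)
  gt <- .check_genes(genes)
  ex <- .exon_table(genes)
  out <- rep("intergenic", nrow(calls))
  if (nrow(calls) == 0) return(out)
  cgr <- .as_granges(calls)
  if (!is.null(ex) && nrow(ex) > 0) {
    hit_ex <- unique(S4Vectors::queryHits(
      .overlaps(cgr, .as_granges(ex))))
    out[hit_ex] <- "exonic"
  }
  if (nrow(gt) > 0) {
    hit_gene <- unique(S4Vectors::queryHits(
      .overlaps(cgr, .as_granges(gt))))
    out[setdiff(hit_gene, which(out == "exonic"))] <- "intronic"
  }
  out
}

#' Wilcoxon rank-sum comparison of two samples of values
#'
#' Mann-Whitney/Wilcoxon rank-sum test for group comparisons of descriptive
#' quantities (unique eccDNA counts, mitochondrial split-read totals, length
#' distributions between region classes). Uses the exact null distribution
#' for small tie-free samples and the tie-corrected normal approximation
#' with continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (both nonempty).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"` (the
#'   alternative that `values_a` is shifted relative to `values_b`).
#' @return List with `statistic` (Mann-Whitney U for `values_a`) and
#'   `p_value`.
#' @export
compare_groups_ranksum <- function(values_a, values_b,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       exact = NULL, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
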