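# End-to-end pipeline: process -> quantify -> differential (scaled and
# unscaled) -> democratic voting per group -> whole-gene detection, with a
# reproducible run manifest.

#' Run the full eccDNA differential pipeline
#'
#' Executes every stage on an in-memory dataset: the per-sample filter /
#' merge / split-read cascade, PpGC quantification with gene-length scaling
#' and log2 equalization, DPpGC calling on both the scaled and the unscaled
#' table (the two runs share one code path; the unscaled variant simply
#' skips the scale factor), the scaled-vs-unscaled rank comparison,
#' democratic CPpGC voting within each group, the CPpGC overlap between
#' groups, and whole-gene detection. Stage record counts are collected so
#' the filter cascade is auditable.
#'
#' @param calls Raw circle-call data frame covering all samples (e.g. from
#'   [read_circle_calls()] rbind-ed, or [simulate_eccdna()]).
#' @param genes A `gene_annotation`.
#' @param samples Sample sheet data frame.
#' @param params A [processing_params()].
#' @param theta,alpha,mtc,welch Differential settings, see [difcir()].
#' @param min_votes Democratic vote quorum.
#' @param min_samples Whole-gene recurrence minimum.
#' @param bin_width Histogram bin width for [vote_threshold()].
#' @param l_max_from Longest-gene choice for scaling, see
#'   [scale_by_gene_length()].
#' @param groups Optional explicit (A, B) group labels.
#' @return A list of class `difcir_run` with elements `processed`,
#'   `mito_sr`, `counts`, `ppgc` (list of `raw`, `scaled`, `equalized`,
#'   `equalized_unscaled`), `fit`, `fit_unscaled`, `rank_comparison`,
#'   `votes` (per group: threshold and vote table), `cppgc_overlap`,
#'   `whole_gene`, and `manifest` (parameters and stage record counts).
#' @export
run_difcir <- function(calls, genes, samples,
                       params = processing_params(),
                       theta = 1, alpha = 0.05, mtc = "none", welch = FALSE,
                       min_votes = 4, min_samples = 2, bin_width = 0.5,
                       l_max_from = "table", groups = NULL) {
  if (inherits(calls, "eccdna_sim")) {
    if (missing(genes)) genes <- calls$genes
    if (missing(samples)) samples <- calls$samples
    calls <- calls$calls
  }
  .check_calls(calls)
  .check_sample_sheet(samples)
  .check_genes(genes)

  proc <- process_circles(calls, params)
  mito_by_sample <- split(proc$mito, proc$mito$sample_id)
  mito_sr <- vapply(samples$sample_id, function(s) {
    m <- mito_by_sample[[s]]
    if (is.null(m)) 0 else count_mt_split_reads(m)
  }, numeric(1))
  counts <- count_unique_eccdna(proc$kept, sample_ids = samples$sample_id)

  pairs <- annotate_circles(proc$kept, genes)
  raw <- compute_ppgc(pairs, samples, genes)
  scaled <- scale_by_gene_length(raw, l_max_from = l_max_from)
  eq <- equalize(scaled)
  eq_unscaled <- equalize(raw)

  fit <- difcir(eq, samples, theta = theta, alpha = alpha, mtc = mtc,
                welch = welch, groups = groups)
  fit_unscaled <- difcir(eq_unscaled, samples, theta = theta, alpha = alpha,
                         mtc = mtc, welch = welch, groups = groups)
  rank_cmp <- compare_scaling_ranks(fit, fit_unscaled)

  lev <- .group_levels(samples, groups)
  votes <- lapply(stats::setNames(lev, lev), function(g) {
    ids <- samples$sample_id[samples$group == g]
    thr <- tryCatch(vote_threshold(eq, ids, bin_width = bin_width),
                    error = function(e) NA_real_)
    tab <- if (is.na(thr)) NULL
           else vote_cppgc(eq, ids, threshold = thr, min_votes = min_votes)
    list(threshold = thr, table = tab)
  })
  overlap <- if (!is.null(votes[[1]]$table) && !is.null(votes[[2]]$table)) {
    cppgc_overlap(votes[[1]]$table, votes[[2]]$table)
  } else NULL

  wg <- find_whole_gene_circles(proc$kept, genes, min_samples = min_samples,
                                sample_ids = samples$sample_id)

  manifest <- list(
    params = unclass(params),
    theta = theta, alpha = alpha, mtc = mtc, welch = welch,
    min_votes = min_votes, min_samples = min_samples,
    bin_width = bin_width, l_max_from = l_max_from,
    groups = lev, n_samples = nrow(samples),
    stage_counts = c(proc$log,
                     annotated_pairs = nrow(pairs),
                     genes_quantified = nrow(raw$values)))

  structure(list(processed = proc$kept, mito_sr = mito_sr, counts = counts,
                 ppgc = list(raw = raw, scaled = scaled, equalized = eq,
                             equalized_unscaled = eq_unscaled),
                 fit = fit, fit_unscaled = fit_unscaled,
                 rank_comparison = rank_cmp, votes = votes,
                 cppgc_overlap = overlap, whole_gene = wg,
                 manifest = manifest),
            class = "difcir_run")
}

#' @export
print.difcir_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("difcir_run\n")
  cat(sprintf("  calls: %d input -> %d after mito/length filter -> %d merged -> %d after split-read filter\n",
              sc[["input"]], sc[["after_filter"]], sc[["after_merge"]],
              sc[["after_jt"]]))
  cat(sprintf("  PpGC matrix: %d gene(s) x %d sample(s)\n",
              nrow(x$ppgc$raw$values), ncol(x$ppgc$raw$values)))
  print(x$fit)
  for (g in names(x$votes)) {
    v <- x$votes[[g]]
    n_c <- if (is.null(v$table)) 0 else sum(v$table$is_cppgc)
    cat(sprintf("  CPpGCs in %s: %d (vote threshold %s)\n", g, n_c,
                format(v$threshold)))
  }
  cat(sprintf("  whole-gene eccDNA (>= %d sample(s)): %d gene(s)\n",
              x$manifest$min_samples, nrow(x$whole_gene$hits)))
  invisible(x)
}

#' Write all result tables of a pipeline run
#'
#' @param run A `difcir_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "difcir_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    paths <<- c(paths, p)
  }
  put(run$processed, "processed_calls.tsv")
  put(data.frame(sample_id = names(run$counts),
                 unique_eccdna = unname(run$counts),
                 mito_split_reads = unname(run$mito_sr)),
      "sample_summary.tsv")
  for (stage in names(run$ppgc)) {
    put(as.data.frame(run$ppgc[[stage]]), paste0("ppgc_", stage, ".tsv"))
  }
  put(run$fit$records, "differential.tsv")
  put(run$fit_unscaled$records, "differential_unscaled.tsv")
  put(run$rank_comparison$table, "rank_comparison.tsv")
  for (g in names(run$votes)) {
    if (!is.null(run$votes[[g]]$table)) {
      put(run$votes[[g]]$table, paste0("cppgc_", g, ".tsv"))
    }
  }
  put(run$whole_gene$hits, "whole_gene_hits.tsv")
  put(data.frame(gene_id = rownames(run$whole_gene$presence),
                 run$whole_gene$presence, check.names = FALSE),
      "whole_gene_presence.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, manifest_path))
}
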