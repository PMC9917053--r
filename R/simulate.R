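# Seeded synthetic circle-call datasets with known ground truth, so every
# pipeline stage can be validated without external sequencing data.
#
# The generator emulates the structure of processed Circle-Seq call sets:
# per-gene circle production with group-specific rate multipliers,
# nucleosome-periodic circle lengths (~160/320/480 bp peaks plus a long
# tail), shifted-geometric split-read support, intergenic noise circles,
# mitochondrial calls, jittered near-duplicate calls that exercise the
# junction merging, and occasional circles carrying a whole gene. It does
# not emulate read-level artifacts (PCR amplification bias, sequencing
# depth differences, mapping ambiguity), so passing tests validate the
# downstream arithmetic, not robustness to those upstream effects.
#
# Circle start positions are laid on a coarse coordinate grid (spacing
# 2 * d_min) so that distinct circles can never satisfy the both-endpoint
# linkage rule, while near-duplicates (jitter < d_min) always merge back
# onto their parent; the ground-truth PpGC matrix is therefore exact by
# construction. Intergenic noise circles use the grid offset by d_min so
# they cannot link to anything either.

#' Simulation configuration
#'
#' Defaults mirror a two-group Circle-Seq study with 8 samples per group,
#' calibrated against the descriptive statistics of purified skeletal
#' muscle eccDNA: with 120 genes and a baseline of 20 circles per gene per
#' sample, each sample carries on the order of 2,500-3,000 unique circles,
#' and the mode of the group's scaled, log2-equalized per-gene production
#' lands near 6 (about 64 split-read equivalents), matching the magnitude
#' at which the democratic vote threshold operates on real data. Rates are
#' expectations per gene (or per sample) and all randomness is governed by
#' the seed passed to [simulate_eccdna()].
#'
#' @param n_chroms Number of nuclear chromosomes.
#' @param genes_per_chrom Genes laid per chromosome.
#' @param gene_length_range Gene-body length range (bp).
#' @param gap_range Intergenic gap range (bp).
#' @param n_samples_per_group Samples per group (two groups).
#' @param group_labels The two group labels.
#' @param baseline_rate Expected circles per gene per sample (Poisson).
#' @param spike Optional data frame (`gene_id`, `group`, `multiplier`)
#'   multiplying the production rate of chosen genes in one group.
#' @param split_read_prob Success probability of the shifted geometric law
#'   for split-read counts (minimum 1; mean 1/p).
#' @param length_peaks,length_peak_weights,length_sd Periodic circle-length
#'   peaks (bp), their mixture weights, and the within-peak spread.
#' @param tail_weight,tail_mean Weight and mean (bp) of the exponential
#'   long-length tail.
#' @param mito_rate Expected mitochondrial calls per sample (Poisson).
#' @param noise Intergenic noise circles as a fraction of the expected
#'   genic circle count.
#' @param near_duplicate_rate Probability that a genic circle emits a
#'   jittered duplicate call (jitter < `d_min`), exercising the merge.
#' @param whole_gene_rate Probability per gene per sample of a circle
#'   containing the whole gene.
#' @param d_min,l_max,jt_min Processing parameters the ground truth
#'   accounts for (see [processing_params()]).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 4,
                              genes_per_chrom = 30,
                              gene_length_range = c(2000, 50000),
                              gap_range = c(10000, 30000),
                              n_samples_per_group = 8,
                              group_labels = c("A", "B"),
                              baseline_rate = 20,
                              spike = NULL,
                              split_read_prob = 0.5,
                              length_peaks = c(160, 320, 480),
                              length_peak_weights = c(5, 3, 1),
                              length_sd = 15,
                              tail_weight = 0.1,
                              tail_mean = 2000,
                              mito_rate = 5,
                              noise = 0.2,
                              near_duplicate_rate = 0.1,
                              whole_gene_rate = 0.02,
                              d_min = 10, l_max = 100000, jt_min = 2) {
  stopifnot(n_chroms >= 1, genes_per_chrom >= 1,
            n_samples_per_group >= 2, length(group_labels) == 2)
  rates <- c(baseline_rate, mito_rate, noise, near_duplicate_rate,
             whole_gene_rate, tail_weight)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (split_read_prob <= 0 || split_read_prob > 1) {
    stop("split_read_prob must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(spike) &&
      !all(c("gene_id", "group", "multiplier") %in% names(spike))) {
    stop("spike needs columns gene_id, group, multiplier", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic circle-call dataset with ground truth
#'
#' Builds a genome layout, a two-group sample sheet, and per-sample circle
#' calls under the configured production model. The returned ground truth
#' holds what the pipeline should recover: the per-gene split-read totals
#' per sample after merging and the minimum split-read filter
#' (`truth$ppgc`), the per-sample unique-circle counts (`truth$counts`),
#' the raw mitochondrial split-read totals (`truth$mito_sr`), the
#' whole-gene carrying events (`truth$whole_gene`), and the spiked gene
#' set (`truth$spike`). The same seed reproduces the dataset bit-for-bit.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed fixing the entire dataset.
#' @param out_dir Optional directory; when given, per-sample generic-bed
#'   call files, the gene/exon BEDs, the sample sheet, and the truth tables
#'   are written there as TSV.
#' @return A list of class `eccdna_sim`: `calls` (raw calls, all samples),
#'   `genes` (a `gene_annotation`), `samples` (sample sheet), `truth`,
#'   `config`, `seed`.
#' @export
simulate_eccdna <- function(config = simulation_config(), seed = 1,
                            out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  cfg <- config
  grid <- 2 * cfg$d_min

  # Genome layout: genes separated by intergenic gaps, coordinates gridded.
  genes <- list(); exons <- list()
  gap_starts <- list()   # per chromosome: gap intervals for noise circles
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- paste0("chr", ci)
    pos <- 0
    for (gi in seq_len(cfg$genes_per_chrom)) {
      gap <- round(stats::runif(1, cfg$gap_range[1], cfg$gap_range[2]) /
                     grid) * grid
      len <- round(stats::runif(1, cfg$gene_length_range[1],
                                cfg$gene_length_range[2]) / grid) * grid
      gs <- pos + gap; ge <- gs + len
      gid <- sprintf("G%02d_%03d", ci, gi)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = gid, gene_name = gid, chrom = chrom, start = gs, end = ge,
        stringsAsFactors = FALSE)
      gap_starts[[length(gap_starts) + 1]] <- data.frame(
        chrom = chrom, start = pos, end = gs, stringsAsFactors = FALSE)
      n_ex <- sample(1:4, 1)
      ex_s <- sort(sample(seq(gs, ge - 200, by = 100), n_ex))
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = gid, chrom = chrom, start = ex_s,
        end = pmin(ex_s + sample(c(100, 200), n_ex, replace = TRUE), ge),
        stringsAsFactors = FALSE)
      pos <- ge
    }
  }
  gene_tab <- do.call(rbind, genes)
  gene_tab$length <- gene_tab$end - gene_tab$start
  annotation <- gene_annotation(gene_tab, do.call(rbind, exons))
  gaps <- do.call(rbind, gap_starts)

  samples <- data.frame(
    sample_id = c(paste0(cfg$group_labels[1], seq_len(cfg$n_samples_per_group)),
                  paste0(cfg$group_labels[2], seq_len(cfg$n_samples_per_group))),
    group = rep(cfg$group_labels, each = cfg$n_samples_per_group),
    stringsAsFactors = FALSE)

  rate_for <- function(gene_id, group) {
    r <- cfg$baseline_rate
    if (!is.null(cfg$spike)) {
      hit <- cfg$spike$gene_id == gene_id & cfg$spike$group == group
      if (any(hit)) r <- r * cfg$spike$multiplier[which(hit)[1]]
    }
    r
  }
  draw_sr <- function(n) 1 + stats::rgeom(n, cfg$split_read_prob)
  draw_len <- function(n, max_len) {
    tail <- stats::runif(n) < cfg$tail_weight
    peak <- sample(seq_along(cfg$length_peaks), n, replace = TRUE,
                   prob = cfg$length_peak_weights)
    len <- round(stats::rnorm(n, cfg$length_peaks[peak], cfg$length_sd))
    len[tail] <- round(stats::rexp(sum(tail), 1 / cfg$tail_mean)) + 100
    pmax(pmin(len, max_len), 50)
  }

  calls <- list()
  truth_ppgc <- matrix(0, nrow = nrow(gene_tab), ncol = nrow(samples),
                       dimnames = list(gene_tab$gene_id, samples$sample_id))
  truth_counts <- stats::setNames(integer(nrow(samples)), samples$sample_id)
  truth_mito <- stats::setNames(numeric(nrow(samples)), samples$sample_id)
  truth_wg <- list()

  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    grp <- samples$group[si]
    # Vector accumulators: one element per emitted call.
    a_chrom <- list(); a_start <- list(); a_end <- list(); a_sr <- list()
    emit <- function(chrom, start, end, sr) {
      i <- length(a_chrom) + 1L
      a_chrom[[i]] <<- rep_len(chrom, length(start))
      a_start[[i]] <<- start; a_end[[i]] <<- end; a_sr[[i]] <<- sr
    }

    for (gi in seq_len(nrow(gene_tab))) {
      g <- gene_tab[gi, ]
      n_circ <- stats::rpois(1, rate_for(g$gene_id, grp))
      if (n_circ > 0) {
        # Circles are gene fragments: cap at half the gene body so even
        # short genes keep many distinct placement slots.
        max_len <- min(floor(g$length / 2), cfg$l_max - cfg$d_min)
        lens <- draw_len(n_circ, max_len)
        # Distinct grid slots within the gene so distinct circles can
        # never fall within linking distance of one another.
        n_slots <- floor((g$length - max(lens)) / grid) + 1L
        n_circ <- min(n_circ, n_slots)
        lens <- lens[seq_len(n_circ)]
        slot <- sample.int(n_slots, n_circ, replace = FALSE)
        st <- g$start + grid * (slot - 1L)
        en <- st + lens
        sr <- draw_sr(n_circ)
        emit(g$chrom, st, en, sr)
        dup <- stats::runif(n_circ) < cfg$near_duplicate_rate
        totals <- sr
        if (any(dup)) {
          nd <- sum(dup)
          js <- sample.int(cfg$d_min - 1, nd, replace = TRUE)
          je <- sample.int(cfg$d_min - 1, nd, replace = TRUE)
          dup_sr <- draw_sr(nd)
          emit(g$chrom, st[dup] + js, en[dup] + je, dup_sr)
          totals[dup] <- totals[dup] + dup_sr
        }
        keep <- totals >= cfg$jt_min
        truth_ppgc[g$gene_id, sid] <- truth_ppgc[g$gene_id, sid] +
          sum(totals[keep])
        truth_counts[sid] <- truth_counts[sid] + sum(keep)
      }
      if (stats::runif(1) < cfg$whole_gene_rate) {
        ext <- grid * sample.int(4, 2, replace = TRUE)
        st <- g$start - ext[1]; en <- g$end + ext[2]
        if (st >= 0 && (en - st) <= cfg$l_max) {
          sr <- max(draw_sr(1), cfg$jt_min)   # whole-gene events well supported
          emit(g$chrom, st, en, sr)
          truth_ppgc[g$gene_id, sid] <- truth_ppgc[g$gene_id, sid] + sr
          truth_counts[sid] <- truth_counts[sid] + 1L
          truth_wg[[length(truth_wg) + 1]] <- data.frame(
            gene_id = g$gene_id, sample_id = sid, stringsAsFactors = FALSE)
        }
      }
    }

    # Intergenic noise circles, on the offset grid inside gaps.
    n_noise <- stats::rpois(1, cfg$noise * nrow(gene_tab) * cfg$baseline_rate)
    if (n_noise > 0) {
      wide <- gaps[gaps$end - gaps$start > 2000, , drop = FALSE]
      pick <- sample.int(nrow(wide), n_noise, replace = TRUE)
      w <- wide$end[pick] - wide$start[pick]
      len <- draw_len(n_noise, w - 2 * grid)
      slots <- floor((w - len - cfg$d_min) / grid)
      k <- vapply(slots, function(s) sample.int(s + 1, 1), integer(1)) - 1L
      st <- wide$start[pick] + cfg$d_min + grid * k
      sr <- draw_sr(n_noise)
      i <- length(a_chrom) + 1L
      a_chrom[[i]] <- wide$chrom[pick]
      a_start[[i]] <- st; a_end[[i]] <- st + len; a_sr[[i]] <- sr
      truth_counts[sid] <- truth_counts[sid] + sum(sr >= cfg$jt_min)
    }

    n_mito <- stats::rpois(1, cfg$mito_rate)
    if (n_mito > 0) {
      st <- sort(sample(seq(0, 16000, by = grid), n_mito, replace = FALSE))
      sr <- draw_sr(n_mito)
      emit("chrM", st,
           pmin(st + 200 + round(stats::rexp(n_mito, 1 / 500)), 16569), sr)
      truth_mito[sid] <- sum(sr)
    }

    calls[[si]] <- data.frame(
      chrom = unlist(a_chrom), start = unlist(a_start),
      end = unlist(a_end), split_reads = unlist(a_sr),
      sample_id = sid, stringsAsFactors = FALSE)
  }

  calls <- do.call(rbind, c(calls, make.row.names = FALSE))
  if (is.null(calls) || nrow(calls) == 0) calls <- .empty_calls()
  truth_wg <- if (length(truth_wg) > 0) {
    unique(do.call(rbind, c(truth_wg, make.row.names = FALSE)))
  } else {
    data.frame(gene_id = character(0), sample_id = character(0),
               stringsAsFactors = FALSE)
  }

  sim <- structure(list(
    calls = calls, genes = annotation, samples = samples,
    truth = list(ppgc = truth_ppgc, counts = truth_counts,
                 mito_sr = truth_mito, whole_gene = truth_wg,
                 spike = cfg$spike),
    config = cfg, seed = as.integer(seed)), class = "eccdna_sim")

  if (!is.null(out_dir)) .write_sim(sim, out_dir)
  sim
}

#' @export
print.eccdna_sim <- function(x, ...) {
  cat(sprintf(
    "eccdna_sim (seed %d): %d call(s), %d sample(s), %d gene(s)\n",
    x$seed, nrow(x$calls), nrow(x$samples), nrow(x$genes$genes)))
  invisible(x)
}

.write_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in sim$samples$sample_id) {
    sub <- sim$calls[sim$calls$sample_id == sid,
                     c("chrom", "start", "end", "split_reads"), drop = FALSE]
    utils::write.table(sub, file.path(out_dir, paste0(sid, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  gt <- sim$genes$genes
  utils::write.table(gt[, c("chrom", "start", "end", "gene_id", "gene_name")],
                     file.path(out_dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$genes$exons[, c("chrom", "start", "end", "gene_id")],
                     file.path(out_dir, "exons.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_table(sim$samples, file.path(out_dir, "sample_sheet.tsv"))
  truth <- data.frame(gene_id = rownames(sim$truth$ppgc),
                      sim$truth$ppgc, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write_table(truth, file.path(out_dir, "truth_ppgc.tsv"))
  write_table(data.frame(sample_id = names(sim$truth$counts),
                         unique_eccdna = unname(sim$truth$counts),
                         mito_split_reads = unname(sim$truth$mito_sr)),
              file.path(out_dir, "truth_samples.tsv"))
  write_table(sim$truth$whole_gene, file.path(out_dir, "truth_whole_gene.tsv"))
  invisible(NULL)
}

#' Hand-computed worked micro-dataset
#'
#' A deterministic 3-chromosome, 8-gene, 2 x 4-sample fixture of 43 raw
#' circle calls, small enough that every pipeline stage has been worked out
#' by hand. It exercises the filter boundary cases (one circle of length
#' exactly 100 kb is kept; split-read counts equal to the minimum are
#' kept; one pair of calls at endpoint distance exactly 10 bp is not
#' merged), one genuine merge of jittered duplicates, mitochondrial calls,
#' an over-long circle that is filtered, a sub-threshold circle removed by
#' the split-read filter, and one gene fully carried by circles in two
#' samples.
#'
#' @return A list with `calls`, `genes` (a `gene_annotation`), `samples`,
#'   `params` (the default [processing_params()]), and `expected` -- the
#'   hand-computed stage outputs: per-sample unique-circle `counts`,
#'   `mito_sr` totals, the raw PpGC `ppgc_raw` matrix, scale factors and
#'   the longest-gene length, the up-DPpGC gene per direction, the
#'   democratic vote thresholds and CPpGC sets per group, and the
#'   whole-gene hit table.
#' @export
worked_toy_dataset <- function() {
  g <- function(id, chrom, start, end) {
    data.frame(gene_id = id, gene_name = id, chrom = chrom,
               start = start, end = end, stringsAsFactors = FALSE)
  }
  genes <- rbind(
    g("G1", "chr1", 1000, 6000), g("G2", "chr1", 10000, 30000),
    g("G3", "chr1", 40000, 41000), g("G4", "chr2", 0, 40000),
    g("G5", "chr2", 50000, 52000), g("G6", "chr3", 5000, 15000),
    g("G7", "chr3", 20000, 24000), g("G8", "chr3", 30000, 31000))
  exons <- data.frame(
    gene_id = c("G1", "G1", "G1", "G6", "G6"),
    chrom = c("chr1", "chr1", "chr1", "chr3", "chr3"),
    start = c(1000, 3000, 5500, 5000, 14000),
    end = c(1500, 3500, 6000, 5500, 15000),
    stringsAsFactors = FALSE)
  annotation <- gene_annotation(genes, exons)

  cc <- function(sid, chrom, start, end, sr) {
    data.frame(chrom = chrom, start = start, end = end, split_reads = sr,
               sample_id = sid, stringsAsFactors = FALSE)
  }
  calls <- rbind(
    # A1: a jittered duplicate pair that merges, a boundary-length circle
    # (exactly 100 kb, kept), a sub-threshold circle (1 split read,
    # dropped), a mitochondrial call, an over-long circle (dropped).
    cc("A1", "chr1", 1100, 1600, 5), cc("A1", "chr1", 1105, 1595, 3),
    cc("A1", "chr1", 2000, 2500, 4), cc("A1", "chr1", 40000, 41000, 6),
    cc("A1", "chr2", 5000, 6000, 3), cc("A1", "chr2", 60000, 160000, 2),
    cc("A1", "chr3", 6000, 6400, 1), cc("A1", "chrM", 0, 16000, 9),
    cc("A1", "chr1", 200000, 350000, 7),
    # A2: second whole-gene carrier of G3.
    cc("A2", "chr1", 1200, 1700, 6), cc("A2", "chr1", 3000, 3800, 7),
    cc("A2", "chr1", 39990, 41050, 5), cc("A2", "chr2", 10000, 10010, 2),
    cc("A2", "chr3", 20500, 20700, 2), cc("A2", "chrM", 100, 300, 4),
    # A3
    cc("A3", "chr1", 1500, 2200, 9), cc("A3", "chr2", 20000, 21000, 3),
    cc("A3", "chr3", 9000, 9200, 2), cc("A3", "chr1", 100, 700, 2),
    # A4: endpoint distance exactly d_min = 10, must NOT merge.
    cc("A4", "chr1", 4000, 4600, 8), cc("A4", "chr1", 4610, 4800, 2),
    cc("A4", "chr2", 30000, 30500, 2), cc("A4", "chr3", 22000, 22300, 2),
    cc("A4", "chr3", 22010, 22310, 3), cc("A4", "chrM", 500, 1500, 3),
    # B group: G6 production dominates.
    cc("B1", "chr3", 6000, 6500, 7), cc("B1", "chr3", 7000, 7900, 6),
    cc("B1", "chr1", 1300, 1500, 2), cc("B1", "chr2", 15000, 15600, 3),
    cc("B1", "chrM", 0, 16000, 11),
    cc("B2", "chr3", 8000, 8400, 9), cc("B2", "chr3", 12000, 12500, 5),
    cc("B2", "chr2", 100, 900, 2), cc("B2", "chr3", 30100, 30800, 4),
    cc("B3", "chr3", 5500, 6100, 8), cc("B3", "chr3", 13000, 13900, 4),
    cc("B3", "chr1", 2500, 2900, 2), cc("B3", "chr2", 35000, 35800, 2),
    cc("B3", "chr3", 19000, 25000, 6),
    cc("B4", "chr3", 6200, 6800, 6), cc("B4", "chr3", 14000, 14800, 7),
    cc("B4", "chr2", 8000, 8700, 3), cc("B4", "chrM", 200, 400, 2))

  samples <- data.frame(
    sample_id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4"),
    group = rep(c("A", "B"), each = 4), stringsAsFactors = FALSE)

  sample_ids <- samples$sample_id
  ppgc_raw <- matrix(
    c(12, 13, 9, 10, 2, 0, 2, 0,      # G1
      6, 5, 0, 0, 0, 0, 0, 0,         # G3
      3, 2, 3, 2, 3, 2, 2, 3,         # G4
      0, 0, 2, 0, 13, 14, 12, 13,     # G6
      0, 2, 0, 5, 0, 0, 6, 0,         # G7
      0, 0, 0, 0, 0, 4, 0, 0),        # G8
    nrow = 6, byrow = TRUE,
    dimnames = list(c("G1", "G3", "G4", "G6", "G7", "G8"), sample_ids))

  expected <- list(
    counts = stats::setNames(c(5L, 5L, 4L, 5L, 4L, 4L, 5L, 3L), sample_ids),
    mito_sr = stats::setNames(c(9, 4, 0, 3, 11, 0, 0, 2), sample_ids),
    merged_a1 = data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3"),
      start = c(1100, 2000, 40000, 5000, 60000, 6000),
      end = c(1600, 2500, 41000, 6000, 160000, 6400),
      split_reads = c(8, 4, 6, 3, 2, 1),
      sample_id = "A1", stringsAsFactors = FALSE),
    ppgc_raw = ppgc_raw,
    l_max_gene = 40000,
    scale_factors = stats::setNames(c(8, 40, 1, 4, 10, 40),
                                    rownames(ppgc_raw)),
    up_in_A = "G1", up_in_B = "G6",
    vote_threshold = c(A = 6, B = 5),
    cppgc = list(A = "G1", B = "G6"),
    whole_gene = data.frame(gene_id = "G3", gene_length = 1000,
                            n_samples = 2L, samples = "A1,A2",
                            stringsAsFactors = FALSE))

  list(calls = calls, genes = annotation, samples = samples,
       params = processing_params(), expected = expected)
}
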