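cc <- function(chrom, start, end, sr, sid = "S1") {
  data.frame(chrom = chrom, start = start, end = end, split_reads = sr,
             sample_id = sid, stringsAsFactors = FALSE)
}

two_sample_sheet <- function(ids_a, ids_b, labels = c("A", "B")) {
  data.frame(sample_id = c(ids_a, ids_b),
             group = rep(labels, c(length(ids_a), length(ids_b))),
             stringsAsFactors = FALSE)
}

test_that("gene-body overlap pairs respect half-open adjacency", {
  genes <- rand_genes(0)
  genes <- data.frame(gene_id = c("GA", "GB"), gene_name = c("GA", "GB"),
                      chrom = "chr1", start = c(400, 500),
                      end = c(900, 900), stringsAsFactors = FALSE)
  pairs <- annotate_circles(cc("chr1", 100, 500, 3), genes)
  expect_equal(pairs$gene_id, "GA")   # [100,500) vs [500,900) do not touch

  # A circle over two genes yields two pairs.
  pairs2 <- annotate_circles(cc("chr1", 100, 600, 4), genes)
  expect_setequal(pairs2$gene_id, c("GA", "GB"))
  expect_equal(pairs2$split_reads, c(4, 4))

  expect_equal(nrow(annotate_circles(cc("chr5", 0, 100, 2), genes)), 0)
})

test_that("overlap pairs match the all-pairs brute-force oracle", {
  withr::local_seed(202)
  for (rep in 1:40) {
    calls <- rand_calls(sample.int(40, 1))
    genes <- rand_genes(sample.int(25, 1))
    got <- annotate_circles(calls, genes)
    want <- oracle_overlap_pairs(calls, genes)
    got_keys <- sort(paste(got$start, got$end, got$gene_id))
    want_keys <- sort(paste(calls$start[want$i], calls$end[want$i],
                            want$gene_id))
    expect_identical(got_keys, want_keys)
  }
})

test_that("PpGC matrix sums split reads per gene and sample", {
  genes <- data.frame(gene_id = c("GA", "GB"), gene_name = c("GA", "GB"),
                      chrom = "chr1", start = c(0, 2000),
                      end = c(1000, 3000), stringsAsFactors = FALSE)
  sheet <- two_sample_sheet(c("S1", "S2"), "S3")
  calls <- rbind(cc("chr1", 100, 300, 3, "S1"), cc("chr1", 400, 600, 5, "S1"),
                 cc("chr1", 2100, 2200, 2, "S2"))
  tab <- compute_ppgc(annotate_circles(calls, genes), sheet, genes)
  expect_s3_class(tab, "ppgc_table")
  expect_equal(tab$stage, "raw")
  expect_equal(tab$values["GA", "S1"], 8)
  expect_equal(tab$values["GB", "S2"], 2)
  expect_equal(unname(tab$values[, "S3"]), c(0, 0))   # sample kept as zeros

  # A circle overlapping both genes counts fully toward each.
  both <- annotate_circles(cc("chr1", 900, 2100, 4, "S1"), genes)
  tab2 <- compute_ppgc(both, sheet, genes)
  expect_equal(unname(tab2$values[, "S1"]), c(4, 4))

  bad <- annotate_circles(cc("chr1", 100, 300, 3, "S9"), genes)
  expect_error(compute_ppgc(bad, sheet, genes), "S9")
})

test_that("quantification is additive over call batches", {
  withr::local_seed(303)
  genes <- rand_genes(12)
  sheet <- two_sample_sheet(c("S1", "S2"), c("S3", "S4"))
  calls <- do.call(rbind, lapply(sheet$sample_id, function(s)
    rand_calls(30, sample_id = s)))
  split_idx <- sample(c(TRUE, FALSE), nrow(calls), replace = TRUE)
  whole <- compute_ppgc(annotate_circles(calls, genes), sheet, genes)
  p1 <- annotate_circles(calls[split_idx, ], genes)
  p2 <- annotate_circles(calls[!split_idx, ], genes)
  m1 <- compute_ppgc(p1, sheet, genes)
  m2 <- compute_ppgc(p2, sheet, genes)
  added <- matrix(0, nrow(whole$values), ncol(whole$values),
                  dimnames = dimnames(whole$values))
  added[rownames(m1$values), ] <- added[rownames(m1$values), ] + m1$values
  added[rownames(m2$values), ] <- added[rownames(m2$values), ] + m2$values
  expect_equal(added, whole$values)
})

test_that("gene-length scaling uses the longest gene and preserves sample ratios", {
  values <- matrix(c(2, 2, 2, 2), nrow = 2,
                   dimnames = list(c("GA", "GB"), c("S1", "S2")))
  lens <- c(GA = 10000, GB = 5000)
  raw <- ppgc_table(values, lens, stage = "raw")
  sc <- scale_by_gene_length(raw)
  expect_equal(sc$l_max_gene, 10000)
  expect_equal(unname(sc$values["GA", ]), c(2, 2))   # longest gene unchanged
  expect_equal(unname(sc$values["GB", ]), c(4, 4))

  single <- scale_by_gene_length(ppgc_table(values["GA", , drop = FALSE],
                                            lens["GA"], stage = "raw"))
  expect_equal(single$values, values["GA", , drop = FALSE])

  withr::local_seed(9)
  vals <- matrix(rpois(60, 20) + 1, nrow = 10,
                 dimnames = list(sprintf("G%02d", 1:10), sprintf("S%d", 1:6)))
  lens2 <- stats::setNames(sample.int(50000, 10) + 1000, rownames(vals))
  sc2 <- scale_by_gene_length(ppgc_table(vals, lens2, stage = "raw"))
  expect_equal(sc2$values[, 1] / sc2$values[, 2], vals[, 1] / vals[, 2])
  # Annotation-wide longest gene as the alternative numerator.
  ann_lens <- c(lens2, OTHER = 90000)
  sc3 <- scale_by_gene_length(ppgc_table(vals, lens2, stage = "raw",
                                         annotation_lengths = ann_lens),
                              l_max_from = "annotation")
  expect_equal(sc3$l_max_gene, 90000)
})

test_that("log2 equalization has the right closed forms and monotonicity", {
  values <- matrix(c(0, 1, 3, 7), nrow = 2,
                   dimnames = list(c("GA", "GB"), c("S1", "S2")))
  eq <- equalize(ppgc_table(values, c(GA = 100, GB = 200), stage = "raw"))
  expect_equal(unname(eq$values), matrix(c(0, 1, 2, 3), nrow = 2))
  expect_equal(eq$stage, "equalized")
  expect_error(equalize(eq), "already")
  # Ordering of any pair of cells is preserved.
  withr::local_seed(2)
  v <- matrix(runif(40, 0, 100), nrow = 8,
              dimnames = list(sprintf("G%d", 1:8), sprintf("S%d", 1:5)))
  e <- equalize(ppgc_table(v, stats::setNames(rep(1000, 8), rownames(v)),
                           stage = "raw"))
  expect_identical(order(v), order(e$values))
})
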