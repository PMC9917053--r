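sheet_ab <- function(na = 4, nb = 4, labels = c("A", "B")) {
  data.frame(
    sample_id = c(paste0("A", seq_len(na)), paste0("B", seq_len(nb))),
    group = rep(labels, c(na, nb)), stringsAsFactors = FALSE)
}

rand_table <- function(n_genes, na = 4, nb = 4, shift = 0) {
  m <- matrix(abs(rnorm(n_genes * (na + nb), mean = 5)), nrow = n_genes,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              c(paste0("A", seq_len(na)),
                                paste0("B", seq_len(nb)))))
  m[, seq_len(na)] <- m[, seq_len(na)] + shift
  m
}

test_that("difcir handles degenerate zero-variance rows by the t limits", {
  sheet <- sheet_ab(3, 3)
  m <- rbind(GX = c(5, 5, 5, 1, 1, 1),     # both variances 0, means differ
             GY = c(2, 3, 4, 2, 3, 4),     # identical groups
             GZ = c(4, 4, 4, 4, 4, 4))     # constant everywhere
  colnames(m) <- sheet$sample_id
  fit <- difcir(m, sheet)
  rec <- fit$records
  expect_equal(rec$p_value[rec$gene_id == "GX"], 0)
  expect_equal(rec$direction[rec$gene_id == "GX"], "up_in_A")
  expect_equal(rec$log2fc[rec$gene_id == "GX"], 4)
  expect_equal(rec$p_value[rec$gene_id == "GY"], 1)
  expect_equal(rec$direction[rec$gene_id == "GY"], "none")
  expect_equal(rec$p_value[rec$gene_id == "GZ"], 1)
})

test_that("pooled t p-values match the independent per-row reference to 1e-10", {
  withr::local_seed(404)
  sheet <- sheet_ab(4, 4)
  m <- rand_table(300)
  fit <- difcir(m, sheet)
  rec <- fit$records[match(rownames(m), fit$records$gene_id), ]
  want <- apply(m, 1, function(row) {
    stats::t.test(row[1:4], row[5:8], var.equal = TRUE)$p.value
  })
  expect_lt(max(abs(rec$p_value - want)), 1e-10)

  # The worked example with a known closed-form check.
  a <- c(3.1, 2.9, 3.0, 3.2); b <- c(1.0, 1.2, 0.9, 1.1)
  m1 <- matrix(c(a, b), nrow = 1, dimnames = list("G1", sheet$sample_id))
  p1 <- difcir(m1, sheet)$records$p_value
  expect_equal(p1, stats::t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  # Welch variant against its reference.
  fitw <- difcir(m, sheet, welch = TRUE)
  recw <- fitw$records[match(rownames(m), fitw$records$gene_id), ]
  wantw <- apply(m, 1, function(row) {
    stats::t.test(row[1:4], row[5:8], var.equal = FALSE)$p.value
  })
  expect_lt(max(abs(recw$p_value - wantw)), 1e-10)
})

test_that("selection gates on both the fold-change and significance thresholds", {
  sheet <- sheet_ab(4, 4)
  withr::local_seed(5)
  base <- rand_table(1)
  # Strong but sub-theta shift: significant p yet |log2fc| < theta.
  m <- rbind(SMALL = c(5.0, 5.1, 4.9, 5.0, 4.5, 4.6, 4.4, 4.5),
             BIG = c(9.0, 9.1, 8.9, 9.0, 4.5, 4.6, 4.4, 4.5))
  colnames(m) <- sheet$sample_id
  fit <- difcir(m, sheet, theta = 1, alpha = 0.05)
  rec <- fit$records
  expect_equal(rec$direction[rec$gene_id == "SMALL"], "none")
  expect_equal(rec$direction[rec$gene_id == "BIG"], "up_in_A")
  # theta = 0 admits the small shift too.
  fit0 <- difcir(m, sheet, theta = 0)
  expect_equal(sort(fit0$records$direction), c("up_in_A", "up_in_A"))
  # BH correction is monotone-conservative: never more calls than raw p.
  fitbh <- difcir(m, sheet, mtc = "BH")
  expect_lte(sum(fitbh$records$direction != "none"),
             sum(fit$records$direction != "none"))
})

test_that("swapping group labels negates fold changes and exchanges the up-sets", {
  withr::local_seed(505)
  sheet <- sheet_ab(4, 4)
  m <- rand_table(400)
  m[1:30, 1:4] <- m[1:30, 1:4] + 2.5
  m[31:50, 5:8] <- m[31:50, 5:8] + 2.5
  fit_ab <- difcir(m, sheet, groups = c("A", "B"))
  fit_ba <- difcir(m, sheet, groups = c("B", "A"))
  ra <- fit_ab$records[order(fit_ab$records$gene_id), ]
  rb <- fit_ba$records[order(fit_ba$records$gene_id), ]
  expect_equal(rb$log2fc, -ra$log2fc)
  expect_equal(rb$p_value, ra$p_value)
  expect_identical(rb$gene_id[rb$direction == "up_in_A"],
                   ra$gene_id[ra$direction == "up_in_B"])
  expect_identical(rb$gene_id[rb$direction == "up_in_B"],
                   ra$gene_id[ra$direction == "up_in_A"])
})

test_that("permuting gene rows permutes the records and leaves ranks intact", {
  withr::local_seed(606)
  sheet <- sheet_ab(4, 4)
  m <- rand_table(100)
  m[1:10, 1:4] <- m[1:10, 1:4] + 3
  fit1 <- difcir(m, sheet)
  fit2 <- difcir(m[sample.int(nrow(m)), ], sheet)
  r1 <- fit1$records[order(fit1$records$gene_id), ]
  r2 <- fit2$records[order(fit2$records$gene_id), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
  # Ranks within each direction are 1..n and unique.
  for (d in c("up_in_A", "up_in_B")) {
    rk <- fit1$records$rank[fit1$records$direction == d]
    if (length(rk) > 0) expect_identical(sort(rk), seq_along(rk))
  }
})

test_that("null tables produce a calibrated false-positive fraction", {
  withr::local_seed(707)
  sheet <- sheet_ab(8, 8)
  m <- rand_table(2000, na = 8, nb = 8)
  fit <- difcir(m, sheet, theta = 0)
  frac <- mean(fit$records$p_value <= 0.05)
  band <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("rank comparison separates shared, scaled-only and unscaled-only genes", {
  withr::local_seed(808)
  sheet <- sheet_ab(4, 4)
  m <- rand_table(50)
  m[1:8, 1:4] <- m[1:8, 1:4] + 3
  fit <- difcir(m, sheet)
  same <- compare_scaling_ranks(fit, fit)
  expect_true(all(same$table$membership == "both"))
  expect_true(all(same$table$rank_delta == 0))
  expect_equal(unname(same$summary[c("ascending", "descending")]), c(0, 0))

  # Scaling as a no-op: equal gene lengths make scaled == raw, so the two
  # variants coincide end-to-end.
  vals <- matrix(rpois(50 * 8, 30), nrow = 50,
                 dimnames = list(sprintf("G%04d", 1:50), sheet$sample_id))
  vals[1:6, 1:4] <- vals[1:6, 1:4] * 8
  lens <- stats::setNames(rep(20000, 50), rownames(vals))
  raw <- ppgc_table(vals, lens, stage = "raw")
  fit_scaled <- difcir(equalize(scale_by_gene_length(raw)), sheet)
  fit_unscaled <- difcir(equalize(raw), sheet)
  expect_equal(fit_scaled$records, fit_unscaled$records)

  # A gene significant in only one run is labelled accordingly.
  rec_minus <- fit$records[fit$records$gene_id != fit$records$gene_id[1], ]
  cmp <- compare_scaling_ranks(fit, rec_minus)
  only <- cmp$table$membership[cmp$table$gene_id == fit$records$gene_id[1]]
  expect_equal(only, "scaled-only")
})

test_that("length-bias regression recovers collinear, flat, and null patterns", {
  rec <- data.frame(gene_id = sprintf("G%d", 1:5),
                    p_value = rep(0.01, 5),
                    direction = "up_in_A", stringsAsFactors = FALSE)
  lens <- stats::setNames(c(1, 2, 3, 4, 5) * 1000, rec$gene_id)
  flat <- length_bias_regression(rec, lens)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  rec2 <- rec
  rec2$p_value <- 10^(-(1:5))   # -log10 p exactly collinear with length
  lin <- length_bias_regression(rec2, lens)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$slope, 1 / 1000, tolerance = 1e-12)

  withr::local_seed(909)
  rec3 <- data.frame(gene_id = sprintf("G%d", 1:150),
                     p_value = runif(150, 1e-6, 0.05),
                     direction = "up_in_A", stringsAsFactors = FALSE)
  lens3 <- stats::setNames(runif(150, 1000, 2e5), rec3$gene_id)
  null <- length_bias_regression(rec3, lens3)
  expect_lt(abs(null$r_squared), 0.1)

  expect_error(length_bias_regression(rec[1:2, ], lens), ">= 3")
})
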