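# Differential analysis of PpGC tables: per-gene two-group comparison on
# the equalized scale, with threshold-based DPpGC selection, rank
# comparison between scaled and unscaled runs, and the gene-length bias
# regression.

#' Call differentially produced per-gene circles (DPpGCs)
#'
#' Fits the per-gene two-group model on the equalized PpGC table: for each
#' gene the two group means are computed, their difference is the log2 fold
#' change, and a two-sample Student's t-test (pooled variance by default)
#' gives the p-value. A gene is called up in group A when log2FC >= `theta`
#' and p <= `alpha`, and up in group B when -log2FC >= `theta` and
#' p <= `alpha`; everything else gets direction `"none"`. Significant
#' records are ranked within each direction by p ascending, then |log2FC|
#' descending, then gene id.
#'
#' Zero-variance degenerate rows follow the limits of the t statistic: if
#' both group variances are zero and the means differ, p = 0 (infinite t);
#' if additionally the means are equal, p = 1.
#'
#' @param table An equalized `ppgc_table`, or a plain numeric genes x
#'   samples matrix already on the equalized scale.
#' @param samples Sample sheet data frame (`sample_id`, `group`); exactly
#'   two groups, each with >= 2 samples.
#' @param theta Log2 fold-change selection threshold (>= 0).
#' @param alpha Significance threshold on the (optionally adjusted) p-value.
#' @param mtc Multiple-testing correction: `"none"` (raw p-values, the
#'   default) or `"BH"` (Benjamini-Hochberg; selection then gates on the
#'   adjusted p-value).
#' @param welch Use the Welch unequal-variance t-test instead of the pooled
#'   Student's t-test.
#' @param groups Optional length-2 vector fixing which group label is A and
#'   which is B; defaults to order of first appearance in the sheet.
#' @return An object of class `difcir`: the record table (`gene_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `t`, `p_value`, optionally `p_adj`,
#'   `direction`, `rank`) plus the fit settings. Methods: `print`,
#'   `summary`, `coef` (named log2FC vector), `plot` (volcano),
#'   `as.data.frame`.
#' @examples
#' m <- rbind(GENE_A = c(6, 7, 6.5, 1, 1.2, 0.8),
#'            GENE_B = c(2, 2.1, 1.9, 2, 2.2, 1.8))
#' colnames(m) <- paste0("S", 1:6)
#' sheet <- data.frame(sample_id = paste0("S", 1:6),
#'                     group = rep(c("case", "ctrl"), each = 3))
#' difcir(m, sheet)
#' @export
difcir <- function(table, samples, theta = 1, alpha = 0.05,
                   mtc = c("none", "BH"), welch = FALSE, groups = NULL) {
  mtc <- match.arg(mtc)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  .check_sample_sheet(samples)

  if (inherits(table, "ppgc_table")) {
    if (table$stage != "equalized") {
      stop("difcir expects an equalized table (run equalize() first)",
           call. = FALSE)
    }
    values <- table$values
  } else if (is.matrix(table)) {
    values <- table
  } else {
    stop("`table` must be a ppgc_table or a numeric matrix", call. = FALSE)
  }
  lev <- .group_levels(samples, groups)
  ids_a <- samples$sample_id[samples$group == lev[1]]
  ids_b <- samples$sample_id[samples$group == lev[2]]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  miss <- setdiff(c(ids_a, ids_b), colnames(values))
  if (length(miss) > 0) {
    stop("sample(s) absent from the table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  a <- values[, ids_a, drop = FALSE]
  b <- values[, ids_b, drop = FALSE]

  tt <- .two_sample_t(a, b, welch = welch)
  log2fc <- tt$mean_a - tt$mean_b
  p_adj <- if (mtc == "BH") stats::p.adjust(tt$p, method = "BH") else NULL
  p_gate <- if (is.null(p_adj)) tt$p else p_adj

  direction <- rep("none", nrow(values))
  direction[log2fc >= theta & p_gate <= alpha] <- "up_in_A"
  direction[-log2fc >= theta & p_gate <= alpha] <- "up_in_B"

  rec <- data.frame(gene_id = rownames(values),
                    mean_a = tt$mean_a, mean_b = tt$mean_b,
                    log2fc = log2fc, t = tt$t, p_value = tt$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(p_adj)) rec$p_adj <- p_adj
  rec$direction <- direction
  rec$rank <- NA_integer_
  for (d in c("up_in_A", "up_in_B")) {
    sel <- which(rec$direction == d)
    if (length(sel) > 0) {
      o <- sel[order(rec$p_value[sel], -abs(rec$log2fc[sel]),
                     rec$gene_id[sel])]
      rec$rank[o] <- seq_along(o)
    }
  }
  blk <- match(rec$direction, c("up_in_A", "up_in_B", "none"))
  rec <- rec[order(blk, rec$rank, rec$p_value, rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL

  structure(list(records = rec,
                 group_labels = c(A = lev[1], B = lev[2]),
                 n_samples = c(A = length(ids_a), B = length(ids_b)),
                 theta = theta, alpha = alpha, mtc = mtc, welch = welch),
            class = "difcir")
}

# Vectorised two-sample t-test over matrix rows. Pooled variance by
# default; Welch as an option. Degenerate rows (both variances zero)
# follow the t limits: equal means -> p = 1, distinct means -> p = 0.
.two_sample_t <- function(a, b, welch = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  var_a <- apply(a, 1, stats::var); var_b <- apply(b, 1, stats::var)
  if (welch) {
    se2 <- var_a / na + var_b / nb
    df <- se2^2 / ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(mean_a))
  }
  delta <- mean_a - mean_b
  t_stat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    t_stat[degen] <- ifelse(delta[degen] == 0, 0,
                            sign(delta[degen]) * Inf)
    p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  }
  list(mean_a = mean_a, mean_b = mean_b, t = t_stat, p = p)
}

#' @export
print.difcir <- function(x, ...) {
  n_a <- sum(x$records$direction == "up_in_A")
  n_b <- sum(x$records$direction == "up_in_B")
  cat(sprintf("difcir fit: %d gene(s); groups A = %s (n=%d), B = %s (n=%d)\n",
              nrow(x$records), x$group_labels[["A"]], x$n_samples[["A"]],
              x$group_labels[["B"]], x$n_samples[["B"]]))
  cat(sprintf("  theta = %g, alpha = %g, test = %s, mtc = %s\n", x$theta,
              x$alpha, if (x$welch) "Welch" else "Student (pooled)", x$mtc))
  cat(sprintf("  up-DPpGCs: %d in %s, %d in %s\n", n_a,
              x$group_labels[["A"]], n_b, x$group_labels[["B"]]))
  invisible(x)
}

#' @export
summary.difcir <- function(object, n = 5, ...) {
  print(object)
  for (d in c("up_in_A", "up_in_B")) {
    top <- object$records[object$records$direction == d, , drop = FALSE]
    if (nrow(top) == 0) next
    lbl <- object$group_labels[[sub("up_in_", "", d)]]
    cat(sprintf("\nTop up-DPpGCs in %s:\n", lbl))
    show <- utils::head(top[, c("gene_id", "log2fc", "p_value", "rank")], n)
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.difcir <- function(object, ...) {
  stats::setNames(object$records$log2fc, object$records$gene_id)
}

#' @export
as.data.frame.difcir <- function(x, ...) x$records

#' Volcano plot of a difcir fit
#'
#' @param x A `difcir` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.difcir <- function(x, ...) {
  rec <- x$records
  col <- ifelse(rec$direction == "up_in_A", "firebrick",
                ifelse(rec$direction == "up_in_B", "steelblue", "grey60"))
  graphics::plot(rec$log2fc, -log10(pmax(rec$p_value, 1e-300)), col = col,
                 pch = 16, xlab = "log2 fold change",
                 ylab = "-log10(p-value)", ...)
  graphics::abline(v = c(-x$theta, x$theta), lty = 2, col = "grey40")
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "grey40")
  invisible(x)
}

#' Compare DPpGC ranks between scaled and unscaled runs
#'
#' Given two fits of the same table -- one on gene-length-scaled values,
#' one on unscaled values -- reports, per significant gene and direction,
#' the rank under each run, the rank change, and the membership
#' (`"both"`, `"scaled-only"`, `"unscaled-only"`), plus summary counts of
#' ascending / descending / equal ranks among shared genes.
#'
#' @param with_scaling,without_scaling `difcir` objects (or their record
#'   data frames).
#' @return List with `table` and `summary`.
#' @export
compare_scaling_ranks <- function(with_scaling, without_scaling) {
  recs <- function(x) {
    r <- if (inherits(x, "difcir")) x$records else as.data.frame(x)
    r[r$direction != "none", c("gene_id", "direction", "rank"), drop = FALSE]
  }
  ws <- recs(with_scaling); wo <- recs(without_scaling)
  key_ws <- paste(ws$gene_id, ws$direction)
  key_wo <- paste(wo$gene_id, wo$direction)
  all_keys <- union(key_ws, key_wo)
  i_ws <- match(all_keys, key_ws); i_wo <- match(all_keys, key_wo)
  tab <- data.frame(
    gene_id = ifelse(is.na(i_ws), wo$gene_id[i_wo], ws$gene_id[i_ws]),
    direction = ifelse(is.na(i_ws), wo$direction[i_wo],
                       ws$direction[i_ws]),
    rank_scaled = ws$rank[i_ws],
    rank_unscaled = wo$rank[i_wo],
    stringsAsFactors = FALSE
  )
  tab$rank_delta <- tab$rank_unscaled - tab$rank_scaled
  tab$membership <- ifelse(is.na(tab$rank_scaled), "unscaled-only",
                           ifelse(is.na(tab$rank_unscaled), "scaled-only",
                                  "both"))
  both <- tab$membership == "both"
  summary <- c(ascending = sum(tab$rank_delta[both] > 0),
               descending = sum(tab$rank_delta[both] < 0),
               equal = sum(tab$rank_delta[both] == 0),
               scaled_only = sum(tab$membership == "scaled-only"),
               unscaled_only = sum(tab$membership == "unscaled-only"))
  tab <- tab[order(tab$direction, tab$rank_scaled, tab$rank_unscaled,
                   tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, summary = summary)
}

#' Gene-length bias regression of significant DPpGCs
#'
#' Ordinary least-squares regression of -log10(p) on gene-body length over
#' the significant up-DPpGCs of a fit. A slope near zero and a small R2
#' indicate that gene-length scaling has not introduced a length bias into
#' the significance ranking.
#'
#' @param fit A `difcir` object (or record data frame).
#' @param gene_lengths Named vector of gene-body lengths (bp).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
length_bias_regression <- function(fit, gene_lengths) {
  rec <- if (inherits(fit, "difcir")) fit$records else as.data.frame(fit)
  sig <- rec[rec$direction != "none", , drop = FALSE]
  if (nrow(sig) < 3) {
    stop("need >= 3 significant records for the regression", call. = FALSE)
  }
  miss <- setdiff(sig$gene_id, names(gene_lengths))
  if (length(miss) > 0) {
    stop("gene length(s) missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- unname(gene_lengths[sig$gene_id])
  y <- -log10(pmax(sig$p_value, .Machine$double.xmin))
  m <- stats::lm(y ~ x)
  # An exactly collinear input is legitimate here; silence the perfect-fit
  # note summary.lm emits for it.
  r2 <- if (stats::var(y) == 0) 0
        else suppressWarnings(summary(m)$r.squared)
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       r_squared = r2, n = nrow(sig))
}
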