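# Independent brute-force oracles and random-instance generators used
# across the suite. These deliberately share no code with the package
# internals: merging is checked against an O(n^2) transitive closure,
# interval overlap/containment against all-pairs scans, and the rank-sum
# p-value against exhaustive enumeration of rank assignments.

rand_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000,
                       max_len = 300, sample_id = "S1") {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    split_reads = sample.int(10, n, replace = TRUE),
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}

rand_genes <- function(m, chroms = c("chr1", "chr2"), max_pos = 2000,
                       max_len = 500) {
  start <- sample.int(max_pos, m, replace = TRUE)
  len <- sample.int(max_len, m, replace = TRUE)
  data.frame(
    gene_id = sprintf("G%03d", seq_len(m)),
    gene_name = sprintf("G%03d", seq_len(m)),
    chrom = sample(chroms, m, replace = TRUE),
    start = start, end = start + len,
    stringsAsFactors = FALSE
  )
}

# O(n^2) pairwise linking + connected components by breadth-first search
# over the full adjacency matrix.
oracle_merge <- function(calls, d_min) {
  n <- nrow(calls)
  if (n == 0) return(calls)
  linked <- outer(calls$chrom, calls$chrom, "==") &
    abs(outer(calls$start, calls$start, "-")) < d_min &
    abs(outer(calls$end, calls$end, "-")) < d_min
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    while (length(frontier) > 0) {
      comp[frontier] <- cur
      nxt <- which(colSums(linked[frontier, , drop = FALSE]) > 0)
      frontier <- nxt[is.na(comp[nxt])]
    }
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    data.frame(chrom = calls$chrom[idx[1]],
               start = min(calls$start[idx]),
               end = max(calls$end[idx]),
               split_reads = sum(calls$split_reads[idx]),
               sample_id = calls$sample_id[idx[1]],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs >= 1 bp overlap on half-open intervals.
oracle_overlap_pairs <- function(calls, genes) {
  pairs <- list()
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(genes))) {
      if (calls$chrom[i] == genes$chrom[j] &&
          calls$start[i] < genes$end[j] && genes$start[j] < calls$end[i]) {
        pairs[[length(pairs) + 1]] <- c(i = i, gene = genes$gene_id[j])
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(i = integer(0), gene_id = character(0)))
  }
  data.frame(
    i = as.integer(vapply(pairs, `[[`, character(1), "i")),
    gene_id = vapply(pairs, `[[`, character(1), "gene"),
    stringsAsFactors = FALSE
  )
}

# All-pairs whole-gene containment (inclusive ends).
oracle_containment <- function(calls, genes) {
  hits <- list()
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(genes))) {
      if (calls$chrom[i] == genes$chrom[j] &&
          calls$start[i] <= genes$start[j] &&
          calls$end[i] >= genes$end[j]) {
        hits[[length(hits) + 1]] <-
          data.frame(gene_id = genes$gene_id[j],
                     sample_id = calls$sample_id[i],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gene_id = character(0), sample_id = character(0)))
  }
  unique(do.call(rbind, hits))
}

# Presence matrix -> (gene_id, sample_id) pair lists for set comparison.
expand_presence <- function(presence) {
  idx <- which(presence == 1L, arr.ind = TRUE)
  list(gene_id = rownames(presence)[idx[, 1]],
       sample_id = colnames(presence)[idx[, 2]])
}

# Exact rank-sum p-value by enumerating every assignment of group-A ranks
# (tie-free inputs only). Statistic: Mann-Whitney U of group A.
oracle_ranksum_enum <- function(a, b, alternative) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r_obs <- sum(rank(pooled)[seq_len(na)])
  u_obs <- r_obs - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(ix) sum(ix) - na * (na + 1) / 2)
  switch(alternative,
    less = mean(u_all <= u_obs),
    greater = mean(u_all >= u_obs),
    two.sided = min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  )
}
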