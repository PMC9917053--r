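# Readers and writers for on-disk artifacts: circle-call tables, gene
# annotations, sample sheets, and TSV result tables.
#
# All internal coordinates are 0-based half-open (BED convention). GTF input
# (1-based inclusive) is converted at the boundary; a `one_based` flag does
# the same for circle-call tables exported by 1-based tools.

#' Read a per-sample circle-call table
#'
#' Parses one sample's eccDNA circle calls into a data frame with columns
#' `chrom`, `start`, `end`, `split_reads`, `sample_id`. Each row is one
#' detected circular junction; `split_reads` is the number of junction
#' spanning split reads supporting it, the primary quantitative signal of
#' Circle-Seq data.
#'
#' Two dialects are supported. `"generic-bed"` is a TSV with at least four
#' columns (chrom, start, end, split_reads); a header line is auto-detected.
#' `"circle-finder"` reads the microDNA-style TSV emitted by the external
#' Circle_finder caller; because that format varies between versions, the
#' column mapping is configurable through `columns` and defaults to the
#' first four columns (chrom, start, end, split reads) -- this default is an
#' assumption and should be overridden to match the files at hand.
#'
#' @param path Path to the TSV file.
#' @param dialect `"generic-bed"` or `"circle-finder"`.
#' @param sample_id Sample label attached to every call.
#' @param one_based If `TRUE`, input start coordinates are 1-based inclusive
#'   and are converted to the internal 0-based half-open convention.
#' @param columns Named integer vector mapping `chrom`, `start`, `end`,
#'   `split_reads` to column indices (circle-finder dialect only).
#' @return Data frame of circle calls, in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t500\t3", "chr1\t900\t1200\t7"), f)
#' read_circle_calls(f, sample_id = "S1")
#' @export
read_circle_calls <- function(path,
                              dialect = c("generic-bed", "circle-finder"),
                              sample_id,
                              one_based = FALSE,
                              columns = c(chrom = 1L, start = 2L, end = 3L,
                                          split_reads = 4L)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(sample_id) || !nzchar(sample_id)) {
    stop("`sample_id` must be a non-empty string", call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(.empty_calls())

  need <- c("chrom", "start", "end", "split_reads")
  if (!all(need %in% names(columns))) {
    stop("`columns` must name chrom, start, end and split_reads",
         call. = FALSE)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1]]
  skip_header <- FALSE
  if (length(first) >= max(columns)) {
    s <- suppressWarnings(as.numeric(first[[columns[["start"]]]]))
    e <- suppressWarnings(as.numeric(first[[columns[["end"]]]]))
    if (is.na(s) || is.na(e)) skip_header <- TRUE
  } else {
    # A short first line is a header when its second field is not numeric;
    # a short data-looking line falls through to the field-count error.
    skip_header <- length(first) < 2 ||
      is.na(suppressWarnings(as.numeric(first[[2]])))
  }
  rows <- if (skip_header) fields[-1] else fields
  line_no <- if (skip_header) seq_along(rows) + 1L else seq_along(rows)
  if (length(rows) == 0) return(.empty_calls())

  parse_row <- function(f, ln) {
    if (length(f) < max(columns)) {
      stop(sprintf("line %d of %s: expected >= %d tab-separated fields, got %d",
                   ln, path, max(columns), length(f)), call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[[columns[["start"]]]]))
    e <- suppressWarnings(as.numeric(f[[columns[["end"]]]]))
    sr <- suppressWarnings(as.numeric(f[[columns[["split_reads"]]]]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      stop(sprintf("line %d of %s: non-integer coordinates", ln, path),
           call. = FALSE)
    }
    if (is.na(sr) || sr != floor(sr)) {
      stop(sprintf("line %d of %s: non-integer split-read count", ln, path),
           call. = FALSE)
    }
    if (sr < 0) {
      stop(sprintf("line %d of %s: negative split-read count", ln, path),
           call. = FALSE)
    }
    if (one_based) s <- s - 1
    if (e <= s) {
      stop(sprintf("line %d of %s: end <= start", ln, path), call. = FALSE)
    }
    list(chrom = f[[columns[["chrom"]]]], start = s, end = e, split_reads = sr)
  }

  parsed <- mapply(parse_row, rows, line_no, SIMPLIFY = FALSE)
  data.frame(
    chrom = vapply(parsed, `[[`, character(1), "chrom"),
    start = vapply(parsed, `[[`, numeric(1), "start"),
    end = vapply(parsed, `[[`, numeric(1), "end"),
    split_reads = vapply(parsed, `[[`, numeric(1), "split_reads"),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Read a gene annotation (BED or GTF)
#'
#' Builds the gene models used for circle annotation: identifier, display
#' name, genomic interval, derived gene-body length, and (from GTF) exon
#' sub-intervals. BED input (BED4+: chrom, start, end, gene_id, optional
#' gene_name in column 5) yields genes with empty exon sets; GTF input keeps
#' `gene` and `exon` features, attaches exons to their gene via the
#' `gene_id` attribute, and converts coordinates from 1-based inclusive to
#' 0-based half-open.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gtf"`.
#' @return A `gene_annotation` object: a list with `genes` (data frame
#'   `gene_id`, `gene_name`, `chrom`, `start`, `end`, `length`) and `exons`
#'   (data frame `gene_id`, `chrom`, `start`, `end`; zero rows for BED).
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "bed") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 4) {
      stop("gene BED must have >= 4 columns (chrom, start, end, gene_id)",
           call. = FALSE)
    }
    genes <- data.frame(
      gene_id = as.character(tab[[4]]),
      gene_name = if (ncol(tab) >= 5) as.character(tab[[5]])
                  else as.character(tab[[4]]),
      chrom = as.character(tab[[1]]),
      start = as.numeric(tab[[2]]),
      end = as.numeric(tab[[3]]),
      stringsAsFactors = FALSE
    )
    exons <- data.frame(gene_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (!"gene_id" %in% names(md)) {
      stop("GTF has no gene_id attribute", call. = FALSE)
    }
    is_gene <- md$type == "gene"
    is_exon <- md$type == "exon"
    if (!any(is_gene)) stop("GTF contains no gene features", call. = FALSE)
    gg <- gr[is_gene]
    gm <- S4Vectors::mcols(gg)
    genes <- data.frame(
      gene_id = as.character(gm$gene_id),
      gene_name = if ("gene_name" %in% names(gm) && !all(is.na(gm$gene_name)))
                    ifelse(is.na(gm$gene_name), as.character(gm$gene_id),
                           as.character(gm$gene_name))
                  else as.character(gm$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gg)),
      start = GenomicRanges::start(gg) - 1,   # to 0-based half-open
      end = as.numeric(GenomicRanges::end(gg)),
      stringsAsFactors = FALSE
    )
    ge <- gr[is_exon]
    em <- S4Vectors::mcols(ge)
    exons <- data.frame(
      gene_id = as.character(em$gene_id),
      chrom = as.character(GenomicRanges::seqnames(ge)),
      start = GenomicRanges::start(ge) - 1,
      end = as.numeric(GenomicRanges::end(ge)),
      stringsAsFactors = FALSE
    )
    orphan <- setdiff(exons$gene_id, genes$gene_id)
    if (length(orphan) > 0) {
      stop("GTF exon(s) reference unknown gene_id: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    key <- paste(genes$chrom, genes$start, genes$end)
    conflict <- vapply(unique(dup), function(g) {
      length(unique(key[genes$gene_id == g])) > 1
    }, logical(1))
    if (any(conflict)) {
      stop("duplicate gene_id with conflicting coordinates: ",
           paste(unique(dup)[conflict], collapse = ", "), call. = FALSE)
    }
    keep <- !duplicated(genes$gene_id)
    genes <- genes[keep, , drop = FALSE]
  }
  if (any(genes$end <= genes$start)) {
    stop("gene(s) with end <= start: ",
         paste(genes$gene_id[genes$end <= genes$start], collapse = ", "),
         call. = FALSE)
  }
  genes$length <- genes$end - genes$start
  rownames(genes) <- NULL
  gene_annotation(genes, exons)
}

#' Construct a gene annotation object
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open); `gene_name` and `length` are derived if absent.
#' @param exons Optional data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` of exon sub-intervals.
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(genes, exons = NULL) {
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  if (is.null(genes$length)) genes$length <- genes$end - genes$start
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        stringsAsFactors = FALSE)
  }
  obj <- list(genes = genes, exons = exons)
  class(obj) <- "gene_annotation"
  .check_genes(obj)
  obj
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s), %d exon(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom)), nrow(x$exons)))
  invisible(x)
}

#' Read a sample sheet
#'
#' A sample sheet assigns every sample to a group. For differential analysis
#' exactly two distinct group labels are required, each with at least two
#' samples.
#'
#' @param path TSV with columns `sample_id` and `group` (header optional;
#'   headerless files are read as two columns in that order).
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("sample sheet must have 2 columns", call. = FALSE)
  if (identical(tolower(as.character(tab[1, 1])), "sample_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  out <- data.frame(sample_id = as.character(tab[[1]]),
                    group = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  .check_sample_sheet(out)
  out
}

#' Write a result table as TSV
#'
#' Writes any result data frame (circle calls, PpGC tables converted with
#' [as.data.frame()], differential records, vote results, ...) as a
#' tab-separated file with a header, deterministic column order, and floats
#' rendered at full precision (>= 6 significant digits), so tables
#' round-trip exactly through [read_result_table()].
#'
#' @param records Data frame (may have zero rows).
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  fmt <- vapply(records, function(col) {
    if (is.double(col)) format(col, digits = 15, trim = TRUE,
                               scientific = FALSE)
    else as.character(col)
  }, FUN.VALUE = character(nrow(records)))
  if (nrow(records) == 1) fmt <- matrix(fmt, nrow = 1)
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records) > 0) {
    writeLines(apply(as.matrix(fmt), 1, paste, collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame with numeric columns restored.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
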