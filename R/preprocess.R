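#' Geometric mean, defined as zero when any element is zero
#'
#' Used by the housekeeping sample filter and the size-factor reference set.
#' No pseudocount is added: a single zero annihilates the mean, which makes
#' the sample filter strict about cells that fail to express a housekeeping
#' gene at all.
#'
#' @param x Non-negative numeric vector.
#' @return The geometric mean of `x`; 0 if any element is 0.
#' @export
geometric_mean <- function(x) {
  if (any(x < 0)) abort("geometric mean requires non-negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Gene lengths from exon records
#'
#' Computes per-gene lengths as the number of bases covered by the union of
#' the gene's exons: overlapping exons are merged so shared bases are counted
#' once. Coordinates are 1-based inclusive, so a single-base exon
#' (start == end) has length 1.
#'
#' @param exons Data frame with columns `gene_id`, `start`, `end`
#'   (1-based inclusive genomic coordinates).
#' @param genes Optional character vector of gene identifiers that must all
#'   be present; a gene with no exon record raises an error naming it.
#' @return A tibble with columns `gene_id` and `length` (base pairs).
#' @export
gene_lengths_from_exons <- function(exons, genes = NULL) {
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  if (nrow(exons) == 0) abort("no exon records supplied")
  bad <- exons$end < exons$start
  if (any(bad)) {
    abort(sprintf("reversed exon interval(s) (end < start) for gene(s): %s",
                  paste(unique(exons$gene_id[bad]), collapse = ", ")))
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, exons$gene_id)
    if (length(missing) > 0) {
      abort(sprintf("no exon records for gene(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  ir <- IRanges::IRanges(start = exons$start, end = exons$end)
  by_gene <- S4Vectors::split(ir, exons$gene_id)
  len <- sum(IRanges::width(IRanges::reduce(by_gene)))
  tibble::tibble(gene_id = names(len), length = as.integer(len))
}

#' Read exon records from a GTF/GFF file
#'
#' @param path GTF-style annotation (tab-separated, 1-based inclusive
#'   coordinates, `gene_id` in the attributes field).
#' @return A tibble with columns `gene_id`, `start`, `end` for exon features,
#'   suitable for [gene_lengths_from_exons()].
#' @export
read_gtf_exons <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort("annotation contains no exon features")
  tibble::tibble(gene_id = as.character(gr$gene_id),
                 start = BiocGenerics::start(gr),
                 end = BiocGenerics::end(gr))
}

#' Read a two-column gene-length table
#'
#' @param path TSV with columns `gene_id` and `length` (bp); gzip transparent.
#' @return A tibble with columns `gene_id`, `length`.
#' @export
read_gene_lengths <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("gene_id", "length")
  if (any(tbl$length < 1)) abort("gene lengths must be >= 1 bp")
  tbl
}

#' Convert raw fragment counts to FPKM
#'
#' FPKM_ij = counts_ij * 1e9 / (length_i * total_j), where total_j is the
#' per-sample sum of counted fragments.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param lengths Gene lengths: a tibble from [gene_lengths_from_exons()] /
#'   [read_gene_lengths()], or a named numeric vector of base-pair lengths.
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths) {
  validate_expression_matrix(counts, "counts")
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$gene_id)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0) {
    abort(sprintf("no length for gene(s): %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..." else ""))
  }
  len <- lengths[rownames(counts)]
  if (any(len < 1)) abort("gene lengths must be >= 1 bp")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total fragments: %s",
                  paste(colnames(counts)[totals == 0], collapse = ", ")))
  }
  fpkm <- counts * 1e9 / outer(len, totals)
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Median-of-ratios size-factor normalization
#'
#' For each gene with strictly positive expression in every sample, the
#' per-sample ratio to the gene's geometric mean across samples is formed;
#' a sample's size factor is the median of these ratios. Factors are rescaled
#' to geometric mean 1 and each sample's column is divided by its factor.
#'
#' @param m Expression matrix, genes x samples.
#' @return A list with `values` (the normalized matrix) and `size_factors`
#'   (named per-sample factors, geometric mean 1).
#' @export
normalize_size_factors <- function(m) {
  validate_expression_matrix(m)
  log_geo <- rowMeans(log(m))
  ref <- is.finite(log_geo)
  if (!any(ref)) {
    abort(paste("no gene is positive in every sample; add a pseudocount or",
                "skip size-factor normalization"))
  }
  log_ratios <- log(m[ref, , drop = FALSE]) - log_geo[ref]
  factors <- exp(apply(log_ratios, 2, median))
  factors <- factors / exp(mean(log(factors)))
  list(values = sweep(m, 2, factors, "/"), size_factors = factors)
}

#' Remove abnormal samples by housekeeping-gene expression
#'
#' A sample is kept iff the geometric mean of its expression over the
#' housekeeping genes present in the matrix is at least `threshold`
#' (default 4 FPKM). A zero for any housekeeping gene gives geometric mean 0
#' and removes the sample.
#'
#' @param m Expression matrix (FPKM or molecule counts), genes x samples.
#' @param housekeeping Character vector of housekeeping gene identifiers.
#' @param threshold Minimum geometric-mean expression to keep a sample.
#' @return The matrix restricted to kept samples, order preserved.
#' @export
filter_samples <- function(m, housekeeping, threshold = 4) {
  validate_expression_matrix(m)
  if (threshold < 0) abort("`threshold` must be >= 0")
  hk <- intersect(housekeeping, rownames(m))
  if (length(hk) == 0) {
    abort("none of the housekeeping genes are present in the matrix")
  }
  gm <- apply(m[hk, , drop = FALSE], 2, geometric_mean)
  m[, gm >= threshold, drop = FALSE]
}

#' Remove genes with too many zeros
#'
#' A gene is kept iff its fraction of samples with expression exactly 0 is
#' at most `max_zero_fraction` (default 0.7: genes unexpressed in over 70%
#' of cells are removed).
#'
#' @param m Expression matrix, genes x samples.
#' @param max_zero_fraction Largest tolerated zero fraction.
#' @return The matrix restricted to kept genes, order preserved.
#' @export
filter_genes <- function(m, max_zero_fraction = 0.7) {
  validate_expression_matrix(m)
  if (ncol(m) < 1) abort("matrix has no samples")
  zero_frac <- rowMeans(m == 0)
  keep <- zero_frac <= max_zero_fraction
  if (!any(keep)) warn("gene filter removed every gene")
  m[keep, , drop = FALSE]
}

#' Full preprocessing: FPKM, sample filter, gene filter, normalization
#'
#' Stages run in order: FPKM conversion (when `lengths` is given; UMI
#' molecule-count matrices skip it), housekeeping sample filter (when
#' `housekeeping` is given), zero-fraction gene filter, then median-of-ratios
#' size-factor normalization. Samples are filtered before genes, so gene
#' zero-fractions are computed on retained samples.
#'
#' @param counts Raw count, molecule-count or FPKM matrix, genes x samples.
#' @param lengths Optional gene lengths (see [compute_fpkm()]); `NULL`
#'   leaves the values in their input units.
#' @param housekeeping Optional housekeeping gene identifiers; `NULL` skips
#'   the sample filter.
#' @param hk_threshold Sample-filter threshold (geometric-mean expression).
#' @param max_zero_fraction Gene-filter zero-fraction cutoff.
#' @param normalize Apply size-factor normalization after filtering.
#' @return A list with `values` (the processed matrix), `size_factors`
#'   (or `NULL`), and `log`: a tibble of per-stage gene/sample dimensions.
#' @export
preprocess_counts <- function(counts, lengths = NULL, housekeeping = NULL,
                              hk_threshold = 4, max_zero_fraction = 0.7,
                              normalize = TRUE) {
  validate_expression_matrix(counts, "counts")
  stages <- list(input = dim(counts))
  m <- counts
  if (!is.null(lengths)) {
    m <- compute_fpkm(m, lengths)
    stages$fpkm <- dim(m)
  }
  if (!is.null(housekeeping)) {
    m <- filter_samples(m, housekeeping, threshold = hk_threshold)
    stages$sample_filter <- dim(m)
  }
  m <- filter_genes(m, max_zero_fraction = max_zero_fraction)
  stages$gene_filter <- dim(m)
  size_factors <- NULL
  if (normalize) {
    norm <- normalize_size_factors(m)
    m <- norm$values
    size_factors <- norm$size_factors
    stages$normalized <- dim(m)
  }
  log <- tibble::tibble(stage = names(stages),
                        n_genes = vapply(stages, `[`, 0L, 1),
                        n_samples = vapply(stages, `[`, 0L, 2))
  list(values = m, size_factors = size_factors, log = log)
}

#' Default housekeeping gene symbols
#'
#' A compact list of classical housekeeping genes commonly used for
#' quality-control thresholds. Human symbols are upper-case; mouse symbols
#' capitalize the first letter only. Supply your own list to
#' [filter_samples()] when your identifiers use another namespace.
#'
#' @param species `"human"` or `"mouse"`.
#' @return Character vector of gene symbols.
#' @export
default_housekeeping_genes <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  symbols <- c("ACTB", "GAPDH", "B2M", "TUBB", "RPL13A", "RPLP0", "RPS18",
               "PPIA", "PGK1", "HPRT1", "TBP", "GUSB", "YWHAZ", "SDHA",
               "UBC", "EEF1A1", "HMBS", "TFRC")
  if (species == "mouse") {
    symbols <- paste0(substr(symbols, 1, 1),
                      tolower(substr(symbols, 2, nchar(symbols))))
  }
  symbols
}
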