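# counts tibbles have a locus_tag column followed by one column per sample

counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "locus_tag"), drop = FALSE])
  rownames(m) <- counts$locus_tag
  storage.mode(m) <- "double"
  if (any(m < 0) || anyNA(m)) abort("counts must be non-negative and complete")
  m
}

matrix_to_counts <- function(m) {
  tibble::as_tibble(m, rownames = "locus_tag")
}

#' Transcripts-per-million normalization
#'
#' Per sample, counts are divided by gene length in kb and the resulting rates
#' rescaled to sum to 10^6, so TPM columns are comparable across samples with
#' different library sizes and are invariant to rescaling a sample's counts.
#'
#' @param counts Tibble with a `locus_tag` column and one numeric column per
#'   sample.
#' @param gene_lengths Tibble with columns `locus_tag` and `length` (bp).
#' @return A tibble of the same shape holding TPM values; every sample column
#'   sums to 10^6.
#' @export
tpm <- function(counts, gene_lengths) {
  m <- counts_to_matrix(counts)
  len <- gene_lengths$length[match(rownames(m), gene_lengths$locus_tag)]
  if (anyNA(len)) {
    abort(paste0("gene length missing for: ",
                 paste(utils::head(rownames(m)[is.na(len)], 5), collapse = ", ")))
  }
  if (any(len <= 0)) abort("gene lengths must be positive")
  zero_col <- colSums(m) == 0
  if (any(zero_col)) {
    abort(paste0("all-zero sample column(s): ",
                 paste(colnames(m)[zero_col], collapse = ", ")))
  }
  rate <- m / (len / 1000)
  tpmm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  matrix_to_counts(tpmm)
}

#' Median-of-ratios (RLE) size factors
#'
#' For each gene with all-positive counts, its geometric mean across samples
#' is a pseudo-reference; a sample's size factor is the median over those
#' genes of the ratio of its count to the reference. Factors are rescaled so
#' their geometric mean is 1, keeping fitted means on the counts scale.
#'
#' @inheritParams tpm
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
rle_size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) abort("no gene has all-positive counts; cannot compute RLE size factors")
  logm <- log(m[pos, , drop = FALSE])
  log_geo <- rowMeans(logm)
  sf <- apply(logm - log_geo, 2, stats::median)
  sf <- exp(sf - mean(sf)) # geometric mean 1
  tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Filter weakly expressed genes
#'
#' Keeps genes whose counts-per-million (on raw library sizes) reach
#' `min_cpm` in at least `min_samples` samples. With the default 3-replicate
#' design the defaults require CPM >= 1 across one full replicate group.
#' Gene order is preserved and the operation is idempotent.
#'
#' @inheritParams tpm
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Number of samples that must reach it (default 3).
#' @return The filtered counts tibble.
#' @export
filter_low_expression <- function(counts, min_cpm = 1.0, min_samples = 3L) {
  m <- counts_to_matrix(counts)
  if (min_samples > ncol(m)) abort("min_samples exceeds the number of samples")
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) abort("low-expression filter removed every gene")
  counts[keep, , drop = FALSE]
}

#' Scale counts by size factors
#'
#' @inheritParams tpm
#' @param size_factors Tibble from [rle_size_factors()].
#' @return A tibble of size-factor-scaled values.
#' @export
scale_by_size_factors <- function(counts, size_factors) {
  m <- counts_to_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  if (anyNA(sf)) abort("size factor missing for some samples")
  matrix_to_counts(sweep(m, 2, sf, "/"))
}

#' Read / write count matrices, designs and gene lengths
#'
#' Counts are TSV with genes in rows (`locus_tag` column, header = sample
#' ids); the design is TSV with columns `sample_id`, `condition`,
#' `replicate`; gene lengths are 2-column TSV (`locus_tag`, `length`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"locus_tag" %in% names(x)) abort("counts file must have a locus_tag column")
  x
}

#' @rdname read_counts
#' @export
read_design <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "condition")
  if (!all(need %in% names(x))) {
    abort("design file must have sample_id and condition columns")
  }
  x
}

#' @rdname read_counts
#' @export
read_gene_lengths <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("locus_tag", "length") %in% names(x))) {
    abort("gene length file must have locus_tag and length columns")
  }
  x
}

#' @rdname read_counts
#' @param counts Tibble to write.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

check_design <- function(counts, design, min_replicates = 2L) {
  m <- counts_to_matrix(counts)
  missing_s <- setdiff(colnames(m), design$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("samples absent from design: ", paste(missing_s, collapse = ", ")))
  }
  design <- design[design$sample_id %in% colnames(m), ]
  tab <- table(design$condition)
  if (length(tab) < 2) abort("need at least 2 conditions")
  if (any(tab < min_replicates)) {
    abort(paste0("condition(s) with fewer than ", min_replicates,
                 " replicates: ",
                 paste(names(tab)[tab < min_replicates], collapse = ", ")))
  }
  design
}
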