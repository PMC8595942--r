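#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a single-contig
#' archaeal genome of ~2,000 strand-mixed CDS with uniformly incremented
#' locus tags, SurR motifs planted in about 8% of 200-bp promoters, and
#' negative-binomial counts for a 3-condition x 3-replicate pressure design
#' with 10% planted 4-fold changes and per-sample library-size distortions.
#'
#' @param n_genes Number of CDS (default 2000).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal CDS length
#'   parameters (median `exp(meanlog)` ~ 900 bp); lengths clamped to
#'   `[150, 6000]` and rounded to codon multiples.
#' @param intergenic_mean Mean intergenic gap, geometric (default 120 bp).
#' @param promoter_length Promoter length (default 200 bp).
#' @param motif_fraction Fraction of promoters receiving a planted motif
#'   (default 0.08).
#' @param patterns Patterns to plant (default [surr_patterns()]); planted
#'   distances are uniform on `[span, promoter_length]`.
#' @param conditions Condition labels (default the three growth pressures).
#' @param replicates Replicates per condition (default 3).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean expression
#'   (defaults 4 and 1.5).
#' @param dispersion NB dispersion alpha (default 0.1; 0 gives Poisson).
#' @param de_fraction Fraction of genes with a planted fold change
#'   (default 0.10).
#' @param planted_lfc Absolute planted log2 fold change (default 2), sign
#'   Bernoulli(0.5), applied in one randomly chosen condition per DE gene.
#' @param size_factor_range Per-sample library-size distortions, log-uniform
#'   (default `c(0.5, 2)`).
#' @param seed Required integer seed; fully determines all output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, gene_length_meanlog = log(900),
                       gene_length_sdlog = 0.6, intergenic_mean = 120,
                       promoter_length = 200, motif_fraction = 0.08,
                       patterns = surr_patterns(),
                       conditions = c("0.1MPa", "50MPa", "90MPa"),
                       replicates = 3, baseline_meanlog = 4,
                       baseline_sdlog = 1.5, dispersion = 0.1,
                       de_fraction = 0.10, planted_lfc = 2.0,
                       size_factor_range = c(0.5, 2.0), seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  stopifnot(motif_fraction >= 0, motif_fraction <= 1,
            de_fraction >= 0, de_fraction <= 1,
            n_genes >= 1, replicates >= 2, length(conditions) >= 2)
  spans <- purrr::map_int(patterns, "span")
  if (any(spans > promoter_length)) {
    abort("motif span exceeds promoter_length; cannot plant")
  }
  structure(
    list(n_genes = n_genes, gene_length_meanlog = gene_length_meanlog,
         gene_length_sdlog = gene_length_sdlog,
         intergenic_mean = intergenic_mean,
         promoter_length = promoter_length, motif_fraction = motif_fraction,
         patterns = patterns, conditions = conditions,
         replicates = replicates, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, dispersion = dispersion,
         de_fraction = de_fraction, planted_lfc = planted_lfc,
         size_factor_range = size_factor_range, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# one random realization of a gapped pattern (gap bases uniform ACGT)
realize_pattern <- function(pattern) {
  parts <- character(0)
  for (i in seq_along(pattern$blocks)) {
    parts <- c(parts, pattern$blocks[i])
    if (i <= length(pattern$gaps)) {
      parts <- c(parts, paste(sample(c("A", "C", "G", "T"), pattern$gaps[i],
                                     replace = TRUE), collapse = ""))
    }
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic genome with planted promoter motifs
#'
#' Genes are tiled on a single contig with geometric intergenic gaps; where a
#' motif is to be planted the relevant flank is widened to hold a full
#' promoter (both flanks when adjacent planted genes face away from each
#' other), so planted promoters are never truncated and never overwrite each
#' other. Background sequence is i.i.d. uniform ACGT; planting overwrites
#' promoter bases at a distance drawn uniformly from `[span,
#' promoter_length]` (5'-anchor convention), keeping coordinates stable.
#' Locus tags are `SYN_RS` plus zero-padded multiples of 5.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (tibble: `contig_id`, `sequence`), `genes`
#'   (gene-model tibble), `gene_lengths`, and `truth` — a tibble of planted
#'   motifs (`locus_tag`, `pattern_id`, `distance`, `planted_seq`).
#' @export
generate_genome <- function(config) {
  withr::with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  n <- config$n_genes
  pl <- config$promoter_length
  len <- round(pmin(6000, pmax(150, stats::rlnorm(
    n, config$gene_length_meanlog, config$gene_length_sdlog))) / 3) * 3
  strand <- sample(c("+", "-"), n, replace = TRUE)
  planted <- stats::runif(n) < config$motif_fraction
  pat_idx <- sample(length(config$patterns), n, replace = TRUE)

  # gap_i precedes gene i; gap_{n+1} is the trailing gap
  gaps <- stats::rgeom(n + 1, 1 / (config$intergenic_mean + 1))
  need_before <- c(strand == "+" & planted, FALSE)
  need_after <- c(FALSE, strand == "-" & planted)
  gaps <- pmax(gaps,
               ifelse(need_before & need_after, 2L * pl,
                      ifelse(need_before | need_after, pl, 0L)))
  starts <- cumsum(gaps[seq_len(n)] + c(0, len[-n])) + 1L
  ends <- starts + len - 1L
  contig_len <- ends[n] + gaps[n + 1]

  seq_chars <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  # real CDS begin with a start codon; write ATG (CAT on the minus strand)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      seq_chars[starts[i]:(starts[i] + 2L)] <- c("A", "T", "G")
    } else {
      seq_chars[(ends[i] - 2L):ends[i]] <- c("C", "A", "T")
    }
  }
  tags <- sprintf("SYN_RS%05d", 5L * seq_len(n))

  truth <- purrr::map_dfr(which(planted), function(i) {
    pat <- config$patterns[[pat_idx[i]]]
    d <- sample(seq(pat$span, pl), 1)
    real <- realize_pattern(pat)
    if (strand[i] == "+") {
      pos <- (starts[i] - d):(starts[i] - d + pat$span - 1L)
      seq_chars[pos] <<- strsplit(real, "", fixed = TRUE)[[1]]
    } else {
      pos <- (ends[i] + d - pat$span + 1L):(ends[i] + d)
      seq_chars[pos] <<- strsplit(revcomp_chr(real), "", fixed = TRUE)[[1]]
    }
    tibble::tibble(locus_tag = tags[i], pattern_id = pat$pattern_id,
                   distance = d, planted_seq = real)
  })
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(locus_tag = character(0), pattern_id = character(0),
                            distance = integer(0), planted_seq = character(0))
  }
  list(
    genome = tibble::tibble(contig_id = "SYN_contig1",
                            sequence = paste(seq_chars, collapse = "")),
    genes = tibble::tibble(locus_tag = tags, contig_id = "SYN_contig1",
                           start = starts, end = ends, strand = strand),
    gene_lengths = tibble::tibble(locus_tag = tags, length = len),
    truth = truth
  )
}

#' Generate a synthetic NB count matrix with planted fold changes
#'
#' Counts are drawn as `NB(mean = s_j * mu_i * 2^(lfc_i * [cond(j) = target_i]),
#' dispersion = alpha)`; `dispersion = 0` gives Poisson draws. Baseline means
#' are log-normal, size factors log-uniform, and each planted DE gene gets the
#' configured |log2fc| with random sign in one randomly chosen condition.
#'
#' @param config A [sim_config()].
#' @param gene_ids Locus tags (default from the config's gene count).
#' @param de_genes Optional locus tags to receive the planted fold change;
#'   when given, `de_fraction` is ignored (used e.g. to make a planted
#'   regulon differentially expressed).
#' @return A list with `counts` (tibble), `design` (tibble: `sample_id`,
#'   `condition`, `replicate`) and `truth` — a list holding `genes`
#'   (`locus_tag`, `baseline_mean`, `is_de`, `target_condition`, `log2fc`)
#'   and `size_factors` (`sample_id`, `size_factor`, rescaled to geometric
#'   mean 1).
#' @export
generate_counts <- function(config, gene_ids = NULL, de_genes = NULL) {
  withr::with_seed(config$seed + 1L,
                   generate_counts_impl(config, gene_ids, de_genes))
}

generate_counts_impl <- function(config, gene_ids, de_genes = NULL) {
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("SYN_RS%05d", 5L * seq_len(config$n_genes))
  }
  n <- length(gene_ids)
  design <- tidyr::expand_grid(condition = config$conditions,
                               replicate = seq_len(config$replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$condition, "_r", .data$replicate)) |>
    dplyr::select("sample_id", "condition", "replicate")
  ns <- nrow(design)
  mu <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  sf <- exp(stats::runif(ns, log(config$size_factor_range[1]),
                         log(config$size_factor_range[2])))
  sf <- sf / exp(mean(log(sf)))
  is_de <- if (is.null(de_genes)) {
    stats::runif(n) < config$de_fraction
  } else {
    gene_ids %in% de_genes
  }
  target <- ifelse(is_de, sample(config$conditions, n, replace = TRUE),
                   NA_character_)
  lfc <- ifelse(is_de, config$planted_lfc * sample(c(-1, 1), n, replace = TRUE),
                0)
  shift <- matrix(0, n, ns)
  for (j in seq_len(ns)) {
    on <- !is.na(target) & target == design$condition[j]
    shift[on, j] <- lfc[on]
  }
  mean_mat <- outer(mu, sf) * 2^shift
  counts <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(n * ns, mu = mean_mat, size = 1 / config$dispersion),
           n, ns)
  } else {
    matrix(stats::rpois(n * ns, lambda = mean_mat), n, ns)
  }
  colnames(counts) <- design$sample_id
  rownames(counts) <- gene_ids
  list(
    counts = matrix_to_counts(counts),
    design = design,
    truth = list(
      genes = tibble::tibble(locus_tag = gene_ids, baseline_mean = mu,
                             is_de = is_de, target_condition = target,
                             log2fc = lfc),
      size_factors = tibble::tibble(sample_id = design$sample_id,
                                    size_factor = sf)
    )
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits FASTA, GFF3, counts TSV, design TSV, gene-length TSV and a
#' ground-truth JSON under `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param link_de_to_regulon When `TRUE`, the planted DE genes are exactly
#'   the motif-bearing genes (the planted regulon) instead of a random
#'   `de_fraction` draw.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(config, outdir, link_de_to_regulon = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  cnt <- generate_counts(config, gene_ids = gen$genes$locus_tag,
                         de_genes = if (link_de_to_regulon)
                           unique(gen$truth$locus_tag) else NULL)
  paths <- c(
    genome = file.path(outdir, "genome.fasta"),
    annotation = file.path(outdir, "annotation.gff3"),
    counts = file.path(outdir, "counts.tsv"),
    design = file.path(outdir, "design.tsv"),
    gene_lengths = file.path(outdir, "gene_lengths.tsv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  readr::write_lines(c(paste0(">", gen$genome$contig_id),
                       gen$genome$sequence), paths["genome"])
  gff <- c("##gff-version 3",
           sprintf("%s\tpiezoregulon\tCDS\t%d\t%d\t.\t%s\t0\tlocus_tag=%s",
                   gen$genes$contig_id, gen$genes$start, gen$genes$end,
                   gen$genes$strand, gen$genes$locus_tag))
  readr::write_lines(gff, paths["annotation"])
  readr::write_tsv(cnt$counts, paths["counts"])
  readr::write_tsv(cnt$design, paths["design"])
  readr::write_tsv(gen$gene_lengths, paths["gene_lengths"])
  jsonlite::write_json(
    list(planted_motifs = gen$truth, de_genes = cnt$truth$genes,
         size_factors = cnt$truth$size_factors, seed = config$seed),
    paths["truth"], dataframe = "columns", digits = NA
  )
  invisible(paths)
}
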