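#' Assemble a pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. A YAML
#' file with the same field names can be loaded with [read_pipeline_config()];
#' arguments given here override file values.
#'
#' @param genome,annotation,counts,design,gene_lengths,clusters Input paths
#'   (`clusters` and `gene_lengths` optional; gene lengths default to CDS
#'   spans from the annotation; clusters default to the bundled
#'   [hydrogenase_clusters()] table only when its tags occur in the data,
#'   otherwise the cluster summary is skipped).
#' @param outdir Output directory.
#' @param promoter_length,patterns,max_mismatch,distance_from Motif-screen
#'   parameters; `patterns` is a character vector of pattern specs (default
#'   the two SurR motifs).
#' @param min_cpm,min_samples Low-expression filter parameters.
#' @param alpha Adjusted-p threshold for DE calls (default 0.01).
#' @param annotation_dialect `"gff3"` or `"gene_table"`.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, counts, design, outdir,
                            gene_lengths = NULL, clusters = NULL,
                            promoter_length = 200,
                            patterns = c(surr_short = "GTTn{3}AAC",
                                         surr_long = "GTTn{3}AACn{5}GTT"),
                            max_mismatch = 0,
                            distance_from = "5prime",
                            min_cpm = 1.0, min_samples = 3L, alpha = 0.01,
                            annotation_dialect = "gff3", seed = 1L) {
  structure(
    list(genome = genome, annotation = annotation, counts = counts,
         design = design, gene_lengths = gene_lengths, clusters = clusters,
         outdir = outdir, promoter_length = promoter_length,
         patterns = patterns, max_mismatch = max_mismatch,
         distance_from = distance_from, min_cpm = min_cpm,
         min_samples = min_samples, alpha = alpha,
         annotation_dialect = annotation_dialect, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with `pipeline_config` fields.
#' @param ... Overrides passed to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

#' Run the full promoter-to-regulon pipeline
#'
#' Executes promoter extraction, motif screening, normalization, all pairwise
#' negative-binomial contrasts, and the overlap / cluster / Venn summaries,
#' writing every table under `config$outdir` along with a run manifest
#' (parameters, package version, seed, input checksums). The run is
#' deterministic for fixed inputs and parameters. Any stage error aborts with
#' the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`promoters`, `hits`,
#'   `regulon`, `size_factors`, `tpm`, `de` — one `nb_de` per contrast —
#'   `overlap`, `cluster_summary`, `venn`, `paths`).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  for (p in c("genome", "annotation", "counts", "design")) {
    if (!file.exists(config[[p]])) {
      abort(paste0("input file for '", p, "' not found: ", config[[p]]))
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  genome <- stage("read_genome", read_genome_fasta(config$genome))
  genes <- stage("read_annotation",
                 read_annotation(config$annotation, config$annotation_dialect))
  promoters <- stage("promoters",
                     extract_promoters(genes, genome, config$promoter_length))
  write_promoters_fasta(promoters, out("promoters.fasta"))
  write_promoters_bed(promoters, out("promoters.bed"))

  specs <- unlist(config$patterns, use.names = FALSE)
  pattern_ids <- names(config$patterns) %||% specs
  pattern_ids[pattern_ids == ""] <- specs[pattern_ids == ""]
  patterns <- purrr::map2(config$patterns, pattern_ids, function(sp, id) {
    compile_pattern(sp, pattern_id = id, max_mismatch = config$max_mismatch)
  })
  hits <- stage("scan",
                scan_promoters(promoters, patterns,
                               distance_from = config$distance_from))
  write_hits_tsv(hits, out("motif_hits.tsv"))
  write_hits_bed(hits, promoters, patterns, out("motif_hits.bed"))
  regulon <- promoters_with_motif(hits)

  counts <- stage("read_counts", read_counts(config$counts))
  design <- stage("read_design", read_design(config$design))
  gene_lengths <- if (is.null(config$gene_lengths)) {
    tibble::tibble(locus_tag = genes$locus_tag,
                   length = genes$end - genes$start + 1L)
  } else {
    read_gene_lengths(config$gene_lengths)
  }
  filtered <- stage("filter",
                    filter_low_expression(counts, config$min_cpm,
                                          config$min_samples))
  tpm_tbl <- stage("tpm", tpm(filtered, gene_lengths))
  write_counts(tpm_tbl, out("tpm.tsv"))
  sf <- stage("size_factors", rle_size_factors(filtered))
  readr::write_tsv(sf, out("size_factors.tsv"))
  disp <- stage("dispersion", estimate_dispersion(filtered, design, sf))

  conds <- unique(design$condition)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  de <- stage("de", purrr::map(pairs, function(p) {
    nb_wald_test(filtered, design, comparison = p, size_factors = sf,
                 dispersion = disp, alpha = config$alpha)
  }))
  names(de) <- purrr::map_chr(pairs, paste, collapse = "_vs_")
  de_all <- purrr::map_dfr(de, tidy)
  readr::write_tsv(de_all, out("de_results.tsv"))

  universe <- counts$locus_tag
  degs <- unique(de_all$locus_tag[de_all$call != "ns"])
  overlap <- stage("overlap",
                   overlap_stats(universe, intersect(regulon, universe), degs))
  readr::write_tsv(overlap, out("overlap_stats.tsv"))

  per_cmp_sets <- de_all |>
    dplyr::filter(.data$call != "ns") |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(tags = list(unique(.data$locus_tag))) |>
    (\(d) stats::setNames(d$tags, d$comparison))()
  venn <- if (length(per_cmp_sets) >= 2) venn_counts(per_cmp_sets) else
    tibble::tibble(region = character(0), n = integer(0))
  jsonlite::write_json(venn, out("venn_counts.json"),
                       dataframe = "columns", digits = NA)

  clusters <- if (!is.null(config$clusters)) {
    readr::read_tsv(config$clusters, show_col_types = FALSE)
  } else {
    bundled <- hydrogenase_clusters()
    if (any(unlist(purrr::map(bundled$locus_range, expand_locus_range)) %in%
              universe)) bundled else NULL
  }
  clu <- if (!is.null(clusters)) {
    stage("cluster_summary", cluster_summary(de_all, clusters))
  } else {
    tibble::tibble(name = character(0), contrast = character(0),
                   n_over = integer(0), total_cds = integer(0),
                   rendered = character(0))
  }
  readr::write_tsv(clu, out("cluster_summary.tsv"))

  manifest <- list(
    package = "piezoregulon",
    version = as.character(utils::packageVersion("piezoregulon")),
    seed = config$seed,
    parameters = config[c("promoter_length", "patterns", "max_mismatch",
                          "distance_from", "min_cpm", "min_samples", "alpha")],
    inputs = purrr::map(
      config[c("genome", "annotation", "counts", "design")],
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(
    promoters = promoters, hits = hits, regulon = regulon,
    size_factors = sf, tpm = tpm_tbl, dispersion = disp, de = de,
    overlap = overlap, cluster_summary = clu, venn = venn,
    paths = list(outdir = config$outdir)
  ))
}
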