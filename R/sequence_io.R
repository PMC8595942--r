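#' Read a genome FASTA into a tibble
#'
#' Reads one or more contigs from a FASTA file. Sequences are uppercased and
#' RNA `U` is mapped to `T`; any residue other than `A`, `C`, `G`, `T`, `N`
#' is an error. The contig id is the first whitespace-delimited word of the
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id` and `sequence`, one row per
#'   contig, in file order.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("FASTA file is empty: ", path))
  ids <- stringr::str_split_fixed(names(seqs), "\\s+", 2)[, 1]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate contig ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sequence <- chartr("U", "T", toupper(as.character(seqs)))
  bad <- stringr::str_detect(sequence, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("non-DNA characters in contig(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  if (any(nchar(sequence) == 0)) {
    abort(paste0("empty sequence for contig(s): ",
                 paste(ids[nchar(sequence) == 0], collapse = ", ")))
  }
  tibble::tibble(contig_id = ids, sequence = unname(sequence))
}

#' Read a gene annotation into a tibble of gene models
#'
#' Supports GFF3 (`dialect = "gff3"`; CDS features carrying a `locus_tag`
#' attribute) and a plain tab-separated gene table (`dialect = "gene_table"`;
#' columns `locus_tag`, `contig`, `start`, `end`, `strand`). Coordinates are
#' kept 1-based inclusive, as in GFF3. For a CDS annotated in several
#' segments under one locus tag, the segment containing the start codon is
#' kept: lowest start on `+`, highest end on `-`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"gene_table"`.
#' @return A tibble with columns `locus_tag`, `contig_id`, `start`, `end`,
#'   `strand`, one row per distinct locus tag.
#' @export
read_annotation <- function(path, dialect = c("gff3", "gene_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (dialect == "gff3") {
    genes <- parse_gff3_cds(path)
  } else {
    genes <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("locus_tag", "contig", "start", "end", "strand")
    missing_cols <- setdiff(need, names(genes))
    if (length(missing_cols) > 0) {
      abort(paste0("gene table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    genes <- tibble::tibble(
      locus_tag = as.character(genes$locus_tag),
      contig_id = as.character(genes$contig),
      start = as.integer(genes$start),
      end = as.integer(genes$end),
      strand = as.character(genes$strand),
      line = seq_len(nrow(genes)) + 1L
    )
  }
  validate_gene_models(genes)
}

parse_gff3_cds <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- stringr::str_split_fixed(lines[keep], "\t", 9)
  is_cds <- fields[, 3] == "CDS"
  fields <- fields[is_cds, , drop = FALSE]
  lineno <- lineno[is_cds]
  if (nrow(fields) == 0) abort(paste0("no CDS features in ", path))
  lt <- stringr::str_match(fields[, 9], "locus_tag=([^;]+)")[, 2]
  if (anyNA(lt)) {
    abort(paste0("CDS without locus_tag attribute at line ",
                 lineno[which(is.na(lt))[1]], " of ", path))
  }
  tibble::tibble(
    locus_tag = lt,
    contig_id = fields[, 1],
    start = suppressWarnings(as.integer(fields[, 4])),
    end = suppressWarnings(as.integer(fields[, 5])),
    strand = fields[, 7],
    line = lineno
  )
}

validate_gene_models <- function(genes) {
  bad_coord <- which(is.na(genes$start) | is.na(genes$end) |
                       genes$start > genes$end | genes$start < 1)
  if (length(bad_coord) > 0) {
    abort(paste0("invalid coordinates (need 1 <= start <= end) at line ",
                 genes$line[bad_coord[1]]))
  }
  bad_strand <- which(!genes$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("unknown strand symbol '", genes$strand[bad_strand[1]],
                 "' at line ", genes$line[bad_strand[1]]))
  }
  # collapse multi-segment CDS to the segment holding the start codon
  genes |>
    dplyr::group_by(.data$locus_tag) |>
    dplyr::arrange(
      dplyr::if_else(.data$strand == "+", .data$start, -.data$end),
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig_id, .data$start) |>
    dplyr::select("locus_tag", "contig_id", "start", "end", "strand")
}

#' Extract fixed-length promoter regions upstream of start codons
#'
#' The promoter of a gene is the `promoter_length` bases immediately upstream
#' of its start codon, reported 5'->3' on the gene's coding strand so that the
#' promoter's 3' end abuts the first base of the start codon. Promoters at a
#' contig edge are truncated (possibly to length zero), never an error.
#' Promoters may overlap upstream genes or other promoters; no masking is
#' applied. Contigs are treated as linear.
#'
#' @param genes Tibble of gene models (`locus_tag`, `contig_id`, `start`,
#'   `end`, `strand`), as from [read_annotation()].
#' @param genome Tibble of contigs (`contig_id`, `sequence`), as from
#'   [read_genome_fasta()].
#' @param promoter_length Promoter length in bp (default 200).
#' @return A tibble with columns `locus_tag`, `sequence`, `genomic_start`,
#'   `genomic_end` (1-based inclusive; `NA` when the promoter is empty),
#'   `strand`, `truncated`.
#' @export
extract_promoters <- function(genes, genome, promoter_length = 200) {
  stopifnot(promoter_length >= 1)
  missing_contig <- setdiff(genes$contig_id, genome$contig_id)
  if (length(missing_contig) > 0) {
    abort(paste0("contig(s) in annotation but not in genome: ",
                 paste(missing_contig, collapse = ", ")))
  }
  g <- dplyr::left_join(
    genes,
    tibble::tibble(contig_id = genome$contig_id,
                   contig_seq = genome$sequence,
                   contig_len = nchar(genome$sequence)),
    by = "contig_id"
  )
  if (any(g$end > g$contig_len)) {
    abort(paste0("gene extends beyond its contig: ",
                 g$locus_tag[which(g$end > g$contig_len)[1]]))
  }
  # check annotated start codons; annotation is trusted, so warn only
  first_codon <- ifelse(
    g$strand == "+",
    substr(g$contig_seq, g$start, g$start + 2),
    revcomp_chr(substr(g$contig_seq, g$end - 2, g$end))
  )
  n_odd <- sum(!first_codon %in% c("ATG", "GTG", "TTG"))
  if (n_odd > 0) {
    warn(paste0(n_odd, " gene(s) do not begin with ATG/GTG/TTG; ",
                "annotation used as-is"))
  }
  plus <- g$strand == "+"
  len <- ifelse(plus,
                pmin(promoter_length, g$start - 1L),
                pmin(promoter_length, g$contig_len - g$end))
  p_start <- ifelse(plus, g$start - len, g$end + 1L)
  p_end <- ifelse(plus, g$start - 1L, g$end + len)
  seq <- substr(g$contig_seq, p_start, p_end)
  seq[len == 0] <- ""
  seq[!plus & len > 0] <- revcomp_chr(seq[!plus & len > 0])
  tibble::tibble(
    locus_tag = g$locus_tag,
    sequence = seq,
    genomic_start = ifelse(len == 0, NA_integer_, as.integer(p_start)),
    genomic_end = ifelse(len == 0, NA_integer_, as.integer(p_end)),
    strand = g$strand,
    contig_id = g$contig_id,
    truncated = len < promoter_length
  )
}

#' Write promoters as FASTA (header = locus tag)
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  keep <- nchar(promoters$sequence) > 0
  lines <- rbind(paste0(">", promoters$locus_tag[keep]),
                 promoters$sequence[keep])
  readr::write_lines(as.vector(lines), path)
  invisible(path)
}

#' Write promoters as BED6 (0-based half-open)
#'
#' @inheritParams write_promoters_fasta
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  keep <- !is.na(promoters$genomic_start)
  p <- promoters[keep, ]
  bed <- tibble::tibble(
    chrom = p$contig_id,
    start = p$genomic_start - 1L,
    end = p$genomic_end,
    name = p$locus_tag,
    score = 0L,
    strand = p$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
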