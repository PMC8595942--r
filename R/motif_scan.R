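#' Compile a gapped motif pattern
#'
#' Patterns are written as upper-case conserved blocks separated by fixed-length
#' gaps `n{k}`, e.g. `"GTTn{3}AACn{5}GTT"` — the long SurR binding motif. Gap
#' positions match any base; the mismatch budget applies to conserved-block
#' positions only. An `N` in the scanned sequence never matches a conserved
#' position.
#'
#' @param spec Pattern string, e.g. `"GTTn{3}AAC"`.
#' @param pattern_id Identifier carried into hit tables; defaults to the spec
#'   string itself.
#' @param max_mismatch Mismatch budget over conserved-block positions
#'   (default 0).
#' @return An object of class `motif_pattern` with elements `pattern_id`,
#'   `blocks`, `gaps`, `span`, `max_mismatch`.
#' @examples
#' compile_pattern("GTTn{3}AAC", "surr_short")
#' @export
compile_pattern <- function(spec, pattern_id = spec, max_mismatch = 0) {
  stopifnot(is.character(spec), length(spec) == 1, max_mismatch >= 0)
  tokens <- stringr::str_match_all(spec, "([ACGT]+)|n\\{(\\d+)\\}|(.)")[[1]]
  if (any(!is.na(tokens[, 4]))) {
    abort(paste0("malformed pattern spec '", spec, "': unexpected token '",
                 tokens[which(!is.na(tokens[, 4]))[1], 4], "'"))
  }
  is_block <- !is.na(tokens[, 2])
  # must alternate block, gap, block, ... starting and ending with a block
  expected <- rep(c(TRUE, FALSE), length.out = nrow(tokens))
  if (!all(is_block == expected) || !is_block[nrow(tokens)]) {
    abort(paste0("malformed pattern spec '", spec,
                 "': blocks and gaps must alternate, starting and ending ",
                 "with a conserved block"))
  }
  blocks <- tokens[is_block, 2]
  gaps <- as.integer(tokens[!is_block, 3])
  span <- sum(nchar(blocks)) + sum(gaps)
  structure(
    list(pattern_id = pattern_id, blocks = blocks, gaps = gaps,
         span = as.integer(span), max_mismatch = as.integer(max_mismatch)),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$pattern_id, ": ",
      pattern_to_spec(x), " (span ", x$span,
      ", max mismatch ", x$max_mismatch, ")\n", sep = "")
  invisible(x)
}

pattern_to_spec <- function(pattern) {
  parts <- character(0)
  for (i in seq_along(pattern$blocks)) {
    parts <- c(parts, pattern$blocks[i])
    if (i <= length(pattern$gaps)) {
      parts <- c(parts, sprintf("n{%d}", pattern$gaps[i]))
    }
  }
  paste(parts, collapse = "")
}

#' The SurR binding motif patterns
#'
#' The short motif `GTTn{3}AAC` (its own reverse complement) and the long
#' motif `GTTn{3}AACn{5}GTT`, as bound by the ArsR-type sulfur/hydrogen
#' master regulator SurR of Thermococcales.
#'
#' @param max_mismatch Mismatch budget for both patterns (default 0).
#' @return A named list of two `motif_pattern` objects, `surr_short` and
#'   `surr_long`.
#' @export
surr_patterns <- function(max_mismatch = 0) {
  list(
    surr_short = compile_pattern("GTTn{3}AAC", "surr_short", max_mismatch),
    surr_long = compile_pattern("GTTn{3}AACn{5}GTT", "surr_long", max_mismatch)
  )
}

# conserved (0-based offset, expected char) pairs of a pattern
conserved_positions <- function(pattern) {
  off <- 0L
  pos <- integer(0)
  chars <- character(0)
  for (i in seq_along(pattern$blocks)) {
    b <- strsplit(pattern$blocks[i], "", fixed = TRUE)[[1]]
    pos <- c(pos, off + seq_along(b) - 1L)
    chars <- c(chars, b)
    off <- off + length(b) + (if (i <= length(pattern$gaps)) pattern$gaps[i] else 0L)
  }
  list(pos = pos, chars = chars)
}

# mismatch count of every window of one strand; returns integer vector of
# length nchar(seq) - span + 1 (empty when the sequence is shorter than span)
window_mismatches <- function(seq_chars, pattern) {
  n <- length(seq_chars)
  nw <- n - pattern$span + 1L
  if (nw < 1L) return(integer(0))
  cp <- conserved_positions(pattern)
  mism <- integer(nw)
  for (k in seq_along(cp$pos)) {
    mism <- mism + (seq_chars[(1L + cp$pos[k]):(nw + cp$pos[k])] != cp$chars[k])
  }
  mism
}

#' Scan one sequence for a gapped motif
#'
#' Every window of the pattern's span whose conserved-block positions carry at
#' most `max_mismatch` mismatches is reported. With `both_strands = TRUE` the
#' reverse complement is scanned too and hits are mapped back to forward
#' offsets; a window matching at the same forward offset on both strands (as
#' every hit of a palindromic pattern does) is reported once with strand
#' `"promoter"`.
#'
#' @param seq A single DNA string.
#' @param pattern A `motif_pattern` from [compile_pattern()].
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @param max_mismatch Override of the pattern's mismatch budget.
#' @return A tibble with columns `promoter_offset` (0-based offset of the
#'   match's 5'-most base on the forward sequence), `strand` (`"promoter"` or
#'   `"opposite"`), `matched_seq` (the spanned string on the reported strand),
#'   `mismatches`; ordered by offset.
#' @export
scan_sequence <- function(seq, pattern, both_strands = TRUE,
                          max_mismatch = pattern$max_mismatch) {
  stopifnot(is.character(seq), length(seq) == 1)
  empty <- tibble::tibble(promoter_offset = integer(0),
                          strand = character(0),
                          matched_seq = character(0),
                          mismatches = integer(0))
  n <- nchar(seq)
  if (n < pattern$span) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mism_fwd <- window_mismatches(chars, pattern)
  hits <- tibble::tibble(
    promoter_offset = which(mism_fwd <= max_mismatch) - 1L,
    strand = "promoter",
    mismatches = mism_fwd[mism_fwd <= max_mismatch]
  )
  if (both_strands) {
    rc <- revcomp_chr(seq)
    mism_rev <- window_mismatches(strsplit(rc, "", fixed = TRUE)[[1]], pattern)
    rc_off <- which(mism_rev <= max_mismatch) - 1L
    rev_hits <- tibble::tibble(
      promoter_offset = n - pattern$span - rc_off,
      strand = "opposite",
      mismatches = mism_rev[mism_rev <= max_mismatch]
    )
    # palindromic double-report: keep the promoter-strand record
    rev_hits <- rev_hits[!rev_hits$promoter_offset %in% hits$promoter_offset, ]
    hits <- dplyr::bind_rows(hits, rev_hits)
  }
  windows <- if (nrow(hits) == 0) character(0) else {
    substring(seq, hits$promoter_offset + 1L,
              hits$promoter_offset + pattern$span)
  }
  hits$matched_seq <- ifelse(hits$strand == "promoter", windows,
                             revcomp_chr(windows))
  hits[order(hits$promoter_offset),
       c("promoter_offset", "strand", "matched_seq", "mismatches")]
}

#' Scan a set of promoters for motif patterns
#'
#' Runs [scan_sequence()] over every promoter and pattern and reports each hit
#' with its distance from the start codon. By default (`distance_from =
#' "5prime"`) the distance is the 1-based position of the match's 5'-most base
#' counting backwards from the base immediately preceding the start codon, so
#' a motif occupying the promoter's last `span` bases has distance `span`;
#' `"3prime"` anchors at the match's 3'-most base instead.
#'
#' @param promoters Tibble from [extract_promoters()] (columns `locus_tag`,
#'   `sequence` required).
#' @param patterns A `motif_pattern` or list of them (e.g. [surr_patterns()]).
#' @param both_strands Scan promoter reverse complements too (default `TRUE`).
#' @param max_mismatch Optional override of each pattern's mismatch budget.
#' @param distance_from `"5prime"` (default) or `"3prime"`; see Details.
#' @return A tibble with columns `locus_tag`, `pattern_id`, `distance`,
#'   `promoter_offset`, `strand`, `matched_seq`, `mismatches`, sorted by
#'   locus tag then distance ascending.
#' @export
scan_promoters <- function(promoters, patterns, both_strands = TRUE,
                           max_mismatch = NULL,
                           distance_from = c("5prime", "3prime")) {
  distance_from <- match.arg(distance_from)
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  if (anyDuplicated(promoters$locus_tag)) {
    abort(paste0("duplicate locus tags among promoters: ",
                 paste(unique(promoters$locus_tag[
                   duplicated(promoters$locus_tag)]), collapse = ", ")))
  }
  hits <- purrr::map_dfr(patterns, function(pat) {
    mm <- max_mismatch %||% pat$max_mismatch
    per_prom <- purrr::map2(promoters$locus_tag, promoters$sequence,
      function(tag, seq) {
        h <- scan_sequence(seq, pat, both_strands = both_strands,
                           max_mismatch = mm)
        if (nrow(h) == 0) return(NULL)
        h$locus_tag <- tag
        h$pattern_id <- pat$pattern_id
        h$distance <- if (distance_from == "5prime") {
          nchar(seq) - h$promoter_offset
        } else {
          nchar(seq) - h$promoter_offset - pat$span + 1L
        }
        h
      })
    dplyr::bind_rows(per_prom)
  })
  if (nrow(hits) == 0) {
    return(tibble::tibble(locus_tag = character(0), pattern_id = character(0),
                          distance = integer(0), promoter_offset = integer(0),
                          strand = character(0), matched_seq = character(0),
                          mismatches = integer(0)))
  }
  hits |>
    dplyr::select("locus_tag", "pattern_id", "distance", "promoter_offset",
                  "strand", "matched_seq", "mismatches") |>
    dplyr::arrange(.data$locus_tag, .data$distance)
}

#' Collapse hits nested inside longer-pattern hits
#'
#' The long SurR motif starts with a full short motif, so every long hit
#' carries a nested short hit at the same 5' offset. [scan_promoters()]
#' reports both; this helper removes any hit whose spanned interval lies
#' entirely inside a hit of a different, longer pattern in the same promoter,
#' giving occurrence counts in which a composite site is counted once under
#' its longest matching pattern.
#'
#' @param hits Tibble from [scan_promoters()].
#' @param patterns The pattern list used for the scan (for spans).
#' @return The hits tibble with nested hits removed.
#' @export
collapse_nested_hits <- function(hits, patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  spans <- purrr::map_int(patterns, "span")
  names(spans) <- purrr::map_chr(patterns, "pattern_id")
  span <- spans[hits$pattern_id]
  lo <- hits$promoter_offset
  hi <- hits$promoter_offset + span - 1L
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    host <- hits$locus_tag == hits$locus_tag[i] &
      hits$pattern_id != hits$pattern_id[i] &
      span > span[i] & lo <= lo[i] & hi >= hi[i]
    !any(host)
  }, logical(1))
  hits[keep, , drop = FALSE]
}

#' Locus tags whose promoter carries at least one motif hit
#'
#' Hits carrying mismatches (the "mutated motif" report) are excluded unless
#' `include_mismatched = TRUE`.
#'
#' @param hits Tibble from [scan_promoters()].
#' @param pattern_ids Patterns to consider; default all present.
#' @param include_mismatched Count hits with `mismatches > 0` (default
#'   `FALSE`).
#' @return A character vector of distinct locus tags, sorted.
#' @export
promoters_with_motif <- function(hits, pattern_ids = NULL,
                                 include_mismatched = FALSE) {
  h <- hits
  if (!is.null(pattern_ids)) h <- h[h$pattern_id %in% pattern_ids, ]
  if (!include_mismatched) h <- h[h$mismatches == 0, ]
  sort(unique(h$locus_tag))
}

#' Write motif hits as TSV
#'
#' @param hits Tibble from [scan_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' Map promoter-relative motif hits to genomic BED6 intervals
#'
#' Converts hit offsets within promoters to 0-based half-open genomic
#' coordinates. The BED strand is the genomic strand of the match: the
#' promoter's strand for `"promoter"`-strand hits, the other strand for
#' `"opposite"` hits.
#'
#' @param hits Tibble from [scan_promoters()].
#' @param promoters Tibble from [extract_promoters()].
#' @param patterns The pattern list used for the scan (for spans).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, promoters, patterns, path) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  spans <- purrr::map_int(patterns, "span")
  names(spans) <- purrr::map_chr(patterns, "pattern_id")
  h <- dplyr::left_join(
    hits,
    promoters[, c("locus_tag", "contig_id", "genomic_start", "genomic_end",
                  "strand")] |>
      dplyr::rename(gene_strand = "strand"),
    by = "locus_tag"
  )
  span <- spans[h$pattern_id]
  plus <- h$gene_strand == "+"
  g_start <- ifelse(plus,
                    h$genomic_start + h$promoter_offset,
                    h$genomic_end - h$promoter_offset - span + 1L)
  flip <- c("+" = "-", "-" = "+")
  bed <- tibble::tibble(
    chrom = h$contig_id,
    start = g_start - 1L,
    end = g_start + span - 1L,
    name = paste(h$locus_tag, h$pattern_id, h$distance, sep = "|"),
    score = h$mismatches,
    strand = ifelse(h$strand == "promoter", h$gene_strand,
                    flip[h$gene_strand])
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
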