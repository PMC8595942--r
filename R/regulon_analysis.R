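#' Expand a locus-tag range into member tags
#'
#' Gene clusters are written compactly as `"PREFIX04230-04165"`: both
#' endpoints share the prefix and their numeric suffixes differ by a multiple
#' of the annotation's tag increment (`step`, usually 5). The expansion is the
#' inclusive arithmetic sequence between the endpoints (descending ranges are
#' allowed), zero-padded to the width of the first endpoint's numeric part.
#' A bare tag without `-` expands to itself. The second endpoint may drop
#' leading zeros (e.g. `"A7C91_RS06205-6210"`).
#'
#' @param range_text Range string, e.g. `"A7C91_RS04230-04165"`.
#' @param step Locus-tag increment (default 5).
#' @return Character vector of locus tags.
#' @export
expand_locus_range <- function(range_text, step = 5L) {
  stopifnot(length(range_text) == 1, step >= 1)
  m <- stringr::str_match(range_text, "^(.*?)(\\d+)(?:-(\\d+))?$")
  if (is.na(m[1, 1]) || m[1, 2] == "" && is.na(m[1, 3])) {
    abort(paste0("cannot parse locus-tag range: '", range_text, "'"))
  }
  prefix <- m[1, 2]
  from_txt <- m[1, 3]
  to_txt <- m[1, 4]
  if (is.na(to_txt)) to_txt <- from_txt
  from <- as.integer(from_txt)
  to <- as.integer(to_txt)
  if ((to - from) %% step != 0) {
    abort(paste0("range '", range_text, "' does not span a multiple of step ",
                 step, "; wrong step?"))
  }
  nums <- seq(from, to, by = if (to >= from) step else -step)
  paste0(prefix, formatC(nums, width = nchar(from_txt), flag = "0"))
}

#' Bundled hydrogen/sulfur-metabolism gene clusters
#'
#' The SurR-associated gene clusters of the Thermococcus piezophilus genome
#' annotation (membrane-bound hydrogenase and sulfane reductase, formate
#' dehydrogenase, soluble hydrogenase, Nfn transhydrogenase clusters, and
#' related singletons), as cluster name, locus-tag range and expected member
#' count.
#'
#' @return A tibble with columns `name`, `locus_range`, `total_cds`.
#' @export
hydrogenase_clusters <- function() {
  readr::read_tsv(
    system.file("extdata", "hydrogenase_clusters.tsv",
                package = "piezoregulon"),
    show_col_types = FALSE
  )
}

#' Overlap statistics between two gene sets in a universe
#'
#' Counts and percentages for set A (e.g. a regulon: promoters carrying a
#' binding motif), set B (e.g. pressure-regulated genes) and their overlap.
#' Percentages are rounded half-up to 1 decimal: `pct_of_universe` is A as a
#' share of the universe, `pct_of_a` and `pct_of_b` are the overlap as a
#' share of A and of B.
#'
#' @param universe Character vector of all locus tags.
#' @param set_a,set_b Character vectors; must be subsets of `universe`.
#' @return A one-row tibble with `n_universe`, `n_set_a`, `n_set_b`,
#'   `n_overlap`, `pct_of_universe`, `pct_of_a`, `pct_of_b`.
#' @export
overlap_stats <- function(universe, set_a, set_b) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("set_a and set_b must be subsets of the universe")
  }
  n_overlap <- length(intersect(set_a, set_b))
  pct <- function(num, den) if (den == 0) 0 else round_half_up(100 * num / den, 1)
  tibble::tibble(
    n_universe = length(universe),
    n_set_a = length(set_a),
    n_set_b = length(set_b),
    n_overlap = n_overlap,
    pct_of_universe = pct(length(set_a), length(universe)),
    pct_of_a = pct(n_overlap, length(set_a)),
    pct_of_b = pct(n_overlap, length(set_b))
  )
}

#' Per-cluster overexpression summary
#'
#' For each cluster and each directional contrast, counts the cluster members
#' called overexpressed in that direction. Contrast labels follow the
#' `"A>B"` convention: genes higher at condition A than at B.
#'
#' @param de_results Tibble binding [tidy()] results of all pairwise
#'   [nb_wald_test()] runs (columns `locus_tag`, `comparison` as
#'   `"A_vs_B"`, `call`).
#' @param clusters Tibble with columns `name` and `locus_range` (and
#'   optionally pre-expanded `member_tags` list-column).
#' @param step Locus-tag increment for range expansion (default 5).
#' @return A tibble with columns `name`, `contrast`, `n_over`, `total_cds`
#'   and `rendered` (the count as text, `"nd"` for zero). Cluster members
#'   absent from the DE universe are counted as not-called, with a warning.
#' @export
cluster_summary <- function(de_results, clusters, step = 5L) {
  if (nrow(clusters) == 0) {
    return(tibble::tibble(name = character(0), contrast = character(0),
                          n_over = integer(0), total_cds = integer(0),
                          rendered = character(0)))
  }
  members <- clusters[["member_tags"]] %||%
    purrr::map(clusters$locus_range, expand_locus_range, step = step)
  universe <- unique(de_results$locus_tag)
  absent <- setdiff(unlist(members), universe)
  if (length(absent) > 0) {
    warn(paste0(length(absent), " cluster member(s) absent from the DE ",
                "universe; counted as not-called"))
  }
  comparisons <- unique(de_results$comparison)
  purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    tags <- members[[i]]
    purrr::map_dfr(comparisons, function(cmp) {
      ab <- strsplit(cmp, "_vs_", fixed = TRUE)[[1]]
      res <- de_results[de_results$comparison == cmp &
                          de_results$locus_tag %in% tags, ]
      tibble::tibble(
        name = clusters$name[i],
        contrast = c(paste0(ab[1], ">", ab[2]), paste0(ab[2], ">", ab[1])),
        n_over = c(sum(res$call == "over_in_A"), sum(res$call == "over_in_B")),
        total_cds = length(tags)
      )
    })
  }) |>
    dplyr::mutate(rendered = ifelse(.data$n_over == 0, "nd",
                                    as.character(.data$n_over)))
}

#' Venn region counts for DEG sets
#'
#' @param deg_sets Named list of character vectors (one DEG set per
#'   comparison); at least two.
#' @return A tibble with `region` (set names joined by `&` for pairwise
#'   intersections; for exactly three sets also the 7 exclusive regions,
#'   suffixed `_only`) and `n`.
#' @export
venn_counts <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 2, !is.null(names(deg_sets)))
  sets <- purrr::map(deg_sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(region = paste(p, collapse = " & "),
                   n = length(intersect(sets[[p[1]]], sets[[p[2]]])))
  })
  if (length(sets) == 3) {
    a <- sets[[1]]; b <- sets[[2]]; c <- sets[[3]]
    abc <- intersect(intersect(a, b), c)
    excl <- tibble::tibble(
      region = c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                 paste0(nm[3], "_only"),
                 paste0(nm[1], " & ", nm[2], "_only"),
                 paste0(nm[1], " & ", nm[3], "_only"),
                 paste0(nm[2], " & ", nm[3], "_only"),
                 paste(nm, collapse = " & ")),
      n = c(length(setdiff(setdiff(a, b), c)),
            length(setdiff(setdiff(b, a), c)),
            length(setdiff(setdiff(c, a), b)),
            length(setdiff(intersect(a, b), c)),
            length(setdiff(intersect(a, c), b)),
            length(setdiff(intersect(b, c), a)),
            length(abc))
    )
    out <- dplyr::bind_rows(out, excl)
  }
  out
}

#' EASE enrichment statistic
#'
#' A conservative one-tailed Fisher exact p-value for enrichment of a term in
#' a gene list: one hit is removed from the list-hits cell (floored at 0)
#' before taking the hypergeometric upper tail on the original margins, so a
#' single-gene overlap is never significant. Penalization can only raise the
#' p-value relative to the plain Fisher test.
#'
#' @param list_hits Genes in the list annotated with the term.
#' @param list_size Genes in the list.
#' @param pop_hits Genes in the population annotated with the term.
#' @param pop_size Genes in the population.
#' @return The EASE p-value (scalar).
#' @export
ease_score <- function(list_hits, list_size, pop_hits, pop_size) {
  if (list_hits > list_size || list_size > pop_size || list_hits > pop_hits ||
      pop_hits > pop_size || min(list_hits, list_size, pop_hits, pop_size) < 0) {
    abort("impossible 2x2 table for EASE score")
  }
  a <- max(list_hits - 1, 0)
  stats::phyper(a - 1, pop_hits, pop_size - pop_hits, list_size,
                lower.tail = FALSE)
}

#' One-tailed Fisher enrichment p-value (unpenalized)
#'
#' @inheritParams ease_score
#' @return The hypergeometric upper-tail p-value.
#' @export
fisher_enrichment <- function(list_hits, list_size, pop_hits, pop_size) {
  if (list_hits > list_size || list_size > pop_size || list_hits > pop_hits ||
      pop_hits > pop_size || min(list_hits, list_size, pop_hits, pop_size) < 0) {
    abort("impossible 2x2 table")
  }
  stats::phyper(list_hits - 1, pop_hits, pop_size - pop_hits, list_size,
                lower.tail = FALSE)
}

#' Annotation-cluster enrichment score
#'
#' The DAVID-style group score: minus log10 of the geometric mean of the
#' member terms' EASE p-values. Scores above 1 correspond to a geometric-mean
#' p below 0.1.
#'
#' @param ease_p Numeric vector of EASE p-values in `(0, 1]`.
#' @return The enrichment score (scalar).
#' @export
enrichment_score <- function(ease_p) {
  if (any(ease_p <= 0 | ease_p > 1)) abort("EASE p-values must lie in (0, 1]")
  -log10(exp(mean(log(ease_p))))
}
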