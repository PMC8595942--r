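#' Estimate negative-binomial dispersions
#'
#' Per-gene dispersions are estimated by method of moments on size-factor
#' normalized counts, pooled within conditions: for each condition,
#' `alpha = max(0, (s^2 - m) / m^2)` with `m` and `s^2` the within-condition
#' mean and variance, averaged across conditions. A mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` is fitted by least squares over genes with a
#' positive moment estimate, and the final per-gene dispersion is the
#' weighted blend `w * trend + (1 - w) * moment`, floored at 1e-8. The blend
#' borrows strength across genes, stabilizing the noisy 3-replicate moment
#' estimates without erasing genuine gene-level signal.
#'
#' @param counts Tibble with a `locus_tag` column and one column per sample.
#' @param design Tibble with columns `sample_id`, `condition`; every
#'   condition needs at least 2 replicates.
#' @param size_factors Tibble from [rle_size_factors()]; computed from
#'   `counts` when `NULL`.
#' @param shrinkage_weight Weight `w` on the trend (default 0.5).
#' @return An object of class `dispersion_fit`: a list with `per_gene` (a
#'   tibble with `locus_tag`, `base_mean`, `alpha_mom`, `alpha_trend`,
#'   `alpha`), `trend` (coefficients `a0`, `a1`) and `weight`.
#' @export
estimate_dispersion <- function(counts, design, size_factors = NULL,
                                shrinkage_weight = 0.5) {
  design <- check_design(counts, design, min_replicates = 2L)
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  m <- counts_to_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  x <- sweep(m, 2, sf, "/")
  conds <- unique(design$condition)
  mom_by_cond <- vapply(conds, function(cc) {
    xs <- x[, design$sample_id[design$condition == cc], drop = FALSE]
    mu <- rowMeans(xs)
    v <- apply(xs, 1, stats::var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- 0
    pmax(a, 0)
  }, numeric(nrow(x)))
  alpha_mom <- rowMeans(mom_by_cond)
  base_mean <- rowMeans(x)
  fit_genes <- alpha_mom > 0 & base_mean > 0
  if (sum(fit_genes) >= 2) {
    fit <- stats::lm.fit(cbind(a0 = 1, a1 = 1 / base_mean[fit_genes]),
                         alpha_mom[fit_genes])
    trend <- fit$coefficients
  } else {
    trend <- c(a0 = mean(alpha_mom), a1 = 0)
  }
  alpha_trend <- pmax(trend[["a0"]] + trend[["a1"]] / pmax(base_mean, 1e-8), 0)
  alpha <- pmax(shrinkage_weight * alpha_trend +
                  (1 - shrinkage_weight) * alpha_mom, 1e-8)
  structure(
    list(
      per_gene = tibble::tibble(
        locus_tag = rownames(x), base_mean = unname(base_mean),
        alpha_mom = unname(alpha_mom), alpha_trend = unname(alpha_trend),
        alpha = unname(alpha)
      ),
      trend = c(a0 = unname(trend[["a0"]]), a1 = unname(trend[["a1"]])),
      weight = shrinkage_weight
    ),
    class = "dispersion_fit"
  )
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("<dispersion_fit> ", nrow(x$per_gene), " genes; trend alpha(mu) = ",
      signif(x$trend[["a0"]], 3), " + ", signif(x$trend[["a1"]], 3),
      "/mu; weight ", x$weight, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.dispersion_fit <- function(x, ...) x$per_gene

#' Negative-binomial Wald test between two conditions
#'
#' Per gene, the expression level of each condition is the mean of
#' size-factor-normalized counts plus a 0.5 pseudocount; the reported effect
#' is `log2fc = log2(q_B / q_A)`. The standard error of each log level comes
#' from the NB variance `mu + alpha * mu^2` by the delta method,
#' `Var(ln q_c) = (1/n_c^2) * sum_j (1 / (s_j q_c) + alpha)`, and the Wald
#' statistic `z = (ln q_B - ln q_A) / SE` is referred to the standard normal
#' (two-sided). P-values are BH-adjusted across genes and calls made at
#' `alpha` (adjusted p below `alpha`, default 1%).
#'
#' @inheritParams estimate_dispersion
#' @param comparison Length-2 character vector `c(A, B)` of condition labels;
#'   positive `log2fc` means higher in `B`.
#' @param dispersion A `dispersion_fit`; estimated from `counts` when `NULL`.
#' @param alpha Adjusted-p significance threshold for calls (default 0.01).
#' @return An object of class `nb_de`: `results` tibble (`locus_tag`,
#'   `comparison`, `base_mean_a`, `base_mean_b`, `log2fc`, `p_value`,
#'   `p_adj`, `call` in `over_in_B` / `over_in_A` / `ns`), plus the
#'   comparison, alpha and size factors used. Use [tidy()] / [glance()].
#' @export
nb_wald_test <- function(counts, design, comparison, size_factors = NULL,
                         dispersion = NULL, alpha = 0.01) {
  stopifnot(length(comparison) == 2)
  design <- check_design(counts, design, min_replicates = 2L)
  if (!all(comparison %in% design$condition)) {
    abort(paste0("comparison condition(s) absent from design: ",
                 paste(setdiff(comparison, design$condition), collapse = ", ")))
  }
  if (is.null(size_factors)) size_factors <- rle_size_factors(counts)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, design, size_factors)
  }
  m <- counts_to_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  names(sf) <- colnames(m)
  x <- sweep(m, 2, sf, "/")
  a_samples <- design$sample_id[design$condition == comparison[1]]
  b_samples <- design$sample_id[design$condition == comparison[2]]
  alpha_i <- dispersion$per_gene$alpha[
    match(rownames(m), dispersion$per_gene$locus_tag)]
  if (anyNA(alpha_i)) abort("dispersion fit does not cover all genes")

  cond_stats <- function(samples) {
    xs <- x[, samples, drop = FALSE]
    n <- length(samples)
    q <- rowMeans(xs) + 0.5
    # Var(ln q) via delta method on the mean of normalized NB counts
    var_ln <- rowSums(outer(rep(1, nrow(xs)), 1 / sf[samples]) / q +
                        alpha_i) / n^2
    list(q = q, var_ln = var_ln, raw_mean = rowMeans(xs))
  }
  sa <- cond_stats(a_samples)
  sb <- cond_stats(b_samples)
  log2fc <- log2(sb$q / sa$q)
  se_ln <- sqrt(sa$var_ln + sb$var_ln)
  z <- (log(sb$q) - log(sa$q)) / se_ln
  p <- 2 * stats::pnorm(-abs(z))
  # genes absent in both conditions carry no information
  p[sa$raw_mean == 0 & sb$raw_mean == 0] <- 1
  results <- tibble::tibble(
    locus_tag = rownames(m),
    comparison = paste(comparison, collapse = "_vs_"),
    base_mean_a = unname(sa$raw_mean),
    base_mean_b = unname(sb$raw_mean),
    log2fc = unname(log2fc),
    p_value = unname(p),
    p_adj = bh_adjust(unname(p))
  )
  results <- call_deg(results, alpha = alpha)
  structure(
    list(results = results, comparison = comparison, alpha = alpha,
         size_factors = size_factors, dispersion = dispersion),
    class = "nb_de"
  )
}

#' @export
print.nb_de <- function(x, ...) {
  g <- glance(x)
  cat("<nb_de> ", x$comparison[1], " vs ", x$comparison[2], ": ",
      g$n_genes, " genes, ", g$n_over_in_b, " over in ", x$comparison[2],
      ", ", g$n_over_in_a, " over in ", x$comparison[1],
      " (adjusted p < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @rdname nb_wald_test
#' @param x An `nb_de` object.
#' @param ... Unused.
#' @export
tidy.nb_de <- function(x, ...) x$results

#' @rdname nb_wald_test
#' @export
glance.nb_de <- function(x, ...) {
  tibble::tibble(
    comparison = paste(x$comparison, collapse = "_vs_"),
    n_genes = nrow(x$results),
    n_over_in_a = sum(x$results$call == "over_in_A"),
    n_over_in_b = sum(x$results$call == "over_in_B"),
    alpha = x$alpha
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in input order. This is the standard
#' `p.adjust(method = "BH")` computation with input validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' @param results Tibble with `p_adj` and `log2fc` columns.
#' @param alpha Adjusted-p threshold (default 0.01, i.e. the 1% rule).
#' @return `results` with a `call` column: `over_in_B` (`p_adj < alpha`,
#'   `log2fc > 0`), `over_in_A` (`p_adj < alpha`, `log2fc < 0`), else `ns`.
#' @export
call_deg <- function(results, alpha = 0.01) {
  results$call <- dplyr::case_when(
    results$p_adj < alpha & results$log2fc > 0 ~ "over_in_B",
    results$p_adj < alpha & results$log2fc < 0 ~ "over_in_A",
    .default = "ns"
  )
  results
}

#' Split DE results into directional locus-tag sets
#'
#' @param results Tibble with `locus_tag` and `call` columns (from
#'   [tidy()] on an `nb_de` object, possibly after [call_deg()]).
#' @return A list with character vectors `over_in_A` and `over_in_B`.
#' @export
deg_sets <- function(results) {
  list(over_in_A = results$locus_tag[results$call == "over_in_A"],
       over_in_B = results$locus_tag[results$call == "over_in_B"])
}

#' Z-score sample clustering
#'
#' Each gene's values are standardized to mean 0, sd 1 across samples (genes
#' with zero variance are dropped), then samples are clustered
#' agglomeratively on Euclidean distance with average linkage (UPGMA). Sample
#' columns are taken in sorted order so the leaf order is deterministic.
#'
#' @param normalized Tibble with a `locus_tag` column and one column per
#'   sample (e.g. TPM or size-factor-scaled values).
#' @return An object of class `zscore_clust`: `z` (tibble of z-scores),
#'   `hclust` (the [stats::hclust()] tree), `order` (leaf order as sample
#'   ids) and `heights` (merge heights).
#' @export
zscore_cluster <- function(normalized) {
  m <- counts_to_matrix(normalized)
  if (ncol(m) < 2) abort("need at least 2 samples to cluster")
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0
  z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
    sds[keep]
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  structure(
    list(z = matrix_to_counts(z), hclust = hc,
         order = colnames(z)[hc$order], heights = hc$height),
    class = "zscore_clust"
  )
}

#' @export
print.zscore_clust <- function(x, ...) {
  cat("<zscore_clust> ", nrow(x$z), " genes x ", length(x$order),
      " samples; leaf order: ", paste(x$order, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cut a z-score clustering into k sample groups
#'
#' @param clust A `zscore_clust` object.
#' @param k Number of groups.
#' @return A named integer vector of group labels, one per sample.
#' @export
cut_sample_tree <- function(clust, k) {
  stats::cutree(clust$hclust, k = k)
}
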