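# brute-force reference implementations used as independent oracles

# position-by-position sliding-window motif scan (single strand)
oracle_scan <- function(seq, blocks, gaps, max_mismatch = 0) {
  span <- sum(nchar(blocks)) + sum(gaps)
  chars <- strsplit(seq, "")[[1]]
  pos <- integer(0); expected <- character(0); off <- 0L
  for (i in seq_along(blocks)) {
    b <- strsplit(blocks[i], "")[[1]]
    pos <- c(pos, off + seq_along(b))
    expected <- c(expected, b)
    off <- off + length(b) + (if (i <= length(gaps)) gaps[i] else 0L)
  }
  hits <- integer(0)
  for (o in 0:(nchar(seq) - span)) {
    mm <- sum(chars[o + pos] != expected)
    if (mm <= max_mismatch) hits <- c(hits, o)
  }
  hits
}

oracle_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# direct BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)
}

# O(n^3) UPGMA agglomeration returning merge heights
oracle_upgma_heights <- function(m) {
  d <- as.matrix(dist(t(m)))
  diag(d) <- Inf
  sizes <- rep(1, ncol(d))
  heights <- numeric(0)
  while (nrow(d) > 1) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, d[i, j])
    new_d <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    d[i, ] <- new_d; d[, i] <- new_d
    d[i, i] <- Inf
    d <- d[-j, -j, drop = FALSE]
    sizes[i] <- sizes[i] + sizes[j]
    sizes <- sizes[-j]
  }
  heights
}

# hypergeometric upper-tail by direct summation
oracle_hyper_tail <- function(k, pop_hits, pop_size, list_size) {
  ks <- k:min(pop_hits, list_size)
  sum(choose(pop_hits, ks) * choose(pop_size - pop_hits, list_size - ks)) /
    choose(pop_size, list_size)
}

random_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""),
         character(1))
}

# small toy count tibble: genes x samples
toy_counts <- function(m, gene_ids = paste0("g", seq_len(nrow(m))),
                       sample_ids = paste0("s", seq_len(ncol(m)))) {
  colnames(m) <- sample_ids
  tibble::as_tibble(m) |>
    dplyr::mutate(locus_tag = gene_ids, .before = 1)
}

toy_design <- function(conditions, replicates) {
  tibble::tibble(
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conditions))
  ) |>
    dplyr::mutate(sample_id = paste0(condition, "_r", replicate),
                  .before = 1)
}
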