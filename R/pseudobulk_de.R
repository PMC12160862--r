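# Pseudobulk aggregation, gene filters, differential expression, and
# preranked gene-set enrichment.

#' Aggregate single-cell counts into a pseudobulk matrix
#'
#' Entry (sample, gene) is the sum of raw counts of that gene over the
#' subset cells of that sample. Total matrix mass therefore equals the total
#' subset counts exactly. Samples with zero subset cells are dropped with a
#' warning.
#'
#' @param cohort an `sc_cohort`.
#' @param subset cell-type label, or prefix when `prefix = TRUE`.
#' @param prefix match `subset` as a cell-type prefix (default `FALSE`).
#' @return samples x genes integer matrix.
#' @export
aggregate_pseudobulk <- function(cohort, subset, prefix = FALSE) {
  stopifnot(inherits(cohort, "sc_cohort"))
  ann <- cohort$annotation
  in_subset <- if (prefix) startsWith(ann$cell_type, subset)
               else ann$cell_type == subset
  samples <- unique(ann$sample)
  with_cells <- vapply(samples, function(s) any(in_subset & ann$sample == s),
                       logical(1))
  if (sum(with_cells) < 2)
    stop("subset cells must exist in at least 2 samples", call. = FALSE)
  if (any(!with_cells))
    warning("samples without subset cells dropped: ",
            paste(samples[!with_cells], collapse = ", "))
  samples <- samples[with_cells]
  pb <- t(vapply(samples, function(s) {
    idx <- in_subset & ann$sample == s
    as.numeric(Matrix::rowSums(cohort$counts[, idx, drop = FALSE]))
  }, numeric(nrow(cohort$counts))))
  dimnames(pb) <- list(samples, rownames(cohort$counts))
  pb
}

#' Filter pseudobulk genes
#'
#' A gene is kept iff its total count is at least 2 and it is detected
#' (count >= 1) in at least 2 samples — i.e. genes with total count <= 1 or
#' detected in fewer than two samples are excluded.
#'
#' @param pb samples x genes pseudobulk matrix.
#' @return the filtered matrix.
#' @export
filter_pseudobulk_genes <- function(pb) {
  keep <- colSums(pb) >= 2 & colSums(pb >= 1) >= 2
  pb[, keep, drop = FALSE]
}

#' Two-group pseudobulk differential expression
#'
#' Log fold changes are pseudocount-stabilized ratios of group mean CPM:
#' `log2((mean CPM_num + 1) / (mean CPM_den + 1))`; p-values come from a
#' Welch (unequal-variance) two-sample t-test on `log2(CPM + 1)`. A gene is
#' flagged as differentially expressed when `|log2FC| >= lfc_cut` (inclusive)
#' and `p < p_cut`. A Benjamini-Hochberg column is reported but plays no role
#' in the flag.
#'
#' @param pb samples x genes pseudobulk matrix (ideally pre-filtered).
#' @param groups two-level factor/vector over samples; each level needs at
#'   least 2 samples.
#' @param numerator group forming the fold-change numerator (default: the
#'   last level, so `high` over `low` for [stratify_by_score()] output).
#' @param lfc_cut,p_cut DEG thresholds (defaults 1.0 and 0.05).
#' @return data.frame: `gene`, `log2_fc`, `p_value`, `padj`, `deg_flag`.
#' @export
de_test <- function(pb, groups, numerator = NULL, lfc_cut = 1.0, p_cut = 0.05) {
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  numerator <- numerator %||% levels(groups)[nlevels(groups)]
  denominator <- setdiff(levels(groups), numerator)

  cpm <- pb / rowSums(pb) * 1e6
  lcpm <- log2(cpm + 1)
  a <- groups == numerator
  b <- groups == denominator

  log2_fc <- log2((colMeans(cpm[a, , drop = FALSE]) + 1) /
                  (colMeans(cpm[b, , drop = FALSE]) + 1))
  p <- vapply(seq_len(ncol(pb)), function(j) {
    x <- lcpm[a, j]; y <- lcpm[b, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else NA_real_)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))

  data.frame(gene = colnames(pb), log2_fc = log2_fc, p_value = p,
             padj = stats::p.adjust(p, "BH"),
             deg_flag = !is.na(p) & abs(log2_fc) >= lfc_cut & p < p_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score on a ranking.
# `stats` must be ordered (decreasing) and named by gene.
gsea_es <- function(ranked_genes, ranked_stats, set, weight = 1) {
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  if (nh == 0) return(NA_real_)
  w <- abs(ranked_stats)^weight
  w_hit <- w * hit
  denom_hit <- sum(w_hit)
  p_hit <- if (denom_hit > 0) cumsum(w_hit) / denom_hit
           else cumsum(hit) / nh  # all-zero stats: unweighted steps
  p_miss <- cumsum(!hit) / max(1, length(ranked_genes) - nh)
  run <- p_hit - p_miss
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on a gene ranking
#' (genes ordered by a score such as log2 fold change, descending). The
#' enrichment score (ES) lies in `[-1, 1]`. The null distribution comes from
#' `n_perm` random gene sets of the same size drawn from the ranking
#' (gene-permutation null); `NES = ES / mean(|null ES of the same sign|)` and
#' the p-value is the one-sided permutation tail with the +1 correction.
#'
#' @param ranking named numeric vector of per-gene scores; sorted internally
#'   in decreasing order.
#' @param gene_set character vector; at least one gene must be in the
#'   ranking.
#' @param weight exponent on `|score|` for the hit increments (default 1).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return list with `es`, `nes`, `p_value`, `n_set_genes`.
#' @export
preranked_enrichment <- function(ranking, gene_set, weight = 1, n_perm = 1000,
                                 seed = 1L) {
  stopifnot(!is.null(names(ranking)))
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  stats_sorted <- as.numeric(ranking)[ord]
  set <- intersect(gene_set, genes)
  if (!length(set))
    stop("no gene-set genes present in the ranking", call. = FALSE)

  es <- gsea_es(genes, stats_sorted, set, weight)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      gsea_es(genes, stats_sorted, sample(genes, length(set)), weight),
      numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  list(es = es, nes = nes, p_value = p, n_set_genes = length(set))
}

#' Over-representation test of a gene set in a hit list
#'
#' Hypergeometric (one-sided Fisher) test of whether `hits` (for example the
#' upregulated DEGs) over-represents `gene_set` relative to `universe` — the
#' companion entry point to [preranked_enrichment()].
#'
#' @param hits character vector of selected genes.
#' @param gene_set character vector.
#' @param universe all genes tested.
#' @return list with `overlap`, `expected`, `p_value`.
#' @export
ora_test <- function(hits, gene_set, universe) {
  hits <- intersect(hits, universe)
  set <- intersect(gene_set, universe)
  k <- length(intersect(hits, set))
  p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                     length(hits), lower.tail = FALSE)
  list(overlap = k,
       expected = length(hits) * length(set) / length(universe),
       p_value = p)
}
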