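# Gene-set scoring of cells and subjects, and score-based stratification.

#' Module-score parameters
#'
#' Mirrors the control-gene convention of Seurat-style module scoring:
#' genes are binned on cohort-average expression and, for every signature
#' gene, control genes are drawn from the same bin.
#'
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl_per_gene control genes sampled per signature gene
#'   (default 100, capped at the bin size; sampled without replacement
#'   within a bin).
#' @param seed integer seed for the control draw.
#' @return a `score_params` list.
#' @export
score_params <- function(n_bins = 24, n_ctrl_per_gene = 100, seed = 1L) {
  stopifnot(n_bins >= 1, n_ctrl_per_gene >= 1)
  structure(list(n_bins = n_bins, n_ctrl_per_gene = n_ctrl_per_gene,
                 seed = as.integer(seed)),
            class = "score_params")
}

#' Score cells against a gene set (module score)
#'
#' Per cell: mean expression of the signature genes minus mean expression of
#' expression-matched control genes (drawn from the signature genes' bins,
#' excluding the signature itself). A constant matrix therefore scores 0,
#' and adding a constant to every gene in every cell leaves scores unchanged.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param gene_set character vector of gene ids; at least one must be present.
#' @param params a [score_params()].
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(norm, gene_set, params = score_params()) {
  genes <- rownames(norm)
  set_genes <- intersect(gene_set, genes)
  if (!length(set_genes))
    stop("none of the signature genes are present in the matrix", call. = FALSE)

  avg <- Matrix::rowMeans(norm)
  # rank-based binning: equal-occupancy bins over average expression
  bin <- if (params$n_bins == 1) rep(1L, length(avg))
         else cut(rank(avg, ties.method = "first"),
                  breaks = params$n_bins, labels = FALSE)
  names(bin) <- genes

  ctrl_genes <- with_seed(params$seed, {
    unlist(lapply(set_genes, function(g) {
      pool <- genes[bin == bin[g]]
      pool <- setdiff(pool, set_genes)
      if (!length(pool)) return(character(0))
      sample(pool, min(params$n_ctrl_per_gene, length(pool)))
    }))
  })
  ctrl_genes <- unique(ctrl_genes)

  set_mean <- Matrix::colMeans(norm[set_genes, , drop = FALSE])
  ctrl_mean <- if (length(ctrl_genes))
    Matrix::colMeans(norm[ctrl_genes, , drop = FALSE]) else 0
  score <- set_mean - ctrl_mean
  names(score) <- colnames(norm)
  score
}

#' Rank-based single-sample signature score
#'
#' The centered, normalized mean rank of the signature genes within one
#' subject's expression profile:
#' `2 * (mean_rank - (n + 1) / 2) / (n - 1)`, lying in `[-1, 1]` with
#' expectation 0 for random gene sets. Because it only uses ranks, any
#' monotone transformation of the profile leaves the score unchanged. It
#' serves the role of a single-sample enrichment value for stratifying bulk
#' profiles by a subtype signature.
#'
#' @param expr_profile named numeric vector, one subject's expression.
#' @param gene_set character vector of gene ids.
#' @return scalar score in `[-1, 1]`.
#' @export
rank_set_score <- function(expr_profile, gene_set) {
  stopifnot(!is.null(names(expr_profile)))
  present <- intersect(gene_set, names(expr_profile))
  if (!length(present)) return(NA_real_)
  n <- length(expr_profile)
  if (n < 2) return(0)
  r <- rank(expr_profile, ties.method = "average")
  2 * (mean(r[present]) - (n + 1) / 2) / (n - 1)
}

#' Stratify subjects into high and low score groups
#'
#' Subjects strictly above the cutoff are labeled `"high"`, all others
#' `"low"` — ties at the cutoff deliberately go to the low group. The cutoff
#' is the median or a percentile of the score distribution (type-7 empirical
#' quantile).
#'
#' @param scores named numeric vector of per-subject scores (>= 4 subjects).
#' @param rule `"median"` or `"percentile"`.
#' @param q percentile in (0, 100) when `rule = "percentile"` (default 75).
#' @return named factor with levels `low`, `high`.
#' @export
stratify_by_score <- function(scores, rule = c("median", "percentile"), q = 75) {
  rule <- match.arg(rule)
  stopifnot(length(scores) >= 4, all(is.finite(scores)))
  if (max(scores) == min(scores))
    stop("degenerate cutoff: all scores are equal", call. = FALSE)
  cutoff <- if (rule == "median") stats::median(scores)
            else stats::quantile(scores, q / 100, type = 7, names = FALSE)
  out <- factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
  names(out) <- names(scores)
  out
}
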