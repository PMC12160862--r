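# Per-sample NMF program extraction and meta-program discovery.
#
# The procedure: for every sample, run NMF on the non-negativized
# log-expression matrix over a rank sweep K = 3..10 and reduce each factor to
# its top-50 genes; keep programs that are stable across K within a sample and
# recurrent across samples; hierarchically cluster the survivors on Jaccard
# distance; each cluster is a meta-program summarized by a 50-gene consensus.

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`; defined as 0 when both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return similarity in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Multiplicative-update NMF (Frobenius loss), seeded uniform init.
# V: non-negative genes x cells dense matrix. Returns list(W, H).
nmf_mu <- function(V, k, seed, max_iter = 200, tol = 1e-4) {
  eps <- 1e-10
  g <- nrow(V); n <- ncol(V)
  with_seed(seed, {
    scale0 <- sqrt(mean(V) / k)
    W <- matrix(stats::runif(g * k, 0, 2 * scale0), g, k)
    H <- matrix(stats::runif(k * n, 0, 2 * scale0), k, n)
  })
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(W = W, H = H)
}

# Non-negativity preprocessing for meta-program NMF: per-gene centering of the
# log-normalized expression, negatives clipped to 0.
center_clip <- function(norm) {
  V <- as_dense(norm)
  V <- V - rowMeans(V)
  V[V < 0] <- 0
  V
}

new_gene_program <- function(sample_id, rank_K, factor_index, top_genes, weights) {
  structure(list(sample_id = sample_id, rank_K = as.integer(rank_K),
                 factor_index = as.integer(factor_index),
                 top_genes = top_genes, weights = weights),
            class = "gene_program")
}

#' Extract expression programs from one sample by NMF
#'
#' Runs multiplicative-update NMF on the sample's non-negativized
#' log-expression matrix for every rank `K` in `k_min..k_max`. Each factor is
#' reduced to its top `n_top` genes by gene loading (ties broken by gene id),
#' yielding `sum(k_min:k_max)` programs per sample.
#'
#' @param norm_sample genes x cells log-normalized matrix for one sample;
#'   must have at least `k_max` cells.
#' @param k_min,k_max rank sweep bounds (defaults 3 and 10).
#' @param seed integer seed; initialization is seeded per (K, seed) so the
#'   sweep is fully deterministic.
#' @param n_top genes retained per program (default 50).
#' @param sample_id label stored on each program.
#' @param max_iter,tol solver controls (200 iterations, relative tolerance
#'   1e-4).
#' @return list of `gene_program` objects.
#' @export
fit_sample_nmf <- function(norm_sample, k_min = 3, k_max = 10, seed = 1L,
                           n_top = 50, sample_id = "S1",
                           max_iter = 200, tol = 1e-4) {
  stopifnot(k_min >= 1, k_max >= k_min)
  if (ncol(norm_sample) < k_max)
    stop("sample has fewer cells than k_max", call. = FALSE)
  V <- center_clip(norm_sample)
  if (all(V == 0)) stop("degenerate all-zero matrix after preprocessing",
                        call. = FALSE)
  genes <- rownames(V)
  n_top <- min(n_top, nrow(V))
  programs <- list()
  for (K in k_min:k_max) {
    fit <- nmf_mu(V, K, seed = seed + K, max_iter = max_iter, tol = tol)
    for (j in seq_len(K)) {
      w <- fit$W[, j]
      ord <- order(-w, genes)[seq_len(n_top)]
      programs[[length(programs) + 1L]] <-
        new_gene_program(sample_id, K, j, genes[ord], w[ord])
    }
  }
  programs
}

#' @export
print.gene_program <- function(x, ...) {
  cat(sprintf("<gene_program> %s K=%d factor=%d; top genes: %s ...\n",
              x$sample_id, x$rank_K, x$factor_index,
              paste(utils::head(x$top_genes, 5), collapse = ", ")))
  invisible(x)
}

#' Robustness-selection parameters
#'
#' @param intra_min_overlap genes a program must share with a program of a
#'   different K in the same sample to count as stable (default 35 of 50).
#' @param intra_redundancy_cap redundancy slack: retained programs of one
#'   sample sharing more than `50 - intra_redundancy_cap` genes are collapsed
#'   to a single representative (default 10, i.e. > 40 shared genes).
#' @param inter_min_overlap genes shared with another sample's program for
#'   that sample to count towards recurrence (default 10).
#' @param min_samples_recurrent minimum number of distinct samples (including
#'   the program's own) a program must recur in (default 2).
#' @return a `robustness_params` list.
#' @export
robustness_params <- function(intra_min_overlap = 35, intra_redundancy_cap = 10,
                              inter_min_overlap = 10, min_samples_recurrent = 2) {
  stopifnot(intra_min_overlap >= 0, intra_min_overlap <= 50,
            intra_redundancy_cap >= 0, intra_redundancy_cap <= 50,
            inter_min_overlap >= 0, inter_min_overlap <= 50)
  structure(list(intra_min_overlap = intra_min_overlap,
                 intra_redundancy_cap = intra_redundancy_cap,
                 inter_min_overlap = inter_min_overlap,
                 min_samples_recurrent = min_samples_recurrent),
            class = "robustness_params")
}

overlap_size <- function(a, b) length(intersect(a, b))

#' Select stable, recurrent, non-redundant programs
#'
#' A program is kept iff (a) it shares at least `intra_min_overlap` genes
#' with some program of a *different* K in the same sample (stability across
#' rank), and (b) programs from at least `min_samples_recurrent - 1` *other*
#' samples share at least `inter_min_overlap` genes with it (cross-sample
#' recurrence). Within a sample, retained programs sharing more than
#' `50 - intra_redundancy_cap` genes are collapsed, keeping the one with the
#' highest cross-sample recurrence; ties go to lower K, then lower factor
#' index.
#'
#' @param programs list of `gene_program` objects (>= 1 sample).
#' @param params a [robustness_params()].
#' @return filtered list of `gene_program` objects, each annotated with its
#'   `recurrence` (number of other samples supporting it).
#' @export
select_robust_programs <- function(programs, params = robustness_params()) {
  if (!length(programs)) return(programs)
  samples <- vapply(programs, `[[`, character(1), "sample_id")
  ks <- vapply(programs, `[[`, integer(1), "rank_K")
  genes <- lapply(programs, `[[`, "top_genes")
  n <- length(programs)

  stable <- logical(n)
  recurrence <- integer(n)
  for (i in seq_len(n)) {
    same_sample <- which(samples == samples[i] & ks != ks[i])
    stable[i] <- any(vapply(same_sample, function(j)
      overlap_size(genes[[i]], genes[[j]]) >= params$intra_min_overlap, logical(1)))
    other <- which(samples != samples[i])
    if (length(other)) {
      hits <- vapply(other, function(j)
        overlap_size(genes[[i]], genes[[j]]) >= params$inter_min_overlap, logical(1))
      recurrence[i] <- length(unique(samples[other][hits]))
    }
  }
  keep <- stable & (recurrence >= params$min_samples_recurrent - 1L)

  # non-redundancy within sample, greedy by (recurrence desc, K asc, factor asc)
  redundant_cut <- 50L - params$intra_redundancy_cap
  for (s in unique(samples)) {
    idx <- which(keep & samples == s)
    if (length(idx) < 2) next
    fac <- vapply(programs[idx], `[[`, integer(1), "factor_index")
    ord <- idx[order(-recurrence[idx], ks[idx], fac)]
    kept_here <- integer(0)
    for (i in ord) {
      dup <- any(vapply(kept_here, function(j)
        overlap_size(genes[[i]], genes[[j]]) > redundant_cut, logical(1)))
      if (dup) keep[i] <- FALSE else kept_here <- c(kept_here, i)
    }
  }

  out <- programs[keep]
  rec <- recurrence[keep]
  for (i in seq_along(out)) out[[i]]$recurrence <- rec[i]
  out
}

#' Cluster robust programs into meta-programs
#'
#' Average-linkage hierarchical clustering on distance `1 - Jaccard` over the
#' programs' top-gene sets, cut either at a fixed distance (default 0.75) or
#' into a fixed number of clusters. Clusters smaller than `min_cluster_size`
#' are discarded; each surviving cluster becomes a meta-program with a
#' 50-gene consensus list.
#'
#' @param programs list of `gene_program` objects (>= 2).
#' @param linkage hclust agglomeration method (default `"average"`).
#' @param min_cluster_size minimum programs per meta-program (default 3).
#' @param cut_height distance cut (default 0.75); ignored when `n_clusters`
#'   is given.
#' @param n_clusters optional fixed cluster count (mirrors pinning the
#'   meta-program count a priori).
#' @return a `meta_programs` object: list of meta-programs, each with
#'   `mp_id`, `member_programs`, `consensus_genes`, `n_samples`.
#' @export
cluster_meta_programs <- function(programs, linkage = "average",
                                  min_cluster_size = 3, cut_height = 0.75,
                                  n_clusters = NULL) {
  if (length(programs) < 2) {
    warning("need at least 2 programs to cluster; returning empty result")
    return(structure(list(), class = "meta_programs"))
  }
  genes <- lapply(programs, `[[`, "top_genes")
  n <- length(genes)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- 1 - jaccard_index(genes[[i]], genes[[j]])
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  # tied merge heights can come out microscopically non-monotone
  hc$height <- round(hc$height, 10)
  cl <- if (is.null(n_clusters)) stats::cutree(hc, h = cut_height)
        else stats::cutree(hc, k = min(n_clusters, n))

  mps <- list()
  # deterministic order: largest cluster first, ties by smallest member index
  sizes <- table(cl)
  cl_order <- order(-as.integer(sizes), as.integer(names(sizes)))
  for (ci in as.integer(names(sizes))[cl_order]) {
    members <- programs[cl == ci]
    if (length(members) < min_cluster_size) next
    mp_id <- sprintf("MP%02d", length(mps) + 1L)
    mp <- structure(list(mp_id = mp_id, member_programs = members,
                         consensus_genes = NULL,
                         n_samples = length(unique(vapply(members, `[[`,
                                                          character(1), "sample_id")))),
                    class = "meta_program")
    mp$consensus_genes <- consensus_gene_list(mp)
    mps[[mp_id]] <- mp
  }
  structure(mps, class = "meta_programs")
}

#' Consensus gene list of a meta-program
#'
#' Genes of the member programs ranked by (frequency across members, mean
#' loading, gene id); the top 50 complete the consensus list. When the member
#' union holds fewer than 50 genes, the full union is returned with a
#' warning.
#'
#' @param mp a `meta_program` with at least one member.
#' @param n_genes consensus length (default 50).
#' @return character vector of gene ids.
#' @export
consensus_gene_list <- function(mp, n_genes = 50) {
  members <- mp$member_programs
  stopifnot(length(members) >= 1)
  all_genes <- unlist(lapply(members, `[[`, "top_genes"))
  all_w <- unlist(lapply(members, `[[`, "weights"))
  freq <- table(all_genes)
  mean_w <- tapply(all_w, all_genes, mean)
  genes <- names(freq)
  ord <- order(-as.integer(freq), -as.numeric(mean_w[genes]), genes)
  genes <- genes[ord]
  if (length(genes) < n_genes) {
    warning("member-gene union smaller than the consensus length; returning union")
    return(genes)
  }
  genes[seq_len(n_genes)]
}

#' @export
print.meta_programs <- function(x, ...) {
  cat(sprintf("<meta_programs> %d meta-programs\n", length(x)))
  for (mp in x)
    cat(sprintf("  %s: %d member programs from %d samples; consensus: %s ...\n",
                mp$mp_id, length(mp$member_programs), mp$n_samples,
                paste(utils::head(mp$consensus_genes, 4), collapse = ", ")))
  invisible(x)
}

#' Discover meta-programs in a cohort end to end
#'
#' Convenience pipeline over the epithelial compartment: per-sample
#' log-normalization, restriction to highly variable genes, per-sample NMF
#' over the rank sweep, robustness selection, and Jaccard clustering into
#' meta-programs.
#'
#' @param cohort an `sc_cohort` (ideally already QC-filtered).
#' @param cell_type_prefix cells whose type starts with this prefix enter the
#'   analysis (default `"epi"`).
#' @param n_hvg highly variable genes retained (default 2000).
#' @param k_min,k_max NMF rank sweep (defaults 3 and 10).
#' @param params robustness selection parameters.
#' @param seed integer seed.
#' @param ... passed to [cluster_meta_programs()].
#' @return a `meta_programs` object.
#' @export
discover_meta_programs <- function(cohort, cell_type_prefix = "epi",
                                   n_hvg = 2000, k_min = 3, k_max = 10,
                                   params = robustness_params(), seed = 1L, ...) {
  stopifnot(inherits(cohort, "sc_cohort"))
  ann <- cohort$annotation
  keep <- startsWith(ann$cell_type, cell_type_prefix)
  if (!any(keep)) stop("no cells match the cell-type prefix", call. = FALSE)
  counts <- cohort$counts[, keep, drop = FALSE]
  samples <- ann$sample[keep]

  norm <- normalize_log(counts)
  hvg <- select_hvg(norm, n = n_hvg)
  norm <- norm[hvg, , drop = FALSE]

  programs <- list()
  for (s in unique(samples)) {
    sub <- norm[, samples == s, drop = FALSE]
    if (ncol(sub) < k_max) next
    programs <- c(programs,
                  fit_sample_nmf(sub, k_min = k_min, k_max = k_max,
                                 seed = seed, sample_id = s))
  }
  robust <- select_robust_programs(programs, params)
  cluster_meta_programs(robust, ...)
}

#' Export meta-programs as GMT gene sets
#'
#' @param mps a `meta_programs` object.
#' @param path output GMT path.
#' @return `path`, invisibly.
#' @export
export_meta_programs_gmt <- function(mps, path) {
  sets <- lapply(mps, `[[`, "consensus_genes")
  names(sets) <- vapply(mps, `[[`, character(1), "mp_id")
  write_gmt(sets, path, description = sprintf("n_samples=%d",
    vapply(mps, `[[`, integer(1), "n_samples")))
}
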