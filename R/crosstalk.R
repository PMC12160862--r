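# Ligand-receptor crosstalk scoring with a permutation null, interaction
# networks, and sender-ligand sample stratification.
#
# The communication score follows the CellPhoneDB convention: mean ligand
# expression in the sender cluster times the minimum over receptor subunits of
# mean subunit expression in the receiver cluster. Significance comes from an
# explicit label-permutation null with the +1 correction, so p-values are
# never exactly zero.

#' Define a ligand-receptor pair
#'
#' @param pair_id label, e.g. `"POSTN_ITGAV:ITGB5"`.
#' @param ligand_gene ligand gene id.
#' @param receptor_genes one or two receptor subunit gene ids.
#' @param annotation `"secreted"` or `"contact"`.
#' @return an `lr_pair` list.
#' @export
lr_pair <- function(pair_id, ligand_gene, receptor_genes,
                    annotation = c("secreted", "contact")) {
  stopifnot(length(receptor_genes) >= 1, length(receptor_genes) <= 2)
  annotation <- match.arg(annotation)
  structure(list(pair_id = pair_id, ligand_gene = ligand_gene,
                 receptor_genes = receptor_genes, annotation = annotation),
            class = "lr_pair")
}

#' Read a ligand-receptor pair table
#'
#' CSV with columns `pair`, `ligand`, `receptor` (subunits joined by `;`)
#' and optionally `annotation`.
#'
#' @param path CSV path.
#' @return list of [lr_pair()] objects.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pair", "ligand", "receptor") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    lr_pair(df$pair[i], df$ligand[i],
            strsplit(df$receptor[i], ";", fixed = TRUE)[[1]],
            annotation = if ("annotation" %in% names(df)) df$annotation[i]
                         else "secreted"))
}

# mean expression of `gene` over the cells indexed by `idx`; 0 if absent
.gene_row <- function(norm, gene) {
  if (!gene %in% rownames(norm)) return(NULL)
  as.numeric(norm[gene, ])
}

#' Score one ligand-receptor pair between two clusters
#'
#' Observed score: `mean(ligand | sender cells) * min over subunits of
#' mean(subunit | receiver cells)` on log-normalized expression. The null
#' permutes cluster labels over cells (`n_perm` times) and
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`. A ligand or subunit gene
#' absent from the matrix yields score 0, p 1, and `flag = "gene absent"`.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param labels cluster label per cell.
#' @param pair an [lr_pair()].
#' @param sender,receiver cluster labels (each with >= 10 cells).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `score`, `p_value`, `flag` (`NA` or `"gene absent"`),
#'   and `null_scores`.
#' @export
interaction_score <- function(norm, labels, pair, sender, receiver,
                              n_perm = 1000, seed = 1L) {
  stopifnot(inherits(pair, "lr_pair"), length(labels) == ncol(norm))
  s_idx <- which(labels == sender)
  r_idx <- which(labels == receiver)
  if (length(s_idx) < 10 || length(r_idx) < 10)
    stop("sender and receiver clusters each need at least 10 cells", call. = FALSE)

  lig <- .gene_row(norm, pair$ligand_gene)
  subs <- lapply(pair$receptor_genes, .gene_row, norm = norm)
  if (is.null(lig) || any(vapply(subs, is.null, logical(1))))
    return(list(score = 0, p_value = 1, flag = "gene absent",
                null_scores = numeric(0)))

  score_fun <- function(si, ri) {
    mean(lig[si]) * min(vapply(subs, function(v) mean(v[ri]), numeric(1)))
  }
  obs <- score_fun(s_idx, r_idx)

  n <- length(labels); ns <- length(s_idx); nr <- length(r_idx)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n, ns + nr)
      score_fun(perm[seq_len(ns)], perm[ns + seq_len(nr)])
    }, numeric(1))
  })
  p <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  list(score = obs, p_value = p, flag = NA_character_,
       null_scores = null_scores)
}

#' Score a panel of ligand-receptor pairs over cluster combinations
#'
#' @param norm genes x cells log-normalized matrix.
#' @param labels cluster label per cell.
#' @param pairs list of [lr_pair()] objects.
#' @param senders,receivers cluster labels to scan (defaults: every cluster
#'   with at least 10 cells).
#' @param n_perm,seed permutation controls.
#' @return data.frame with one row per (pair, sender, receiver) triple:
#'   `pair`, `sender`, `receiver`, `score`, `p_value`, `flag`.
#' @export
score_lr_pairs <- function(norm, labels, pairs, senders = NULL,
                           receivers = NULL, n_perm = 1000, seed = 1L) {
  big <- names(which(table(labels) >= 10))
  senders <- senders %||% big
  receivers <- receivers %||% big
  grid <- expand.grid(pair = seq_along(pairs), sender = senders,
                      receiver = receivers, stringsAsFactors = FALSE)
  grid <- grid[grid$sender != grid$receiver, , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- pairs[[grid$pair[i]]]
    res <- interaction_score(norm, labels, pr, grid$sender[i],
                             grid$receiver[i], n_perm = n_perm,
                             seed = seed + i)
    data.frame(pair = pr$pair_id, sender = grid$sender[i],
               receiver = grid$receiver[i], score = res$score,
               p_value = res$p_value, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a sender x receiver interaction network
#'
#' Per directed cluster pair: count of pairs significant at `alpha` and
#' strength (sum of their scores).
#'
#' @param results data.frame from [score_lr_pairs()].
#' @param alpha significance level (default 0.05).
#' @param clusters cluster universe (default: all clusters in `results`).
#' @return an `interaction_network`: list with `count` and `strength`
#'   matrices (senders x receivers) and `alpha`.
#' @export
build_network <- function(results, alpha = 0.05, clusters = NULL) {
  clusters <- clusters %||% sort(unique(c(results$sender, results$receiver)))
  count <- strength <- matrix(0, length(clusters), length(clusters),
                              dimnames = list(clusters, clusters))
  sig <- results[!is.na(results$p_value) & results$p_value < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    s <- sig$sender[i]; r <- sig$receiver[i]
    if (!(s %in% clusters) || !(r %in% clusters)) next
    count[s, r] <- count[s, r] + 1
    strength[s, r] <- strength[s, r] + sig$score[i]
  }
  structure(list(count = count, strength = strength, alpha = alpha),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d clusters, %d significant pairs (alpha %.3g)\n",
              nrow(x$count), sum(x$count), x$alpha))
  invisible(x)
}

#' Differential interaction network
#'
#' Edge-wise `a - b` for counts and strengths; positive entries mean more /
#' stronger communication in `net_a` (e.g. malignant) than `net_b`.
#'
#' @param net_a,net_b `interaction_network`s over the same cluster universe.
#' @return an `interaction_network_diff` with signed `count` and `strength`.
#' @export
diff_network <- function(net_a, net_b) {
  if (!identical(dimnames(net_a$count), dimnames(net_b$count)))
    stop("networks are defined over different cluster universes", call. = FALSE)
  structure(list(count = net_a$count - net_b$count,
                 strength = net_a$strength - net_b$strength),
            class = "interaction_network_diff")
}

#' Stratify samples by summed sender-cell ligand counts
#'
#' Per sample, the raw counts of the ligand gene are summed over sender-type
#' cells; samples strictly above the `q`-th percentile of these sums are
#' labeled `"high"`. A sample without sender-type cells contributes 0 with a
#' warning.
#'
#' @param cohort an `sc_cohort` (raw counts; at least 4 samples).
#' @param gene ligand gene id.
#' @param sender_type cell-type label of the sending population.
#' @param q percentile cutoff (default 75).
#' @return list with `values` (named per-sample sums) and `groups`
#'   (factor `low`/`high`).
#' @export
stratify_by_sender_ligand <- function(cohort, gene, sender_type, q = 75) {
  stopifnot(inherits(cohort, "sc_cohort"))
  ann <- cohort$annotation
  samples <- unique(ann$sample)
  if (length(samples) < 4) stop("need at least 4 samples", call. = FALSE)
  if (!gene %in% rownames(cohort$counts))
    stop("ligand gene absent from the count matrix", call. = FALSE)
  gv <- as.numeric(cohort$counts[gene, ])
  values <- vapply(samples, function(s) {
    idx <- ann$sample == s & ann$cell_type == sender_type
    if (!any(idx)) {
      warning(sprintf("sample %s has no %s cells; ligand sum set to 0",
                      s, sender_type))
      return(0)
    }
    sum(gv[idx])
  }, numeric(1))
  names(values) <- samples
  list(values = values,
       groups = stratify_by_score(values, rule = "percentile", q = q))
}
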