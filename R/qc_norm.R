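# Cell and sample quality control, depth normalization, HVG selection.

# Hemoglobin genes are matched from an explicit list rather than a bare "HB"
# prefix, which would sweep in HBEGF, HBS1L and similar false positives.
HB_GENES <- c("HBA1", "HBA2", "HBB", "HBD", "HBE1", "HBG1", "HBG2",
              "HBM", "HBQ1", "HBZ")

#' Quality-control thresholds
#'
#' Defaults follow the conventional droplet scRNA-seq recipe for tumor
#' cohorts: 300-8,000 detected genes, under 40,000 UMI, under 10 percent
#' mitochondrial and 1 percent hemoglobin content, and whole-sample exclusion
#' below 500 surviving cells.
#'
#' @param min_genes,max_genes detected-gene bounds (a gene counts as detected
#'   at count >= 1).
#' @param max_umi maximum total UMI per cell.
#' @param max_mito_pct maximum mitochondrial percentage (genes prefixed `MT-`).
#' @param max_hb_pct maximum hemoglobin percentage (explicit gene list).
#' @param min_cells_per_sample samples with fewer surviving cells are dropped.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 300, max_genes = 8000, max_umi = 40000,
                          max_mito_pct = 10, max_hb_pct = 1,
                          min_cells_per_sample = 500) {
  stopifnot(min_genes < max_genes,
            max_mito_pct >= 0, max_mito_pct <= 100,
            max_hb_pct >= 0, max_hb_pct <= 100)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umi = max_umi, max_mito_pct = max_mito_pct,
                 max_hb_pct = max_hb_pct,
                 min_cells_per_sample = min_cells_per_sample),
            class = "qc_thresholds")
}

#' Filter cells and samples on quality metrics
#'
#' Cells violating any per-cell rule are removed first; samples whose
#' surviving cell count falls below `min_cells_per_sample` are then removed
#' entirely. The report accounts for every input cell exactly once.
#'
#' @param cohort an `sc_cohort` (counts + annotation with a `sample` column).
#' @param thr a [qc_thresholds()].
#' @return the filtered cohort, with a `qc_report` attached as
#'   `cohort$qc_report`.
#' @export
qc_filter <- function(cohort, thr = qc_thresholds()) {
  stopifnot(inherits(cohort, "sc_cohort"), inherits(thr, "qc_thresholds"))
  counts <- cohort$counts
  ann <- cohort$annotation
  stopifnot(!is.null(rownames(counts)), "sample" %in% names(ann))

  umi <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts >= 1)
  mt <- startsWith(rownames(counts), "MT-")
  hb <- rownames(counts) %in% HB_GENES
  mito_pct <- ifelse(umi > 0, 100 * Matrix::colSums(counts[mt, , drop = FALSE]) / umi, 0)
  hb_pct <- ifelse(umi > 0, 100 * Matrix::colSums(counts[hb, , drop = FALSE]) / umi, 0)

  fail_low_genes <- detected < thr$min_genes
  fail_high_genes <- !fail_low_genes & detected > thr$max_genes
  fail_umi <- !(fail_low_genes | fail_high_genes) & umi >= thr$max_umi
  fail_mito <- !(fail_low_genes | fail_high_genes | fail_umi) &
    mito_pct >= thr$max_mito_pct
  fail_hb <- !(fail_low_genes | fail_high_genes | fail_umi | fail_mito) &
    hb_pct >= thr$max_hb_pct
  keep <- !(fail_low_genes | fail_high_genes | fail_umi | fail_mito | fail_hb)

  surv_per_sample <- table(ann$sample[keep])
  small <- names(surv_per_sample)[surv_per_sample < thr$min_cells_per_sample]
  small <- c(small, setdiff(unique(ann$sample), names(surv_per_sample)))
  fail_sample <- keep & ann$sample %in% small
  keep <- keep & !fail_sample

  if (!any(keep)) stop("no cells survive QC", call. = FALSE)

  report <- structure(list(
    cells_in = ncol(counts),
    cells_removed_by_rule = c(low_genes = sum(fail_low_genes),
                              high_genes = sum(fail_high_genes),
                              high_umi = sum(fail_umi),
                              high_mito = sum(fail_mito),
                              high_hb = sum(fail_hb),
                              small_sample = sum(fail_sample)),
    samples_dropped = sort(unique(small)),
    cells_out = sum(keep)), class = "qc_report")

  out <- cohort
  out$counts <- counts[, keep, drop = FALSE]
  out$annotation <- ann[keep, , drop = FALSE]
  rownames(out$annotation) <- NULL
  if (!is.null(out$truth)) {
    out$truth$malignant <- out$truth$malignant[keep]
    if (!is.null(out$truth$program_on))
      out$truth$program_on <- out$truth$program_on[keep, , drop = FALSE]
    if (!is.null(out$truth$depth)) out$truth$depth <- out$truth$depth[keep]
  }
  out$qc_report <- report
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d cells in -> %d out\n", x$cells_in, x$cells_out))
  for (r in names(x$cells_removed_by_rule))
    cat(sprintf("  removed by %-12s %d\n", r, x$cells_removed_by_rule[[r]]))
  if (length(x$samples_dropped))
    cat("  samples dropped:", paste(x$samples_dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Depth-normalize and log-transform counts
#'
#' Each cell is scaled to a common depth of `scale` total counts, then
#' `log1p`-transformed — the standard log-normalization used before module
#' scoring, NMF and CNV profiling.
#'
#' @param counts genes x cells non-negative count matrix (sparse or dense),
#'   or an `sc_cohort`.
#' @param scale target depth per cell (default 10,000).
#' @return a genes x cells matrix of log-normalized expression (dgCMatrix).
#' @export
normalize_log <- function(counts, scale = 1e4) {
  if (inherits(counts, "sc_cohort")) counts <- counts$counts
  counts <- as_dgc(counts)
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) stop("all-zero cell encountered", call. = FALSE)
  norm <- counts %*% Matrix::Diagonal(x = scale / depth)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  as_dgc(norm)
}

#' Select highly variable genes by mean-adjusted dispersion
#'
#' Dispersion (variance / mean) is computed on the un-logged normalized
#' scale, where overdispersion and bimodal expression inflate the ratio, and
#' the pervasive mean-dispersion trend is removed before ranking. The
#' default removes it continuously — a loess fit of log dispersion on log
#' mean, ranking genes by their residual — which is robust where variable
#' genes cluster at similar mean expression. The `"bins"` method instead
#' z-scores dispersion within `n_bins` equal-occupancy mean bins (the
#' classic binned-dispersion flavor); it is retained for comparison but can
#' demote genuinely variable genes when they crowd a bin. Ties are broken by
#' gene id so the selection is deterministic, and constant genes are never
#' selected.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param n number of genes to select (default 2000).
#' @param method `"trend"` (loess residual, default) or `"bins"`.
#' @param n_bins number of mean-expression bins for `method = "bins"`.
#' @return character vector of selected gene ids (at most `n`).
#' @export
select_hvg <- function(norm, n = 2000, method = c("trend", "bins"),
                       n_bins = 20) {
  stopifnot(n >= 1)
  method <- match.arg(method)
  e <- expm1(norm)
  mu <- Matrix::rowMeans(e)
  v <- Matrix::rowMeans(e^2) - mu^2
  v <- v * ncol(norm) / max(1, ncol(norm) - 1)
  v[v < 1e-10 * pmax(mu^2, 1)] <- 0  # numerically constant genes
  variable <- v > 0 & mu > 0
  disp <- ifelse(variable, v / pmax(mu, 1e-12), NA_real_)

  z <- rep(NA_real_, length(mu))
  if (method == "trend") {
    idx <- which(variable)
    if (length(idx) >= 10) {
      ld <- log(disp[idx]); lm_ <- log(mu[idx])
      fit <- stats::loess(ld ~ lm_, span = 0.5,
                          family = "symmetric", degree = 1)
      z[idx] <- ld - stats::predict(fit)
    } else {
      z[idx] <- disp[idx]
    }
  } else {
    bins <- cut(mu, breaks = unique(stats::quantile(mu[variable],
                                                    probs = seq(0, 1, length.out = n_bins + 1),
                                                    type = 7)),
                include.lowest = TRUE)
    for (b in levels(bins)) {
      idx <- which(bins == b & variable)
      if (!length(idx)) next
      m <- stats::median(disp[idx])
      s <- stats::mad(disp[idx])
      if (is.na(s) || s == 0) s <- stats::sd(disp[idx])
      z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
    }
  }
  ord <- order(-z, rownames(norm), na.last = TRUE)
  ord <- ord[!is.na(z[ord])]
  rownames(norm)[utils::head(ord, n)]
}
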