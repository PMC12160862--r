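# Simplified copy-number-variation profiling along genome order and the
# reference-percentile malignancy classifier.
#
# The profile is the moving-average core of inferCNV-style estimation:
# per-gene relative log-expression against the reference-cell mean, clipped,
# smoothed by a centered moving average within each chromosome, and re-centered
# per cell by its median. A cell's CNV score is the mean squared smoothed
# deviation; cells above the 90th percentile of reference-cell scores are
# called malignant.

#' CNV profiling parameters
#'
#' @param window odd moving-average width in genes (default 101).
#' @param clip absolute bound on relative log-expression before smoothing
#'   (default 3).
#' @param reference_label cell-type label of the diploid reference population
#'   (default `"reference"`).
#' @return a `cnv_params` list.
#' @export
cnv_params <- function(window = 101, clip = 3, reference_label = "reference") {
  window <- assert_count(window, "window", 1)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  assert_scalar_num(clip, "clip", lower = 0)
  structure(list(window = window, clip = clip,
                 reference_label = reference_label),
            class = "cnv_params")
}

# centered moving average with shrinking windows at chromosome edges
running_mean <- function(x, window) {
  if (window == 1 || length(x) == 1) return(x)
  half <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Infer per-cell CNV profiles along genome order
#'
#' For every gene: relative log-expression = cell value minus reference-cell
#' mean, clipped to `+/- clip`; smoothing by a centered moving average of
#' width `window` strictly within each chromosome (windows shrink at
#' chromosome edges and never cross boundaries); finally each cell's profile
#' is re-centered by its median.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param genome genome map (`gene`, `chromosome`, `rank`) covering the
#'   analyzed genes.
#' @param reference logical/character/integer index of reference cells
#'   (at least 20), or an annotation data.frame with `cell_type` matching
#'   `params$reference_label`.
#' @param params a [cnv_params()].
#' @return a `cnv_profiles` object: list with `profile` (genes x cells
#'   smoothed deviations, genome order), `genome`, `reference` (logical).
#' @export
infer_cnv_profile <- function(norm, genome, reference, params = cnv_params()) {
  if (is.data.frame(reference))
    reference <- reference$cell_type == params$reference_label
  if (is.character(reference)) reference <- colnames(norm) %in% reference
  if (is.numeric(reference))
    reference <- seq_len(ncol(norm)) %in% reference
  if (sum(reference) < 20)
    stop("insufficient reference: need at least 20 reference cells", call. = FALSE)

  genome <- genome[genome$gene %in% rownames(norm), , drop = FALSE]
  genome <- genome[order(genome$rank), , drop = FALSE]
  X <- as_dense(norm[genome$gene, , drop = FALSE])

  ref_mean <- rowMeans(X[, reference, drop = FALSE])
  R <- X - ref_mean
  R[R > params$clip] <- params$clip
  R[R < -params$clip] <- -params$clip

  for (chr in unique(genome$chromosome)) {
    idx <- which(genome$chromosome == chr)
    R[idx, ] <- apply(R[idx, , drop = FALSE], 2, running_mean,
                      window = params$window)
  }
  med <- apply(R, 2, stats::median)
  R <- sweep(R, 2, med, "-")

  structure(list(profile = R, genome = genome,
                 reference = reference, params = params),
            class = "cnv_profiles")
}

#' CNV score: mean squared smoothed deviation
#'
#' @param profiles a `cnv_profiles` object, or a genes x cells matrix of
#'   smoothed deviations.
#' @return named numeric vector, one non-negative score per cell.
#' @export
cnv_score <- function(profiles) {
  R <- if (inherits(profiles, "cnv_profiles")) profiles$profile else profiles
  colMeans(R^2)
}

#' Classify cells as malignant by a reference-percentile threshold
#'
#' The threshold is the empirical 90th percentile (type-7, linearly
#' interpolated) of the reference-cell scores; cells strictly above it are
#' called malignant. Applied to the reference cells themselves this flags
#' the cells above their own empirical 90th percentile (about 10 percent).
#'
#' @param scores per-cell CNV scores.
#' @param ref_scores reference-cell scores (at least 20).
#' @param probs percentile for the threshold (default 0.9).
#' @return logical vector (`TRUE` = malignant), with the threshold attached
#'   as attribute `"threshold"`.
#' @export
classify_malignant <- function(scores, ref_scores, probs = 0.9) {
  if (length(ref_scores) < 20)
    stop("need at least 20 reference scores", call. = FALSE)
  thr <- stats::quantile(ref_scores, probs, type = 7, names = FALSE)
  structure(scores > thr, threshold = thr)
}

#' @export
print.cnv_profiles <- function(x, ...) {
  cat(sprintf("<cnv_profiles> %d genes x %d cells (%d reference), window %d\n",
              nrow(x$profile), ncol(x$profile), sum(x$reference),
              x$params$window))
  invisible(x)
}

#' Score and classify a cohort's epithelial cells
#'
#' Convenience wrapper: log-normalizes, profiles all cells against the
#' reference population, scores them, and classifies non-reference cells
#' against the reference 90th-percentile threshold.
#'
#' @param cohort an `sc_cohort` whose annotation contains reference cells.
#' @param params a [cnv_params()].
#' @return data.frame with `cell`, `cnv_score`, `reference`, `malignant`.
#' @export
classify_cohort_cnv <- function(cohort, params = cnv_params()) {
  stopifnot(inherits(cohort, "sc_cohort"), !is.null(cohort$genome))
  norm <- normalize_log(cohort$counts)
  prof <- infer_cnv_profile(norm, cohort$genome, cohort$annotation, params)
  sc <- cnv_score(prof)
  call <- classify_malignant(sc, sc[prof$reference])
  data.frame(cell = colnames(cohort$counts), cnv_score = sc,
             reference = prof$reference, malignant = as.logical(call),
             row.names = NULL, stringsAsFactors = FALSE)
}
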