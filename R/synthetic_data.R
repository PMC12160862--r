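# Synthetic multi-sample single-cell cohorts with planted ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: multi-sample cohorts with shared expression programs active in a
# fraction of epithelial cells, copy-number-altered malignant cells alongside
# diploid reference cells, a fibroblast subtype over-expressing a secreted
# ligand whose receptor is elevated in an epithelial subtype, and survival
# outcomes whose hazard is linear (on the log scale) in a covariate.

#' Specify a planted expression program
#'
#' A program is a fixed 50-gene module whose genes are multiplicatively
#' up-shifted in a random fraction of cells ("on" cells) of the samples in
#' which the program is active.
#'
#' @param gene_ids integer indices of the program's genes (conventionally 50).
#' @param samples_active integer indices of samples in which the program fires.
#' @param fraction_cells_on proportion of eligible cells that are "on", in (0, 1].
#' @param effect multiplicative mean shift (>= 1) applied to program genes in
#'   "on" cells.
#' @param cell_types optional character vector restricting the program to
#'   cells of these types; `NULL` means all cells of an active sample.
#' @return a `program_spec` list.
#' @export
program_spec <- function(gene_ids, samples_active, fraction_cells_on = 0.2,
                         effect = 4, cell_types = NULL) {
  gene_ids <- as.integer(gene_ids)
  stopifnot(length(gene_ids) >= 1, !anyDuplicated(gene_ids), all(gene_ids >= 1))
  assert_scalar_num(fraction_cells_on, "fraction_cells_on", lower = 1e-12, upper = 1)
  assert_scalar_num(effect, "effect", lower = 1)
  structure(list(gene_ids = gene_ids,
                 samples_active = as.integer(samples_active),
                 fraction_cells_on = fraction_cells_on,
                 effect = effect,
                 cell_types = cell_types),
            class = "program_spec")
}

#' Specify a planted copy-number segment
#'
#' Coordinates are 0-based half-open gene ranks in genome order (CNV smoothing
#' operates on gene order, so base pairs are unnecessary).
#'
#' @param chromosome chromosome label, e.g. `"chr2"`.
#' @param start_gene_rank,end_gene_rank 0-based half-open genome-order ranks.
#' @param fold multiplicative copy factor (> 0); 1 is a no-op.
#' @return a `cnv_segment_spec` list.
#' @export
cnv_segment_spec <- function(chromosome, start_gene_rank, end_gene_rank, fold = 2) {
  assert_scalar_num(fold, "fold", lower = 1e-12)
  stopifnot(start_gene_rank >= 0, end_gene_rank > start_gene_rank)
  structure(list(chromosome = chromosome,
                 start_gene_rank = as.integer(start_gene_rank),
                 end_gene_rank = as.integer(end_gene_rank),
                 fold = fold),
            class = "cnv_segment_spec")
}

#' Specify a planted ligand-receptor axis
#'
#' Emulates a secreted-ligand axis (POSTN binding the integrin complex
#' ITGAV/ITGB5): the ligand is elevated in sender-type cells of malignant
#' samples and the receptor subunits in receiver-type cells.
#'
#' @param ligand_gene gene id of the ligand.
#' @param receptor_genes one or two gene ids (receptor complex subunits).
#' @param sender_type,receiver_type distinct cell-type labels.
#' @param effect multiplicative shift (>= 1).
#' @return an `lr_axis_spec` list.
#' @export
lr_axis_spec <- function(ligand_gene = "POSTN",
                         receptor_genes = c("ITGAV", "ITGB5"),
                         sender_type = "fib_ECM", receiver_type = "epi_EMT",
                         effect = 4) {
  stopifnot(length(receptor_genes) %in% 1:2)
  if (identical(sender_type, receiver_type))
    stop("sender and receiver cell types must differ", call. = FALSE)
  assert_scalar_num(effect, "effect", lower = 1)
  structure(list(ligand_gene = ligand_gene, receptor_genes = receptor_genes,
                 sender_type = sender_type, receiver_type = receiver_type,
                 effect = effect),
            class = "lr_axis_spec")
}

#' Configure a synthetic cohort
#'
#' Defaults describe the cohort used throughout the package's own recovery
#' tests: negative-binomial counts with log-normal per-cell depth factors,
#' a small panel of mitochondrial (`MT-`) and hemoglobin (`HB*`) genes so
#' quality-control filters are exercised, 22 pseudo-chromosomes assigned in
#' gene-index order, and a mostly malignant sample mix echoing a tumor-heavy
#' clinical cohort.
#'
#' @param n_samples number of samples.
#' @param cells_per_sample cells per sample.
#' @param n_genes total genes (including the MT/HB panel appended at the end).
#' @param base_mean expected counts per gene per cell for background genes.
#' @param gene_mean_sd log-normal spread of per-gene baseline means around
#'   `base_mean` (default 0.5), mimicking the skewed mean-expression
#'   distribution of real transcriptomes; 0 gives a flat baseline.
#' @param dispersion negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2`.
#' @param programs list of [program_spec()] objects. Gene sets of distinct
#'   programs must be disjoint unless `allow_program_overlap = TRUE`.
#' @param cnv_segments list of [cnv_segment_spec()] objects planted into
#'   malignant epithelial cells.
#' @param lr_axis an [lr_axis_spec()] or `NULL`.
#' @param cell_type_props named proportions of cell types per sample; names
#'   starting with `"epi"` are treated as epithelial, `"fib"` as fibroblast,
#'   and `"reference"` as the diploid reference population.
#' @param malignant_sample_fraction fraction of samples labeled malignant.
#' @param malignant_cell_fraction fraction of epithelial cells of malignant
#'   samples that carry the planted CNV segments.
#' @param depth_sd standard deviation of the log-normal per-cell depth factor.
#' @param mito_fraction,hb_fraction expected fractions of counts landing on
#'   the MT-/HB gene panels.
#' @param allow_program_overlap permit overlapping program gene sets.
#' @param seed integer seed; fully determines the generated cohort.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 6, cells_per_sample = 500,
                             n_genes = 1000, base_mean = 0.5,
                             gene_mean_sd = 0.5, dispersion = 0.5,
                             programs = list(), cnv_segments = list(),
                             lr_axis = NULL,
                             cell_type_props = c(epi_EMT = 0.15, epi_classical = 0.25,
                                                 fib_ECM = 0.15, fib_other = 0.15,
                                                 reference = 0.30),
                             malignant_sample_fraction = 0.8,
                             malignant_cell_fraction = 0.3,
                             depth_sd = 0.3,
                             mito_fraction = 0.05, hb_fraction = 0.003,
                             allow_program_overlap = FALSE,
                             seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples", 1)
  cells_per_sample <- assert_count(cells_per_sample, "cells_per_sample", 1)
  n_genes <- assert_count(n_genes, "n_genes", 20)
  assert_scalar_num(base_mean, "base_mean", lower = 1e-12)
  assert_scalar_num(dispersion, "dispersion", lower = 1e-12)
  stopifnot(abs(sum(cell_type_props) - 1) < 1e-8)
  prog_genes <- unlist(lapply(programs, `[[`, "gene_ids"))
  if (length(prog_genes) && max(prog_genes) > n_genes)
    stop("n_genes must cover the union of planted program genes", call. = FALSE)
  if (!allow_program_overlap && anyDuplicated(prog_genes))
    stop("program gene sets overlap; set allow_program_overlap = TRUE if intended",
         call. = FALSE)
  structure(list(n_samples = n_samples, cells_per_sample = cells_per_sample,
                 n_genes = n_genes, base_mean = base_mean,
                 gene_mean_sd = gene_mean_sd,
                 dispersion = dispersion, programs = programs,
                 cnv_segments = cnv_segments, lr_axis = lr_axis,
                 cell_type_props = cell_type_props,
                 malignant_sample_fraction = malignant_sample_fraction,
                 malignant_cell_fraction = malignant_cell_fraction,
                 depth_sd = depth_sd, mito_fraction = mito_fraction,
                 hb_fraction = hb_fraction,
                 allow_program_overlap = allow_program_overlap,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Assign genes to pseudo-chromosomes in index order
#'
#' Genes are split into `n_chromosomes` contiguous, near-equal blocks in their
#' given order; ranks are 0-based genome-order positions.
#'
#' @param genes character vector of gene ids (in genome order).
#' @param n_chromosomes number of pseudo-chromosomes (default 22).
#' @return data.frame with columns `gene`, `chromosome`, `rank`.
#' @export
make_genome_map <- function(genes, n_chromosomes = 22) {
  n <- length(genes)
  n_chromosomes <- min(n_chromosomes, n)
  sizes <- rep(n %/% n_chromosomes, n_chromosomes)
  extra <- n %% n_chromosomes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  data.frame(gene = genes,
             chromosome = rep(paste0("chr", seq_len(n_chromosomes)), sizes),
             rank = seq_len(n) - 1L,
             stringsAsFactors = FALSE)
}

new_cohort <- function(counts, annotation, genome = NULL, truth = NULL,
                       config = NULL) {
  structure(list(counts = counts, annotation = annotation, genome = genome,
                 truth = truth, config = config),
            class = "sc_cohort")
}

#' @export
print.sc_cohort <- function(x, ...) {
  cat(sprintf("<sc_cohort> %d genes x %d cells, %d samples\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$annotation$sample))))
  tt <- table(x$annotation$cell_type)
  cat("  cell types:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: %d planted programs, %d malignant cells\n",
                length(x$truth$program_genes), sum(x$truth$malignant)))
  invisible(x)
}

#' Generate a synthetic single-cell cohort
#'
#' Counts are drawn gene-wise from a negative binomial whose mean is
#' `base_mean x program effects x CNV folds x ligand-receptor effects x
#' per-cell depth factor`. The returned object carries the raw counts, a cell
#' annotation (sample, cell type, condition), a genome map and the full
#' ground truth (program on/off states, malignant flags, planted gene sets).
#'
#' @param cfg a [synthetic_config()].
#' @return an `sc_cohort` list with elements `counts` (sparse genes x cells),
#'   `annotation`, `genome`, `truth`, `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n_mt <- 10L; n_hb <- 3L
    n_bg <- cfg$n_genes - n_mt - n_hb
    genes <- c(sprintf("G%05d", seq_len(n_bg)),
               c("HBB", "HBA1", "HBA2"),
               sprintf("MT-%02d", seq_len(n_mt)))
    # reserve names for the ligand-receptor axis among background genes
    if (!is.null(cfg$lr_axis)) {
      lr_names <- c(cfg$lr_axis$ligand_gene, cfg$lr_axis$receptor_genes)
      prog_genes <- unlist(lapply(cfg$programs, `[[`, "gene_ids"))
      free <- setdiff(seq_len(n_bg), prog_genes)
      if (length(free) < length(lr_names))
        stop("not enough free genes to place the ligand-receptor axis", call. = FALSE)
      genes[free[seq_along(lr_names)]] <- lr_names
    }
    genome <- make_genome_map(genes)

    n_cells <- cfg$n_samples * cfg$cells_per_sample
    sample_id <- rep(sprintf("S%02d", seq_len(cfg$n_samples)),
                     each = cfg$cells_per_sample)
    n_malig <- round(cfg$malignant_sample_fraction * cfg$n_samples)
    sample_condition <- rep(c("malignant", "non-malignant"),
                            c(n_malig, cfg$n_samples - n_malig))
    names(sample_condition) <- sprintf("S%02d", seq_len(cfg$n_samples))
    condition <- sample_condition[sample_id]

    cell_type <- sample(names(cfg$cell_type_props), n_cells, replace = TRUE,
                        prob = cfg$cell_type_props)
    is_epi <- startsWith(cell_type, "epi")

    # gene-level base means: log-normal spread around base_mean (mean
    # preserved); MT/HB panels carry configured fractions of total expression
    sdl <- cfg$gene_mean_sd %||% 0
    mu_gene <- cfg$base_mean * exp(stats::rnorm(cfg$n_genes, 0, sdl) - sdl^2 / 2)
    total_bg <- n_bg * cfg$base_mean
    mu_gene[genes %in% c("HBB", "HBA1", "HBA2")] <-
      cfg$hb_fraction * total_bg / n_hb
    mu_gene[startsWith(genes, "MT-")] <- cfg$mito_fraction * total_bg / n_mt

    mu <- matrix(mu_gene, nrow = cfg$n_genes, ncol = n_cells)

    # planted programs -----------------------------------------------------
    program_on <- matrix(FALSE, n_cells, length(cfg$programs))
    if (length(cfg$programs))
      colnames(program_on) <- sprintf("P%02d", seq_along(cfg$programs))
    for (j in seq_along(cfg$programs)) {
      p <- cfg$programs[[j]]
      eligible <- sample_id %in% sprintf("S%02d", p$samples_active)
      if (!is.null(p$cell_types)) eligible <- eligible & cell_type %in% p$cell_types
      on <- eligible & (stats::runif(n_cells) < p$fraction_cells_on)
      program_on[, j] <- on
      if (any(on) && p$effect != 1)
        mu[p$gene_ids, on] <- mu[p$gene_ids, on] * p$effect
    }

    # planted CNV segments into malignant epithelial cells ------------------
    malignant <- rep(FALSE, n_cells)
    active_segments <- Filter(function(s) s$fold != 1, cfg$cnv_segments)
    if (length(active_segments)) {
      pool <- is_epi & condition == "malignant"
      malignant <- pool & (stats::runif(n_cells) < cfg$malignant_cell_fraction)
      for (s in active_segments) {
        idx <- seg_gene_index(s, genome)
        mu[idx, malignant] <- mu[idx, malignant] * s$fold
      }
    }

    # planted ligand-receptor axis -----------------------------------------
    if (!is.null(cfg$lr_axis) && cfg$lr_axis$effect != 1) {
      ax <- cfg$lr_axis
      send <- cell_type == ax$sender_type & condition == "malignant"
      recv <- cell_type == ax$receiver_type
      if (!any(cell_type == ax$sender_type) || !any(recv))
        stop("ligand-receptor axis refers to a cell type absent from the cohort",
             call. = FALSE)
      mu[match(ax$ligand_gene, genes), send] <-
        mu[match(ax$ligand_gene, genes), send] * ax$effect
      mu[match(ax$receptor_genes, genes), recv] <-
        mu[match(ax$receptor_genes, genes), recv] * ax$effect
    }

    depth <- exp(stats::rnorm(n_cells, 0, cfg$depth_sd))
    mu <- sweep(mu, 2, depth, "*")

    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes)
    dimnames(counts) <- list(genes, sprintf("%s_C%04d", sample_id, seq_len(n_cells)))
    counts <- as_dgc(counts)

    annotation <- data.frame(cell = colnames(counts), sample = sample_id,
                             cell_type = cell_type, condition = condition,
                             stringsAsFactors = FALSE)
    truth <- list(
      program_on = program_on,
      program_genes = lapply(cfg$programs, function(p) genes[p$gene_ids]),
      malignant = malignant,
      sample_condition = as.list(sample_condition),
      depth = depth)
    if (length(cfg$programs))
      names(truth$program_genes) <- colnames(program_on)
    new_cohort(counts, annotation, genome = genome, truth = truth, config = cfg)
  })
}

# genome-map row indices (1-based, matrix order) covered by a segment
seg_gene_index <- function(seg, genome) {
  on_chr <- genome$chromosome == seg$chromosome
  if (!any(on_chr))
    stop("segment chromosome not in genome map: ", seg$chromosome, call. = FALSE)
  rng <- range(genome$rank[on_chr])
  if (seg$start_gene_rank < rng[1] || seg$end_gene_rank > rng[2] + 1L)
    stop("segment gene ranks fall outside its chromosome", call. = FALSE)
  which(genome$rank >= seg$start_gene_rank & genome$rank < seg$end_gene_rank)
}

#' Plant copy-number segments into an existing count matrix
#'
#' Counts of segment genes in the affected cells are rescaled by the segment
#' fold and the counting noise re-drawn (Poisson around the rescaled value),
#' so group mean ratios recover the fold. `fold = 1` is a strict no-op.
#'
#' @param counts genes x cells count matrix with gene names matching `genome`.
#' @param genome genome map from [make_genome_map()].
#' @param segments list of [cnv_segment_spec()].
#' @param affected_cells character cell ids or logical/integer index of
#'   affected cells.
#' @param seed optional seed for the noise re-draw.
#' @return the modified count matrix (same class as input).
#' @export
plant_cnv_segments <- function(counts, genome, segments, affected_cells,
                               seed = NULL) {
  if (is.character(affected_cells))
    affected_cells <- match(affected_cells, colnames(counts))
  if (is.logical(affected_cells)) affected_cells <- which(affected_cells)
  if (anyNA(affected_cells)) stop("unknown affected cells", call. = FALSE)
  if (!length(segments)) return(counts)
  with_seed(seed, {
    for (s in segments) {
      if (s$fold == 1) next
      idx <- seg_gene_index(s, genome)
      block <- as_dense(counts[idx, affected_cells, drop = FALSE])
      counts[idx, affected_cells] <-
        stats::rpois(length(block), lambda = s$fold * block)
    }
    counts
  })
}

#' Plant a ligand-receptor axis into an existing cohort
#'
#' Elevates the ligand in sender-type cells of malignant samples and every
#' receptor subunit in receiver-type cells (all samples), rescaling counts by
#' `effect` with Poisson noise re-drawn. `effect = 1` is a strict no-op.
#'
#' @param cohort an `sc_cohort`.
#' @param axis an [lr_axis_spec()]; its genes must exist in the matrix.
#' @param seed optional seed.
#' @return the modified cohort.
#' @export
plant_lr_axis <- function(cohort, axis, seed = NULL) {
  stopifnot(inherits(cohort, "sc_cohort"), inherits(axis, "lr_axis_spec"))
  ann <- cohort$annotation
  if (!any(ann$cell_type == axis$sender_type) ||
      !any(ann$cell_type == axis$receiver_type))
    stop("sender or receiver cell type absent from annotation", call. = FALSE)
  lr_genes <- c(axis$ligand_gene, axis$receptor_genes)
  if (!all(lr_genes %in% rownames(cohort$counts)))
    stop("ligand/receptor genes absent from the count matrix", call. = FALSE)
  if (axis$effect == 1) return(cohort)
  with_seed(seed, {
    send <- ann$cell_type == axis$sender_type & ann$condition == "malignant"
    recv <- ann$cell_type == axis$receiver_type
    bump <- function(gene, cells) {
      v <- as.numeric(cohort$counts[gene, cells])
      cohort$counts[gene, cells] <<- stats::rpois(length(v), axis$effect * v)
    }
    bump(axis$ligand_gene, send)
    for (g in axis$receptor_genes) bump(g, recv)
    cohort
  })
}

#' Generate survival records with a log-linear hazard
#'
#' Event times are exponential with rate `baseline_rate * exp(beta *
#' covariate)`; censoring times are independent exponentials calibrated so
#' that roughly `censor_rate` of subjects are censored (`censor_rate = 0`
#' yields no censoring at all).
#'
#' @param covariate numeric per-subject score.
#' @param beta log-hazard coefficient.
#' @param censor_rate target censoring proportion in `[0, 1)`.
#' @param seed integer seed.
#' @param baseline_rate baseline hazard rate.
#' @return data.frame with columns `subject`, `time`, `event` (0/1),
#'   `covariate`.
#' @export
generate_survival <- function(covariate, beta, censor_rate = 0.2, seed = 1L,
                              baseline_rate = 0.1) {
  stopifnot(all(is.finite(covariate)))
  assert_scalar_num(censor_rate, "censor_rate", lower = 0, upper = 1 - 1e-9)
  n <- length(covariate)
  with_seed(seed, {
    rate <- baseline_rate * exp(beta * covariate)
    t_event <- stats::rexp(n, rate)
    if (censor_rate > 0) {
      # exponential race: P(censor) = rc / (rc + rate) per subject; calibrate
      # rc against the mean event rate
      rc <- mean(rate) * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, rc)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(subject = sprintf("P%04d", seq_len(n)),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               covariate = covariate)
  })
}
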