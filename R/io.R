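#' Write a cohort to disk as MTX + sidecars
#'
#' Writes the sparse count matrix in MatrixMarket format together with
#' `features.tsv` (gene ids), `barcodes.tsv` (cell ids), the cell annotation
#' as CSV, the gene genome map as CSV, and the ground truth (when present) as
#' JSON. The layout mirrors the conventional CellRanger-style triplet so that
#' standard single-cell readers can ingest the matrix.
#'
#' @param cohort an `sc_cohort` object from [generate_cohort()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(cohort$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cohort$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(cohort$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$genome, file.path(dir, "genome_map.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    truth$program_on <- NULL  # cell x program matrix: too bulky for JSON
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `annotation.csv` and optionally `genome_map.csv`.
#' @return an `sc_cohort` (without ground truth).
#' @export
read_cohort <- function(dir) {
  counts <- as_dgc(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  annotation <- utils::read.csv(file.path(dir, "annotation.csv"),
                                stringsAsFactors = FALSE)
  genome <- NULL
  gm <- file.path(dir, "genome_map.csv")
  if (file.exists(gm)) genome <- utils::read.csv(gm, stringsAsFactors = FALSE)
  new_cohort(counts, annotation, genome = genome, truth = NULL)
}

#' Read gene sets from a GMT file
#'
#' GMT is the MSigDB tab-separated format: one gene set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line: ", substr(l, 1, 60), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column; recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(name, genes, desc)
    paste(c(name, desc, genes), collapse = "\t"),
    names(sets), sets, description)
  writeLines(lines, path)
  invisible(path)
}
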