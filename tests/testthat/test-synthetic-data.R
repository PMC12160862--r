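test_that("generated cohorts have consistent dimensions and annotations", {
  cfg <- synthetic_config(n_samples = 6, cells_per_sample = 300,
                          n_genes = 200, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(ncol(co$counts), 1800)
  expect_equal(nrow(co$counts), 200)
  expect_equal(nrow(co$annotation), 1800)
  expect_identical(co$annotation$cell, colnames(co$counts))
  expect_setequal(unique(co$annotation$condition),
                  c("malignant", "non-malignant"))
  # genome map covers every gene in matrix order
  expect_identical(co$genome$gene, rownames(co$counts))
  expect_equal(length(unique(co$genome$chromosome)), 22)
})

test_that("the same config and seed give byte-identical cohorts", {
  cfg <- synthetic_config(n_samples = 2, cells_per_sample = 100,
                          n_genes = 150, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
})

test_that("unit program effects leave program genes indistinguishable", {
  # with effect = 1 the on/off split must carry no signal: per-replicate
  # t-test p-values on the program-gene pseudo-mean are uniform
  pvals <- vapply(1:40, function(i) {
    cfg <- synthetic_config(n_samples = 2, cells_per_sample = 150,
                            n_genes = 120,
                            programs = list(program_spec(1:50, 1:2,
                                                         fraction_cells_on = 0.5,
                                                         effect = 1)),
                            seed = 500 + i)
    co <- generate_cohort(cfg)
    on <- co$truth$program_on[, 1]
    m <- Matrix::colMeans(co$counts[1:50, ])
    stats::t.test(m[on], m[!on])$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
  expect_gt(mean(pvals), 0.3)
})

test_that("overlapping programs are rejected unless explicitly allowed", {
  progs <- list(program_spec(1:50, 1), program_spec(40:89, 1))
  expect_error(synthetic_config(n_genes = 200, programs = progs), "overlap")
  expect_s3_class(synthetic_config(n_genes = 200, programs = progs,
                                   allow_program_overlap = TRUE),
                  "synthetic_config")
  expect_error(synthetic_config(n_genes = 60,
                                programs = list(program_spec(1:50, 1),
                                                program_spec(51:100, 1))),
               "n_genes")
})

test_that("planted CNV segments double mean counts in affected cells", {
  co <- small_cohort()
  genome <- co$genome
  seg <- cnv_segment_spec("chr1", 0, 13, fold = 2)  # chr1 holds 14 genes here
  affected <- which(co$annotation$sample == "S01")  # 150 cells
  planted <- plant_cnv_segments(co$counts, genome, list(seg), affected,
                                seed = 7)
  idx <- seq_len(13)
  ratio <- mean(as.matrix(planted[idx, affected])) /
    mean(as.matrix(co$counts[idx, affected]))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  # untouched cells and genes unchanged
  expect_identical(planted[, -affected], co$counts[, -affected])
  # fold 1 and empty segment lists are strict no-ops
  expect_identical(plant_cnv_segments(co$counts, genome, list(), affected),
                   co$counts)
  seg1 <- cnv_segment_spec("chr1", 0, 13, fold = 1)
  expect_identical(plant_cnv_segments(co$counts, genome, list(seg1), affected,
                                      seed = 7),
                   co$counts)
  # out-of-range ranks error
  bad <- cnv_segment_spec("chr1", 0, 200, fold = 2)
  expect_error(plant_cnv_segments(co$counts, genome, list(bad), affected),
               "outside")
})

test_that("a planted ligand-receptor axis elevates the right populations", {
  co <- axis_cohort()
  ann <- co$annotation
  mal <- ann$condition == "malignant"
  lig <- as.numeric(co$counts["POSTN", ])
  type_means <- tapply(lig[mal], ann$cell_type[mal], mean)
  expect_identical(names(which.max(type_means)), "fib_ECM")
  for (g in c("ITGAV", "ITGB5")) {
    v <- as.numeric(co$counts[g, ])
    tm <- tapply(v, ann$cell_type, mean)
    expect_identical(names(which.max(tm)), "epi_EMT")
  }
  # standalone planting with effect 1 is a no-op; missing types error
  expect_identical(plant_lr_axis(co, lr_axis_spec(effect = 1))$counts,
                   co$counts)
  expect_error(plant_lr_axis(co, lr_axis_spec(sender_type = "nope",
                                              receiver_type = "epi_EMT")),
               "absent")
  expect_error(lr_axis_spec(sender_type = "x", receiver_type = "x"), "differ")
})

test_that("every cell flagged malignant lies in a CNV-affected set", {
  segs <- list(cnv_segment_spec("chr1", 0, 10, fold = 2))
  cfg <- synthetic_config(n_samples = 3, cells_per_sample = 120,
                          n_genes = 250, cnv_segments = segs,
                          malignant_sample_fraction = 2 / 3, seed = 9)
  co <- generate_cohort(cfg)
  ann <- co$annotation
  flagged <- co$truth$malignant
  expect_gt(sum(flagged), 0)
  # affected pool: epithelial cells of malignant samples
  pool <- startsWith(ann$cell_type, "epi") & ann$condition == "malignant"
  expect_true(all(pool[flagged]))
})

test_that("survival generation respects censoring and recovers parameters", {
  d0 <- generate_survival(rnorm(50), beta = 0.5, censor_rate = 0, seed = 1)
  expect_true(all(d0$event == 1))
  expect_true(all(d0$time >= 0))
  d <- generate_survival(rnorm(400), beta = 0, censor_rate = 0.3, seed = 2)
  expect_gt(mean(d$event == 0), 0.15)
  expect_lt(mean(d$event == 0), 0.45)
  # beta = 0: fitted hazard ratio CI covers 1 in most replicates
  covers <- vapply(1:40, function(i) {
    x <- rep(0:1, each = 100)
    di <- generate_survival(x, beta = 0, censor_rate = 0.2, seed = 100 + i)
    fit <- cox_ph(di, "covariate")
    fit$ci_lower <= 1 && 1 <= fit$ci_upper
  }, logical(1))
  expect_gte(mean(covers), 0.9)
  expect_error(generate_survival(1:3, 0, censor_rate = 1), "censor_rate")
})

test_that("cohorts round-trip through MTX + sidecar files", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("matrix.mtx", "features.tsv", "barcodes.tsv", "annotation.csv",
      "genome_map.csv")))))
  back <- read_cohort(dir)
  expect_equal(as.matrix(back$counts), as.matrix(co$counts))
  expect_identical(back$annotation$cell_type, co$annotation$cell_type)
  expect_identical(back$genome$chromosome, co$genome$chromosome)
})
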