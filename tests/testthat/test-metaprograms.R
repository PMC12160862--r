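test_that("Jaccard index satisfies its formula, bounds and symmetry", {
  a <- gene_ids(1:50)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, gene_ids(51:100)), 0)
  expect_equal(jaccard_index(a, gene_ids(26:75)), 25 / 75)
  expect_equal(jaccard_index(character(0), character(0)), 0)
  # property sweep under a fixed seed
  withr::with_seed(1, {
    for (i in 1:25) {
      x <- sample(gene_ids(1:200), sample(1:60, 1))
      y <- sample(gene_ids(1:200), sample(1:60, 1))
      j <- jaccard_index(x, y)
      expect_gte(j, 0); expect_lte(j, 1)
      expect_equal(j, jaccard_index(y, x))
    }
  })
})

test_that("the NMF rank sweep yields sum(k_min:k_max) valid programs", {
  co <- small_cohort()
  norm <- normalize_log(co)
  sub <- norm[, co$annotation$sample == "S01"][1:150, ]
  progs <- fit_sample_nmf(sub, k_min = 3, k_max = 6, seed = 5, sample_id = "S01")
  expect_length(progs, 3 + 4 + 5 + 6)
  for (p in progs) {
    expect_length(unique(p$top_genes), 50)
    expect_true(all(p$weights >= 0))
    expect_true(all(diff(p$weights) <= 1e-12))  # non-increasing
  }
  # deterministic under the same seed
  progs2 <- fit_sample_nmf(sub, k_min = 3, k_max = 6, seed = 5, sample_id = "S01")
  expect_identical(lapply(progs, `[[`, "top_genes"),
                   lapply(progs2, `[[`, "top_genes"))
  expect_error(fit_sample_nmf(sub[, 1:4], k_min = 3, k_max = 6), "fewer cells")
  expect_error(fit_sample_nmf(sub * 0, k_min = 3, k_max = 3), "all-zero")
})

test_that("NMF recovers four planted disjoint modules at K = 4", {
  # one sample, 4 disjoint 50-gene modules at effect 4, each on in half the
  # cells
  progs4 <- lapply(0:3, function(i)
    program_spec(i * 50 + 1:50, samples_active = 1, fraction_cells_on = 0.5,
                 effect = 4))
  cfg <- synthetic_config(n_samples = 1, cells_per_sample = 300, n_genes = 400,
                          programs = progs4, cell_type_props = c(epi = 1),
                          malignant_sample_fraction = 1, seed = 13)
  co <- generate_cohort(cfg)
  norm <- normalize_log(co)
  fits <- fit_sample_nmf(norm, k_min = 4, k_max = 4, seed = 13)
  expect_length(fits, 4)
  for (tg in co$truth$program_genes) {
    best <- max(vapply(fits, function(p)
      length(intersect(p$top_genes, tg)), numeric(1)))
    expect_gte(best, 45)
  }
})

test_that("robustness selection applies stability, recurrence and redundancy", {
  base <- gene_ids(1:50)
  # p1: stable in-sample (40/50 with a different-K program) and recurrent
  # (12/50 with another sample's program) -> retained
  p1 <- toy_program(base, "S1", K = 4, factor_index = 1)
  p1_mate <- toy_program(gene_ids(c(1:40, 101:110)), "S1", K = 5, factor_index = 1)
  other <- toy_program(gene_ids(c(1:12, 201:238)), "S2", K = 4, factor_index = 1)
  other_mate <- toy_program(gene_ids(c(1:12, 201:231, 301:307)), "S2", K = 5,
                            factor_index = 1)
  kept <- select_robust_programs(list(p1, p1_mate, other, other_mate))
  kept_keys <- vapply(kept, function(p)
    paste(p$sample_id, p$rank_K, p$factor_index), character(1))
  expect_true("S1 4 1" %in% kept_keys)

  # a program unique to one K with no cross-sample support is dropped
  lone <- toy_program(gene_ids(401:450), "S1", K = 6, factor_index = 2)
  kept2 <- select_robust_programs(list(p1, p1_mate, other, other_mate, lone))
  expect_false(any(vapply(kept2, function(p)
    identical(p$top_genes, gene_ids(401:450)), logical(1))))

  # two near-identical retained programs (48/50 shared) collapse to one
  p1_dup <- toy_program(gene_ids(c(1:48, 151:152)), "S1", K = 6, factor_index = 1)
  p1_dup_mate <- toy_program(gene_ids(c(1:48, 151, 153)), "S1", K = 7,
                             factor_index = 1)
  kept3 <- select_robust_programs(list(p1, p1_mate, p1_dup, p1_dup_mate,
                                       other, other_mate))
  s1_hits <- sum(vapply(kept3, function(p)
    p$sample_id == "S1" && length(intersect(p$top_genes, base)) > 40,
    logical(1)))
  expect_equal(s1_hits, 1)
})

test_that("raising the recurrence overlap never increases retained programs", {
  withr::with_seed(3, {
    pool <- gene_ids(1:400)
    progs <- unlist(lapply(paste0("S", 1:4), function(s)
      lapply(3:6, function(K) lapply(seq_len(2), function(f)
        toy_program(c(gene_ids(1:30), sample(pool[101:400], 20)), s, K, f)))),
      recursive = FALSE)
    progs <- unlist(progs, recursive = FALSE)
    counts <- vapply(c(1, 5, 10, 20, 30), function(thr)
      length(select_robust_programs(progs,
        robustness_params(intra_min_overlap = 25, inter_min_overlap = thr))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("Jaccard clustering separates constructed program groups", {
  # group A: programs sharing a 40-gene core; group B: disjoint 42-gene core
  mk_group <- function(core, filler_from, sample_ids) {
    lapply(seq_along(sample_ids), function(i)
      toy_program(c(core, gene_ids(filler_from + i * 10 + 1:10)),
                  sample_ids[i], K = 3 + i, factor_index = 1))
  }
  ga <- mk_group(gene_ids(1:40), 500, paste0("S", 1:4))
  gb <- mk_group(gene_ids(101:142), 700, paste0("S", 1:4))
  mps <- cluster_meta_programs(c(ga, gb), min_cluster_size = 3)
  expect_length(mps, 2)
  expect_setequal(
    vapply(mps, function(mp) jaccard_index(mp$consensus_genes,
                                           gene_ids(1:40)) > 0.5, logical(1)),
    c(TRUE, FALSE))

  # all programs identical -> a single meta-program; single program -> warning
  same <- lapply(1:4, function(i) toy_program(gene_ids(1:50), paste0("S", i)))
  expect_length(cluster_meta_programs(same, min_cluster_size = 2), 1)
  expect_warning(out <- cluster_meta_programs(same[1]), "at least 2")
  expect_length(out, 0)
})

test_that("consensus lists rank by frequency, then loading, then id", {
  members <- lapply(1:3, function(i) toy_program(gene_ids(1:50), paste0("S", i)))
  mp <- structure(list(member_programs = members), class = "meta_program")
  expect_identical(sort(consensus_gene_list(mp)), sort(gene_ids(1:50)))

  # a gene present in all members outranks one present in a single member
  mixed <- c(members,
             list(toy_program(gene_ids(c(1:40, 61:70)), "S4")))
  mp2 <- structure(list(member_programs = mixed), class = "meta_program")
  cons <- consensus_gene_list(mp2)
  expect_length(cons, 50)
  expect_true(all(gene_ids(1:40) %in% cons))

  # union below 50 genes: return the union with a warning
  small <- list(toy_program(gene_ids(1:20)))
  mp3 <- structure(list(member_programs = small), class = "meta_program")
  expect_warning(u <- consensus_gene_list(mp3), "union")
  expect_setequal(u, gene_ids(1:20))
})

test_that("meta-programs export as GMT and read back", {
  same <- lapply(1:4, function(i) toy_program(gene_ids(1:50), paste0("S", i)))
  mps <- cluster_meta_programs(same, min_cluster_size = 2)
  path <- withr::local_tempfile(fileext = ".gmt")
  export_meta_programs_gmt(mps, path)
  sets <- read_gmt(path)
  expect_identical(names(sets), "MP01")
  expect_setequal(sets[[1]], gene_ids(1:50))
})
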