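test_that("interaction scores degrade gracefully and p-values never reach 0", {
  withr::with_seed(21, {
    m <- matrix(rexp(50 * 80), 50, 80,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    labels <- rep(c("A", "B", "C", "D"), each = 20)
    m["g01", labels == "A"] <- 0  # ligand silent in the sender cluster
    res0 <- interaction_score(m, labels, lr_pair("p", "g01", "g02"), "A", "B",
                              n_perm = 99, seed = 1)
    expect_equal(res0$score, 0)
    expect_equal(res0$p_value, 1)

    miss <- interaction_score(m, labels, lr_pair("p", "nope", "g02"), "A", "B")
    expect_equal(miss$score, 0)
    expect_equal(miss$p_value, 1)
    expect_equal(miss$flag, "gene absent")

    # +1 correction bounds p away from 0 even for an extreme observed score
    m2 <- m; m2["g05", labels == "A"] <- 50; m2["g06", labels == "B"] <- 50
    res <- interaction_score(m2, labels, lr_pair("p", "g05", "g06"), "A", "B",
                             n_perm = 99, seed = 2)
    expect_equal(res$p_value, 1 / 100)
    expect_error(interaction_score(m, labels, lr_pair("p", "g01", "g02"),
                                   "A", "missing"),
                 "at least 10")
  })
})

test_that("the observed score is the sender-mean times min subunit mean", {
  m <- matrix(1, 6, 40, dimnames = list(paste0("g", 1:6), NULL))
  labels <- rep(c("A", "B"), each = 20)
  m["g1", labels == "A"] <- 3
  m["g2", labels == "B"] <- 2
  m["g3", labels == "B"] <- 5
  res <- interaction_score(m, labels, lr_pair("p", "g1", c("g2", "g3")),
                           "A", "B", n_perm = 10, seed = 3)
  expect_equal(res$score, 3 * min(2, 5))
  # receiver cell order is irrelevant
  perm <- c(which(labels == "B")[20:1], which(labels == "A"))
  res2 <- interaction_score(m[, perm], labels[perm],
                            lr_pair("p", "g1", c("g2", "g3")), "A", "B",
                            n_perm = 10, seed = 3)
  expect_equal(res2$score, res$score)
})

test_that("networks count and sum significant pairs, and differences are antisymmetric", {
  res <- data.frame(pair = c("p1", "p2", "p3", "p4"),
                    sender = c("A", "A", "B", "A"),
                    receiver = c("B", "B", "A", "C"),
                    score = c(2, 3, 1, 4),
                    p_value = c(0.01, 0.2, 0.03, 0.004),
                    flag = NA_character_)
  net <- build_network(res, alpha = 0.05)
  expect_equal(net$count["A", "B"], 1)
  expect_equal(net$strength["A", "B"], 2)
  expect_equal(net$count["B", "A"], 1)
  expect_equal(net$count["A", "C"], 1)
  expect_true(all(net$strength[net$count == 0] == 0))

  # adding one significant pair increments the edge by 1 and its score
  res2 <- rbind(res, data.frame(pair = "p5", sender = "A", receiver = "B",
                                score = 7, p_value = 0.02, flag = NA_character_))
  net2 <- build_network(res2, alpha = 0.05)
  expect_equal(net2$count["A", "B"], net$count["A", "B"] + 1)
  expect_equal(net2$strength["A", "B"], net$strength["A", "B"] + 7)

  d_ab <- diff_network(net2, net)
  d_ba <- diff_network(net, net2)
  expect_equal(d_ab$count, -d_ba$count)
  expect_equal(d_ab$strength, -d_ba$strength)
  expect_true(all(diff_network(net, net)$count == 0))

  bad <- build_network(res, alpha = 0.05, clusters = c("A", "B"))
  expect_error(diff_network(net, bad), "cluster universes")
})

test_that("a planted fibroblast-to-epithelial axis produces a positive differential", {
  co <- axis_cohort()
  ann <- co$annotation
  norm <- normalize_log(co)
  pairs <- list(lr_pair("POSTN_ITGAV:ITGB5", "POSTN", c("ITGAV", "ITGB5")))
  run <- function(cond) {
    idx <- ann$condition == cond
    score_lr_pairs(norm[, idx], ann$cell_type[idx], pairs,
                   senders = "fib_ECM", receivers = "epi_EMT",
                   n_perm = 200, seed = 4)
  }
  net_mal <- build_network(run("malignant"),
                           clusters = c("fib_ECM", "epi_EMT"))
  net_non <- build_network(run("non-malignant"),
                           clusters = c("fib_ECM", "epi_EMT"))
  d <- diff_network(net_mal, net_non)
  # the receptor is elevated in receivers of every sample, so the edge can be
  # nominally significant in both conditions; the planted ligand surplus must
  # still show up as extra strength in the malignant network
  expect_gte(d$count["fib_ECM", "epi_EMT"], 0)
  expect_gt(d$strength["fib_ECM", "epi_EMT"], 0)
})

test_that("ligand-receptor pair tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair,ligand,receptor,annotation",
               "POSTN_ITGAV:ITGB5,POSTN,ITGAV;ITGB5,secreted",
               "MDK_NCL,MDK,NCL,secreted"), path)
  pairs <- read_lr_pairs(path)
  expect_length(pairs, 2)
  expect_identical(pairs[[1]]$receptor_genes, c("ITGAV", "ITGB5"))
  expect_identical(pairs[[2]]$receptor_genes, "NCL")
  expect_s3_class(pairs[[1]], "lr_pair")
})

test_that("sender-ligand sums stratify samples at the 75th percentile", {
  co <- axis_cohort()
  out <- stratify_by_sender_ligand(co, "POSTN", "fib_ECM", q = 75)
  expect_equal(sum(out$groups == "high"), 2)  # 6 samples, distinct sums
  # brute-force oracle for one sample
  ann <- co$annotation
  s <- ann$sample[1]
  idx <- ann$sample == s & ann$cell_type == "fib_ECM"
  expect_equal(unname(out$values[s]), sum(co$counts["POSTN", idx]))
  # malignant samples carry the planted surplus
  mal <- unique(ann$sample[ann$condition == "malignant"])
  expect_true(all(names(sort(out$values, decreasing = TRUE))[1:2] %in% mal))

  # a sample without sender cells contributes zero, with a warning
  co2 <- co
  drop <- ann$sample == "S06" & ann$cell_type == "fib_ECM"
  co2$annotation$cell_type[drop] <- "fib_other"
  expect_warning(out2 <- stratify_by_sender_ligand(co2, "POSTN", "fib_ECM"),
                 "no fib_ECM cells")
  expect_equal(unname(out2$values["S06"]), 0)
})
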