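test_that("exact Wilcoxon path equals full permutation enumeration", {
  set.seed(51)
  # every group-size pair up to the exact-path bound, with ties present
  for (n in 1:8) for (m in 1:8) {
    x <- sample(1:4, n, replace = TRUE)  # heavy ties
    y <- sample(2:5, m, replace = TRUE)
    expect_equal(organoidkit:::wilcox_p(x, y), oracle_wilcox_p(x, y),
                 tolerance = 1e-12, label = sprintf("n=%d m=%d", n, m))
  }
  # spec worked example: {1,2,3} vs {4,5,6} is the most extreme ranking
  expect_equal(organoidkit:::wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)
  # tie-free exact path agrees with the standard implementation
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(organoidkit:::wilcox_p(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  # large-sample path agrees with the tie-corrected normal approximation
  x <- rnorm(30); y <- rnorm(40) + 0.5
  expect_equal(organoidkit:::wilcox_p(x, y),
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("bonferroni correction is exact arithmetic", {
  expect_equal(bonferroni(0.001, 100), 0.1)
  expect_equal(bonferroni(0.5, 100), 1.0)
  expect_equal(bonferroni(c(0.2, 0.8), 1), c(0.2, 0.8))
  expect_error(bonferroni(1.2, 10), class = "value_error")
})

test_that("marker detection applies fold pre-filter, Bonferroni and organoid scoping", {
  # two organoids; gene g1 is a strong cluster-A marker only in organoid o1
  set.seed(61)
  n_per <- 10
  cells <- paste0("c", 1:(4 * n_per))
  labels <- data.frame(
    cell = cells,
    cluster = rep(c("A", "B", "A", "B"), each = n_per),
    organoid = rep(c("o1", "o1", "o2", "o2"), each = n_per))
  norm <- matrix(rlnorm(20 * 4 * n_per, 0, 0.1), nrow = 20,
                 dimnames = list(paste0("g", 1:20), cells))
  norm["g1", labels$organoid == "o1" & labels$cluster == "A"] <- 3
  norm["g1", labels$organoid == "o1" & labels$cluster == "B"] <- 0.1
  res <- wilcoxon_markers(norm, labels)
  hit <- res[res$gene == "g1" & res$organoid == "o1" & res$cluster == "A", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$significant)
  expect_identical(hit$direction, "up")
  expect_gte(hit$fold_change, 1.8)
  # the g1 effect exists only in o1
  expect_false(any(res$gene == "g1" & res$organoid == "o2" & res$significant))
  # Bonferroni accounting: p_bonferroni = min(1, m * p)
  expect_equal(res$p_bonferroni, pmin(1, res$m_tested * res$p_value))
  # identical in/out distributions are never significant
  flat <- matrix(rep(c(1, 2), each = 10), nrow = 1,
                 dimnames = list("g", paste0("k", 1:20)))
  flat[] <- 1
  lab2 <- data.frame(cell = colnames(flat), cluster = rep(c("A", "B"), 10),
                     organoid = "o")
  expect_equal(nrow(wilcoxon_markers(flat, lab2)), 0L)  # fold filter removes it
})

test_that("marker detection is invariant to cell order", {
  sim <- small_sc_sim(seed = 31)
  qc <- compute_qc(sim$counts)
  gf <- filter_genes(qc$counts)
  norm <- lognormalize(gf$counts)
  labels <- data.frame(cell = colnames(norm),
                       cluster = sim$truth$cluster[colnames(norm)],
                       organoid = "o1")
  res1 <- wilcoxon_markers(norm, labels)
  perm <- sample(ncol(norm))
  res2 <- wilcoxon_markers(norm[, perm], labels[perm, ])
  ord <- function(d) d[order(d$cluster, d$gene), c("cluster", "gene",
                                                   "fold_change", "p_value")]
  expect_equal(ord(res1), ord(res2), ignore_attr = TRUE)
})

test_that("significant-set size is monotone in alpha and fold cutoff", {
  sim <- small_sc_sim(seed = 37)
  qc <- compute_qc(sim$counts)
  gf <- filter_genes(qc$counts)
  norm <- lognormalize(gf$counts)
  labels <- data.frame(cell = colnames(norm),
                       cluster = sim$truth$cluster[colnames(norm)],
                       organoid = "o1")
  run <- function(fold, alpha)
    wilcoxon_markers(norm, labels, fold_cutoff = fold, alpha = alpha)
  r_05 <- run(1.8, 0.05); r_01 <- run(1.8, 0.01)
  # significant sets are nested in alpha (same m, smaller threshold)
  expect_gte(sum(r_05$significant), sum(r_01$significant))
  key <- function(d) paste(d$cluster, d$gene)
  expect_true(all(key(r_01[r_01$significant, ]) %in% key(r_05[r_05$significant, ])))
  # the tested set shrinks as the fold cutoff rises
  r_25 <- run(2.5, 0.05)
  expect_true(all(key(r_25) %in% key(r_05)))
  expect_gte(nrow(r_05), nrow(r_25))
})

test_that("planted markers are recovered; null data is calibrated", {
  sim <- small_sc_sim(seed = 41, marker_fold = 3)
  qc <- compute_qc(sim$counts)
  gf <- filter_genes(qc$counts)
  norm <- lognormalize(gf$counts)
  labels <- data.frame(cell = colnames(norm),
                       cluster = sim$truth$cluster[colnames(norm)],
                       organoid = "o1")
  res <- wilcoxon_markers(norm, labels)
  planted <- sim$truth$cluster_markers
  hits <- 0; total <- 0
  for (cl in names(planted)) {
    genes <- intersect(planted[[cl]], rownames(norm))
    total <- total + length(genes)
    sig_up <- res$gene[res$cluster == cl & res$significant & res$direction == "up"]
    hits <- hits + sum(genes %in% sig_up)
  }
  expect_gte(hits / total, 0.9)

  # null: marker_fold = 1 plants nothing; Bonferroni-significant share <= alpha
  sim0 <- small_sc_sim(seed = 43, marker_fold = 1)
  qc0 <- compute_qc(sim0$counts)
  gf0 <- filter_genes(qc0$counts)
  norm0 <- lognormalize(gf0$counts)
  labels0 <- data.frame(cell = colnames(norm0),
                        cluster = sim0$truth$cluster[colnames(norm0)],
                        organoid = "o1")
  res0 <- wilcoxon_markers(norm0, labels0)
  # false marker calls relative to all genes examined per comparison
  n_comparisons <- length(unique(labels0$cluster))
  fp_rate <- sum(res0$significant) / (nrow(norm0) * n_comparisons)
  expect_lte(fp_rate, 0.05)
})

test_that("cell typing assigns by correlation and majority vote with tie rule", {
  set.seed(71)
  ref <- matrix(rlnorm(60 * 3), nrow = 60,
                dimnames = list(paste0("g", 1:60),
                                c("epithelial", "neuroepithelial", "stromal")))
  # cells that are noisy copies of reference columns
  types <- rep(colnames(ref), times = c(4, 3, 3))
  norm <- sapply(seq_along(types), function(i)
    ref[, types[i]] * rlnorm(60, 0, 0.05))
  dimnames(norm) <- list(rownames(ref), paste0("c", seq_along(types)))
  labels <- data.frame(cell = colnames(norm),
                       cluster = rep(c("k1", "k2"), each = 5))
  res <- assign_cell_types(norm, labels, ref)
  expect_identical(res$cells$cell_type, types)   # zero-noise-level accuracy
  # k1 votes: 4 epithelial + 1 neuroepithelial -> epithelial
  expect_identical(res$clusters$cell_type[res$clusters$cluster == "k1"],
                   "epithelial")
  # exact cell = reference column gets that label
  norm2 <- cbind(norm, exact = ref[, "stromal"])
  labels2 <- rbind(labels, data.frame(cell = "exact", cluster = "k3"))
  res2 <- assign_cell_types(norm2, labels2, ref)
  expect_identical(res2$cells$cell_type[res2$cells$cell == "exact"], "stromal")
  # 2-2 tie broken alphabetically
  votes_norm <- cbind(norm[, types == "epithelial"][, 1:2],
                      norm[, types == "stromal"][, 1:2])
  colnames(votes_norm) <- paste0("t", 1:4)
  labels3 <- data.frame(cell = colnames(votes_norm), cluster = "kt")
  res3 <- assign_cell_types(votes_norm, labels3, ref)
  expect_identical(res3$clusters$cell_type, "epithelial")
  # too few shared genes errors
  expect_error(assign_cell_types(norm[1:5, ], labels, ref),
               class = "value_error")
})
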