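test_that("cell QC applies both rules at exact boundaries", {
  cm <- toy_qc_matrix()
  qc <- compute_qc(cm)
  rep <- qc$report
  expect_identical(rep$pass, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(rep$reasons[1], "mito")             # 0.444 > 0.40
  expect_false(rep$fail_mito[2])                       # 0.40 exactly passes
  expect_identical(rep$reasons[3], "min_transcripts")  # 999 < 1000
  expect_false(rep$fail_depth[4])                      # 1000 exactly passes
  expect_identical(rep$reasons[5], "mito;min_transcripts")
  # mito fraction computed on the full matrix, totals after mito removal
  expect_equal(rep$mito_fraction[1], 800 / 1800, tolerance = 1e-12)
  expect_equal(rep$total_transcripts[1], 1000)
  # the filtered matrix has no mitochondrial genes and only passing cells
  expect_identical(colnames(qc$counts$counts), c("c2", "c4", "c6"))
  expect_false(any(qc$counts$genes$is_mito))

  # surviving set matches exhaustive enumeration over all cells
  full <- cm$counts
  is_mito <- cm$genes$is_mito
  survivors <- character()
  for (cell in colnames(full)) {
    mf <- sum(full[is_mito, cell]) / sum(full[, cell])
    tot <- sum(full[!is_mito, cell])
    if (!(mf > 0.40) && !(tot < 1000)) survivors <- c(survivors, cell)
  }
  expect_identical(colnames(qc$counts$counts), survivors)

  # order stability: permuting cells permutes the report identically
  perm <- c(4, 2, 6, 1, 3, 5)
  qc_p <- compute_qc(subset_count_matrix_for_test(cm, perm))
  expect_identical(qc_p$report$pass, rep$pass[perm])
  expect_equal(qc_p$report$mito_fraction, rep$mito_fraction[perm])
})

test_that("gene filter evaluates both expression rules", {
  build <- function(counts_by_cell) {
    n <- length(counts_by_cell)
    m <- rbind(gene = counts_by_cell,
               filler1 = rep(2, n), filler2 = rep(2, n))
    colnames(m) <- paste0("c", seq_len(n))
    count_matrix(m)
  }
  # 5 expressing cells, counts (2,2,1,1,1): kept
  cm <- build(c(2, 2, 1, 1, 1))
  expect_true(filter_genes(cm)$report$keep[1])
  # 4 expressing cells at high counts: removed by the expressing-cells rule
  cm <- build(c(5, 5, 5, 5, 0))
  gf <- filter_genes(cm)
  expect_false(gf$report$keep[1])
  expect_false("gene" %in% rownames(gf$counts$counts))
  # 6 cells all count 1: removed by the >=2-transcripts rule
  cm <- build(c(1, 1, 1, 1, 1, 1))
  expect_false(filter_genes(cm)$report$keep[1])
  # boundary enumeration: every (n1, n2) combination near the cutoffs
  for (n1 in 3:6) for (n2 in 0:3) {
    if (n2 > n1) next
    counts <- c(rep(2, n2), rep(1, n1 - n2), rep(0, 7 - n1))
    cm <- build(counts)
    expected <- (n1 >= 5) && (n2 >= 2)
    expect_identical(filter_genes(cm)$report$keep[1], expected,
                     label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("log-normalization matches the closed form and preserves ranks", {
  m <- matrix(c(10, 90, 0, 50, 25, 25), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  norm <- lognormalize(m, scale = 10000)
  expect_equal(norm["g1", "c1"], log(1 + 1000), tolerance = 1e-12)
  expect_equal(norm["g3", "c1"], 0)
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(lognormalize(m2)[, 1], norm[, 1], tolerance = 1e-12)
  # rank order within a cell is preserved
  expect_identical(order(norm[, 2]), order(m[, 2]))
  m3 <- cbind(m, c0 = c(0, 0, 0))
  expect_error(lognormalize(m3), class = "value_error")
})

test_that("cycle scores separate planted phases and cutoffs flag cycle genes", {
  sim <- small_sc_sim(seed = 11)
  qc <- compute_qc(sim$counts)
  gf <- filter_genes(qc$counts)
  norm <- lognormalize(gf$counts)
  tr <- sim$truth
  s_genes <- intersect(tr$s_known, rownames(norm))
  g2m_genes <- intersect(tr$g2m_known, rownames(norm))
  scores <- cycle_score(norm, s_genes, g2m_genes, seed = 7)
  phase <- tr$phase[colnames(norm)]
  expect_gt(mean(scores$s_score[phase == "S"]),
            mean(scores$s_score[phase == "G1"]))
  expect_gt(mean(scores$g2m_score[phase == "G2M"]),
            mean(scores$g2m_score[phase == "G1"]))
  # same seed, same scores
  scores2 <- cycle_score(norm, s_genes, g2m_genes, seed = 7)
  expect_identical(scores, scores2)

  corr <- gene_score_correlations(norm, scores)
  expect_true(all(abs(corr$r_s) <= 1 & abs(corr$r_g2m) <= 1, na.rm = TRUE))
  cuts <- cycle_cutoffs(corr, s_genes, g2m_genes)
  flags <- flag_cycle_genes(corr, cuts, known_markers = c(s_genes, g2m_genes))
  # known markers always flagged
  expect_true(all(flags$flagged[flags$gene %in% c(s_genes, g2m_genes)]))
})

test_that("planted cycle-correlated genes are caught by the formula cutoffs", {
  # strongly cycling population (half the cells in S/G2M, strong phase
  # modulation), as in proliferative tumour organoids
  sim <- gen_sc_counts(n_genes = 2500, n_cells = 400, n_clusters = 3,
                       n_cycle_markers = 45, n_extra_cycle = 20,
                       cycle_fraction = 0.5, n_cluster_markers = 30,
                       marker_fold = 6, seed = 11)
  qc <- compute_qc(sim$counts)
  gf <- filter_genes(qc$counts)
  norm <- lognormalize(gf$counts)
  tr <- sim$truth
  s_genes <- intersect(tr$s_known, rownames(norm))
  g2m_genes <- intersect(tr$g2m_known, rownames(norm))
  scores <- cycle_score(norm, s_genes, g2m_genes, seed = 7)
  corr <- gene_score_correlations(norm, scores)
  cuts <- cycle_cutoffs(corr, s_genes, g2m_genes)
  flags <- flag_cycle_genes(corr, cuts, known_markers = c(s_genes, g2m_genes))
  extra <- intersect(c(tr$s_extra, tr$g2m_extra), flags$gene)
  expect_gte(mean(flags$flagged[flags$gene %in% extra]), 0.9)
})

test_that("cutoff formulas reproduce hand-computed examples exactly", {
  mk_corr <- function(s_s, s_g2m, g_g, g_s) {
    data.frame(gene = c(paste0("S", seq_along(s_s)), paste0("G", seq_along(g_g))),
               r_s = c(s_s, g_s), r_g2m = c(s_g2m, g_g))
  }
  corr <- mk_corr(c(0.5, 0.6, 0.7, 0.8), c(0.1, 0.2, 0.3, 0.4),
                  c(0.5, 0.5, 0.5, 0.5), c(0.1, 0.1, 0.1, 0.1))
  cuts <- cycle_cutoffs(corr, paste0("S", 1:4), paste0("G", 1:4))
  # Med diff = 0.65 - 0.25 = 0.40; Q25 type-7 of {.5,.6,.7,.8} = 0.575
  expect_equal(cuts$s_cut, 0.575, tolerance = 1e-12)
  corr2 <- mk_corr(rep(0.8, 4), rep(0.2, 4), rep(0.9, 4), rep(0.3, 4))
  cuts2 <- cycle_cutoffs(corr2, paste0("S", 1:4), paste0("G", 1:4))
  expect_equal(cuts2$s_cut, max(0.6, 0.8), tolerance = 1e-12)   # = 0.8
  expect_equal(cuts2$g2m_cut, max(0.6, 0.9), tolerance = 1e-12) # = 0.9
  # identical sets: difference term vanishes, Q25 wins for positive r
  corr3 <- mk_corr(c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.4, 0.6, 0.8),
                   c(0.5, 0.5, 0.5, 0.5), c(0.5, 0.5, 0.5, 0.5))
  cuts3 <- cycle_cutoffs(corr3, paste0("S", 1:4), paste0("G", 1:4))
  expect_equal(cuts3$s_cut, oracle_q25(c(0.2, 0.4, 0.6, 0.8)), tolerance = 1e-12)
})

test_that("cutoffs match a sort-based oracle on random correlation sets", {
  set.seed(202)
  for (i in 1:200) {
    n_s <- sample(3:12, 1); n_g <- sample(3:12, 1)
    s_s <- runif(n_s, -1, 1); s_g2m <- runif(n_s, -1, 1)
    g_g <- runif(n_g, -1, 1); g_s <- runif(n_g, -1, 1)
    corr <- data.frame(gene = c(paste0("S", 1:n_s), paste0("G", 1:n_g)),
                       r_s = c(s_s, g_s), r_g2m = c(s_g2m, g_g))
    cuts <- cycle_cutoffs(corr, paste0("S", 1:n_s), paste0("G", 1:n_g))
    expect_equal(cuts$s_cut,
                 max(oracle_median(s_s) - oracle_median(s_g2m), oracle_q25(s_s)),
                 tolerance = 1e-12)
    expect_equal(cuts$g2m_cut,
                 max(oracle_median(g_g) - oracle_median(g_s), oracle_q25(g_g)),
                 tolerance = 1e-12)
  }
})

test_that("gene flagging uses strict inequalities and correlation identities", {
  # gene equal to the s_score vector correlates perfectly
  norm <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:20)))
  scores <- list(s_score = norm[1, ], g2m_score = -norm[2, ])
  corr <- gene_score_correlations(norm, scores)
  expect_equal(corr$r_s[1], 1.0, tolerance = 1e-12)
  expect_equal(corr$r_g2m[2], -1.0, tolerance = 1e-12)
  # constant gene flagged as constant, correlation zero
  norm2 <- rbind(norm, gconst = rep(3, 20))
  corr2 <- gene_score_correlations(norm2, scores)
  expect_true(corr2$constant[6])
  expect_equal(corr2$r_s[6], 0)
  # boundary: r exactly at the cutoff is NOT flagged
  corr_b <- data.frame(gene = c("a", "b"), r_s = c(0.5, 0.500001),
                       r_g2m = c(0, 0))
  flags <- flag_cycle_genes(corr_b, list(s_cut = 0.5, g2m_cut = 0.5))
  expect_identical(flags$flagged, c(FALSE, TRUE))
})

test_that("variable-gene blacklists follow the two profiles", {
  genes <- c("RPL13A", "RPS6", "MKI67", "HSPA1A", "EIF4A1", "USP9Y", "XIST", "ACTB")
  bl <- list(heatshock = "HSPA1A", ribosome = "EIF4A1", chrY = "USP9Y")
  fig3 <- blacklist_variable_genes(genes, "fig3", cycle_genes = "MKI67",
                                   blacklists = bl)
  expect_identical(fig3, c("HSPA1A", "EIF4A1", "USP9Y", "XIST", "ACTB"))
  late <- blacklist_variable_genes(genes, "early_late", cycle_genes = "MKI67",
                                   blacklists = bl)
  expect_identical(late, "ACTB")
  expect_identical(blacklist_variable_genes(genes, "fig3"),
                   setdiff(genes, c("RPL13A", "RPS6")))
  expect_error(blacklist_variable_genes(genes, "fig5"), class = "config_error")
})

test_that("end-to-end QC exclusions equal generator truth exactly", {
  sim <- small_sc_sim(seed = 23)
  qc <- compute_qc(sim$counts)
  excluded <- qc$report$cell[!qc$report$pass]
  truth_excluded <- union(sim$truth$realized_high_mito,
                          sim$truth$realized_low_depth)
  expect_setequal(excluded, truth_excluded)
})
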