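# Shared fixtures, all built in code.

# Tiny hand-built signature set: forced signatures on disjoint channel
# blocks, candidates elsewhere. Useful when tests need full control over
# geometry (the generator's pairwise-dissimilarity constraint does not
# apply here).
toy_signature_set <- function(n_candidates = 3) {
  m <- matrix(0, 96, 2 + n_candidates)
  m[1:8, 1] <- 1 / 8
  m[9:16, 2] <- 1 / 8
  for (k in seq_len(n_candidates)) m[16 + (k - 1) * 8 + 1:8, 2 + k] <- 1 / 8
  colnames(m) <- c("SBS1", "SBS5", paste0("CAND", seq_len(n_candidates)))
  rownames(m) <- sbs_channels()
  signature_set(m)
}

# 6-cell toy count matrix with two mitochondrial genes and known per-cell
# mito fractions / totals, exercising the QC boundaries exactly.
toy_qc_matrix <- function() {
  g <- c("MT-1", "MT-2", "G1", "G2", "G3")
  cells <- paste0("c", 1:6)
  m <- matrix(0, 5, 6, dimnames = list(g, cells))
  m[, 1] <- c(700, 100, 500, 500, 0)    # mito 800/1800 = 0.444 > 0.40: fail mito only
  m[, 2] <- c(400, 400, 500, 400, 300)  # mito 800/2000 = 0.40 exactly: pass
  m[, 3] <- c(0, 0, 333, 333, 333)      # 999 non-mito, no mito: fail depth only
  m[, 4] <- c(0, 0, 400, 300, 300)      # 1000 non-mito exactly: pass
  m[, 5] <- c(300, 300, 200, 200, 100)  # mito 0.545 and depth 500: fail both
  m[, 6] <- c(10, 10, 600, 600, 600)    # pass
  gene_info <- data.frame(gene = g, chromosome = c("MT", "MT", "1", "1", "1"))
  count_matrix(m, gene_info)
}

# Seeded small single-cell simulation shared by several tests (kept modest
# so the default test run stays fast).
small_sc_sim <- function(seed = 11, marker_fold = 3) {
  gen_sc_counts(n_genes = 800, n_cells = 250, n_clusters = 3,
                n_cycle_markers = 25, n_extra_cycle = 20,
                n_cluster_markers = 30, marker_fold = marker_fold,
                seed = seed)
}

# Reorder cells of a count_matrix (tests of order stability).
subset_count_matrix_for_test <- function(cm, cell_order) {
  count_matrix(cm$counts[, cell_order, drop = FALSE],
               gene_info = cm$genes)
}

# Independent Wilcoxon rank-sum oracle: full enumeration over all
# assignments of the pooled observations, written separately from the
# implementation's exact path.
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); n <- length(x)
  r <- rank(pooled)
  mu <- n * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - mu)
  sets <- utils::combn(N, n)
  stats_all <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(abs(stats_all - mu) >= obs - 1e-9)
}

# Brute-force quantile by sorting and linear interpolation (type 7),
# independent of stats::quantile.
oracle_q25 <- function(x) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * 0.25 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
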