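# Wilcoxon rank-sum p-value with the package's dual path: exact permutation
# enumeration when both groups have <= `exact_max` observations (correct
# under ties, since the observed midranks are enumerated), tie-corrected
# normal approximation otherwise.
wilcox_p <- function(x, y, exact_max = 8L) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (n <= exact_max && m <= exact_max) {
    combs <- utils::combn(N, n)
    W <- colSums(matrix(r[combs], nrow = n))
    return(mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  min(1, 2 * stats::pnorm(-abs((w_obs - mu) / sqrt(sigma2))))
}

#' Bonferroni correction
#'
#' `min(1, m * p)` elementwise.
#'
#' @param p p-values in \[0, 1\].
#' @param m number of tests (>= 1).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    ok_stop("value", "p-values must lie in [0, 1]")
  if (m < 1) ok_stop("value", "m must be >= 1")
  pmin(1, m * p)
}

#' Cluster marker detection by Wilcoxon rank-sum test
#'
#' Compares each cluster to all other cells originating from the same
#' organoid. Per gene, the fold change is computed on de-logged normalized
#' means with a pseudocount:
#' `fc = (mean(expm1(x_in)) + eps) / (mean(expm1(x_out)) + eps)`.
#' Only genes with `fc >= fold_cutoff` or `fc <= 1/fold_cutoff` are tested
#' (two-sided Wilcoxon; exact permutation enumeration when both groups have
#' <= 8 cells, tie-corrected normal approximation otherwise). Bonferroni
#' correction uses the number of genes tested in that comparison; a marker
#' is significant iff the corrected p-value is below `alpha`.
#'
#' @param norm normalized matrix from [lognormalize()].
#' @param labels data.frame with columns `cell`, `cluster`, `organoid`.
#' @param fold_cutoff minimum fold change (default 1.8).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param eps pseudocount for the fold-change ratio.
#' @return data.frame (organoid, cluster, gene, fold_change, direction,
#'   p_value, m_tested, p_bonferroni, significant), one row per tested
#'   gene x comparison.
#' @export
wilcoxon_markers <- function(norm, labels, fold_cutoff = 1.8, alpha = 0.05,
                             eps = 1e-9) {
  if (!all(c("cell", "cluster", "organoid") %in% names(labels)))
    ok_stop("format", "labels needs columns cell, cluster, organoid")
  missing <- setdiff(colnames(norm), labels$cell)
  if (length(missing))
    ok_stop("value", "%d cell(s) without labels (e.g. %s)", length(missing),
            missing[1])
  out <- list()
  for (org in unique(labels$organoid)) {
    lab <- labels[labels$organoid == org, ]
    if (length(unique(lab$cluster)) < 2L) next
    for (cl in sort(unique(lab$cluster))) {
      in_cells <- lab$cell[lab$cluster == cl]
      out_cells <- lab$cell[lab$cluster != cl]
      if (length(in_cells) < 2L) {
        warning(sprintf("cluster %s in organoid %s has <2 cells; skipped", cl, org))
        next
      }
      xin <- norm[, in_cells, drop = FALSE]
      xout <- norm[, out_cells, drop = FALSE]
      mean_in <- rowMeans(expm1(xin))
      mean_out <- rowMeans(expm1(xout))
      fc <- (mean_in + eps) / (mean_out + eps)
      tested <- which(fc >= fold_cutoff | fc <= 1 / fold_cutoff)
      m <- length(tested)
      if (!m) next
      p <- vapply(tested, function(g) wilcox_p(xin[g, ], xout[g, ]), numeric(1))
      p_bonf <- bonferroni(p, m)
      out[[length(out) + 1L]] <- data.frame(
        organoid = org, cluster = cl, gene = rownames(norm)[tested],
        fold_change = unname(fc[tested]),
        direction = ifelse(fc[tested] >= 1, "up", "down"),
        p_value = p, m_tested = m, p_bonferroni = p_bonf,
        significant = p_bonf < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(organoid = character(), cluster = character(),
               gene = character(), fold_change = numeric(),
               direction = character(), p_value = numeric(),
               m_tested = integer(), p_bonferroni = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Reference-based cell typing by correlation and majority vote
#'
#' Correlates every cell's expression profile (Spearman, over the genes
#' shared with the reference) with each reference cell-type column; each
#' cell gets the best-correlated label, and each cluster the modal label of
#' its cells (ties broken alphabetically).
#'
#' @param norm normalized genes x cells matrix.
#' @param labels data.frame with columns `cell`, `cluster`.
#' @param reference genes x cell-types expression matrix with unique column
#'   labels.
#' @return list with `cells` (cell, cell_type, best_cor) and `clusters`
#'   (cluster, cell_type).
#' @export
assign_cell_types <- function(norm, labels, reference) {
  reference <- as.matrix(reference)
  if (anyDuplicated(colnames(reference)))
    ok_stop("format", "duplicate reference cell-type labels")
  shared <- intersect(rownames(norm), rownames(reference))
  if (length(shared) < 10L)
    ok_stop("value", "only %d genes shared with the reference (need >= 10)",
            length(shared))
  cors <- stats::cor(norm[shared, , drop = FALSE],
                     reference[shared, , drop = FALSE], method = "spearman")
  best <- apply(cors, 1, which.max)
  cells <- data.frame(cell = rownames(cors),
                      cell_type = colnames(cors)[best],
                      best_cor = cors[cbind(seq_len(nrow(cors)), best)],
                      stringsAsFactors = FALSE, row.names = NULL)
  idx <- match(labels$cell, cells$cell)
  clusters <- do.call(rbind, lapply(sort(unique(labels$cluster)), function(cl) {
    votes <- cells$cell_type[idx[labels$cluster == cl]]
    tab <- table(votes)
    winners <- names(tab)[tab == max(tab)]
    data.frame(cluster = cl, cell_type = sort(winners)[1],
               stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL
  list(cells = cells, clusters = clusters)
}
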