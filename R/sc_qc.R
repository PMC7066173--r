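#' Per-cell quality control
#'
#' Computes the mitochondrial transcript fraction on the full matrix, then
#' removes mitochondrial genes, computes per-cell transcript totals on the
#' mitochondria-free matrix, and drops cells whose mitochondrial fraction
#' strictly exceeds `max_mito` ("exceeding 40%") or whose total is strictly
#' below `min_transcripts` ("<1000 unique transcripts"). Both rules are
#' evaluated independently and reported per cell.
#'
#' @param counts a [count_matrix()] with mitochondrial annotation.
#' @param max_mito maximum mitochondrial fraction (default 0.40).
#' @param min_transcripts minimum post-mitochondrial transcript total
#'   (default 1000).
#' @return list with `report` (cell, mito_fraction, total_transcripts,
#'   fail_mito, fail_depth, pass, reasons) and `counts`, the filtered
#'   [count_matrix()] (mitochondrial genes removed, failing cells dropped).
#' @export
compute_qc <- function(counts, max_mito = 0.40, min_transcripts = 1000) {
  if (!inherits(counts, "count_matrix")) ok_stop("value", "expected a count_matrix")
  m <- counts$counts
  if (nrow(m) == 0L || ncol(m) == 0L) ok_stop("value", "empty count matrix")
  is_mito <- counts$genes$is_mito
  grand <- colSums(m)
  mito_frac <- ifelse(grand > 0, colSums(m[is_mito, , drop = FALSE]) / grand, 0)
  total <- colSums(m[!is_mito, , drop = FALSE])
  fail_mito <- mito_frac > max_mito
  fail_depth <- total < min_transcripts
  pass <- !fail_mito & !fail_depth
  reasons <- mapply(function(fm, fd) paste(
    c(if (fm) "mito", if (fd) "min_transcripts"), collapse = ";"),
    fail_mito, fail_depth)
  report <- data.frame(cell = colnames(m), mito_fraction = mito_frac,
                       total_transcripts = total, fail_mito = fail_mito,
                       fail_depth = fail_depth, pass = pass,
                       reasons = unname(reasons), stringsAsFactors = FALSE,
                       row.names = NULL)
  ok_log("INFO", "QC: %d/%d cells pass", sum(pass), ncol(m))
  list(report = report,
       counts = subset_count_matrix(counts, genes = which(!is_mito),
                                    cells = which(pass)))
}

#' Remove lowly-expressed genes
#'
#' A gene is kept iff it is expressed (count >= 1) in at least `min_cells`
#' cells AND has at least `min_cells_ge2` cells with count >= 2. Applied
#' after cell filtering.
#'
#' @param counts a [count_matrix()].
#' @param min_cells minimum expressing cells (default 5).
#' @param min_cells_ge2 minimum cells with >= 2 transcripts (default 2).
#' @return list with `report` (gene, n_cells_expressing, n_cells_ge2, keep)
#'   and the filtered `counts`.
#' @export
filter_genes <- function(counts, min_cells = 5, min_cells_ge2 = 2) {
  m <- counts$counts
  n1 <- rowSums(m >= 1)
  n2 <- rowSums(m >= 2)
  keep <- n1 >= min_cells & n2 >= min_cells_ge2
  ok_log("INFO", "gene filter: %d/%d genes kept", sum(keep), nrow(m))
  list(report = data.frame(gene = rownames(m), n_cells_expressing = n1,
                           n_cells_ge2 = n2, keep = keep,
                           stringsAsFactors = FALSE, row.names = NULL),
       counts = subset_count_matrix(counts, genes = which(keep)))
}

#' Log-normalize counts to a fixed transcript total
#'
#' `x_hat[g, c] = ln(1 + scale * x[g, c] / total_c)` with `total_c` the
#' cell's transcript total — natural-log normalization to 10,000 transcripts
#' by default. Preserves zeros and each cell's gene rank order.
#'
#' @param counts a [count_matrix()] or bare genes x cells matrix.
#' @param scale target transcript total (default 10000).
#' @return dense numeric matrix of normalized expression.
#' @export
lognormalize <- function(counts, scale = 10000) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0))
    ok_stop("value", "cell(s) with zero total transcripts: %s",
            paste(utils::head(colnames(m)[tot == 0], 3), collapse = ", "))
  log1p(sweep(m, 2, tot, "/") * scale)
}

#' Cell-cycle module scores
#'
#' Per-cell S and G2M scores: mean normalized expression over the marker
#' genes minus mean over a control gene set. Controls are drawn per marker
#' gene from the marker's average-expression bin (`n_bins` equal-frequency
#' bins over all genes, `n_ctrl` controls per marker, seeded sampling
#' without replacement within the bin), so the score is centred against
#' genes of comparable abundance.
#'
#' @param norm normalized matrix from [lognormalize()].
#' @param s_genes,g2m_genes S-phase and G2M-phase marker gene sets (names
#'   absent from the matrix are dropped with a warning).
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes per marker (default 100).
#' @param seed RNG seed for control sampling.
#' @return list with `s_score` and `g2m_score`, named numeric vectors per
#'   cell.
#' @export
cycle_score <- function(norm, s_genes, g2m_genes, n_bins = 24, n_ctrl = 100,
                        seed = 1) {
  avg <- rowMeans(norm)
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  score_one <- function(markers) {
    present <- intersect(markers, rownames(norm))
    if (!length(present))
      ok_stop("value", "no marker genes present in the matrix")
    if (length(present) < length(markers))
      warning(sprintf("%d marker gene(s) absent from matrix, dropped",
                      length(markers) - length(present)))
    ctrl <- unique(unlist(lapply(present, function(g) {
      mates <- names(avg)[bin == bin[g]]
      sample(mates, min(n_ctrl, length(mates)))
    })))
    colMeans(norm[present, , drop = FALSE]) -
      colMeans(norm[ctrl, , drop = FALSE])
  }
  with_seed(seed, {
    s <- score_one(s_genes)
    g2m <- score_one(g2m_genes)
    list(s_score = s, g2m_score = g2m)
  })
}

#' Correlate every gene with the cell-cycle scores
#'
#' Pearson correlation of each gene's normalized expression with the S and
#' G2M scores across all cells. Genes with constant expression get
#' correlation 0 and a flag.
#'
#' @param norm normalized matrix.
#' @param scores list from [cycle_score()].
#' @return data.frame (gene, r_s, r_g2m, constant).
#' @export
gene_score_correlations <- function(norm, scores) {
  if (ncol(norm) < 3L) ok_stop("value", "need at least 3 cells for correlations")
  sds <- apply(norm, 1, stats::sd)
  constant <- sds == 0
  r_s <- r_g2m <- numeric(nrow(norm))
  if (any(!constant)) {
    sub <- norm[!constant, , drop = FALSE]
    r_s[!constant] <- as.numeric(stats::cor(t(sub), scores$s_score))
    r_g2m[!constant] <- as.numeric(stats::cor(t(sub), scores$g2m_score))
  }
  data.frame(gene = rownames(norm), r_s = r_s, r_g2m = r_g2m,
             constant = constant, stringsAsFactors = FALSE, row.names = NULL)
}

#' Formula-defined cell-cycle-gene cutoffs
#'
#' Evaluates, on the correlations of the *known* marker genes,
#' `s_cut = max(Med(S_S) - Med(S_G2M), Q25(S_S))` and
#' `g2m_cut = max(Med(G2M_G2M) - Med(G2M_S), Q25(G2M_G2M))`, where e.g.
#' `S_G2M` is the correlation of the known S-phase genes with the G2M score.
#' Quantiles use linear interpolation between order statistics (type 7) by
#' default; the convention is switchable because it changes the cutoff.
#'
#' @param correlations data.frame from [gene_score_correlations()].
#' @param s_genes,g2m_genes the known marker gene sets.
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return list with `s_cut` and `g2m_cut`.
#' @export
cycle_cutoffs <- function(correlations, s_genes, g2m_genes, quantile_type = 7) {
  pick <- function(genes, col) {
    x <- correlations[[col]][correlations$gene %in% genes]
    if (!length(x)) ok_stop("value", "no marker correlations available")
    x
  }
  S_S <- pick(s_genes, "r_s"); S_G2M <- pick(s_genes, "r_g2m")
  G2M_G2M <- pick(g2m_genes, "r_g2m"); G2M_S <- pick(g2m_genes, "r_s")
  list(
    s_cut = max(stats::median(S_S) - stats::median(S_G2M),
                unname(stats::quantile(S_S, 0.25, type = quantile_type))),
    g2m_cut = max(stats::median(G2M_G2M) - stats::median(G2M_S),
                  unname(stats::quantile(G2M_G2M, 0.25, type = quantile_type))))
}

#' Flag cell-cycle genes
#'
#' A gene is a cell-cycle gene iff its correlation with the S score is
#' strictly above `s_cut` OR with the G2M score strictly above `g2m_cut`;
#' the known markers themselves are always flagged.
#'
#' @param correlations data.frame from [gene_score_correlations()].
#' @param cutoffs list from [cycle_cutoffs()].
#' @param known_markers genes flagged unconditionally.
#' @return data.frame (gene, flagged, reason).
#' @export
flag_cycle_genes <- function(correlations, cutoffs, known_markers = character()) {
  by_corr <- correlations$r_s > cutoffs$s_cut |
    correlations$r_g2m > cutoffs$g2m_cut
  known <- correlations$gene %in% known_markers
  data.frame(
    gene = correlations$gene,
    flagged = by_corr | known,
    reason = ifelse(known, "known_marker",
                    ifelse(by_corr, "correlation", "")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Blacklist filtering of variable genes
#'
#' Removes housekeeping/confounder genes from a variable-gene list. Profile
#' `"fig3"` removes mitochondrial pseudogenes, cell-cycle genes and symbols
#' starting with "RP"; profile `"early_late"` additionally removes
#' heat-shock genes (GO:0006986-derived list), ribosomal-protein genes
#' (GO:0022626-derived list), chromosome-Y genes, and XIST/TSIX. Gene lists
#' are supplied as plain character vectors (e.g. read from text files); no
#' ontology is downloaded.
#'
#' @param genes character vector of candidate variable genes (symbols).
#' @param profile `"fig3"` or `"early_late"`.
#' @param cycle_genes flagged cell-cycle genes (from [flag_cycle_genes()]).
#' @param blacklists named list with any of `mito_pseudogenes`, `heatshock`,
#'   `ribosome`, `chrY`, `xist_tsix` (default `c("XIST","TSIX")`).
#' @return filtered character vector.
#' @export
blacklist_variable_genes <- function(genes, profile = "fig3",
                                     cycle_genes = character(),
                                     blacklists = list()) {
  if (!profile %in% c("fig3", "early_late"))
    ok_stop("config", "unknown blacklist profile '%s'", profile)
  bl <- utils::modifyList(list(
    mito_pseudogenes = character(), heatshock = character(),
    ribosome = character(), chrY = character(),
    xist_tsix = c("XIST", "TSIX")), blacklists)
  drop <- genes %in% bl$mito_pseudogenes | genes %in% cycle_genes |
    startsWith(genes, "RP")
  if (profile == "early_late")
    drop <- drop | genes %in% bl$heatshock | genes %in% bl$ribosome |
      genes %in% bl$chrY | genes %in% bl$xist_tsix
  genes[!drop]
}
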