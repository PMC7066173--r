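# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes. Every generator is a pure function of its
# arguments: the same seed gives identical output, and the caller's RNG
# stream is left untouched. Each returns a `truth` component sufficient to
# score the downstream stage.

#' Generate a synthetic signature reference set
#'
#' Random 96-channel signatures mimicking the structure of real
#' single-base-substitution signatures: the two clock-like columns (named
#' SBS1 and SBS5 so they can serve as the forced signatures) are drawn
#' relatively flat — real SBS5 is famously featureless and SBS1 only
#' moderately peaked — while the remaining candidate signatures are sparse
#' Dirichlet draws with a handful of strongly boosted "peaked" channels,
#' like the APOBEC/UV/POLE-type signatures. Columns are redrawn until all
#' pairwise cosine similarities are below 0.9, so greedy selection is
#' neither trivial nor impossible.
#'
#' @param n_signatures number of signatures (>= 2).
#' @param peaked_channels number of boosted channels per candidate
#'   signature.
#' @param seed RNG seed.
#' @param max_retries redraw attempts before giving up.
#' @return a [signature_set()].
#' @export
gen_signature_set <- function(n_signatures = 10, peaked_channels = 4,
                              seed = 1, max_retries = 200) {
  if (n_signatures < 2) ok_stop("value", "need at least 2 signatures")
  if (peaked_channels < 1 || peaked_channels > 96)
    ok_stop("value", "peaked_channels must be in [1, 96]")
  with_seed(seed, {
    draw_col <- function(flat) {
      if (flat) {
        w <- stats::rgamma(96, shape = 2)
        peaks <- sample.int(96, 2)
        w[peaks] <- w[peaks] + stats::rgamma(2, shape = 2, rate = 0.5)
      } else {
        w <- stats::rgamma(96, shape = 0.15)
        peaks <- sample.int(96, peaked_channels)
        w[peaks] <- w[peaks] + stats::rgamma(peaked_channels, shape = 3, rate = 0.2)
      }
      w / sum(w)
    }
    m <- matrix(0, 96, n_signatures)
    for (j in seq_len(n_signatures)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- draw_col(flat = j <= 2L)
        if (j == 1L || all(apply(m[, seq_len(j - 1L), drop = FALSE], 2,
                                 cosine_similarity, b = cand) < 0.9)) {
          m[, j] <- cand; ok <- TRUE; break
        }
      }
      if (!ok)
        ok_stop("generation",
                "could not draw %d mutually dissimilar signatures; try fewer",
                n_signatures)
    }
    colnames(m) <- c("SBS1", "SBS5",
                     if (n_signatures > 2) sprintf("SIM%02d", seq_len(n_signatures - 2L)))
    rownames(m) <- sbs_channels()
    signature_set(m, forced = c("SBS1", "SBS5"))
  })
}

#' Generate mutation catalogs as signature mixtures
#'
#' Each sample's expected spectrum is `total_mutations * S w` for mixture
#' weights `w`; with `noise = "poisson"` every channel is an independent
#' Poisson draw of that mean, with `"none"` the exact (real-valued)
#' expectation is returned.
#'
#' @param signatures a [signature_set()].
#' @param exposures numeric vector (one sample) or samples x signatures
#'   matrix of non-negative mixture weights summing to one per sample.
#' @param total_mutations expected mutations per sample.
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed (used for Poisson noise).
#' @return 96 x n_samples catalog matrix.
#' @export
gen_catalog <- function(signatures, exposures, total_mutations = 10000,
                        noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  W <- if (is.matrix(exposures)) exposures else
    matrix(exposures, nrow = 1, dimnames = list("sample1", names(exposures)))
  if (any(W < 0)) ok_stop("value", "mixture weights must be non-negative")
  if (is.null(colnames(W))) {
    if (ncol(W) != length(signatures$names))
      ok_stop("value", "unnamed weights must cover every signature")
    colnames(W) <- signatures$names
  }
  bad <- setdiff(colnames(W), signatures$names)
  if (length(bad)) ok_stop("value", "unknown signature(s) in weights: %s",
                           paste(bad, collapse = ", "))
  W <- sweep(W, 1, rowSums(W), "/")
  if (is.null(rownames(W))) rownames(W) <- paste0("sample", seq_len(nrow(W)))
  mean_mat <- total_mutations *
    (signatures$matrix[, colnames(W), drop = FALSE] %*% t(W))
  out <- if (noise == "none") mean_mat else
    with_seed(seed, matrix(stats::rpois(length(mean_mat), lambda = mean_mat),
                           nrow = 96, dimnames = dimnames(mean_mat)))
  rownames(out) <- sbs_channels()
  out
}

#' Generate a synthetic single-cell count matrix with planted structure
#'
#' Negative-binomial gene x cell counts emulating plate-based (Sort-seq
#' style) UMI data: a mitochondrial gene block with per-cell mitochondrial
#' fractions drawn so that roughly `share_high_mito` of cells exceed 40%;
#' log-normal library sizes so that roughly `share_low_depth` of cells fall
#' below 1000 transcripts; S-phase and G2M-phase marker blocks (known
#' markers plus extra cycle-correlated genes) elevated `marker_fold`-fold in
#' cells of that phase; and per-cluster marker blocks elevated
#' `marker_fold`-fold in their cluster. `marker_fold = 1` plants no
#' structure (a null data set for calibration).
#'
#' The returned `truth` records planted memberships *and* the realized QC
#' outcomes (mitochondrial fraction > 0.40; post-mitochondrial totals
#' < 1000) computed from the generated matrix, so downstream QC can be
#' scored exactly.
#'
#' @param n_genes,n_cells,n_clusters matrix dimensions and cluster count.
#' @param frac_mito_genes fraction of genes that are mitochondrial.
#' @param cycle_fraction fraction of cells in S or G2M phase (split evenly).
#' @param marker_fold planted fold-change (> 1, or exactly 1 for a null).
#' @param share_high_mito,share_low_depth target fractions of failing cells.
#' @param n_cycle_markers known S (and G2M) marker genes per phase.
#' @param n_extra_cycle additional cycle-correlated genes per phase (not in
#'   the known-marker lists).
#' @param n_cluster_markers marker genes per cluster.
#' @param nb_size negative-binomial dispersion (size) parameter.
#' @param seed RNG seed.
#' @return list with `counts` (a [count_matrix()]) and `truth`.
#' @export
gen_sc_counts <- function(n_genes = 2000, n_cells = 400, n_clusters = 3,
                          frac_mito_genes = 0.05, cycle_fraction = 0.3,
                          marker_fold = 3, share_high_mito = 0.1,
                          share_low_depth = 0.1, n_cycle_markers = 40,
                          n_extra_cycle = 30, n_cluster_markers = 50,
                          nb_size = 2, seed = 1) {
  if (marker_fold < 1) ok_stop("value", "marker_fold must be >= 1")
  n_mito <- round(frac_mito_genes * n_genes)
  n_special <- n_mito + 2 * (n_cycle_markers + n_extra_cycle) +
    n_clusters * n_cluster_markers
  if (n_special > n_genes)
    ok_stop("value", "gene blocks (%d) exceed n_genes (%d)", n_special, n_genes)
  with_seed(seed, {
    mito_genes <- if (n_mito) sprintf("MT-G%03d", seq_len(n_mito)) else character()
    n_nuc <- n_genes - n_mito
    nuc_genes <- sprintf("G%05d", seq_len(n_nuc))
    idx <- 0L
    take <- function(k) { out <- nuc_genes[idx + seq_len(k)]; idx <<- idx + k; out }
    s_known <- take(n_cycle_markers); g2m_known <- take(n_cycle_markers)
    s_extra <- take(n_extra_cycle); g2m_extra <- take(n_extra_cycle)
    cluster_markers <- lapply(seq_len(n_clusters), function(k) take(n_cluster_markers))
    names(cluster_markers) <- paste0("cluster", seq_len(n_clusters))

    base <- stats::rlnorm(n_nuc, meanlog = 0, sdlog = 1)
    names(base) <- nuc_genes
    special <- c(s_known, g2m_known, s_extra, g2m_extra, unlist(cluster_markers))
    base[special] <- stats::rlnorm(length(special), meanlog = 1.2, sdlog = 0.8)

    cluster <- sample.int(n_clusters, n_cells, replace = TRUE)
    phase <- sample(c("S", "G2M", "G1"), n_cells, replace = TRUE,
                    prob = c(cycle_fraction / 2, cycle_fraction / 2,
                             1 - cycle_fraction))
    high_mito <- stats::runif(n_cells) < share_high_mito
    mito_frac <- ifelse(high_mito, stats::runif(n_cells, 0.50, 0.80),
                        stats::runif(n_cells, 0.02, 0.30))
    sdlog <- 0.6
    lib <- stats::rlnorm(n_cells,
                         meanlog = log(1000) - sdlog * stats::qnorm(share_low_depth),
                         sdlog = sdlog)

    mito_rel <- if (n_mito) {
      r <- stats::rlnorm(n_mito, 0, 0.5); r / sum(r)
    } else numeric()

    counts <- matrix(0, n_genes, n_cells,
                     dimnames = list(c(mito_genes, nuc_genes),
                                     sprintf("cell%04d", seq_len(n_cells))))
    # a share of the known markers is non-responsive in this tissue, as in
    # real generic marker lists; only responsive genes receive the fold
    n_resp <- ceiling(0.7 * n_cycle_markers)
    s_resp <- s_known[seq_len(n_resp)]; g2m_resp <- g2m_known[seq_len(n_resp)]
    s_block <- c(s_resp, s_extra); g2m_block <- c(g2m_resp, g2m_extra)
    # cycling is a continuum: cells in one phase partially co-express the
    # adjacent phase's genes, as in real data (keeps the known-marker
    # correlation structure the cutoff formulas assume)
    minor_fold <- 1 + (marker_fold - 1) / 3
    for (j in seq_len(n_cells)) {
      rel <- base
      if (phase[j] == "S") {
        rel[s_block] <- rel[s_block] * marker_fold
        rel[g2m_block] <- rel[g2m_block] * minor_fold
      }
      if (phase[j] == "G2M") {
        rel[g2m_block] <- rel[g2m_block] * marker_fold
        rel[s_block] <- rel[s_block] * minor_fold
      }
      mk <- cluster_markers[[cluster[j]]]
      rel[mk] <- rel[mk] * marker_fold
      rel <- rel / sum(rel)
      mu_nuc <- lib[j] * (1 - mito_frac[j]) * rel
      mu <- c(if (n_mito) lib[j] * mito_frac[j] * mito_rel, mu_nuc)
      counts[, j] <- stats::rnbinom(n_genes, size = nb_size, mu = mu)
    }
    gene_info <- data.frame(
      gene = rownames(counts),
      chromosome = c(rep("MT", n_mito), rep("1", n_nuc)),
      stringsAsFactors = FALSE)
    cm <- count_matrix(counts, gene_info = gene_info)

    is_mito <- cm$genes$is_mito
    realized_mf <- colSums(counts[is_mito, , drop = FALSE]) / pmax(1, colSums(counts))
    post_mito_total <- colSums(counts[!is_mito, , drop = FALSE])
    truth <- list(
      cluster = stats::setNames(paste0("cluster", cluster), colnames(counts)),
      phase = stats::setNames(phase, colnames(counts)),
      s_known = s_known, g2m_known = g2m_known,
      s_responsive = s_resp, g2m_responsive = g2m_resp,
      s_extra = s_extra, g2m_extra = g2m_extra,
      cluster_markers = cluster_markers,
      mito_genes = mito_genes,
      planted_high_mito = colnames(counts)[high_mito],
      realized_mito_frac = stats::setNames(realized_mf, colnames(counts)),
      realized_high_mito = colnames(counts)[realized_mf > 0.40],
      realized_low_depth = colnames(counts)[post_mito_total < 1000],
      marker_fold = marker_fold)
    list(counts = cm, truth = truth)
  })
}

#' Generate a somatic-variant table with controlled filter violations
#'
#' Constructs `n_pass` records satisfying every hard-filter rule, plus, for
#' each named rule in `violations`, the requested number of records
#' violating that rule *only*. Returns the records, the control-sample
#' called-variant positions needed by the indel-proximity rule, and a truth
#' table labelling every record pass/fail with its reason.
#'
#' Rule names: `normal_evidence`, `dbsnp`, `depth`, `vaf`, `site_qual`,
#' `mq`, `autosome`, `indel_proximity`, `gq_normal`, `gq_tumour`.
#'
#' @param n_pass number of fully-passing records.
#' @param violations named list/vector, rule name -> count.
#' @param matched_normal whether records carry matched-normal fields.
#' @param config thresholds, from [default_config()].
#' @param seed RNG seed.
#' @return list with `records` (`variant_table`), `control_positions`
#'   (data.frame chrom/pos) and `truth` (record/pass/reason).
#' @export
gen_variant_table <- function(n_pass = 10, violations = list(),
                              matched_normal = TRUE,
                              config = default_config(), seed = 1) {
  v <- config$variant
  rule_names <- c("normal_evidence", "dbsnp", "depth", "vaf", "site_qual",
                  "mq", "autosome", "indel_proximity", "gq_normal", "gq_tumour")
  bad <- setdiff(names(violations), rule_names)
  if (length(bad)) ok_stop("value", "unknown rule(s): %s", paste(bad, collapse = ", "))
  if (!matched_normal &&
      any(c("normal_evidence", "indel_proximity", "gq_normal") %in% names(violations)))
    ok_stop("value", "normal-dependent violations need matched_normal = TRUE")
  with_seed(seed, {
    n_ctrl <- 5L
    control_positions <- data.frame(
      chrom = as.character(sample.int(22, n_ctrl, replace = TRUE)),
      pos = sample.int(9e7, n_ctrl) + 1e6, stringsAsFactors = FALSE)

    far_pos <- function(chrom) {
      repeat {
        p <- sample.int(9e7, 1) + 1e6
        near <- control_positions$chrom == chrom &
          abs(control_positions$pos - p) <= v$indel_proximity_bp
        if (!any(near)) return(p)
      }
    }
    base_rec <- function(vtype = "snv") {
      chrom <- as.character(sample.int(22, 1))
      dp <- sample(30:100, 1)
      alt <- round(stats::runif(1, 0.25, 0.6) * dp)
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, 1)
      data.frame(
        chrom = chrom, pos = far_pos(chrom),
        ref = if (vtype == "snv") ref else ref,
        alt = if (vtype == "snv") sample(setdiff(bases, ref), 1)
              else paste0(ref, sample(bases, 1)),
        vtype = vtype,
        site_qual = stats::runif(1, max(v$min_qual_snv, v$min_qual_indel) + 50, 2000),
        mq = stats::runif(1, v$min_mq_indel, v$min_mq_indel + 10),
        dbsnp = FALSE,
        annotation_class = sample(c(v$driver_classes, "synonymous", NA), 1),
        gene = sprintf("GENE%03d", sample.int(500, 1)),
        tumour_depth = dp, tumour_alt_reads = alt, tumour_vaf = alt / dp,
        tumour_gq = 99,
        normal_depth = if (matched_normal) sample(30:80, 1) else NA_real_,
        normal_alt_reads = if (matched_normal) 0 else NA_real_,
        normal_gq = if (matched_normal) sample(30:99, 1) else NA_real_,
        normal_gt = if (matched_normal) "0/0" else NA_character_,
        has_normal = matched_normal,
        stringsAsFactors = FALSE)
    }
    recs <- list(); truth <- list()
    add <- function(rec, pass, reason) {
      recs[[length(recs) + 1L]] <<- rec
      truth[[length(truth) + 1L]] <<- data.frame(
        record = length(recs), pass = pass, reason = reason,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_pass))
      add(base_rec(if (i %% 4 == 0) "indel" else "snv"), TRUE, "")
    for (rule in names(violations)) for (i in seq_len(violations[[rule]])) {
      r <- base_rec(if (rule %in% c("mq", "indel_proximity")) "indel" else "snv")
      if (rule == "normal_evidence") r$normal_alt_reads <- sample(2:8, 1)
      if (rule == "dbsnp") r$dbsnp <- TRUE
      if (rule == "depth") {
        thr <- if (matched_normal) v$min_depth else v$min_depth_unmatched
        r$tumour_depth <- thr - 1
        r$tumour_alt_reads <- max(1, round(0.4 * r$tumour_depth))
        r$tumour_vaf <- r$tumour_alt_reads / r$tumour_depth
      }
      if (rule == "vaf") {
        r$tumour_depth <- 80
        r$tumour_alt_reads <- 4   # VAF 0.05 < 0.1
        r$tumour_vaf <- 0.05
      }
      if (rule == "site_qual")
        r$site_qual <- (if (r$vtype == "snv") v$min_qual_snv else v$min_qual_indel) - 10
      if (rule == "mq") r$mq <- v$min_mq_indel - 5
      if (rule == "autosome") r$chrom <- sample(c("X", "Y"), 1)
      if (rule == "indel_proximity") {
        k <- sample.int(nrow(control_positions), 1)
        r$chrom <- control_positions$chrom[k]
        r$pos <- control_positions$pos[k] +
          sample(seq(-v$indel_proximity_bp, v$indel_proximity_bp), 1)
      }
      if (rule == "gq_normal") r$normal_gq <- v$min_gq_normal - 1
      if (rule == "gq_tumour") r$tumour_gq <- v$min_gq_tumour - 1
      add(r, FALSE, rule)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    class(records) <- c("variant_table", "data.frame")
    list(records = records, control_positions = control_positions,
         truth = do.call(rbind, truth))
  })
}

#' Generate drug-screen plate readings from known dose-response curves
#'
#' Test-well viabilities follow each compound's four-parameter logistic
#' curve, multiplied by mean-one log-normal noise with coefficient of
#' variation `cv`, then converted to raw luminescence through a plate-level
#' scale factor. DMSO vehicle wells sit at 100% viability and staurosporine
#' kill-control wells near 0%.
#'
#' @param compounds data.frame with columns `compound`, `top`, `bottom`,
#'   `ic50_nM`, `hill` (the true curve parameters).
#' @param concentrations_nM tested concentrations (default six, half-log
#'   spaced).
#' @param replicates technical replicates per compound x concentration.
#' @param cv multiplicative noise coefficient of variation (0 = noise-free).
#' @param n_control number of DMSO and of staurosporine wells.
#' @param scale plate luminescence at 100% viability.
#' @param seed RNG seed.
#' @return list with `plate` (a `plate_readings` data.frame) and `truth`
#'   (the compound parameter table).
#' @export
gen_plate <- function(compounds,
                      concentrations_nM = 10^seq(0, 4, length.out = 6),
                      replicates = 4, cv = 0.1, n_control = 16,
                      scale = 20000, seed = 1) {
  if (!all(c("compound", "top", "bottom", "ic50_nM", "hill") %in% names(compounds)))
    ok_stop("value", "compounds needs columns compound, top, bottom, ic50_nM, hill")
  with_seed(seed, {
    noise <- function(n) {
      if (cv == 0) return(rep(1, n))
      sig <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = -sig^2 / 2, sdlog = sig)  # mean exactly 1
    }
    rows <- list(); wid <- 0L
    well <- function() { wid <<- wid + 1L; sprintf("W%04d", wid) }
    for (i in seq_len(nrow(compounds))) {
      p <- compounds[i, ]
      for (conc in concentrations_nM) {
        viab <- pl4(conc, p$top, p$bottom, p$ic50_nM, p$hill)
        for (r in seq_len(replicates))
          rows[[length(rows) + 1L]] <- data.frame(
            well = well(), compound = p$compound, concentration_nM = conc,
            replicate = r, reading = viab / 100 * scale * noise(1),
            role = "test", stringsAsFactors = FALSE)
      }
    }
    for (r in seq_len(n_control))
      rows[[length(rows) + 1L]] <- data.frame(
        well = well(), compound = "DMSO", concentration_nM = NA_real_,
        replicate = r, reading = scale * noise(1), role = "dmso",
        stringsAsFactors = FALSE)
    for (r in seq_len(n_control))
      rows[[length(rows) + 1L]] <- data.frame(
        well = well(), compound = "staurosporine", concentration_nM = NA_real_,
        replicate = r, reading = 0.005 * scale * noise(1),
        role = "staurosporine", stringsAsFactors = FALSE)
    plate <- do.call(rbind, rows)
    class(plate) <- c("plate_readings", "data.frame")
    list(plate = plate, truth = compounds)
  })
}
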