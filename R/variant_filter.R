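#' Somatic hard-filtering of candidate variant records
#'
#' Evaluates the complete hard-filter rule set on each record, accumulating
#' all failures (no short-circuiting): evidence in the matched normal (any
#' alt-supporting read beyond `normal_alt_reads_max`, or a non-reference
#' normal genotype); dbSNP membership; tumour base coverage >= 10x (>= 20x
#' without a matched normal); VAF >= 0.1; phred-scaled site quality >= 100
#' for substitutions / >= 250 for indels; mapping quality >= 60 for indels;
#' autosomes only (chromosomes 1-22, "chr" prefixes normalized at parse);
#' and exclusion of indels within 100 bp of a variant called in the control
#' sample. All comparisons are inclusive (>=) on the stated thresholds.
#'
#' @param records `variant_table` data.frame from [read_variants()] or
#'   [gen_variant_table()].
#' @param control_positions data.frame (chrom, pos) of control-called
#'   variants, required for the indel-proximity rule when `matched_normal`.
#' @param matched_normal whether matched-normal rules apply.
#' @param config thresholds from [default_config()].
#' @return list with `verdicts` (record, pass, reasons), `attrition`
#'   (rule, n_failed, records_in, records_out) and `survivors`, the passing
#'   subset of `records`.
#' @export
apply_somatic_filters <- function(records, control_positions = NULL,
                                  matched_normal = TRUE,
                                  config = default_config()) {
  v <- config$variant
  n <- nrow(records)
  if (matched_normal && any(!records$has_normal | is.na(records$normal_depth)))
    ok_stop("input", "matched_normal = TRUE but record(s) lack normal fields")
  fails <- list()
  fails$normal_evidence <- if (matched_normal) {
    alt_ev <- !is.na(records$normal_alt_reads) &
      records$normal_alt_reads > v$normal_alt_reads_max
    gt_ev <- !is.na(records$normal_gt) &
      !(records$normal_gt %in% c("0/0", "0|0", "./."))
    alt_ev | gt_ev
  } else rep(FALSE, n)
  fails$dbsnp <- records$dbsnp %in% TRUE
  min_dp <- if (matched_normal) v$min_depth else v$min_depth_unmatched
  fails$depth <- !(records$tumour_depth >= min_dp)
  fails$vaf <- !(records$tumour_vaf >= v$min_vaf)
  req_qual <- ifelse(records$vtype == "snv", v$min_qual_snv, v$min_qual_indel)
  fails$site_qual <- !(records$site_qual >= req_qual)
  fails$mq <- records$vtype == "indel" &
    !(!is.na(records$mq) & records$mq >= v$min_mq_indel)
  fails$autosome <- !(sub("^chr", "", records$chrom) %in% as.character(1:22))
  fails$indel_proximity <- if (!is.null(control_positions) && nrow(control_positions)) {
    vapply(seq_len(n), function(i) {
      records$vtype[i] == "indel" &&
        any(control_positions$chrom == records$chrom[i] &
            abs(control_positions$pos - records$pos[i]) <= v$indel_proximity_bp)
    }, logical(1))
  } else rep(FALSE, n)

  fail_mat <- do.call(cbind, fails)
  reasons <- apply(fail_mat, 1, function(f)
    paste(names(fails)[f], collapse = ";"))
  pass <- !apply(fail_mat, 1, any)
  attrition <- data.frame(rule = names(fails),
                          n_failed = colSums(fail_mat),
                          records_in = n, records_out = sum(pass),
                          stringsAsFactors = FALSE, row.names = NULL)
  for (r in names(fails))
    ok_log("INFO", "filter %s: %d in, %d flagged", r, n, sum(fails[[r]]))
  list(verdicts = data.frame(record = seq_len(n), pass = pass,
                             reasons = unname(reasons),
                             stringsAsFactors = FALSE),
       attrition = attrition,
       survivors = records[pass, , drop = FALSE])
}

#' Signature-grade filtering of somatic substitutions
#'
#' The additional genotype-quality filter applied before signature
#' analysis: pass iff normal GQ >= 10 and tumour GQ >= 99. Only base
#' substitutions from samples with a matched normal are eligible; records
#' without a matched normal are marked ineligible (they are not used for
#' signature analysis), and indel input is an error.
#'
#' @param records somatic-passing `variant_table` rows (SNVs).
#' @param config thresholds from [default_config()].
#' @return data.frame (record, eligible, pass, reasons).
#' @export
signature_grade_filter <- function(records, config = default_config()) {
  if (any(records$vtype != "snv"))
    ok_stop("value", "signature-grade filter applies to base substitutions only")
  v <- config$variant
  eligible <- records$has_normal & !is.na(records$normal_gq)
  fail_n <- eligible & !(records$normal_gq >= v$min_gq_normal)
  fail_t <- eligible & !(records$tumour_gq >= v$min_gq_tumour)
  reasons <- mapply(function(el, fn, ft) paste(
    c(if (!el) "no_matched_normal", if (fn) "gq_normal", if (ft) "gq_tumour"),
    collapse = ";"), eligible, fail_n, fail_t)
  data.frame(record = seq_len(nrow(records)), eligible = eligible,
             pass = eligible & !fail_n & !fail_t,
             reasons = unname(reasons), stringsAsFactors = FALSE)
}

#' Candidate driver-mutation report
#'
#' Reports non-synonymous mutations (missense, start loss, stop gain,
#' inframe insertion/deletion, frameshift): all such records for samples
#' with a matched normal, and only those in known driver genes for samples
#' without one.
#'
#' @param records somatic-passing `variant_table` rows with
#'   `annotation_class` (and `gene` when `matched_normal = FALSE`).
#' @param matched_normal whether a matched normal was available.
#' @param driver_genes character vector of known driver genes, required
#'   when `matched_normal = FALSE`.
#' @param config supplies the annotation-class list.
#' @return the reported subset of `records`.
#' @export
driver_report <- function(records, matched_normal = TRUE, driver_genes = NULL,
                          config = default_config()) {
  classes <- config$variant$driver_classes
  keep <- !is.na(records$annotation_class) &
    records$annotation_class %in% classes
  if (!matched_normal) {
    if (is.null(driver_genes))
      ok_stop("config", "driver gene list required when no matched normal")
    keep <- keep & !is.na(records$gene) & records$gene %in% driver_genes
  }
  records[keep, , drop = FALSE]
}
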