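#' Read candidate somatic variant records from a VCF
#'
#' Reads a VCF 4.2 subset: columns CHROM POS ID REF ALT QUAL; FORMAT fields
#' DP, AD (or VAF) and GQ; INFO fields MQ (mapping quality), DB (dbSNP
#' membership flag) and ANN (annotation class). The first sample column is
#' taken as the tumour, the second (if present) as the matched normal.
#' Multi-allelic lines are split into one record per ALT allele; VAF is
#' computed as alt-AD over the sum of AD when no VAF field is present.
#'
#' @param path VCF file path (uncompressed).
#' @param matched_normal_expected error if no normal sample column exists.
#' @return data.frame of class `variant_table`, one row per ALT allele, with
#'   columns chrom, pos, ref, alt, vtype, site_qual, mq, dbsnp,
#'   annotation_class, tumour_depth, tumour_alt_reads, tumour_vaf, tumour_gq,
#'   normal_depth, normal_alt_reads, normal_gq, normal_gt, has_normal.
#' @export
read_variants <- function(path, matched_normal_expected = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  n_samples <- ncol(gt) - 1L
  if (n_samples < 1L) ok_stop("format", "VCF has no sample columns")
  if (matched_normal_expected && n_samples < 2L)
    ok_stop("input", "matched normal expected but VCF has a single sample column")
  info_get <- function(info, key) {  # scalar INFO string -> value or NA
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  parse_fmt <- function(fmt, sample, key, line) {
    keys <- strsplit(fmt, ":", fixed = TRUE)
    vals <- strsplit(sample, ":", fixed = TRUE)
    vapply(seq_along(keys), function(i) {
      j <- match(key, keys[[i]])
      if (is.na(j)) NA_character_ else vals[[i]][j]
    }, character(1))
  }
  require_fmt <- function(x, key) {
    miss <- which(is.na(x))
    if (length(miss))
      ok_stop("format", "FORMAT field %s missing on VCF record line %d",
              key, miss[1])
    x
  }

  fmt <- gt[, 1]
  tum <- gt[, 2]
  nor <- if (n_samples >= 2L) gt[, 3] else NULL
  has_vaf <- all(grepl("(^|:)VAF(:|$)", fmt))
  info <- fix[, "INFO"]

  recs <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    t_dp <- as.numeric(require_fmt(parse_fmt(fmt[i], tum[i], "DP", i), "DP"))
    t_gq <- as.numeric(require_fmt(parse_fmt(fmt[i], tum[i], "GQ", i), "GQ"))
    t_ad <- if (has_vaf) NULL else
      as.numeric(strsplit(require_fmt(parse_fmt(fmt[i], tum[i], "AD", i), "AD"),
                          ",", fixed = TRUE)[[1]])
    t_vaf_field <- if (has_vaf)
      as.numeric(strsplit(parse_fmt(fmt[i], tum[i], "VAF", i),
                          ",", fixed = TRUE)[[1]]) else NULL
    if (!is.null(nor)) {
      n_dp <- as.numeric(parse_fmt(fmt[i], nor[i], "DP", i))
      n_gq <- as.numeric(parse_fmt(fmt[i], nor[i], "GQ", i))
      n_ad <- suppressWarnings(
        as.numeric(strsplit(parse_fmt(fmt[i], nor[i], "AD", i) %||% NA_character_,
                            ",", fixed = TRUE)[[1]]))
      n_gt <- parse_fmt(fmt[i], nor[i], "GT", i)
    }
    ann <- info_get(info[i], "ANN")
    mq <- as.numeric(info_get(info[i], "MQ"))
    db <- grepl("(^|;)DB($|;)", info[i])
    for (k in seq_along(alts)) {
      alt <- alts[k]
      rec <- data.frame(
        chrom = sub("^chr", "", fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alt,
        vtype = if (nchar(fix[i, "REF"]) == 1L && nchar(alt) == 1L) "snv" else "indel",
        site_qual = as.numeric(fix[i, "QUAL"]),
        mq = mq, dbsnp = db,
        annotation_class = ann,
        gene = info_get(info[i], "GENE"),
        tumour_depth = t_dp,
        tumour_alt_reads = if (has_vaf) NA_real_ else t_ad[k + 1L],
        tumour_vaf = if (has_vaf) t_vaf_field[k] else t_ad[k + 1L] / sum(t_ad),
        tumour_gq = t_gq,
        normal_depth = if (is.null(nor)) NA_real_ else n_dp,
        normal_alt_reads = if (is.null(nor)) NA_real_ else
          if (length(n_ad) > k) n_ad[k + 1L] else NA_real_,
        normal_gq = if (is.null(nor)) NA_real_ else n_gq,
        normal_gt = if (is.null(nor)) NA_character_ else n_gt,
        has_normal = !is.null(nor),
        stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write variant records as a VCF
#'
#' Inverse of [read_variants()] for package-internal record tables. When a
#' `filter` character vector is supplied (one entry per record: `"PASS"` or
#' semicolon-joined rule names) it is written to the FILTER column.
#'
#' @param records `variant_table` data.frame.
#' @param path output path.
#' @param filter optional FILTER column values.
#' @export
write_variants <- function(records, path, filter = NULL) {
  if (is.null(filter)) filter <- rep(".", nrow(records))
  has_normal <- any(records$has_normal)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOUR",
           if (has_normal) "\tNORMAL" else "")
  )
  num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    info <- c(
      if (!is.na(r$mq)) paste0("MQ=", num(r$mq)),
      if (isTRUE(r$dbsnp)) "DB",
      if (!is.na(r$annotation_class)) paste0("ANN=", r$annotation_class),
      if (!is.na(r$gene)) paste0("GENE=", r$gene))
    info <- if (length(info)) paste(info, collapse = ";") else "."
    t_ref <- max(0, round(r$tumour_depth - r$tumour_alt_reads))
    tum <- sprintf("0/1:%s:%s,%s:%s", num(r$tumour_depth), num(t_ref),
                   num(r$tumour_alt_reads), num(r$tumour_gq))
    nor <- if (has_normal && isTRUE(r$has_normal)) {
      n_dp <- if (is.na(r$normal_depth)) 0 else r$normal_depth
      n_alt <- if (is.na(r$normal_alt_reads)) 0 else r$normal_alt_reads
      n_gt <- if (is.na(r$normal_gt)) "0/0" else r$normal_gt
      sprintf("\t%s:%s:%s,%s:%s", n_gt, num(r$normal_depth),
              num(max(0, round(n_dp - n_alt))), num(r$normal_alt_reads),
              num(r$normal_gq))
    } else if (has_normal) "\t.:.:.:." else ""
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s\tGT:DP:AD:GQ\t%s%s",
            r$chrom, r$pos, r$ref, r$alt, num(r$site_qual), filter[i],
            info, tum, nor)
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
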