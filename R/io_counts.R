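#' Gene-by-cell count matrix container
#'
#' Thin container around an integer genes x cells matrix of UMI-deduplicated
#' transcript counts plus per-gene annotation (chromosome, mitochondrial
#' flag, symbol).
#'
#' @param counts integer matrix, genes in rows, cells in columns, with
#'   dimnames.
#' @param gene_info optional data.frame with columns `gene` and any of
#'   `chromosome`, `is_mito`, `symbol`; joined by gene identifier. When
#'   `is_mito` is absent it is derived from `chromosome %in% c("MT","chrM")`.
#' @return list of class `count_matrix` with elements `counts` and `genes`.
#' @export
count_matrix <- function(counts, gene_info = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    ok_stop("format", "count matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(m)))
    ok_stop("format", "duplicate gene identifier: %s",
            rownames(m)[duplicated(rownames(m))][1])
  if (anyDuplicated(colnames(m)))
    ok_stop("format", "duplicate cell barcode: %s",
            colnames(m)[duplicated(colnames(m))][1])
  if (any(m < 0) || any(m != round(m)))
    ok_stop("value", "counts must be non-negative integers")
  storage.mode(m) <- "double"
  genes <- data.frame(gene = rownames(m), chromosome = NA_character_,
                      is_mito = FALSE, symbol = rownames(m),
                      stringsAsFactors = FALSE)
  if (!is.null(gene_info)) {
    if (!"gene" %in% names(gene_info))
      ok_stop("format", "gene_info must have a 'gene' column")
    idx <- match(genes$gene, gene_info$gene)
    for (col in intersect(c("chromosome", "symbol"), names(gene_info)))
      genes[[col]] <- ifelse(is.na(idx), genes[[col]],
                             as.character(gene_info[[col]])[idx])
    if ("is_mito" %in% names(gene_info)) {
      gi <- as.logical(gene_info$is_mito)[idx]
      genes$is_mito <- ifelse(is.na(gi), FALSE, gi)
    } else {
      genes$is_mito <- !is.na(genes$chromosome) &
        genes$chromosome %in% c("MT", "chrM", "chrMT", "M")
    }
  }
  structure(list(counts = m, genes = genes), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$genes$is_mito)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

subset_count_matrix <- function(x, genes = NULL, cells = NULL) {
  m <- x$counts
  gi <- x$genes
  if (!is.null(genes)) { m <- m[genes, , drop = FALSE]; gi <- gi[genes, , drop = FALSE] }
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  rownames(gi) <- NULL
  structure(list(counts = m, genes = gi), class = "count_matrix")
}

#' Read a gene x cell count matrix
#'
#' Reads either a dense TSV (gene-identifier first column, one column per
#' cell) or an MTX triplet (`<stem>.mtx` plus `<stem>.genes.txt` and
#' `<stem>.barcodes.txt`, one identifier per line). MTX is interpreted as
#' genes x cells.
#'
#' @param path path to the dense TSV or to the `.mtx` file.
#' @param gene_info optional annotation data.frame or TSV path (columns
#'   `gene`, `chromosome`, optionally `is_mito`, `symbol`).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, gene_info = NULL) {
  if (is.character(gene_info)) gene_info <- read_gene_info(gene_info)
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    gfile <- paste0(stem, ".genes.txt")
    bfile <- paste0(stem, ".barcodes.txt")
    if (!file.exists(gfile) || !file.exists(bfile))
      ok_stop("format", "MTX sidecar files missing for %s", path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gfile)
    cells <- readLines(bfile)
    if (length(genes) != nrow(m))
      ok_stop("format", "gene file has %d lines but MTX declares %d rows",
              length(genes), nrow(m))
    if (length(cells) != ncol(m))
      ok_stop("format", "barcode file has %d lines but MTX declares %d columns",
              length(cells), ncol(m))
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m) || anyNA(m) || any(m != round(m)))
      ok_stop("value", "count TSV has non-integer entries")
    rownames(m) <- as.character(df[[1]])
  }
  count_matrix(m, gene_info = gene_info)
}

#' @rdname read_counts
#' @param x a `count_matrix`.
#' @param format `"tsv"` (dense) or `"mtx"` (triplet).
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(x$counts), x$counts,
                     check.names = FALSE, row.names = NULL)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    paste0(stem, ".mtx"))
    writeLines(rownames(x$counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(x$counts), paste0(stem, ".barcodes.txt"))
  }
  invisible(path)
}

#' @rdname read_counts
#' @export
read_gene_info <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_counts
#' @param genes gene annotation data.frame.
#' @export
write_gene_info <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
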