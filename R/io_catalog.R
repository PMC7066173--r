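#' Canonical 96 single-base-substitution channels
#'
#' Channels follow the COSMIC convention: substitution classes ordered
#' C>A, C>G, C>T, T>A, T>C, T>G, each with its 16 trinucleotide contexts in
#' alphabetical flank order, labelled as e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))
  }))
}

#' Normalize a substitution-channel label
#'
#' Accepts the bracket form `"A[C>A]A"` or the trinucleotide-pair form
#' `"ACA>AAA"` and returns the canonical bracket form.
#'
#' @param x character vector of channel labels.
#' @return character vector of canonical labels.
#' @export
normalize_channel <- function(x) {
  out <- character(length(x))
  bracket <- grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", x)
  out[bracket] <- x[bracket]
  pair <- grepl("^[ACGT]{3}>[ACGT]{3}$", x) & !bracket
  if (any(pair)) {
    ref <- substr(x[pair], 1, 3)
    alt <- substr(x[pair], 5, 7)
    if (any(substr(ref, 1, 1) != substr(alt, 1, 1) |
            substr(ref, 3, 3) != substr(alt, 3, 3) |
            substr(ref, 2, 2) == substr(alt, 2, 2)))
      ok_stop("format", "trinucleotide pair with mismatched flanks or unchanged base: %s",
              paste(x[pair][1], collapse = ""))
    out[pair] <- paste0(substr(ref, 1, 1), "[", substr(ref, 2, 2), ">",
                        substr(alt, 2, 2), "]", substr(ref, 3, 3))
  }
  bad <- !bracket & !pair
  if (any(bad))
    ok_stop("format", "unrecognized channel label(s): %s",
            paste(utils::head(x[bad], 3), collapse = ", "))
  valid <- out %in% sbs_channels()
  if (!all(valid))
    ok_stop("format", "label(s) not a pyrimidine-context SBS channel: %s",
            paste(utils::head(out[!valid], 3), collapse = ", "))
  out
}

#' Read a 96-channel mutation catalog
#'
#' Reads a TSV with one channel-label column (first) and one column of
#' non-negative counts per sample. Rows may be in any order; the returned
#' matrix always has the canonical channel order of [sbs_channels()].
#'
#' @param path TSV file path.
#' @return Numeric 96 x n_samples matrix, rownames = canonical channels,
#'   colnames = sample names.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    ok_stop("format", "catalog must have a channel column plus >=1 sample column")
  labels <- normalize_channel(as.character(df[[1]]))
  if (anyDuplicated(labels))
    ok_stop("format", "duplicate channel label: %s",
            labels[duplicated(labels)][1])
  missing <- setdiff(sbs_channels(), labels)
  if (length(missing))
    ok_stop("format", "catalog missing %d channel(s): %s", length(missing),
            paste(utils::head(missing, 4), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    ok_stop("value", "negative count at channel %s, sample '%s'",
            labels[neg[1, 1]], colnames(m)[neg[1, 2]])
  if (anyNA(m)) ok_stop("value", "non-numeric entries in catalog %s", path)
  rownames(m) <- labels
  m[sbs_channels(), , drop = FALSE]
}

#' @rdname read_catalog
#' @param catalog 96 x n matrix as returned by `read_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(nrow(catalog) == 96L)
  df <- data.frame(channel = rownames(catalog), catalog,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a signature reference set
#'
#' @param matrix 96 x K non-negative matrix; columns are renormalized to sum
#'   to one and reordered to canonical channel order if rownames present.
#' @param forced signature names assumed present in every sample (the
#'   clock-like signatures; default SBS1 and SBS5).
#' @param exclude signature names dropped from the set on load (e.g. SBS40,
#'   which is hard to distinguish from SBS5 in small cohorts).
#' @return list of class `signature_set` with elements `names`, `matrix`
#'   (column-stochastic), `forced`.
#' @export
signature_set <- function(matrix, forced = c("SBS1", "SBS5"), exclude = character()) {
  m <- as.matrix(matrix)
  if (nrow(m) != 96L) ok_stop("format", "signature matrix must have 96 rows")
  if (is.null(colnames(m))) ok_stop("format", "signature columns must be named")
  if (!is.null(rownames(m))) {
    rownames(m) <- normalize_channel(rownames(m))
    m <- m[sbs_channels(), , drop = FALSE]
  } else rownames(m) <- sbs_channels()
  if (length(exclude)) m <- m[, !(colnames(m) %in% exclude), drop = FALSE]
  if (any(m < 0)) ok_stop("value", "signature matrix has negative entries")
  tot <- colSums(m)
  if (any(tot <= 0)) ok_stop("value", "signature column sums to zero")
  m <- sweep(m, 2, tot, "/")
  missing <- setdiff(forced, colnames(m))
  if (length(missing))
    ok_stop("config", "forced signature(s) absent from reference set: %s",
            paste(missing, collapse = ", "))
  structure(list(names = colnames(m), matrix = m, forced = forced),
            class = "signature_set")
}

#' Read / write a signature reference TSV
#'
#' Same layout as catalogs: channel-label column plus one probability column
#' per signature.
#'
#' @param path TSV path.
#' @param forced,exclude passed to [signature_set()].
#' @return a `signature_set`.
#' @export
read_signatures <- function(path, forced = c("SBS1", "SBS5"), exclude = character()) {
  m <- read_catalog(path)  # same tabular contract
  signature_set(m, forced = forced, exclude = exclude)
}

#' @rdname read_signatures
#' @param sigs a `signature_set`.
#' @export
write_signatures <- function(sigs, path) {
  write_catalog(sigs$matrix, path)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d signatures x 96 channels\n", length(x$names)))
  cat("  signatures:", paste(x$names, collapse = ", "), "\n")
  cat("  forced    :", paste(x$forced, collapse = ", "), "\n")
  invisible(x)
}
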