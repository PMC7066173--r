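#' Cosine similarity between two mutation spectra
#'
#' The fit-quality criterion of the signature refit: the normalized dot
#' product `a.b / (||a|| ||b||)`. Symmetric and invariant to rescaling of
#' either vector; for non-negative spectra the value lies in \[0, 1\].
#'
#' @param a,b non-negative numeric vectors of equal length, each with at
#'   least one nonzero entry.
#' @return cosine similarity in \[0, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) ok_stop("value", "vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    ok_stop("value", "cosine similarity undefined for an all-zero vector")
  sum(a * b) / (na * nb)
}

#' Non-negative least-squares signature exposures
#'
#' Solves `min ||counts - S e||_2` subject to `e >= 0` (Lawson-Hanson NNLS)
#' for a profile against a subset of reference signatures. Exposures are on
#' the mutation-count scale.
#'
#' @param profile numeric 96-vector of channel counts.
#' @param sig_matrix 96 x k column-stochastic matrix (columns named).
#' @return named non-negative exposure vector of length k.
#' @export
refit_exposures <- function(profile, sig_matrix) {
  sig_matrix <- as.matrix(sig_matrix)
  if (ncol(sig_matrix) < 1L) ok_stop("value", "signature subset is empty")
  if (length(profile) != nrow(sig_matrix))
    ok_stop("value", "profile length does not match signature matrix rows")
  if (all(profile == 0)) {
    e <- rep(0, ncol(sig_matrix))
  } else {
    e <- pracma::lsqnonneg(sig_matrix, as.numeric(profile))$x
  }
  names(e) <- colnames(sig_matrix)
  e
}

#' Reconstruct a spectrum from signatures and exposures
#'
#' @param sig_matrix 96 x k signature matrix.
#' @param exposures length-k exposure vector.
#' @return numeric 96-vector `sig_matrix %*% exposures`.
#' @export
reconstruct <- function(sig_matrix, exposures) {
  sig_matrix <- as.matrix(sig_matrix)
  if (ncol(sig_matrix) != length(exposures))
    ok_stop("value", "exposure length does not match signature count")
  as.numeric(sig_matrix %*% exposures)
}

#' Greedy forward selection of mutational signatures
#'
#' Refits a sample's 96-channel profile to the forced clock-like signatures
#' (SBS1 and SBS5 by default, assumed present in all samples), then
#' repeatedly adds the candidate signature giving the largest increase in
#' cosine similarity between profile and reconstruction. Selection stops
#' when the cosine similarity reaches `cos_target` (checked after every
#' refit, including the initial forced one), when the best achievable gain
#' drops below `min_gain` (that candidate is *not* added), or when no
#' candidates remain. Candidate evaluation refits all selected signatures
#' plus the candidate jointly; ties in gain are broken by reference-set
#' column order.
#'
#' @param profile numeric 96-vector (a sample's mutation catalog column).
#' @param signatures a [signature_set()].
#' @param cos_target cosine-similarity target (default 0.9).
#' @param min_gain minimum cosine increase to accept another signature
#'   (default 0.01; a candidate with gain `< min_gain` is rejected).
#' @param sample_id optional label carried into the result.
#' @return object of class `sig_refit`: `selected` (forced names first),
#'   `exposures` (mutation-count scale), `relative_contributions`,
#'   `cosine_trace` (one value after the forced refit and after each
#'   addition), `final_cosine`, `stop_reason` (one of `target_reached`,
#'   `gain_below_threshold`, `candidates_exhausted`), `total`.
#' @export
greedy_select <- function(profile, signatures, cos_target = 0.9,
                          min_gain = 0.01, sample_id = "sample") {
  if (!inherits(signatures, "signature_set"))
    ok_stop("value", "signatures must be a signature_set")
  missing <- setdiff(signatures$forced, signatures$names)
  if (length(missing))
    ok_stop("config", "forced signature(s) not in reference set: %s",
            paste(missing, collapse = ", "))
  profile <- as.numeric(profile)
  if (all(profile == 0))
    ok_stop("value", "profile has zero mutations; nothing to refit")
  S <- signatures$matrix

  selected <- signatures$forced
  e <- refit_exposures(profile, S[, selected, drop = FALSE])
  cur <- cosine_similarity(reconstruct(S[, selected, drop = FALSE], e), profile)
  trace <- cur
  stop_reason <- NULL
  repeat {
    if (cur >= cos_target) { stop_reason <- "target_reached"; break }
    candidates <- setdiff(signatures$names, selected)
    if (!length(candidates)) { stop_reason <- "candidates_exhausted"; break }
    cand_cos <- vapply(candidates, function(nm) {
      sub <- c(selected, nm)
      ei <- refit_exposures(profile, S[, sub, drop = FALSE])
      rec <- reconstruct(S[, sub, drop = FALSE], ei)
      if (all(rec == 0)) 0 else cosine_similarity(rec, profile)
    }, numeric(1))
    best_cos <- max(cand_cos)
    # ties (within 1e-12) broken by reference column order
    best <- candidates[which(cand_cos >= best_cos - 1e-12)[1]]
    gain <- cand_cos[best] - cur
    if (gain < min_gain) { stop_reason <- "gain_below_threshold"; break }
    selected <- c(selected, best)
    cur <- cand_cos[[best]]
    trace <- c(trace, cur)
  }
  e <- refit_exposures(profile, S[, selected, drop = FALSE])
  tot_e <- sum(e)
  structure(list(
    sample_id = sample_id,
    selected = selected,
    exposures = e,
    relative_contributions = if (tot_e > 0) e / tot_e else e,
    cosine_trace = trace,
    final_cosine = trace[length(trace)],
    stop_reason = stop_reason,
    total = sum(profile)
  ), class = "sig_refit")
}

#' @export
print.sig_refit <- function(x, ...) {
  cat(sprintf("Greedy signature refit: %s (%s mutations)\n",
              x$sample_id, format(round(x$total))))
  cat(sprintf("  selected : %s\n", paste(x$selected, collapse = " + ")))
  cat(sprintf("  cosine   : %s (stop: %s)\n",
              paste(sprintf("%.4f", x$cosine_trace), collapse = " -> "),
              x$stop_reason))
  cat("  exposures:\n")
  print(round(x$exposures, 1))
  invisible(x)
}

#' @export
coef.sig_refit <- function(object, ...) object$exposures

#' Refit a whole catalog of samples
#'
#' Runs [greedy_select()] on every sample column of a catalog and collects
#' one row per sample: total base substitutions, selected signatures,
#' absolute exposure per selected signature, final cosine similarity and
#' stop reason. Samples with zero mutations are flagged and skipped.
#'
#' @param catalog 96 x n matrix from [read_catalog()] or [gen_catalog()].
#' @param signatures a [signature_set()].
#' @param config configuration from [default_config()].
#' @return list with `table` (one summary row per sample; exposure columns
#'   `exp_<signature>` are NA for unselected signatures), `trace` (long
#'   data.frame sample/step/signature/cosine) and `fits` (the `sig_refit`
#'   objects).
#' @export
refit_cohort <- function(catalog, signatures, config = default_config()) {
  samples <- colnames(catalog)
  fits <- vector("list", length(samples))
  names(fits) <- samples
  rows <- list(); traces <- list()
  for (s in samples) {
    prof <- catalog[, s]
    if (sum(prof) == 0) {
      rows[[s]] <- data.frame(sample = s, total = 0, n_selected = 0,
                              selected = "", final_cosine = NA_real_,
                              stop_reason = "empty_profile",
                              stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(
      greedy_select(prof, signatures,
                    cos_target = config$signature$cos_target,
                    min_gain = config$signature$min_gain, sample_id = s),
      organoidkit_error = function(e)
        ok_stop("value", "sample '%s': %s", s, conditionMessage(e)))
    fits[[s]] <- fit
    rows[[s]] <- data.frame(sample = s, total = fit$total,
                            n_selected = length(fit$selected),
                            selected = paste(fit$selected, collapse = ","),
                            final_cosine = fit$final_cosine,
                            stop_reason = fit$stop_reason,
                            stringsAsFactors = FALSE)
    traces[[s]] <- data.frame(
      sample = s, step = seq_along(fit$cosine_trace),
      signature = c(paste(signatures$forced, collapse = "+"),
                    fit$selected[-seq_along(signatures$forced)]),
      cosine = fit$cosine_trace, stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  # wide exposure columns across the union of selected signatures
  all_sel <- unique(unlist(lapply(fits[!vapply(fits, is.null, logical(1))],
                                  function(f) f$selected)))
  for (sig in all_sel) {
    table[[paste0("exp_", sig)]] <- vapply(table$sample, function(s) {
      f <- fits[[s]]
      if (is.null(f) || !(sig %in% f$selected)) NA_real_
      else unname(f$exposures[sig])
    }, numeric(1))
  }
  rownames(table) <- NULL
  list(table = table, trace = do.call(rbind, c(traces, list(make.row.names = FALSE))),
       fits = fits)
}
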