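#' Default run configuration
#'
#' All thresholds used across the pipeline, as named, overridable parameters.
#' Defaults are the values used throughout the organoid-biobank study design
#' this package implements: cosine-similarity target 0.9 and minimum gain
#' 0.01 for greedy signature selection with clock-like signatures SBS1/SBS5
#' forced; 40% mitochondrial-fraction and 1000-transcript cell cutoffs;
#' 5-cell / 2-cells-with-2-transcripts gene filter; log-normalization to
#' 10,000 transcripts; 1.8-fold and 5% Bonferroni marker cutoffs; the somatic
#' hard-filter thresholds (10x/20x coverage, VAF 0.1, site quality 100/250,
#' MQ 60 for indels, GQ 10/99, 100 bp indel proximity, autosomes only); and
#' 6-concentration, 4-replicate drug-screen plates.
#'
#' @param ... named overrides using dotted paths, e.g.
#'   `default_config(signature.cos_target = 0.95)`.
#' @return A nested named list of class `ok_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$signature$cos_target
default_config <- function(...) {
  cfg <- list(
    signature = list(
      cos_target  = 0.9,
      min_gain    = 0.01,
      forced_ids  = c("SBS1", "SBS5"),
      exclude_ids = c("SBS40")
    ),
    sc = list(
      max_mito_frac    = 0.40,
      min_transcripts  = 1000,
      gene_min_cells   = 5,
      gene_min_cells_ge2 = 2,
      norm_scale       = 10000,
      cycle_n_bins     = 24,
      cycle_n_ctrl     = 100
    ),
    de = list(
      fold_cutoff = 1.8,
      alpha       = 0.05
    ),
    variant = list(
      min_depth            = 10,
      min_depth_unmatched  = 20,
      min_vaf              = 0.1,
      min_qual_snv         = 100,
      min_qual_indel       = 250,
      min_mq_indel         = 60,
      min_gq_normal        = 10,
      min_gq_tumour        = 99,
      indel_proximity_bp   = 100,
      normal_alt_reads_max = 0,
      driver_classes = c("missense", "start_lost", "stop_gained",
                         "inframe_indel", "frameshift")
    ),
    drc = list(
      n_concentrations = 6,
      replicates       = 4
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(path) != 2L || is.null(cfg[[path[1]]]))
      ok_stop("config", "unknown configuration key '%s'", nm)
    cfg[[path[1]]][[path[2]]] <- dots[[nm]]
  }
  class(cfg) <- c("ok_config", "list")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks every threshold is finite and within its domain (fractions in
#' \[0,1\], counts non-negative, fold cutoff > 1).
#'
#' @param cfg configuration list as from [default_config()].
#' @return `cfg`, invisibly, or an error describing the offending field.
#' @export
validate_config <- function(cfg) {
  s <- cfg$signature
  stopifnot_scalar_number(s$cos_target, "signature.cos_target", 0, 1)
  stopifnot_scalar_number(s$min_gain, "signature.min_gain", 0, 1)
  if (!is.character(s$forced_ids) || length(s$forced_ids) < 1L)
    ok_stop("config", "signature.forced_ids must name at least one signature")
  sc <- cfg$sc
  stopifnot_scalar_number(sc$max_mito_frac, "sc.max_mito_frac", 0, 1)
  stopifnot_scalar_number(sc$min_transcripts, "sc.min_transcripts", 0)
  stopifnot_scalar_number(sc$gene_min_cells, "sc.gene_min_cells", 0)
  stopifnot_scalar_number(sc$gene_min_cells_ge2, "sc.gene_min_cells_ge2", 0)
  stopifnot_scalar_number(sc$norm_scale, "sc.norm_scale", 1)
  de <- cfg$de
  if (!is.numeric(de$fold_cutoff) || de$fold_cutoff <= 1)
    ok_stop("config", "de.fold_cutoff must be a ratio > 1 (got %s)",
            format(de$fold_cutoff))
  stopifnot_scalar_number(de$alpha, "de.alpha", 0, 1)
  v <- cfg$variant
  for (f in c("min_depth", "min_depth_unmatched", "min_qual_snv",
              "min_qual_indel", "min_mq_indel", "min_gq_normal",
              "min_gq_tumour", "indel_proximity_bp", "normal_alt_reads_max"))
    stopifnot_scalar_number(v[[f]], paste0("variant.", f), 0)
  stopifnot_scalar_number(v$min_vaf, "variant.min_vaf", 0, 1)
  d <- cfg$drc
  stopifnot_scalar_number(d$n_concentrations, "drc.n_concentrations", 2)
  stopifnot_scalar_number(d$replicates, "drc.replicates", 1)
  invisible(cfg)
}

#' Read / write configuration files
#'
#' YAML serialization that round-trips bit-identically: `read_config()` on a
#' file produced by `write_config()` returns an identical configuration.
#'
#' @param cfg configuration list.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `ok_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ok_stop("config", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(raw)) {
    if (is.null(base[[sec]])) ok_stop("config", "unknown config section '%s'", sec)
    for (k in names(raw[[sec]])) {
      val <- raw[[sec]][[k]]
      # YAML narrows types (1000 -> integer, single strings -> scalar);
      # coerce back to the storage mode of the default so reload is identical
      if (is.numeric(base[[sec]][[k]])) val <- as.numeric(val)
      if (is.character(base[[sec]][[k]])) val <- as.character(val)
      base[[sec]][[k]] <- val
    }
  }
  validate_config(base)
  base
}
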