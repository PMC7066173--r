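#' Read / write drug-screen plate readings
#'
#' Plate CSVs carry one row per well with columns `well`, `compound`,
#' `concentration_nM`, `replicate`, `reading` (raw luminescence) and `role`
#' (one of `test`, `dmso`, `staurosporine`). DMSO wells are the vehicle
#' (100% viability) reference; staurosporine wells are the kill control.
#'
#' @param path CSV file path.
#' @return data.frame of class `plate_readings`.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "compound", "concentration_nM", "replicate", "reading", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ok_stop("format", "plate CSV missing column(s): %s", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(df$role), c("test", "dmso", "staurosporine"))
  if (length(bad_role))
    ok_stop("format", "unknown well role(s): %s", paste(bad_role, collapse = ", "))
  if (!any(df$role == "dmso"))
    ok_stop("format", "plate has no DMSO vehicle wells")
  if (any(df$role == "test" & !(df$concentration_nM > 0)))
    ok_stop("value", "test-well concentrations must be positive")
  class(df) <- c("plate_readings", "data.frame")
  df
}

#' @rdname read_plate
#' @param plate `plate_readings` data.frame.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
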