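#' Four-parameter logistic curve
#'
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)` — the standard
#' variable-slope dose-response family. With `hill > 0` the curve decreases
#' from `top` (no drug) to `bottom` (saturating drug); `ic50` is the
#' midpoint concentration.
#'
#' @param conc concentration(s), same units as `ic50`.
#' @param top,bottom asymptotic viabilities (%).
#' @param ic50 midpoint concentration.
#' @param hill slope.
#' @return viability value(s).
#' @export
pl4 <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Normalize plate readings to DMSO vehicle viability
#'
#' `viability = 100 * reading / mean(DMSO readings)`, per plate, so the
#' mean of the vehicle wells maps to exactly 100%.
#'
#' @param plate `plate_readings` data.frame from [read_plate()] or
#'   [gen_plate()].
#' @return the plate with a `viability` column added.
#' @export
normalize_viability <- function(plate) {
  dmso <- plate$reading[plate$role == "dmso"]
  if (!length(dmso)) ok_stop("value", "no DMSO wells on plate")
  ref <- mean(dmso)
  if (!is.finite(ref) || ref <= 0)
    ok_stop("value", "DMSO mean reading must be positive (got %s)", format(ref))
  plate$viability <- 100 * plate$reading / ref
  plate
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [pl4()] on log10 concentration via bounded
#' Levenberg-Marquardt, with technical replicates averaged per
#' concentration before fitting. Bounds: top in \[50, 150\], bottom in
#' \[-10, 60\], hill in \[0.1, 10\], IC50 within 100x of the tested range.
#' Initialization uses three fixed starts (IC50 at the 25/50/75% points of
#' the log-concentration range) so the fit is deterministic; the best
#' converged start by residual sum of squares wins.
#'
#' @param conc concentrations (one per well; replicates share a value).
#' @param viability normalized viabilities (%) from [normalize_viability()].
#' @param compound optional label carried into the fit.
#' @return object of class `pl4_fit` with elements `coefficients`
#'   (top, bottom, ic50, hill), `ic50_reached`, `ic50_reported`, `auc`,
#'   `rmse`, `data` (averaged points), `conc_range`. Supports `print`,
#'   `coef`, `predict`, `plot`, `residuals`.
#' @export
fit_4pl <- function(conc, viability, compound = "compound") {
  keep <- is.finite(conc) & is.finite(viability) & conc > 0
  conc <- conc[keep]; viability <- viability[keep]
  mean_v <- tapply(viability, conc, mean)
  cc <- as.numeric(names(mean_v))
  o <- order(cc); cc <- cc[o]; vv <- as.numeric(mean_v)[o]
  if (length(cc) < 4L)
    ok_stop("value", "need >= 4 distinct concentrations (got %d)", length(cc))
  lc <- log10(cc)
  lo <- c(top = 50, bottom = -10, lic50 = min(lc) - 2, hill = 0.1)
  hi <- c(top = 150, bottom = 60, lic50 = max(lc) + 2, hill = 10)
  clamp <- function(x, a, b) pmin(pmax(x, a), b)
  starts <- lapply(c(0.25, 0.5, 0.75), function(q) list(
    top = clamp(max(vv), 50, 150), bottom = clamp(min(vv), -10, 60),
    lic50 = min(lc) + q * (max(lc) - min(lc)), hill = 1))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        vv ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
        start = st, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    ok_stop("fit", "4PL fit failed to converge for %s (range %g-%g, viab %g-%g)",
            compound, min(cc), max(cc), min(vv), max(vv))
  cf <- stats::coef(best$fit)
  coefs <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
             ic50 = unname(10^cf["lic50"]), hill = unname(cf["hill"]))
  obj <- structure(list(
    compound = compound, coefficients = coefs,
    data = data.frame(conc = cc, viability = vv),
    conc_range = range(cc),
    rmse = sqrt(best$rss / length(vv))), class = "pl4_fit")
  rep <- ic50_report(obj)
  obj$ic50_reached <- rep$ic50_reached
  obj$ic50_reported <- rep$ic50_reported
  obj$auc <- auc_4pl(obj)
  obj
}

#' @export
coef.pl4_fit <- function(object, ...) object$coefficients

#' @export
predict.pl4_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.list(newdata)) newdata$conc else newdata
  cf <- object$coefficients
  pl4(conc, cf[["top"]], cf[["bottom"]], cf[["ic50"]], cf[["hill"]])
}

#' @export
residuals.pl4_fit <- function(object, ...) {
  object$data$viability - predict(object)
}

#' @export
print.pl4_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("4PL dose-response fit: %s\n", x$compound))
  cat(sprintf("  top %.1f%%  bottom %.1f%%  hill %.2f  rmse %.2f\n",
              cf["top"], cf["bottom"], cf["hill"], x$rmse))
  cat(sprintf("  IC50 %s: %.4g (reported %.4g)\n",
              if (x$ic50_reached) "reached" else "NOT reached (max tested conc used)",
              cf["ic50"], x$ic50_reported))
  cat(sprintf("  AUC (mean viability over log range): %.1f\n", x$auc))
  invisible(x)
}

#' @export
plot.pl4_fit <- function(x, ...) {
  d <- x$data
  grid <- 10^seq(log10(x$conc_range[1]), log10(x$conc_range[2]), length.out = 200)
  plot(d$conc, d$viability, log = "x", xlab = "concentration",
       ylab = "viability (%)", main = x$compound, ylim = range(0, 110, d$viability), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}

#' IC50 with the not-reached fallback
#'
#' The IC50 counts as reached iff the fitted curve attains viability
#' <= 50% at some concentration within the tested range; otherwise the
#' highest tested concentration is reported, flagged.
#'
#' @param fit a `pl4_fit`.
#' @param concentrations tested concentrations (defaults to the fit's).
#' @return list with `ic50_reached` and `ic50_reported`.
#' @export
ic50_report <- function(fit, concentrations = NULL) {
  rng <- if (is.null(concentrations)) fit$conc_range else range(concentrations)
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 512)
  reached <- min(predict(fit, grid)) <= 50
  list(ic50_reached = reached,
       ic50_reported = if (reached) unname(fit$coefficients["ic50"]) else rng[2])
}

# Mean fitted viability over the tested log10-concentration range:
# integral of the fitted curve d(log10 c), divided by the span.
auc_4pl <- function(fit, n_grid = 512) {
  l1 <- log10(fit$conc_range[1]); l2 <- log10(fit$conc_range[2])
  lg <- seq(l1, l2, length.out = n_grid)
  v <- predict(fit, 10^lg)
  trap <- sum((v[-1] + v[-n_grid]) / 2 * diff(lg))
  trap / (l2 - l1)
}

#' Rank compounds by dose-response AUC
#'
#' AUC is the mean fitted viability over the tested log-concentration
#' range (0-100 scale); compounds are sorted ascending, so the most
#' effective come first. Ties are broken by compound name.
#'
#' @param fits list of `pl4_fit` objects.
#' @return data.frame (rank, compound, auc, ic50_reported, ic50_reached,
#'   top, bottom, hill, rmse).
#' @export
auc_rank <- function(fits) {
  spans <- vapply(fits, function(f) diff(log10(f$conc_range)), numeric(1))
  if (length(unique(round(spans, 6))) > 1L)
    warning("compounds fitted on different log-concentration spans; AUCs are per-span means")
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    compound = f$compound, auc = f$auc,
    ic50_reported = f$ic50_reported, ic50_reached = f$ic50_reached,
    top = unname(f$coefficients["top"]), bottom = unname(f$coefficients["bottom"]),
    hill = unname(f$coefficients["hill"]), rmse = f$rmse,
    stringsAsFactors = FALSE)))
  tab <- tab[order(tab$auc, tab$compound), , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Compare IC50 values between lines or groups
#'
#' Two-sample two-tailed Student's t-tests (equal variance by default) on
#' per-experiment mean IC50 values, for every pair of groups with at least
#' two values each; smaller groups are skipped with a warning.
#'
#' @param values numeric IC50 values (each the mean of technical
#'   quadruplicates from one independent experiment).
#' @param groups grouping factor/character, same length as `values`.
#' @param var_equal use the equal-variance Student form (default TRUE;
#'   FALSE gives Welch).
#' @return data.frame (group1, group2, n1, n2, mean1, mean2, t, p_value).
#' @export
compare_groups <- function(values, groups, var_equal = TRUE) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  out <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    x <- values[groups == gs[i]]; y <- values[groups == gs[j]]
    if (length(x) < 2L || length(y) < 2L) {
      warning(sprintf("group pair %s/%s has <2 values; skipped", gs[i], gs[j]))
      next
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    out[[length(out) + 1L]] <- data.frame(
      group1 = gs[i], group2 = gs[j], n1 = length(x), n2 = length(y),
      mean1 = mean(x), mean2 = mean(y),
      t = unname(tt$statistic), p_value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(group1 = character(), group2 = character(),
                                      n1 = integer(), n2 = integer(),
                                      mean1 = numeric(), mean2 = numeric(),
                                      t = numeric(), p_value = numeric()))
  do.call(rbind, out)
}

#' Full drug-screen analysis of one plate
#'
#' Normalizes to DMSO, fits a 4PL per compound (replicates averaged), and
#' returns the fits plus the AUC ranking table.
#'
#' @param plate `plate_readings` data.frame.
#' @return list with `fits` (named list of `pl4_fit`), `ranking`
#'   (from [auc_rank()]) and `viability` (the normalized plate).
#' @export
drc_analyse <- function(plate) {
  norm <- normalize_viability(plate)
  test <- norm[norm$role == "test", ]
  compounds <- sort(unique(test$compound))
  fits <- lapply(compounds, function(cp) {
    d <- test[test$compound == cp, ]
    fit_4pl(d$concentration_nM, d$viability, compound = cp)
  })
  names(fits) <- compounds
  list(fits = fits, ranking = auc_rank(fits), viability = norm)
}
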