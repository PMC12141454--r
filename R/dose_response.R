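# Dose-response processing: plate normalization, clamping with QC flags,
# curve fitting (OLS or probit on log10 concentration), numeric AUC, and
# replicate harmonization with divergence flags.

#' Normalize raw plate signals to viability
#'
#' Viability is computed per plate (a `sample_id` x `panel_id` x `replicate`
#' group) as `(signal - blank mean) / (control mean - blank mean)` using the
#' plate's negative-control (cells, no drug) and blank (no cells) wells.
#' Blank subtraction can be disabled, in which case viability is
#' `signal / control mean`.
#'
#' @param plate data.frame with columns sample_id, drug_id, panel_id,
#'   replicate, conc_uM, signal, well_type (`treated`, `control`, `blank`).
#' @param subtract_blank subtract the blank-well mean (default TRUE).
#' @return The treated rows with a `viability` column appended (unclamped).
#' @export
normalize_plate <- function(plate, subtract_blank = TRUE) {
  need <- c("sample_id", "panel_id", "replicate", "signal", "well_type")
  if (!all(need %in% names(plate))) {
    .fail("plate table must have columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(plate$sample_id, plate$panel_id, plate$replicate,
                     drop = TRUE)
  out <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    p <- plate[key == levels(key)[i], , drop = FALSE]
    ctrl <- p$signal[p$well_type == "control"]
    if (length(ctrl) < 1) {
      .fail("plate ", levels(key)[i], " has no control wells")
    }
    blank <- if (subtract_blank) p$signal[p$well_type == "blank"] else numeric()
    blank_mean <- if (length(blank) > 0) mean(blank) else 0
    ctrl_mean <- mean(ctrl)
    if (ctrl_mean <= blank_mean) {
      .fail("plate failure: control mean <= blank mean on plate ",
            levels(key)[i])
    }
    tr <- p[p$well_type == "treated", , drop = FALSE]
    tr$viability <- (tr$signal - blank_mean) / (ctrl_mean - blank_mean)
    out[[i]] <- tr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clamp viability to [0, 1] and flag negative values
#'
#' Applies a ceiling of 1 and a floor of 0. Any value below 0 before
#' clamping sets the `negative_clamped` flag.
#'
#' @param viability numeric vector.
#' @return list with `viability` (clamped) and `negative_clamped` (logical
#'   scalar).
#' @export
clamp_and_flag <- function(viability) {
  list(viability = pmin(pmax(viability, 0), 1),
       negative_clamped = any(viability < 0, na.rm = TRUE))
}

# trapezoid integral of y over x
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Fit a dose-response curve and compute its AUC
#'
#' Fits viability against log10 concentration either by ordinary least
#' squares (a line) or by a probit model (least squares on the
#' probit-transformed viability, with values squeezed to `[eps, 1 - eps]`,
#' `eps = 1e-3`, to avoid infinities at 0/1). The AUC is the trapezoid
#' integral of the fitted curve, clipped to [0, 1], on a 100-point grid over
#' the observed log10-concentration range; `auc_rescaled` divides by the
#' width of that range so it lies in [0, 1]. Fits whose viability increases
#' with concentration beyond `increasing_slope_tol` (per log10 unit, on the
#' fit's own scale) are flagged `increasing_removed` and should be excluded
#' from replicate averaging.
#'
#' @param concentrations strictly positive concentrations (uM), length >= 2
#'   with >= 2 distinct values.
#' @param viability clamped viability in [0, 1], same length.
#' @param fit_kind `"ols"` or `"probit"`.
#' @param increasing_slope_tol positive-slope tolerance (default 0.05).
#' @param grid_n integration grid size (default 100).
#' @return list: auc_raw, auc_rescaled, slope, fit_kind, increasing_removed.
#' @export
fit_curve_auc <- function(concentrations, viability,
                          fit_kind = c("ols", "probit"),
                          increasing_slope_tol = 0.05, grid_n = 100) {
  fit_kind <- match.arg(fit_kind)
  if (length(concentrations) != length(viability)) {
    .fail("concentrations and viability must have equal length")
  }
  if (any(concentrations <= 0)) .fail("concentrations must be positive")
  x <- log10(concentrations)
  if (length(unique(x)) < 2) {
    .fail("need >= 2 distinct concentrations to fit a curve")
  }
  grid <- seq(min(x), max(x), length.out = grid_n)
  if (fit_kind == "ols") {
    ft <- lm(viability ~ x)
    curve <- pmin(pmax(coef(ft)[1] + coef(ft)[2] * grid, 0), 1)
    slope <- unname(coef(ft)[2])
  } else {
    eps <- 1e-3
    y <- qnorm(pmin(pmax(viability, eps), 1 - eps))
    ft <- lm(y ~ x)
    curve <- pnorm(coef(ft)[1] + coef(ft)[2] * grid)
    slope <- unname(coef(ft)[2])
  }
  auc_raw <- .trapz(grid, curve)
  rng <- max(x) - min(x)
  list(auc_raw = auc_raw,
       auc_rescaled = auc_raw / rng,
       slope = slope,
       fit_kind = fit_kind,
       increasing_removed = slope > increasing_slope_tol)
}

#' Harmonize replicate AUC records for one (sample, drug) pair
#'
#' Records flagged `increasing_removed` are excluded. Within each panel the
#' maximum difference in raw-area AUC among replicates is checked against
#' `within_threshold` (default 1); panel means are then compared across
#' panels against `across_threshold` (default 0.75). Both thresholds operate
#' on the pre-rescaled area scale. The final AUC is the clamped mean of the
#' per-panel means.
#'
#' @param records data.frame with columns sample_id, drug_id, panel_id,
#'   replicate, auc_raw, auc_rescaled, increasing_removed; all rows must
#'   share one (sample_id, drug_id).
#' @param within_threshold within-panel max AUC difference that sets
#'   `within_panel_divergent`.
#' @param across_threshold across-panel difference that sets
#'   `across_panel_divergent`.
#' @return one-row data.frame: sample_id, drug_id, auc_raw, auc_rescaled,
#'   n_runs, within_panel_divergent, across_panel_divergent,
#'   increasing_removed (TRUE if any run was excluded). `auc_*` are `NA`
#'   when every run was excluded.
#' @export
harmonize_replicates <- function(records, within_threshold = 1,
                                 across_threshold = 0.75) {
  if (nrow(records) == 0) .fail("empty replicate group")
  if (length(unique(records$sample_id)) != 1 ||
      length(unique(records$drug_id)) != 1) {
    .fail("records must share one (sample_id, drug_id)")
  }
  any_increasing <- any(records$increasing_removed)
  keep <- records[!records$increasing_removed, , drop = FALSE]
  base <- data.frame(sample_id = records$sample_id[1],
                     drug_id = records$drug_id[1],
                     stringsAsFactors = FALSE)
  if (nrow(keep) == 0) {
    return(cbind(base, data.frame(
      auc_raw = NA_real_, auc_rescaled = NA_real_, n_runs = 0L,
      within_panel_divergent = FALSE, across_panel_divergent = FALSE,
      increasing_removed = any_increasing)))
  }
  within_div <- FALSE
  panel_raw <- tapply(keep$auc_raw, keep$panel_id, function(v) {
    if (length(v) > 1 && diff(range(v)) > within_threshold) {
      within_div <<- TRUE
    }
    mean(v)
  })
  panel_res <- tapply(keep$auc_rescaled, keep$panel_id, mean)
  across_div <- length(panel_raw) > 1 &&
    diff(range(panel_raw)) > across_threshold
  cbind(base, data.frame(
    auc_raw = mean(panel_raw),
    auc_rescaled = min(max(mean(panel_res), 0), 1),
    n_runs = nrow(keep),
    within_panel_divergent = within_div,
    across_panel_divergent = across_div,
    increasing_removed = any_increasing))
}

#' Process a raw plate table into a harmonized AUC matrix
#'
#' Full dose-response flow: per-plate normalization, clamping with
#' negative-viability flags, per-run curve fitting and AUC, and replicate
#' harmonization per (sample, drug).
#'
#' @param plate raw plate data.frame (see [normalize_plate()]).
#' @param fit_kind `"ols"` or `"probit"`, passed to [fit_curve_auc()].
#' @param subtract_blank passed to [normalize_plate()].
#' @param within_threshold,across_threshold passed to
#'   [harmonize_replicates()].
#' @return list with `auc` (drugs x samples matrix of rescaled AUC, `NA`
#'   where unmeasured or fully removed), `records` (per-run fit table with
#'   flags) and `harmonized` (per-pair table with divergence flags).
#' @export
compute_auc_matrix <- function(plate, fit_kind = c("ols", "probit"),
                               subtract_blank = TRUE, within_threshold = 1,
                               across_threshold = 0.75) {
  fit_kind <- match.arg(fit_kind)
  norm <- normalize_plate(plate, subtract_blank = subtract_blank)
  key <- interaction(norm$sample_id, norm$drug_id, norm$panel_id,
                     norm$replicate, drop = TRUE)
  recs <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    run <- norm[key == levels(key)[i], , drop = FALSE]
    run <- run[order(-run$conc_uM), , drop = FALSE]
    cl <- clamp_and_flag(run$viability)
    ft <- fit_curve_auc(run$conc_uM, cl$viability, fit_kind = fit_kind)
    recs[[i]] <- data.frame(
      sample_id = run$sample_id[1], drug_id = run$drug_id[1],
      panel_id = run$panel_id[1], replicate = run$replicate[1],
      auc_raw = ft$auc_raw, auc_rescaled = ft$auc_rescaled,
      slope = ft$slope, negative_clamped = cl$negative_clamped,
      increasing_removed = ft$increasing_removed,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  pair <- interaction(records$sample_id, records$drug_id, drop = TRUE)
  harm <- do.call(rbind, lapply(levels(pair), function(lv) {
    harmonize_replicates(records[pair == lv, , drop = FALSE],
                         within_threshold = within_threshold,
                         across_threshold = across_threshold)
  }))
  drugs <- sort(unique(records$drug_id))
  samples <- sort(unique(records$sample_id))
  auc <- matrix(NA_real_, length(drugs), length(samples),
                dimnames = list(drugs, samples))
  auc[cbind(match(harm$drug_id, drugs), match(harm$sample_id, samples))] <-
    harm$auc_rescaled
  list(auc = auc, records = records, harmonized = harm)
}
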