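# Paired testing of drug combinations against their best single agent on
# the log AUC scale.

.star_label <- function(p) {
  if (is.na(p)) return("N.S.")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "N.S."
}

#' Test a drug combination against its best single agent
#'
#' For each sample the reference is the minimum log AUC over the
#' combination's component drugs; the combination's log AUC is compared to
#' that reference with a paired t-test over samples. The mean difference is
#' the log combination ratio: negative values mean the combination is more
#' sensitive than its best single agent. AUC values of zero are floored at
#' `floor` before taking logs (flagged). Pairs with zero variance in the
#' differences report the ratio with `p = NA` (no test is possible).
#'
#' @param combo_auc named numeric vector of the combination's AUC per
#'   sample.
#' @param component_auc matrix (components x samples) of single-agent AUC.
#' @param combo_id identifier for the output row.
#' @param log_base base of the log (default `exp(1)`; use 2 for log2
#'   ratios).
#' @param floor lower bound applied to AUC before log (default 1e-4).
#' @param min_pairs minimum complete sample pairs (default 3).
#' @return one-row data.frame: combo_id, n, log_combo_ratio, ci_lo, ci_hi,
#'   t, p, stars, floored, zero_variance.
#' @export
combination_ratio_test <- function(combo_auc, component_auc,
                                   combo_id = "combo", log_base = exp(1),
                                   floor = 1e-4, min_pairs = 3) {
  samples <- intersect(names(combo_auc), colnames(component_auc))
  ref <- apply(component_auc[, samples, drop = FALSE], 2, min)
  cb <- combo_auc[samples]
  ok <- !is.na(cb) & !is.na(ref)
  if (sum(ok) < min_pairs) {
    .fail("insufficient data: ", sum(ok), " complete pairs (need >= ",
          min_pairs, ")")
  }
  cb <- cb[ok]; ref <- ref[ok]
  floored <- any(cb < floor) || any(ref < floor)
  diffs <- log(pmax(cb, floor), base = log_base) -
    log(pmax(ref, floor), base = log_base)
  n <- length(diffs)
  est <- mean(diffs)
  if (sd(diffs) < 1e-10) {
    return(data.frame(combo_id = combo_id, n = n, log_combo_ratio = est,
                      ci_lo = est, ci_hi = est, t = NA_real_, p = NA_real_,
                      stars = "N.S.", floored = floored,
                      zero_variance = TRUE, stringsAsFactors = FALSE))
  }
  tt <- t.test(diffs)
  data.frame(combo_id = combo_id, n = n, log_combo_ratio = est,
             ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
             t = unname(tt$statistic), p = tt$p.value,
             stars = .star_label(tt$p.value), floored = floored,
             zero_variance = FALSE, stringsAsFactors = FALSE)
}

#' Test every combination in a combination map
#'
#' @param combo_auc combos x samples AUC matrix.
#' @param single_auc drugs x samples AUC matrix.
#' @param combo_map data.frame (combo_id, component_id).
#' @param ... passed to [combination_ratio_test()].
#' @return data.frame with one row per testable combination; combinations
#'   with insufficient data are skipped with a warning.
#' @export
test_combinations <- function(combo_auc, single_auc, combo_map, ...) {
  combos <- intersect(unique(combo_map$combo_id), rownames(combo_auc))
  rows <- lapply(combos, function(cb) {
    comp <- intersect(combo_map$component_id[combo_map$combo_id == cb],
                      rownames(single_auc))
    if (length(comp) == 0) return(NULL)
    tryCatch(
      combination_ratio_test(combo_auc[cb, ],
                             single_auc[comp, , drop = FALSE],
                             combo_id = cb, ...),
      error = function(e) {
        warning("skipping ", cb, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    .fail("no combination could be tested")
  }
  rownames(out) <- NULL
  out
}
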