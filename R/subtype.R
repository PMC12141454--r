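# Expression subtype assignment by nearest centroid correlation, with an
# indeterminacy rule for weak or ambiguous calls.

#' Call expression subtypes by centroid correlation
#'
#' Expression is median-centered per gene across the cohort being called;
#' each sample is then correlated (Pearson) with every centroid over the
#' genes common to the matrix and the centroid set, and assigned the
#' best-correlated subtype. A call is flagged indeterminate when the best
#' correlation is negative, when the runner-up is within `margin_threshold`
#' (default 0.1), or when the best correlation is exactly tied.
#'
#' @param expression genes x samples matrix (log scale).
#' @param centroids subtypes x genes matrix.
#' @param margin_threshold minimum lead of the best correlation over the
#'   second best (default 0.1).
#' @param min_common minimum number of common genes (default 10).
#' @return data.frame (sample_id, label, best_r, second_r, margin,
#'   indeterminate) with the per-subtype correlation matrix in attribute
#'   `correlations`. `label` is `NA` for indeterminate calls.
#' @export
call_subtypes <- function(expression, centroids, margin_threshold = 0.1,
                          min_common = 10) {
  if (nrow(centroids) < 2) .fail("need >= 2 centroids")
  common <- intersect(rownames(expression), colnames(centroids))
  if (length(common) < min_common) {
    .fail("only ", length(common), " genes shared with the centroids ",
          "(need >= ", min_common, ")")
  }
  ex <- expression[common, , drop = FALSE]
  ex <- ex - apply(ex, 1, median)
  cen <- centroids[, common, drop = FALSE]
  samples <- colnames(ex)
  rmat <- matrix(NA_real_, length(samples), nrow(cen),
                 dimnames = list(samples, rownames(cen)))
  for (s in seq_along(samples)) {
    if (sd(ex[, s]) == 0) {
      warning("sample ", samples[s], " has zero expression variance; ",
              "call is indeterminate", call. = FALSE)
      next
    }
    rmat[s, ] <- apply(cen, 1, function(ct) cor(ex[, s], ct))
  }
  calls <- do.call(rbind, lapply(seq_along(samples), function(s) {
    r <- rmat[s, ]
    if (all(is.na(r))) {
      return(data.frame(sample_id = samples[s], label = NA_character_,
                        best_r = NA_real_, second_r = NA_real_,
                        margin = NA_real_, indeterminate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ord <- order(r, decreasing = TRUE)
    best <- r[ord[1]]; second <- r[ord[2]]
    tied <- sum(r == best) > 1
    ind <- best < 0 || (best - second) < margin_threshold || tied
    data.frame(sample_id = samples[s],
               label = if (ind) NA_character_ else names(r)[ord[1]],
               best_r = best, second_r = second, margin = best - second,
               indeterminate = ind, stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  attr(calls, "correlations") <- rmat
  calls
}

#' Evaluate subtype calls against reference labels
#'
#' Accuracy is computed over determinate calls only; indeterminate calls
#' are counted separately and never enter the accuracy denominator.
#'
#' @param calls a [call_subtypes()] result.
#' @param reference named character vector of true labels (names = sample
#'   ids).
#' @return list: accuracy (`NA` when no determinate call overlaps),
#'   n_determinate, n_indeterminate, confusion (table of truth x call).
#' @export
evaluate_calls <- function(calls, reference) {
  common <- intersect(calls$sample_id, names(reference))
  if (length(common) == 0) .fail("no overlap with reference labels")
  sub <- calls[match(common, calls$sample_id), ]
  det <- !sub$indeterminate
  acc <- if (any(det)) {
    mean(sub$label[det] == reference[common][det])
  } else NA_real_
  conf <- if (any(det)) {
    table(truth = reference[common][det], call = sub$label[det])
  } else table(character(), character())
  list(accuracy = acc, n_determinate = sum(det),
       n_indeterminate = sum(!det), confusion = conf)
}
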