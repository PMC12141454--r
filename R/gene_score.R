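# Per-gene drug-sensitivity scores: per-drug Z-scores of AUC across samples,
# gene scores as the target-gated sum of Z-scores, and a drug-label
# permutation test.

#' Standardize AUC values per drug across samples
#'
#' Each drug row is centered and scaled as `(x - mean(x)) / sd(x)` across
#' the samples in which it was measured (missing entries ignored; sample SD,
#' n - 1 denominator). Drugs measured in fewer than `min_samples` samples,
#' or with zero SD, are dropped with a warning.
#'
#' @param X drugs x samples AUC matrix, `NA` allowed.
#' @param min_samples minimum number of observed samples per drug
#'   (default 2).
#' @return drugs x samples Z-score matrix with attributes `means` and `sds`
#'   (named per-drug).
#' @export
zscore_by_drug <- function(X, min_samples = 2) {
  if (is.null(rownames(X))) .fail("X must have drug row names")
  n_obs <- rowSums(!is.na(X))
  sds <- apply(X, 1, sd, na.rm = TRUE)
  means <- rowMeans(X, na.rm = TRUE)
  ok <- n_obs >= min_samples & !is.na(sds) & sds > 0
  if (!any(ok)) .fail("all drugs dropped during standardization")
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " drug(s) with < ", min_samples,
            " samples or zero SD: ",
            paste(rownames(X)[!ok], collapse = ", "), call. = FALSE)
  }
  Z <- (X[ok, , drop = FALSE] - means[ok]) / sds[ok]
  attr(Z, "means") <- means[ok]
  attr(Z, "sds") <- sds[ok]
  Z
}

#' Compute gene scores from the target matrix and drug Z-scores
#'
#' The score of gene i in sample k is the sum of the Z-scores of all drugs
#' targeting i: `g_ik = sum_j t_ij z_jk`, restricted to the drugs common to
#' both matrices. Strongly negative scores mark genes whose inhibitors the
#' sample is unusually sensitive to. Missing Z entries contribute nothing; a
#' (gene, sample) cell whose targeted drugs are all missing is `NA`, and
#' genes with no drugs in the common set are dropped (reported via the
#' `absent_genes` attribute) rather than scored 0.
#'
#' @param target_matrix binary genes x drugs matrix.
#' @param Z drugs x samples Z-score matrix.
#' @return genes x samples score matrix with attribute `absent_genes`.
#' @export
compute_gene_scores <- function(target_matrix, Z) {
  common <- intersect(colnames(target_matrix), rownames(Z))
  if (length(common) == 0) .fail("no drugs shared by target matrix and Z")
  Tm <- target_matrix[, common, drop = FALSE]
  Zc <- Z[common, , drop = FALSE]
  absent <- rownames(Tm)[rowSums(Tm) == 0]
  Tm <- Tm[rowSums(Tm) > 0, , drop = FALSE]
  Z0 <- Zc
  Z0[is.na(Z0)] <- 0
  G <- Tm %*% Z0
  n_obs <- Tm %*% (!is.na(Zc))
  G[n_obs == 0] <- NA_real_
  attr(G, "absent_genes") <- absent
  G
}

#' Permutation test for gene scores
#'
#' The null distribution permutes the drug labels: whole rows of `Z` are
#' relabeled jointly for all samples (a row's missingness pattern travels
#' with it) and the gene scores recomputed, `n_perm` times. The one-sided
#' empirical p-value for each (gene, sample) cell counts how often the
#' permuted score falls at or below the observed one, with add-one
#' smoothing: `p = (1 + #[g_perm <= g_obs]) / (n_perm + 1)`. Ties are
#' counted so that a score invariant under permutation (e.g. a gene
#' targeting every drug) gets p = 1 rather than spurious significance, and
#' the empirical p is valid under the null. Low p marks strongly negative
#' scores (sensitivity). Tiers are assigned at p < 0.001 (tier 1), < 0.01
#' (tier 2) and < 0.05 (tier 3).
#'
#' @param target_matrix binary genes x drugs matrix.
#' @param Z drugs x samples Z-score matrix.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `gene_score_result`: list with `scores`, `p`,
#'   `tier` (integer matrix, `NA` = not significant), `n_perm`, `seed`.
#' @export
permutation_pvalues <- function(target_matrix, Z, n_perm = 1000,
                                seed = NULL) {
  n_perm <- .check_count(n_perm, "n_perm")
  G <- compute_gene_scores(target_matrix, Z)
  common <- intersect(colnames(target_matrix), rownames(Z))
  Tm <- target_matrix[rownames(G), common, drop = FALSE]
  Zc <- Z[common, , drop = FALSE]
  d <- length(common)
  if (lfactorial(d) < log(n_perm)) {
    warning("only ", factorial(d), " distinct drug-label permutations ",
            "exist for ", d, " drugs; requested ", n_perm, call. = FALSE)
  }
  obs <- !is.na(Zc)
  Z0 <- Zc
  Z0[is.na(Z0)] <- 0
  count <- matrix(0L, nrow(G), ncol(G), dimnames = dimnames(G))
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(d)
      Gp <- Tm %*% Z0[perm, , drop = FALSE]
      n_obs <- Tm %*% obs[perm, , drop = FALSE]
      Gp[n_obs == 0] <- NA_real_
      le <- !is.na(Gp) & !is.na(G) & Gp <= G + 1e-12
      count <- count + le
    }
  })
  p <- (1 + count) / (n_perm + 1)
  p[is.na(G)] <- NA_real_
  tier <- matrix(NA_integer_, nrow(p), ncol(p), dimnames = dimnames(p))
  tier[!is.na(p) & p < 0.05] <- 3L
  tier[!is.na(p) & p < 0.01] <- 2L
  tier[!is.na(p) & p < 0.001] <- 1L
  structure(list(scores = G, p = p, tier = tier, n_perm = n_perm,
                 seed = seed),
            class = "gene_score_result")
}

#' @export
print.gene_score_result <- function(x, ...) {
  cat("Gene score result: ", nrow(x$scores), " genes x ", ncol(x$scores),
      " samples, ", x$n_perm, " permutations\n", sep = "")
  cat("  tier-1 (p < 0.001) cells: ", sum(x$tier == 1L, na.rm = TRUE),
      "\n", sep = "")
  invisible(x)
}
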