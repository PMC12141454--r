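# Drug-target evidence filtering and construction of the binary drug-target
# matrix T.

#' Filter drug-target evidence to high-confidence interactions
#'
#' Keeps only interactions with a recorded binding-assay value below
#' `assay_threshold` (default 100 nM), then, per drug, bins the surviving
#' interactions by publication support into the categories >= 3, == 2 and
#' == 1 and retains only the genes of the highest non-empty category. An
#' optional per-row exclusion list removes specific (drug, gene) pairs
#' whose evidence is considered unreliable (e.g. wildly discrepant assay
#' values between sources).
#'
#' @param evidence data.frame with columns drug_id, gene_id,
#'   assay_value_nM (numeric, `NA` when no assay value is recorded) and
#'   n_publications.
#' @param assay_threshold keep rows with assay value strictly below this
#'   (nM).
#' @param exclude optional data.frame (drug_id, gene_id) of pairs to drop.
#' @param pub_breaks lower bounds of the publication-support categories in
#'   decreasing priority (default `c(3, 2, 1)`, i.e. >= 3 beats == 2 beats
#'   == 1).
#' @return The filtered evidence rows.
#' @export
filter_and_select <- function(evidence, assay_threshold = 100,
                              exclude = NULL, pub_breaks = c(3, 2, 1)) {
  need <- c("drug_id", "gene_id", "assay_value_nM", "n_publications")
  if (!all(need %in% names(evidence))) {
    .fail("evidence must have columns: ", paste(need, collapse = ", "))
  }
  ev <- evidence[!is.na(evidence$assay_value_nM) &
                   evidence$assay_value_nM < assay_threshold, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0) {
    bad <- paste(ev$drug_id, ev$gene_id) %in%
      paste(exclude$drug_id, exclude$gene_id)
    ev <- ev[!bad, , drop = FALSE]
  }
  if (nrow(ev) == 0) return(ev)
  # category index: 1 = highest support
  cat_of <- function(p) {
    idx <- which(p >= pub_breaks)[1]
    if (is.na(idx)) length(pub_breaks) + 1L else idx
  }
  cats <- vapply(ev$n_publications, cat_of, integer(1))
  keep <- unlist(lapply(split(seq_len(nrow(ev)), ev$drug_id), function(idx) {
    idx[cats[idx] == min(cats[idx])]
  }), use.names = FALSE)
  out <- ev[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binary gene x drug target matrix
#'
#' `t[i, j] = 1` when filtered evidence links gene i to drug j. Drugs with
#' no surviving targets are dropped from the matrix with a warning naming
#' them; duplicate (drug, gene) rows collapse to a single 1.
#'
#' @param evidence filtered evidence (see [filter_and_select()]).
#' @param genes,drugs optional universes; default to the ids present in the
#'   evidence. Drugs in `drugs` but absent from the evidence are the dropped
#'   set.
#' @return binary genes x drugs matrix with an attribute
#'   `dropped_drugs` (character vector).
#' @export
build_target_matrix <- function(evidence, genes = NULL, drugs = NULL) {
  if (is.null(genes)) genes <- sort(unique(evidence$gene_id))
  if (is.null(drugs)) drugs <- sort(unique(evidence$drug_id))
  if (length(genes) == 0 && nrow(evidence) == 0) {
    .fail("empty gene universe and no evidence")
  }
  tm <- matrix(0L, length(genes), length(drugs),
               dimnames = list(genes, drugs))
  ev <- evidence[evidence$gene_id %in% genes & evidence$drug_id %in% drugs, ,
                 drop = FALSE]
  if (nrow(ev) > 0) {
    tm[cbind(match(ev$gene_id, genes), match(ev$drug_id, drugs))] <- 1L
  }
  dropped <- drugs[colSums(tm) == 0]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " drug(s) with no targets: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    tm <- tm[, setdiff(drugs, dropped), drop = FALSE]
  }
  attr(tm, "dropped_drugs") <- dropped
  tm
}
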