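# Per-patient Response Card: a deterministic join of drug Z-scores, gene
# scores with permutation significance, drug-target links, and genomic /
# expression / protein evidence, exportable as JSON, a TSV bundle or a
# summary figure.

#' Z-score a modality matrix across a cohort
#'
#' Per-row (gene/antibody) centering and scaling across samples, with the
#' cohort means and SDs retained as attributes. Zero-SD rows return `NA`.
#'
#' @param x features x samples numeric matrix.
#' @return Z-scored matrix with attributes `means` and `sds`.
#' @export
cohort_zscore <- function(x) {
  mns <- rowMeans(x, na.rm = TRUE)
  sds <- apply(x, 1, sd, na.rm = TRUE)
  z <- (x - mns) / ifelse(sds > 0, sds, NA_real_)
  attr(z, "means") <- mns
  attr(z, "sds") <- sds
  z
}

#' Assemble a per-patient Response Card
#'
#' Joins, for one patient: the drug panel (per-drug AUC Z-scores, most
#' sensitive first), the gene panel (all tier-assigned genes ordered by
#' p-value then score, plus any explicitly requested extra genes such as
#' the targets of the most sensitive drug), the drug-target links
#' restricted to those panels, per-gene evidence (mutation flag,
#' copy-number call with concordance label, expression and protein
#' Z-scores; missing modalities are explicit `NA`, never zero), and the
#' network-prioritization block.
#'
#' @param patient_id sample to assemble.
#' @param zscores drugs x samples AUC Z-score matrix.
#' @param score_result a [permutation_pvalues()] result.
#' @param target_matrix binary genes x drugs matrix.
#' @param filtered_variants output of [filter_variants()] (may be empty).
#' @param cna_calls output of [call_gene_copy_number()] or `NULL`.
#' @param expr_z,rppa_z cohort Z-scored modality matrices (features x
#'   samples) or `NULL`.
#' @param prioritized output of [prioritize_altered_genes()] or `NULL`.
#' @param subnetwork output of [extract_subnetwork()] or `NULL`.
#' @param extra_genes genes to include in the gene panel even when
#'   untiered.
#' @return object of class `response_card`.
#' @export
assemble_card <- function(patient_id, zscores, score_result, target_matrix,
                          filtered_variants = NULL, cna_calls = NULL,
                          expr_z = NULL, rppa_z = NULL, prioritized = NULL,
                          subnetwork = NULL, extra_genes = character()) {
  if (!patient_id %in% colnames(zscores) ||
      !patient_id %in% colnames(score_result$scores)) {
    .fail("unknown patient: ", patient_id)
  }
  dz <- zscores[, patient_id]
  drug_panel <- data.frame(drug_id = names(sort(dz)),
                           zscore = unname(sort(dz)),
                           stringsAsFactors = FALSE)

  sc <- score_result$scores[, patient_id]
  pv <- score_result$p[, patient_id]
  tr <- score_result$tier[, patient_id]
  tiered <- names(tr)[!is.na(tr)]
  panel_genes <- tiered[order(pv[tiered], sc[tiered])]
  extra <- setdiff(extra_genes, panel_genes)
  gene_panel <- data.frame(
    gene_id = c(panel_genes, extra),
    score = unname(c(sc[panel_genes],
                     ifelse(extra %in% names(sc), sc[extra], NA_real_))),
    p = unname(c(pv[panel_genes],
                 ifelse(extra %in% names(pv), pv[extra], NA_real_))),
    tier = as.integer(c(tr[panel_genes],
                        ifelse(extra %in% names(tr), tr[extra],
                               NA_integer_))),
    extra = c(rep(FALSE, length(panel_genes)), rep(TRUE, length(extra))),
    stringsAsFactors = FALSE)

  tg <- intersect(gene_panel$gene_id, rownames(target_matrix))
  td <- intersect(drug_panel$drug_id, colnames(target_matrix))
  tm <- target_matrix[tg, td, drop = FALSE]
  hit <- which(tm == 1, arr.ind = TRUE)
  targets <- if (length(hit) == 0) {
    data.frame(gene_id = character(), drug_id = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = rownames(tm)[hit[, 1]],
               drug_id = colnames(tm)[hit[, 2]],
               stringsAsFactors = FALSE)
  }
  targets <- targets[order(targets$gene_id, targets$drug_id), , drop = FALSE]
  rownames(targets) <- NULL

  get_z <- function(zmat, g) {
    if (is.null(zmat) || !patient_id %in% colnames(zmat)) return(NA_real_)
    if (!g %in% rownames(zmat)) return(NA_real_)
    zmat[g, patient_id]
  }
  ev <- do.call(rbind, lapply(gene_panel$gene_id, function(g) {
    mut <- !is.null(filtered_variants) && nrow(filtered_variants) > 0 &&
      any(filtered_variants$sample_id == patient_id &
            filtered_variants$gene_id == g)
    cna <- NA_character_
    if (!is.null(cna_calls)) {
      row <- cna_calls[cna_calls$sample_id == patient_id &
                         cna_calls$gene_id == g, , drop = FALSE]
      if (nrow(row) == 1) cna <- row$call
    }
    ez <- get_z(expr_z, g)
    rz <- get_z(rppa_z, g)
    conc <- classify_concordance(cna, ez, rz)
    data.frame(gene_id = g, mutated = mut, cna_call = cna,
               concordance = conc, expr_z = ez, rppa_z = rz,
               stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL

  network <- list(
    prioritized = if (is.null(prioritized)) {
      data.frame(gene_id = character(), score = numeric(), p = numeric(),
                 stringsAsFactors = FALSE)
    } else prioritized,
    subnetwork_nodes = if (is.null(subnetwork)) NULL else subnetwork$nodes)

  structure(list(patient_id = patient_id,
                 drug_panel = drug_panel,
                 gene_panel = gene_panel,
                 targets = targets,
                 evidence = ev,
                 network = network),
            class = "response_card")
}

#' @export
print.response_card <- function(x, ...) {
  cat("Response Card for ", x$patient_id, "\n", sep = "")
  cat("  drugs: ", nrow(x$drug_panel), " (most sensitive: ",
      x$drug_panel$drug_id[1], ", z = ",
      round(x$drug_panel$zscore[1], 2), ")\n", sep = "")
  cat("  gene panel: ", nrow(x$gene_panel), " genes (",
      sum(x$gene_panel$extra), " extra)\n", sep = "")
  cat("  prioritized altered genes: ", nrow(x$network$prioritized), "\n",
      sep = "")
  invisible(x)
}

#' Export a Response Card
#'
#' `json` writes a single canonical JSON file; `tsv-bundle` writes one TSV
#' per non-empty tabular block into a directory; `figure` renders a
#' heatmap-style summary panel (drug Z-scores on top, per-gene evidence
#' below) to a PNG.
#'
#' @param card a [assemble_card()] result.
#' @param path output file (json/figure) or directory (tsv-bundle).
#' @param format one of `"json"`, `"tsv-bundle"`, `"figure"`.
#' @return invisibly, the path(s) written.
#' @export
export_card <- function(card, path, format = c("json", "tsv-bundle",
                                               "figure")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- unclass(card)
    json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                             digits = NA, na = "null", null = "null",
                             pretty = TRUE)
    writeLines(json, path)
    return(invisible(path))
  }
  if (format == "tsv-bundle") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    blocks <- list(drug_panel = card$drug_panel,
                   gene_panel = card$gene_panel,
                   targets = card$targets,
                   evidence = card$evidence,
                   prioritized = card$network$prioritized,
                   subnetwork_nodes = card$network$subnetwork_nodes)
    written <- character()
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      if (is.null(b) || nrow(b) == 0) next
      f <- file.path(path, paste0(nm, ".tsv"))
      write_tsv_table(b, f)
      written <- c(written, f)
    }
    return(invisible(written))
  }
  # figure
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE)
  graphics::layout(matrix(1:2, 2, 1), heights = c(1, 1.6))
  graphics::par(mar = c(6, 4, 3, 1))
  top <- utils::head(card$drug_panel, 15)
  graphics::barplot(top$zscore, names.arg = top$drug_id, las = 2,
                    col = ifelse(top$zscore < 0, "steelblue", "grey70"),
                    ylab = "drug Z-score",
                    main = paste("Response Card:", card$patient_id))
  ev <- card$evidence
  gp <- card$gene_panel
  mat <- rbind(score = gp$score,
               mutated = as.numeric(ev$mutated),
               expr_z = ev$expr_z,
               rppa_z = ev$rppa_z)
  colnames(mat) <- gp$gene_id
  graphics::par(mar = c(6, 6, 1, 1))
  if (ncol(mat) == 0 || !any(is.finite(mat))) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no gene-level evidence available")
  } else {
    graphics::image(seq_len(ncol(mat)), seq_len(nrow(mat)),
                    t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
                    axes = FALSE, xlab = "", ylab = "",
                    zlim = range(mat, na.rm = TRUE, finite = TRUE),
                    col = grDevices::hcl.colors(25, "Blue-Red 2"))
    graphics::axis(1, at = seq_len(ncol(mat)), labels = colnames(mat),
                   las = 2, cex.axis = 0.8)
    graphics::axis(2, at = seq_len(nrow(mat)), labels = rev(rownames(mat)),
                   las = 1)
  }
  invisible(path)
}

#' Import a Response Card from JSON
#'
#' Inverse of [export_card()] with `format = "json"`; column types of the
#' tabular blocks are restored.
#'
#' @param path JSON file written by [export_card()].
#' @return object of class `response_card`.
#' @export
import_card <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as_df <- function(x, template) {
    if (is.null(x) || (is.list(x) && length(x) == 0)) return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    for (nm in names(template)) {
      if (!nm %in% names(df)) df[[nm]] <- template[[nm]][0]
      mode_fun <- switch(class(template[[nm]])[1],
                         integer = as.integer,
                         numeric = as.numeric,
                         logical = as.logical,
                         as.character)
      df[[nm]] <- mode_fun(df[[nm]])
    }
    df[, names(template), drop = FALSE]
  }
  t_drug <- data.frame(drug_id = character(), zscore = numeric(),
                       stringsAsFactors = FALSE)
  t_gene <- data.frame(gene_id = character(), score = numeric(),
                       p = numeric(), tier = integer(), extra = logical(),
                       stringsAsFactors = FALSE)
  t_tgt <- data.frame(gene_id = character(), drug_id = character(),
                      stringsAsFactors = FALSE)
  t_ev <- data.frame(gene_id = character(), mutated = logical(),
                     cna_call = character(), concordance = character(),
                     expr_z = numeric(), rppa_z = numeric(),
                     stringsAsFactors = FALSE)
  t_pri <- data.frame(gene_id = character(), score = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  t_sub <- data.frame(gene_id = character(), role = character(),
                      stringsAsFactors = FALSE)
  structure(list(
    patient_id = obj$patient_id,
    drug_panel = as_df(obj$drug_panel, t_drug),
    gene_panel = as_df(obj$gene_panel, t_gene),
    targets = as_df(obj$targets, t_tgt),
    evidence = as_df(obj$evidence, t_ev),
    network = list(
      prioritized = as_df(obj$network$prioritized, t_pri),
      subnetwork_nodes = if (is.null(obj$network$subnetwork_nodes)) NULL
      else as_df(obj$network$subnetwork_nodes, t_sub))),
    class = "response_card")
}
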