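# Genomic integration: somatic variant filtering, gene-level copy-number
# calling from allele-specific segments, expression/protein concordance
# classification, binary alteration profiles, Jaccard cell-line matching and
# AUC correlation.

#' Filter annotated somatic variants
#'
#' Keeps variants that (i) pass the caller filter, (ii) have a
#' non-synonymous consequence or are indels, (iii) have population allele
#' frequency below `af_threshold` (a missing frequency is treated as novel
#' and kept, flagged in `af_missing`), and (iv) are either predicted
#' damaging by both protein-impact predictors (not SIFT-tolerated and not
#' PolyPhen-benign) or are rescued by a pathogenic ClinVar annotation.
#' Genes on the caller's curated false-positive blocklist are removed.
#'
#' @param variants data.frame with columns sample_id, gene_id,
#'   filter_status, consequence, population_af, sift, polyphen, clinvar.
#' @param af_threshold population allele-frequency cutoff (default 0.01,
#'   strict `<`).
#' @param blocklist character vector of genes to remove.
#' @param benign_consequences consequence labels treated as non-impactful.
#' @param require_both when TRUE (default) a variant must fail both benign
#'   predictors (unless ClinVar-pathogenic); when FALSE failing either
#'   suffices.
#' @return the surviving rows with an added logical `af_missing` column.
#' @export
filter_variants <- function(variants, af_threshold = 0.01,
                            blocklist = character(),
                            benign_consequences = c("synonymous_variant",
                                                    "intron_variant",
                                                    "silent"),
                            require_both = TRUE) {
  v <- variants
  if (nrow(v) == 0) {
    v$af_missing <- logical(0)
    return(v)
  }
  v$af_missing <- is.na(v$population_af)
  af <- ifelse(v$af_missing, 0, v$population_af)
  pass <- v$filter_status == "PASS"
  impactful <- !(v$consequence %in% benign_consequences)
  rare <- af < af_threshold
  sift_tol <- grepl("tolerated", v$sift, ignore.case = TRUE)
  poly_ben <- grepl("benign", v$polyphen, ignore.case = TRUE)
  clin_path <- grepl("pathogenic", v$clinvar, ignore.case = TRUE) &
    !grepl("benign", v$clinvar, ignore.case = TRUE)
  damaging <- if (require_both) !sift_tol & !poly_ben else !sift_tol | !poly_ben
  keep <- pass & impactful & rare & (damaging | clin_path) &
    !(v$gene_id %in% blocklist)
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call gene-level copy number from allele-specific segments
#'
#' Per sample, the total copy number of each segment is the sum of the major
#' and minor alleles; totals are centered by subtracting the sample median
#' over segments. Each gene is assigned the overlapping segment value of
#' largest absolute magnitude and called `amp` when the centered value is
#' strictly greater than 1, `del` when strictly below -1, otherwise
#' `neutral`. Genes with no overlapping segment get an `NA` call.
#'
#' @param segments data.frame (sample_id, chrom, start, end, major, minor),
#'   1-based closed coordinates.
#' @param gene_intervals data.frame (chrom, start, end, gene_id); BED-like,
#'   0-based half-open (converted internally).
#' @return data.frame (sample_id, gene_id, centered_cn, call).
#' @export
call_gene_copy_number <- function(segments, gene_intervals) {
  gi <- GenomicRanges::GRanges(
    seqnames = gene_intervals$chrom,
    ranges = IRanges::IRanges(start = gene_intervals$start + 1L,
                              end = gene_intervals$end))
  samples <- unique(segments$sample_id)
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[k], , drop = FALSE]
    total <- seg$major + seg$minor
    centered <- total - median(total)
    sg <- GenomicRanges::GRanges(
      seqnames = seg$chrom,
      ranges = IRanges::IRanges(start = seg$start, end = seg$end))
    hits <- GenomicRanges::findOverlaps(gi, sg)
    val <- rep(NA_real_, length(gi))
    for (i in unique(S4Vectors::queryHits(hits))) {
      cand <- centered[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
      val[i] <- cand[which.max(abs(cand))]
    }
    out[[k]] <- data.frame(
      sample_id = samples[k], gene_id = gene_intervals$gene_id,
      centered_cn = val,
      call = ifelse(is.na(val), NA_character_,
                    ifelse(val > 1, "amp",
                           ifelse(val < -1, "del", "neutral"))),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify concordance of a copy-number call with expression/protein
#'
#' An amplification whose available modality Z-scores (expression and/or
#' protein) are all positive is a concordant amplification (`cA`); anything
#' else (all negative, mixed, or zero) is discordant (`dA`). Deletions
#' mirror with signs flipped (`cD`/`dD`). When neither modality is
#' available the label is `NA`.
#'
#' @param cna_call `"amp"` or `"del"` (vectorized).
#' @param expr_z,rppa_z numeric Z-scores, `NA` when unavailable.
#' @return character vector of labels in cA/dA/cD/dD/NA.
#' @export
classify_concordance <- function(cna_call, expr_z, rppa_z) {
  n <- length(cna_call)
  stopifnot(length(expr_z) == n, length(rppa_z) == n)
  vapply(seq_len(n), function(i) {
    if (is.na(cna_call[i]) || cna_call[i] == "neutral") return(NA_character_)
    zs <- c(expr_z[i], rppa_z[i])
    zs <- zs[!is.na(zs)]
    if (length(zs) == 0) return(NA_character_)
    if (cna_call[i] == "amp") {
      if (all(zs > 0)) "cA" else "dA"
    } else {
      if (all(zs < 0)) "cD" else "dD"
    }
  }, character(1))
}

#' Build binary alteration profiles
#'
#' The profile of each sample over `gene_subset` is the union of its
#' filtered mutations and its non-neutral copy-number calls.
#'
#' @param filtered_variants output of [filter_variants()].
#' @param cna_calls output of [call_gene_copy_number()] (may be `NULL`).
#' @param gene_subset genes indexing the profile.
#' @param sample_ids samples to include; defaults to those present in the
#'   inputs.
#' @return binary samples x genes matrix.
#' @export
build_alteration_profile <- function(filtered_variants, cna_calls = NULL,
                                     gene_subset, sample_ids = NULL) {
  if (length(gene_subset) == 0) .fail("`gene_subset` must be non-empty")
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(c(filtered_variants$sample_id,
                                cna_calls$sample_id)))
  }
  prof <- matrix(0L, length(sample_ids), length(gene_subset),
                 dimnames = list(sample_ids, gene_subset))
  mv <- filtered_variants[filtered_variants$gene_id %in% gene_subset &
                            filtered_variants$sample_id %in% sample_ids, ,
                          drop = FALSE]
  if (nrow(mv) > 0) {
    prof[cbind(match(mv$sample_id, sample_ids),
               match(mv$gene_id, gene_subset))] <- 1L
  }
  if (!is.null(cna_calls)) {
    cn <- cna_calls[!is.na(cna_calls$call) & cna_calls$call != "neutral" &
                      cna_calls$gene_id %in% gene_subset &
                      cna_calls$sample_id %in% sample_ids, , drop = FALSE]
    if (nrow(cn) > 0) {
      prof[cbind(match(cn$sample_id, sample_ids),
                 match(cn$gene_id, gene_subset))] <- 1L
    }
  }
  prof
}

# Jaccard distance between two binary vectors
.jaccard_distance <- function(a, b) {
  un <- sum(a | b)
  if (un == 0) return(NA_real_)
  1 - sum(a & b) / un
}

#' Match patients to cell lines by alteration-profile Jaccard distance
#'
#' Computes `1 - |A intersect B| / |A union B|` over the positive entries of
#' each patient/cell-line profile pair and returns, per patient, the
#' minimum-distance cell line(s) (ties all reported). Entities with empty
#' profiles are excluded with a warning.
#'
#' @param patient_profiles,cellline_profiles binary samples x genes
#'   matrices over a shared gene set.
#' @return list with `distances` (patients x cell lines) and `matches`
#'   (data.frame patient_id, cell_line, distance).
#' @export
match_cell_lines <- function(patient_profiles, cellline_profiles) {
  if (!identical(colnames(patient_profiles), colnames(cellline_profiles))) {
    .fail("profiles must share the same gene columns")
  }
  pe <- rowSums(patient_profiles) > 0
  ce <- rowSums(cellline_profiles) > 0
  if (!any(pe) || !any(ce)) .fail("all profiles are empty")
  if (any(!pe) || any(!ce)) {
    warning("excluding ", sum(!pe), " patient(s) and ", sum(!ce),
            " cell line(s) with empty profiles", call. = FALSE)
  }
  P <- patient_profiles[pe, , drop = FALSE]
  C <- cellline_profiles[ce, , drop = FALSE]
  D <- matrix(NA_real_, nrow(P), nrow(C),
              dimnames = list(rownames(P), rownames(C)))
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(C))) {
      D[i, j] <- .jaccard_distance(P[i, ] == 1, C[j, ] == 1)
    }
  }
  matches <- do.call(rbind, lapply(rownames(D), function(p) {
    d <- D[p, ]
    best <- names(d)[d == min(d)]
    data.frame(patient_id = p, cell_line = best, distance = min(d),
               stringsAsFactors = FALSE)
  }))
  list(distances = D, matches = matches)
}

#' Correlate patient and cell-line drug responses
#'
#' Pearson correlation of AUC values over the drugs measured in both, with
#' a two-sided p-value.
#'
#' @param patient_auc,cellline_auc named numeric vectors (names = drug
#'   ids).
#' @param min_common minimum number of complete common drugs (default 3).
#' @return list: r, p, n_common.
#' @export
correlate_auc <- function(patient_auc, cellline_auc, min_common = 3) {
  common <- intersect(names(patient_auc), names(cellline_auc))
  x <- patient_auc[common]
  y <- cellline_auc[common]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_common) {
    .fail("insufficient data: only ", sum(ok), " common complete drugs")
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_common = sum(ok))
}
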