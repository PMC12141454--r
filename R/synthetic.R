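# Synthetic cohort generators. Every pipeline input can be produced with
# known planted structure (sensitive sample/gene pairs, altered driver genes,
# true subtype labels) so that downstream stages are testable without
# external data.

#' Construct the planted-truth record for a synthetic cohort
#'
#' The truth object carries the structure deliberately planted by the
#' generators: which (sample, gene) pairs are drug-sensitive, which genes are
#' altered drivers placed near targeted genes in the network, and the true
#' expression subtype of each sample.
#'
#' @param sensitive_pairs data.frame with columns `sample_id`, `gene_id`:
#'   samples whose viability under drugs targeting the gene is shifted down.
#' @param driver_genes data.frame with columns `sample_id`, `gene_id`: genes
#'   carrying planted somatic alterations in the given samples.
#' @param subtype_labels named character vector, sample id -> subtype label.
#'   May be `NULL` before the expression cohort is generated.
#' @param seed integer seed that generated (or will generate) the cohort.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(sensitive_pairs = NULL, driver_genes = NULL,
                            subtype_labels = NULL, seed = NA_integer_) {
  empty <- data.frame(sample_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(sensitive_pairs)) sensitive_pairs <- empty
  if (is.null(driver_genes)) driver_genes <- empty
  stopifnot(all(c("sample_id", "gene_id") %in% names(sensitive_pairs)),
            all(c("sample_id", "gene_id") %in% names(driver_genes)))
  structure(list(sensitive_pairs = sensitive_pairs,
                 driver_genes = driver_genes,
                 subtype_labels = subtype_labels,
                 seed = seed),
            class = "synthetic_truth")
}

.sample_ids <- function(n) sprintf("S%02d", seq_len(n))
.drug_ids   <- function(n) sprintf("D%03d", seq_len(n))
.gene_ids   <- function(n) sprintf("G%04d", seq_len(n))

#' Generate raw viability plate data
#'
#' Emulates a single-agent inhibitor screen: each (sample, drug) run is a
#' dilution series of `n_doses` concentrations spaced by `dilution_factor`
#' starting at `top_conc`, with within-panel replicates plus negative-control
#' (cells, no drug) and blank (no cells) wells per plate. The generative
#' dose-response shape is a four-parameter logistic in log10 concentration;
#' samples that are planted sensitive to a gene get the viability under every
#' drug targeting that gene pulled down by `effect` at saturation.
#'
#' @param n_samples,n_drugs number of samples and drugs.
#' @param n_doses doses per series (default 7).
#' @param dilution_factor fold change between consecutive doses (default 3).
#' @param top_conc highest concentration in uM.
#' @param noise_sd standard deviation of Gaussian noise added to viability.
#' @param effect maximal planted viability decrease, in [0, 1].
#' @param truth a [synthetic_truth()] object naming sensitive pairs.
#' @param target_matrix binary gene x drug matrix linking genes to the drugs
#'   that inhibit them; required when `effect > 0` and pairs are planted.
#' @param n_replicates within-panel replicates per run (default 2).
#' @param n_panels number of assay panels; drugs are split across panels and
#'   a small overlap set is run on every panel so that across-panel
#'   harmonization is exercised (default 1).
#' @param n_controls,n_blanks control and blank wells per plate.
#' @param control_level,blank_level mean raw optical signal of control and
#'   blank wells.
#' @param seed optional integer seed; fixed seed gives byte-identical output.
#' @return data.frame with columns sample_id, drug_id, panel_id, replicate,
#'   conc_uM, signal, well_type (treated/control/blank).
#' @export
generate_viability_plates <- function(n_samples, n_drugs, n_doses = 7,
                                      dilution_factor = 3, top_conc = 10,
                                      noise_sd = 0.05, effect = 0.5,
                                      truth = synthetic_truth(),
                                      target_matrix = NULL,
                                      n_replicates = 2, n_panels = 1,
                                      n_controls = 8, n_blanks = 4,
                                      control_level = 1.0,
                                      blank_level = 0.05,
                                      seed = NULL) {
  n_samples <- .check_count(n_samples, "n_samples")
  n_drugs <- .check_count(n_drugs, "n_drugs")
  n_doses <- .check_count(n_doses, "n_doses")
  if (n_doses < 2) .fail("`n_doses` must be >= 2")
  effect <- .check_fraction(effect, "effect")
  .with_seed(seed, {
    samples <- .sample_ids(n_samples)
    drugs <- .drug_ids(n_drugs)
    conc <- top_conc / dilution_factor^(seq_len(n_doses) - 1)
    mid_conc <- sqrt(conc[1] * conc[n_doses])  # geometric middle of range
    panel_of <- rep(seq_len(n_panels), length.out = n_drugs)

    # drug -> set of samples with a planted shift
    shifted <- matrix(FALSE, n_drugs, n_samples,
                      dimnames = list(drugs, samples))
    sp <- truth$sensitive_pairs
    if (nrow(sp) > 0 && effect > 0) {
      if (is.null(target_matrix)) {
        .fail("`target_matrix` is required to place planted sensitive pairs")
      }
      for (i in seq_len(nrow(sp))) {
        g <- sp$gene_id[i]
        if (!g %in% rownames(target_matrix)) next
        hit <- colnames(target_matrix)[target_matrix[g, ] == 1]
        hit <- intersect(hit, drugs)
        shifted[hit, sp$sample_id[i]] <- TRUE
      }
    }

    rows <- vector("list", n_samples * n_drugs)
    k <- 0L
    for (s in seq_along(samples)) {
      for (d in seq_along(drugs)) {
        eff <- if (shifted[d, s]) effect else 0
        # decreasing logistic: full viability at low dose, 1 - eff at high
        viab <- 1 - eff / (1 + (mid_conc / conc))
        for (r in seq_len(n_replicates)) {
          sig <- blank_level +
            viab * (control_level - blank_level) +
            (if (noise_sd > 0) rnorm(n_doses, 0, noise_sd) else 0)
          k <- k + 1L
          rows[[k]] <- data.frame(
            sample_id = samples[s], drug_id = drugs[d],
            panel_id = sprintf("P%d", panel_of[d]), replicate = r,
            conc_uM = conc, signal = sig, well_type = "treated",
            stringsAsFactors = FALSE)
        }
      }
    }
    treated <- do.call(rbind, rows)

    # control and blank wells per (sample, panel, replicate) plate
    plates <- unique(treated[, c("sample_id", "panel_id", "replicate")])
    ctrl <- do.call(rbind, lapply(seq_len(nrow(plates)), function(i) {
      data.frame(
        sample_id = plates$sample_id[i], drug_id = NA_character_,
        panel_id = plates$panel_id[i], replicate = plates$replicate[i],
        conc_uM = NA_real_,
        signal = c(control_level +
                     (if (noise_sd > 0) rnorm(n_controls, 0, noise_sd) else
                        rep(0, n_controls)),
                   blank_level +
                     (if (noise_sd > 0) rnorm(n_blanks, 0, noise_sd / 2) else
                        rep(0, n_blanks))),
        well_type = rep(c("control", "blank"), c(n_controls, n_blanks)),
        stringsAsFactors = FALSE)
    }))
    out <- rbind(treated, ctrl)
    rownames(out) <- NULL
    out
  })
}

#' Generate a drug-target evidence table
#'
#' Produces rows (drug, gene, assay_value_nM, n_publications) resembling a
#' curated drug-target resource. A controlled fraction of rows carries assay
#' values at or above the 100 nM confidence cutoff (so they are removed by
#' [filter_and_select()]), and publication counts vary so the
#' highest-category selection is exercised. Planted sensitive genes are
#' guaranteed `drugs_per_planted_gene` distinct drugs with sub-100 nM assay
#' values and top publication support, so they survive filtering.
#'
#' @param n_drugs,n_genes universe sizes.
#' @param targets_per_drug integer vector of length 2, min and max targets
#'   drawn uniformly per drug.
#' @param fraction_above_100nM fraction of background rows given assay
#'   values >= 100 nM.
#' @param truth a [synthetic_truth()] object.
#' @param drugs_per_planted_gene how many drugs target each planted gene
#'   (default 8 - the multi-inhibitor coverage typical of a heavily drugged
#'   kinase in an oncology panel).
#' @param seed optional integer seed.
#' @return data.frame (drug_id, gene_id, assay_value_nM, n_publications).
#' @export
generate_target_db <- function(n_drugs, n_genes,
                               targets_per_drug = c(1, 3),
                               fraction_above_100nM = 0.2,
                               truth = synthetic_truth(),
                               drugs_per_planted_gene = 8,
                               seed = NULL) {
  n_drugs <- .check_count(n_drugs, "n_drugs")
  n_genes <- .check_count(n_genes, "n_genes")
  fraction_above_100nM <- .check_fraction(fraction_above_100nM,
                                          "fraction_above_100nM")
  if (n_genes < max(targets_per_drug)) {
    .fail("`n_genes` must be >= the maximum targets per drug")
  }
  .with_seed(seed, {
    drugs <- .drug_ids(n_drugs)
    genes <- .gene_ids(n_genes)
    rows <- lapply(seq_along(drugs), function(d) {
      k <- sample(seq(targets_per_drug[1], targets_per_drug[2]), 1)
      gs <- sample(genes, k)
      above <- runif(k) < fraction_above_100nM
      data.frame(
        drug_id = drugs[d], gene_id = gs,
        assay_value_nM = ifelse(above,
                                10^runif(k, 2, 4),          # 100 nM - 10 uM
                                10^runif(k, 0, log10(99))), # 1 - 99 nM
        n_publications = sample(1:5, k, replace = TRUE),
        stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, rows)

    planted <- unique(truth$sensitive_pairs$gene_id)
    planted <- intersect(planted, genes)
    if (length(planted) > 0) {
      m <- min(drugs_per_planted_gene, n_drugs)
      for (g in planted) {
        dsel <- sample(drugs, m)
        # drop any background rows for these (drug, gene) pairs first
        ev <- ev[!(ev$drug_id %in% dsel & ev$gene_id == g), ]
        ev <- rbind(ev, data.frame(
          drug_id = dsel, gene_id = g,
          assay_value_nM = 10^runif(m, 0, log10(50)),
          n_publications = 5L, stringsAsFactors = FALSE))
      }
    }
    rownames(ev) <- NULL
    ev
  })
}

#' Generate a scored gene-interaction network
#'
#' Builds a connected preferential-attachment graph over the gene universe
#' with per-edge confidence scores in [0, 1]. Most edges score above the
#' default 0.95 filter; a configurable fraction scores lower so the filter is
#' exercised. Planted driver genes are guaranteed an edge to a targeted
#' (planted sensitive) gene so they sit within one hop of the propagation
#' seeds.
#'
#' @param n_genes number of nodes.
#' @param attach_m edges added per new node (preferential attachment).
#' @param frac_low_score fraction of background edges scored below 0.95.
#' @param truth a [synthetic_truth()] object; edges between each driver gene
#'   and one planted sensitive gene are added (score 0.99) if absent.
#' @param seed optional integer seed.
#' @return data.frame (gene_a, gene_b, score); the graph ignoring scores is
#'   connected.
#' @export
generate_network <- function(n_genes, attach_m = 2, frac_low_score = 0.1,
                             truth = synthetic_truth(), seed = NULL) {
  n_genes <- .check_count(n_genes, "n_genes")
  attach_m <- .check_count(attach_m, "attach_m")
  if (n_genes <= attach_m) .fail("`n_genes` must exceed `attach_m`")
  .with_seed(seed, {
    genes <- .gene_ids(n_genes)
    g <- igraph::sample_pa(n_genes, m = attach_m, directed = FALSE)
    # map gene ids onto graph nodes: planted drivers take low-degree nodes
    # and planted targets take median-degree nodes, so neither is a hub
    # whose propagation score would be explained by degree alone
    drivers <- intersect(unique(truth$driver_genes$gene_id), genes)
    targets <- intersect(unique(truth$sensitive_pairs$gene_id), genes)
    deg <- igraph::degree(g)
    node_of <- integer(n_genes)
    names(node_of) <- genes
    by_deg <- order(deg)                      # node ids, ascending degree
    taken <- integer(0)
    if (length(drivers) > 0) {
      node_of[drivers] <- by_deg[seq_along(drivers)]
      taken <- node_of[drivers]
    }
    if (length(targets) > 0) {
      mid <- by_deg[setdiff(seq_len(n_genes),
                            seq_along(drivers))]
      mid <- mid[ceiling(length(mid) / 2) + seq_along(targets) - 1]
      node_of[targets] <- mid
      taken <- c(taken, mid)
    }
    rest <- setdiff(genes, c(drivers, targets))
    node_of[rest] <- sample(setdiff(seq_len(n_genes), taken))
    gene_of_node <- character(n_genes)
    gene_of_node[node_of] <- names(node_of)
    el <- igraph::as_edgelist(g, names = FALSE)
    el <- data.frame(gene_a = gene_of_node[el[, 1]],
                     gene_b = gene_of_node[el[, 2]],
                     stringsAsFactors = FALSE)
    n_e <- nrow(el)
    low <- runif(n_e) < frac_low_score
    el$score <- ifelse(low, runif(n_e, 0.5, 0.95), runif(n_e, 0.951, 1.0))

    drivers <- unique(truth$driver_genes$gene_id)
    targets <- unique(truth$sensitive_pairs$gene_id)
    if (length(drivers) > 0 && length(targets) > 0) {
      for (dg in drivers) {
        tg <- targets[1]
        has <- (el$gene_a == dg & el$gene_b == tg) |
          (el$gene_a == tg & el$gene_b == dg)
        if (any(has)) {
          el$score[has] <- pmax(el$score[has], 0.99)
        } else {
          el <- rbind(el, data.frame(gene_a = dg, gene_b = tg, score = 0.99,
                                     stringsAsFactors = FALSE))
        }
      }
    }
    rownames(el) <- NULL
    el
  })
}

#' Generate somatic variants, copy-number segments and gene intervals
#'
#' Produces an annotated MAF-like somatic variant table, allele-specific
#' copy-number segments, and a BED-like gene-interval annotation over a toy
#' single-chromosome genome (consecutive 10 kb gene intervals). Background
#' variants occur independently per (sample, gene) at `background_rate` with
#' randomized annotations, so only a subset survives variant filtering.
#' Planted driver alterations are always present and always survive: PASS
#' missense calls with population allele frequency 1e-4, SIFT deleterious,
#' PolyPhen probably_damaging and ClinVar pathogenic.
#'
#' @param samples,genes character vectors of ids.
#' @param background_rate per-(sample, gene) probability of a background
#'   variant row.
#' @param truth a [synthetic_truth()] object; `truth$driver_genes` rows are
#'   planted.
#' @param amp_genes optional character vector of genes given a planted
#'   amplification (total copy number 5) in the driver samples.
#' @param seed optional integer seed.
#' @return list with `variants` (MAF-like data.frame), `segments`
#'   (sample_id, chrom, start, end, major, minor; 1-based closed) and
#'   `gene_intervals` (chrom, start, end, gene_id; BED, 0-based half-open).
#' @export
generate_alterations <- function(samples, genes, background_rate = 0.02,
                                 truth = synthetic_truth(),
                                 amp_genes = character(), seed = NULL) {
  background_rate <- .check_fraction(background_rate, "background_rate")
  .with_seed(seed, {
    n_s <- length(samples); n_g <- length(genes)
    # gene intervals: 10 kb genes with 10 kb gaps on one chromosome (BED)
    width <- 10000L
    starts <- (seq_len(n_g) - 1L) * 2L * width
    gene_intervals <- data.frame(chrom = "chr1", start = starts,
                                 end = starts + width, gene_id = genes,
                                 stringsAsFactors = FALSE)

    consequences <- c("missense_variant", "stop_gained",
                      "frameshift_variant", "synonymous_variant",
                      "intron_variant")
    mk_bg <- function() {
      hit <- which(matrix(runif(n_s * n_g) < background_rate, n_s, n_g),
                   arr.ind = TRUE)
      if (nrow(hit) == 0) return(NULL)
      n <- nrow(hit)
      data.frame(
        sample_id = samples[hit[, 1]], gene_id = genes[hit[, 2]],
        filter_status = sample(c("PASS", "germline", "weak_evidence"), n,
                               replace = TRUE, prob = c(0.7, 0.2, 0.1)),
        consequence = sample(consequences, n, replace = TRUE),
        population_af = ifelse(runif(n) < 0.15, NA_real_,
                               ifelse(runif(n) < 0.2, runif(n, 0.01, 0.5),
                                      runif(n, 0, 0.009))),
        sift = sample(c("deleterious", "tolerated"), n, replace = TRUE),
        polyphen = sample(c("probably_damaging", "possibly_damaging",
                            "benign"), n, replace = TRUE),
        clinvar = sample(c("", "uncertain_significance", "pathogenic"), n,
                         replace = TRUE, prob = c(0.8, 0.15, 0.05)),
        stringsAsFactors = FALSE)
    }
    variants <- mk_bg()

    dv <- truth$driver_genes
    if (nrow(dv) > 0) {
      planted <- data.frame(
        sample_id = dv$sample_id, gene_id = dv$gene_id,
        filter_status = "PASS", consequence = "missense_variant",
        population_af = 1e-4, sift = "deleterious",
        polyphen = "probably_damaging", clinvar = "pathogenic",
        stringsAsFactors = FALSE)
      variants <- rbind(variants, planted)
    }
    if (is.null(variants)) {
      variants <- data.frame(sample_id = character(), gene_id = character(),
                             filter_status = character(),
                             consequence = character(),
                             population_af = numeric(), sift = character(),
                             polyphen = character(), clinvar = character(),
                             stringsAsFactors = FALSE)
    }
    rownames(variants) <- NULL

    # segments: whole-chromosome diploid baseline per sample, plus focal
    # amplification segments over `amp_genes` in the driver samples
    chrom_end <- max(gene_intervals$end)
    segs <- data.frame(sample_id = samples, chrom = "chr1", start = 1L,
                       end = chrom_end, major = 1L, minor = 1L,
                       stringsAsFactors = FALSE)
    if (length(amp_genes) > 0 && nrow(dv) > 0) {
      for (g in intersect(amp_genes, genes)) {
        gi <- gene_intervals[gene_intervals$gene_id == g, ]
        segs <- rbind(segs, data.frame(
          sample_id = unique(dv$sample_id), chrom = "chr1",
          start = gi$start + 1L, end = gi$end, major = 4L, minor = 1L,
          stringsAsFactors = FALSE))
      }
    }
    rownames(segs) <- NULL
    list(variants = variants, segments = segs,
         gene_intervals = gene_intervals)
  })
}

#' Default block-structured subtype centroids
#'
#' Four centroids (Atypical, Basal, Classical, Mesenchymal) over `n_genes`
#' genes: each subtype up-regulates its own quarter of the genes (+2) and
#' mildly down-regulates the rest (-0.5), giving clearly separated,
#' negatively correlated centroids.
#'
#' @param n_genes number of centroid genes.
#' @param subtypes subtype labels (>= 2).
#' @return subtypes x genes numeric matrix.
#' @export
default_centroids <- function(n_genes = 200,
                              subtypes = c("Atypical", "Basal", "Classical",
                                           "Mesenchymal")) {
  if (length(subtypes) < 2) .fail("need >= 2 subtypes")
  genes <- .gene_ids(n_genes)
  cent <- matrix(-0.5, length(subtypes), n_genes,
                 dimnames = list(subtypes, genes))
  block <- rep(seq_along(subtypes), length.out = n_genes)
  for (i in seq_along(subtypes)) cent[i, block == i] <- 2
  cent
}

#' Generate an expression cohort around subtype centroids
#'
#' Each sample is drawn as its subtype centroid plus iid Gaussian noise; a
#' configurable fraction of samples is instead drawn midway between two
#' centroids to create ambiguous cases.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param centroids subtypes x genes matrix; defaults to
#'   [default_centroids()].
#' @param within_sd per-gene noise SD around the centroid.
#' @param ambiguous_frac fraction of samples placed midway between two
#'   centroids.
#' @param truth a [synthetic_truth()] object (used only to carry the seed).
#' @param seed optional integer seed.
#' @return list with `expression` (genes x samples), `centroids` and
#'   `labels` (named character; ambiguous samples keep the first of their
#'   two parent subtypes).
#' @export
generate_expression_cohort <- function(n_samples, n_genes = 200,
                                       centroids = NULL, within_sd = 0.3,
                                       ambiguous_frac = 0,
                                       truth = synthetic_truth(),
                                       seed = NULL) {
  n_samples <- .check_count(n_samples, "n_samples")
  ambiguous_frac <- .check_fraction(ambiguous_frac, "ambiguous_frac")
  if (is.null(centroids)) centroids <- default_centroids(n_genes)
  if (!all(colnames(centroids) %in% .gene_ids(n_genes)) &&
      is.null(colnames(centroids))) {
    .fail("`centroids` must have gene column names")
  }
  .with_seed(seed, {
    samples <- .sample_ids(n_samples)
    subtypes <- rownames(centroids)
    labels <- rep(subtypes, length.out = n_samples)  # balanced by design
    n_amb <- round(ambiguous_frac * n_samples)
    amb <- seq_len(n_amb)
    expr <- matrix(NA_real_, ncol(centroids), n_samples,
                   dimnames = list(colnames(centroids), samples))
    for (s in seq_len(n_samples)) {
      base <- centroids[labels[s], ]
      if (s %in% amb) {
        # cyclic partner keeps the cohort balanced across subtypes, so
        # per-gene median centering does not break the ambiguity
        other <- subtypes[(match(labels[s], subtypes) %% length(subtypes)) + 1]
        base <- (centroids[labels[s], ] + centroids[other, ]) / 2
      }
      expr[, s] <- base + (if (within_sd > 0)
        rnorm(ncol(centroids), 0, within_sd) else 0)
    }
    names(labels) <- samples
    list(expression = expr, centroids = centroids, labels = labels)
  })
}

#' Simulate a rescaled AUC matrix directly
#'
#' Bypasses the plate level: draws drug x sample AUC values around a common
#' baseline and shifts planted carrier samples down by `shift_sd` within-drug
#' standard deviations in every drug targeting the planted gene. Used for
#' calibration and power studies of the gene score where the dose-response
#' stage is not under test.
#'
#' @param n_drugs,n_samples matrix dimensions.
#' @param target_matrix binary gene x drug matrix (may be `NULL` for a pure
#'   null matrix).
#' @param sensitive_pairs data.frame (sample_id, gene_id) of planted
#'   carriers.
#' @param baseline mean AUC (default 0.5).
#' @param sd within-drug AUC standard deviation (default 0.1).
#' @param shift_sd planted downward shift in units of `sd` (default 2).
#' @param seed optional integer seed.
#' @return drugs x samples numeric matrix, clipped to [0, 1].
#' @export
simulate_auc_matrix <- function(n_drugs, n_samples, target_matrix = NULL,
                                sensitive_pairs = NULL, baseline = 0.5,
                                sd = 0.1, shift_sd = 2, seed = NULL) {
  n_drugs <- .check_count(n_drugs, "n_drugs")
  n_samples <- .check_count(n_samples, "n_samples")
  .with_seed(seed, {
    drugs <- .drug_ids(n_drugs)
    samples <- .sample_ids(n_samples)
    X <- matrix(rnorm(n_drugs * n_samples, baseline, sd), n_drugs, n_samples,
                dimnames = list(drugs, samples))
    if (!is.null(sensitive_pairs) && nrow(sensitive_pairs) > 0) {
      if (is.null(target_matrix)) {
        .fail("`target_matrix` required to place planted sensitive pairs")
      }
      for (i in seq_len(nrow(sensitive_pairs))) {
        g <- sensitive_pairs$gene_id[i]
        s <- sensitive_pairs$sample_id[i]
        if (!g %in% rownames(target_matrix) || !s %in% samples) next
        hit <- colnames(target_matrix)[target_matrix[g, ] == 1]
        hit <- intersect(hit, drugs)
        X[hit, s] <- X[hit, s] - shift_sd * sd
      }
    }
    pmin(pmax(X, 0), 1)
  })
}

#' Simulate combination-response AUCs from single-agent AUCs
#'
#' For each combination the per-sample AUC is the minimum of its components
#' multiplied by `potency_ratio` on the natural scale (values < 1 mean the
#' combination is more sensitive than its best single agent), with
#' multiplicative log-normal noise.
#'
#' @param auc single-agent drugs x samples AUC matrix.
#' @param combo_map data.frame (combo_id, component_id), two or more rows per
#'   combination.
#' @param potency_ratio multiplicative shift of the combination relative to
#'   its best single agent.
#' @param noise_sd SD of the log-scale noise.
#' @param seed optional integer seed.
#' @return combos x samples AUC matrix clipped to [0, 1].
#' @export
generate_combination_response <- function(auc, combo_map,
                                          potency_ratio = 0.7,
                                          noise_sd = 0.1, seed = NULL) {
  stopifnot(all(c("combo_id", "component_id") %in% names(combo_map)))
  .with_seed(seed, {
    combos <- unique(combo_map$combo_id)
    out <- matrix(NA_real_, length(combos), ncol(auc),
                  dimnames = list(combos, colnames(auc)))
    for (cb in combos) {
      comp <- combo_map$component_id[combo_map$combo_id == cb]
      comp <- intersect(comp, rownames(auc))
      if (length(comp) == 0) next
      ref <- apply(auc[comp, , drop = FALSE], 2, min)
      out[cb, ] <- ref * potency_ratio * exp(rnorm(ncol(auc), 0, noise_sd))
    }
    pmin(pmax(out, 0), 1)
  })
}
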