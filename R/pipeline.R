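# End-to-end orchestration: synthetic cohort generation -> dose response ->
# target matrix -> gene scores -> network prioritization -> genomic
# integration -> subtype calls -> combination stats -> Response Cards, with
# a manifest of outputs and seeds.

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    cohort = list(n_samples = 12L, n_drugs = 40L, n_genes = 120L,
                  n_expression_genes = 200L, n_rppa = 50L),
    plates = list(n_doses = 7L, dilution_factor = 3, top_conc = 10,
                  noise_sd = 0.05, effect = 0.6, n_replicates = 2L,
                  n_panels = 1L),
    planted = list(sensitive_gene = "G0001",
                   carrier_samples = c("S01", "S02"),
                   driver_gene = "G0050",
                   drugs_per_planted_gene = 8L,
                   amp_genes = character()),
    targets = list(targets_per_drug = c(1L, 3L),
                   fraction_above_100nM = 0.2),
    network = list(attach_m = 2L, frac_low_score = 0.1,
                   score_threshold = 0.95),
    scoring = list(n_perm = 1000L, min_samples = 2L, fit_kind = "ols"),
    propagation = list(c = 0.7, tol = 1e-6, n_rewired = 1000L,
                       swaps_per_edge = 10L, alpha = 0.05),
    alterations = list(background_rate = 0.02),
    expression = list(within_sd = 0.3, ambiguous_frac = 0),
    combinations = list(n_combos = 10L, potency_ratio = 0.7,
                        noise_sd = 0.1))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config path to a YAML file or a named list; values override the
#'   package defaults.
#' @param ... further top-level overrides (e.g. `out_dir`), applied last.
#' @return the merged configuration list.
#' @export
load_config <- function(config = list(), ...) {
  if (is.character(config)) {
    if (!file.exists(config)) .fail("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .fail("`config` must be a list or a YAML path")
  cfg <- .merge_config(.default_config(), config)
  cfg <- .merge_config(cfg, list(...))
  for (req in c("seed", "out_dir")) {
    if (is.null(cfg[[req]])) .fail("config field missing: `", req, "`")
  }
  cfg$seed <- .check_count(cfg$seed, "seed")
  cfg
}

.stage <- function(name, expr) {
  message("[respcard] stage: ", name)
  tryCatch(expr, error = function(e) {
    .fail("pipeline stage `", name, "` failed: ", conditionMessage(e))
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage on generated data with the planted truth recorded:
#' viability plates are processed into harmonized AUC values, drug-target
#' evidence is filtered into the binary target matrix, gene scores and
#' permutation p-values are computed, significant genes are propagated over
#' the generated interaction network with RDPN p-values and altered-gene
#' prioritization for each patient with a seedable tier, genomic and
#' expression evidence is integrated, subtypes are called, combinations are
#' tested, and a Response Card is assembled and exported per scored
#' patient. All tables, card JSONs and a manifest (file checksums and
#' seeds) are written under `out_dir`.
#'
#' @param config path to a YAML config or a named list (see
#'   [load_config()]); `seed` and `out_dir` are required.
#' @param ... top-level config overrides, e.g. `out_dir` when running the
#'   bundled demo config.
#' @return invisibly, a list with all intermediate results, the planted
#'   `truth` and the `manifest`.
#' @export
run_pipeline <- function(config, ...) {
  cfg <- load_config(config, ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  samples <- .sample_ids(cfg$cohort$n_samples)
  genes <- .gene_ids(cfg$cohort$n_genes)
  carriers <- intersect(cfg$planted$carrier_samples, samples)
  truth <- synthetic_truth(
    sensitive_pairs = data.frame(sample_id = carriers,
                                 gene_id = cfg$planted$sensitive_gene,
                                 stringsAsFactors = FALSE),
    driver_genes = data.frame(sample_id = carriers,
                              gene_id = cfg$planted$driver_gene,
                              stringsAsFactors = FALSE),
    seed = cfg$seed)

  evidence <- .stage("targetome", {
    generate_target_db(
      cfg$cohort$n_drugs, cfg$cohort$n_genes,
      targets_per_drug = cfg$targets$targets_per_drug,
      fraction_above_100nM = cfg$targets$fraction_above_100nM,
      truth = truth,
      drugs_per_planted_gene = cfg$planted$drugs_per_planted_gene)
  })
  filtered_ev <- filter_and_select(evidence)
  target_matrix <- suppressWarnings(
    build_target_matrix(filtered_ev, genes = genes,
                        drugs = .drug_ids(cfg$cohort$n_drugs)))

  auc_res <- .stage("dose_response", {
    plates <- generate_viability_plates(
      cfg$cohort$n_samples, cfg$cohort$n_drugs,
      n_doses = cfg$plates$n_doses,
      dilution_factor = cfg$plates$dilution_factor,
      top_conc = cfg$plates$top_conc, noise_sd = cfg$plates$noise_sd,
      effect = cfg$plates$effect, truth = truth,
      target_matrix = target_matrix,
      n_replicates = cfg$plates$n_replicates,
      n_panels = cfg$plates$n_panels)
    compute_auc_matrix(plates, fit_kind = cfg$scoring$fit_kind)
  })

  scores <- .stage("gene_score", {
    Z <- zscore_by_drug(auc_res$auc, min_samples = cfg$scoring$min_samples)
    list(Z = Z,
         result = permutation_pvalues(target_matrix, Z,
                                      n_perm = cfg$scoring$n_perm))
  })

  net <- .stage("network", {
    edges <- generate_network(cfg$cohort$n_genes,
                              attach_m = cfg$network$attach_m,
                              frac_low_score = cfg$network$frac_low_score,
                              truth = truth)
    build_network(edges, score_threshold = cfg$network$score_threshold)
  })

  genomics <- .stage("genomic_integration", {
    alts <- generate_alterations(samples, genes,
                                 background_rate =
                                   cfg$alterations$background_rate,
                                 truth = truth,
                                 amp_genes = cfg$planted$amp_genes)
    list(alterations = alts,
         variants = filter_variants(alts$variants),
         cna = call_gene_copy_number(alts$segments, alts$gene_intervals))
  })
  profile <- build_alteration_profile(genomics$variants, genomics$cna,
                                      gene_subset = genes,
                                      sample_ids = samples)

  expr <- .stage("expression", {
    cohort <- generate_expression_cohort(
      cfg$cohort$n_samples, cfg$cohort$n_expression_genes,
      within_sd = cfg$expression$within_sd,
      ambiguous_frac = cfg$expression$ambiguous_frac, truth = truth)
    rppa <- generate_expression_cohort(
      cfg$cohort$n_samples, cfg$cohort$n_rppa,
      centroids = default_centroids(cfg$cohort$n_rppa),
      within_sd = cfg$expression$within_sd * 2, truth = truth)
    list(cohort = cohort, rppa = rppa,
         expr_z = cohort_zscore(cohort$expression),
         rppa_z = cohort_zscore(rppa$expression),
         calls = call_subtypes(cohort$expression, cohort$centroids))
  })

  combos <- .stage("combination_stats", {
    n_cb <- cfg$combinations$n_combos
    drugs <- rownames(auc_res$auc)
    combo_map <- do.call(rbind, lapply(seq_len(n_cb), function(i) {
      data.frame(combo_id = sprintf("C%03d", i),
                 component_id = sample(drugs, 2),
                 stringsAsFactors = FALSE)
    }))
    combo_auc <- generate_combination_response(
      auc_res$auc, combo_map,
      potency_ratio = cfg$combinations$potency_ratio,
      noise_sd = cfg$combinations$noise_sd)
    list(map = combo_map, auc = combo_auc,
         results = test_combinations(combo_auc, auc_res$auc, combo_map))
  })

  prio <- .stage("network_prioritization", {
    out <- list()
    for (s in samples) {
      p0 <- tryCatch(build_seed_vector(scores$result, s, net$nodes),
                     error = function(e) NULL)
      if (is.null(p0)) next
      rd <- rdpn_pvalues(net, p0,
                         n_rewired = cfg$propagation$n_rewired,
                         c = cfg$propagation$c, tol = cfg$propagation$tol,
                         swaps_per_edge = cfg$propagation$swaps_per_edge)
      altered <- colnames(profile)[profile[s, ] == 1]
      ranked <- prioritize_altered_genes(rd, altered,
                                         alpha = cfg$propagation$alpha)
      seeds <- names(p0)[p0 > 0]
      terminals <- union(seeds, ranked$gene_id)
      sub <- if (length(terminals) > 1) {
        extract_subnetwork(net, terminals)
      } else NULL
      out[[s]] <- list(p0 = p0, rdpn = rd, prioritized = ranked,
                       subnetwork = sub)
    }
    out
  })

  cards <- .stage("response_card", {
    out <- list()
    for (s in names(prio)) {
      dz <- scores$Z[, s]
      # extra panel genes: targets of the most sensitive drug that has
      # annotated targets at all
      covered <- names(dz)[names(dz) %in% colnames(target_matrix)]
      top_drug <- covered[which.min(dz[covered])]
      extra <- rownames(target_matrix)[target_matrix[, top_drug] == 1]
      card <- assemble_card(
        s, scores$Z, scores$result, target_matrix,
        filtered_variants = genomics$variants, cna_calls = genomics$cna,
        expr_z = expr$expr_z, rppa_z = expr$rppa_z,
        prioritized = prio[[s]]$prioritized,
        subnetwork = prio[[s]]$subnetwork, extra_genes = extra)
      export_card(card, file.path(cfg$out_dir,
                                  paste0("card_", s, ".json")),
                  format = "json")
      out[[s]] <- card
    }
    out
  })

  .stage("write_outputs", {
    write_tsv_table(auc_res$auc, file.path(cfg$out_dir, "auc_matrix.tsv"))
    write_tsv_table(auc_res$harmonized,
                    file.path(cfg$out_dir, "auc_flags.tsv"))
    write_tsv_table(target_matrix,
                    file.path(cfg$out_dir, "target_matrix.tsv"))
    write_tsv_table(scores$result$p, file.path(cfg$out_dir, "gene_p.tsv"))
    write_tsv_table(scores$result$scores,
                    file.path(cfg$out_dir, "gene_scores.tsv"))
    write_tsv_table(expr$calls, file.path(cfg$out_dir,
                                          "subtype_calls.tsv"))
    write_tsv_table(combos$results,
                    file.path(cfg$out_dir, "combination_tests.tsv"))
    write_tsv_table(genomics$variants,
                    file.path(cfg$out_dir, "filtered_variants.tsv"))
    write_tsv_table(genomics$cna, file.path(cfg$out_dir, "cna_calls.tsv"))
    truth_json <- jsonlite::toJSON(unclass(truth), dataframe = "rows",
                                   auto_unbox = TRUE, null = "null",
                                   na = "null")
    writeLines(truth_json, file.path(cfg$out_dir, "truth.json"))
  })

  files <- sort(list.files(cfg$out_dir, full.names = TRUE,
                           pattern = "\\.(tsv|json)$"))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = cfg$seed,
                   files = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE))
  writeLines(jsonlite::toJSON(manifest, dataframe = "rows",
                              auto_unbox = TRUE),
             file.path(cfg$out_dir, "manifest.json"))

  invisible(list(config = cfg, truth = truth, auc = auc_res,
                 target_matrix = target_matrix, scores = scores,
                 network = net, genomics = genomics, profile = profile,
                 expression = expr, combinations = combos,
                 prioritization = prio, cards = cards,
                 manifest = manifest))
}
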