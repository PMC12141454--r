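# Synthetic-data generators: determinism, planted structure, and the
# assay-design conventions they emulate.

truth_small <- synthetic_truth(
  sensitive_pairs = data.frame(sample_id = "S01", gene_id = "G0001",
                               stringsAsFactors = FALSE),
  driver_genes = data.frame(sample_id = "S01", gene_id = "G0010",
                            stringsAsFactors = FALSE))

test_that("all generators are byte-identical under a fixed seed", {
  tm <- matrix(1L, 1, 2, dimnames = list("G0001", c("D001", "D002")))
  expect_identical(
    generate_viability_plates(3, 4, truth = truth_small,
                              target_matrix = tm, seed = 7),
    generate_viability_plates(3, 4, truth = truth_small,
                              target_matrix = tm, seed = 7))
  expect_identical(generate_target_db(6, 20, truth = truth_small, seed = 7),
                   generate_target_db(6, 20, truth = truth_small, seed = 7))
  expect_identical(generate_network(30, truth = truth_small, seed = 7),
                   generate_network(30, truth = truth_small, seed = 7))
  expect_identical(
    generate_alterations(c("S01", "S02"), sprintf("G%04d", 1:20),
                         truth = truth_small, seed = 7),
    generate_alterations(c("S01", "S02"), sprintf("G%04d", 1:20),
                         truth = truth_small, seed = 7))
  expect_identical(generate_expression_cohort(8, 40, seed = 7),
                   generate_expression_cohort(8, 40, seed = 7))
})

test_that("dilution series follows the 3-fold 7-point design", {
  pl <- generate_viability_plates(1, 1, n_doses = 7, dilution_factor = 3,
                                  top_conc = 10, noise_sd = 0, effect = 0,
                                  n_replicates = 1, seed = 1)
  conc <- pl$conc_uM[pl$well_type == "treated"]
  expect_equal(conc, 10 / 3^(0:6))
})

test_that("no effect and no noise puts treated wells at the control mean", {
  pl <- generate_viability_plates(2, 3, noise_sd = 0, effect = 0, seed = 1)
  ctrl_mean <- mean(pl$signal[pl$well_type == "control"])
  expect_true(all(abs(pl$signal[pl$well_type == "treated"] -
                        ctrl_mean) < 1e-12))
})

test_that("plate generator rejects non-positive counts", {
  expect_error(generate_viability_plates(0, 3), "n_samples")
  expect_error(generate_viability_plates(3, 3, n_doses = 1), "n_doses")
})

test_that("target db guarantees the planted gene passes filtering on >= 2 drugs", {
  ev <- generate_target_db(20, 50, truth = truth_small,
                           drugs_per_planted_gene = 8, seed = 3)
  kept <- filter_and_select(ev)
  n_drugs_hit <- length(unique(kept$drug_id[kept$gene_id == "G0001"]))
  expect_gte(n_drugs_hit, 2)
  expect_equal(n_drugs_hit, 8)
})

test_that("all-weak assay values leave nothing after the 100 nM filter", {
  ev <- generate_target_db(10, 30, fraction_above_100nM = 1, seed = 3)
  expect_equal(nrow(filter_and_select(ev)), 0)
})

test_that("attach_m = 1 network is a tree and drivers sit within 2 hops of a target", {
  el <- generate_network(25, attach_m = 1, truth = truth_small, seed = 5)
  g <- igraph::graph_from_data_frame(el[, 1:2], directed = FALSE)
  # planted driver edge can add one edge to the tree
  expect_lte(nrow(el), 25)
  el2 <- generate_network(40, attach_m = 2, truth = truth_small, seed = 5)
  g2 <- igraph::graph_from_data_frame(el2[, 1:2], directed = FALSE)
  d <- igraph::distances(g2, v = "G0010", to = "G0001")
  expect_lte(as.numeric(d), 2)
})

test_that("background alteration rate 0 leaves only planted rows", {
  alt <- generate_alterations(c("S01", "S02"), sprintf("G%04d", 1:30),
                              background_rate = 0, truth = truth_small,
                              seed = 2)
  expect_equal(nrow(alt$variants), 1)
  expect_equal(alt$variants$gene_id, "G0010")
  expect_equal(alt$variants$clinvar, "pathogenic")
})

test_that("background variant count is binomial around rate * samples * genes", {
  samples <- sprintf("S%02d", 1:20)
  genes <- sprintf("G%04d", 1:200)
  rate <- 0.05
  alt <- generate_alterations(samples, genes, background_rate = rate,
                              seed = 11)
  n <- nrow(alt$variants)
  mu <- rate * length(samples) * length(genes)
  sd3 <- 3 * sqrt(mu * (1 - rate))
  expect_gt(n, mu - sd3)
  expect_lt(n, mu + sd3)
})

test_that("common-AF variants never survive the frequency filter", {
  v <- make_variant(population_af = 0.5)
  expect_equal(nrow(filter_variants(v)), 0)
})

test_that("noiseless expression equals the centroid and labels are balanced", {
  coh <- generate_expression_cohort(8, 40, within_sd = 0, seed = 4)
  for (s in names(coh$labels)) {
    expect_equal(unname(coh$expression[, s]),
                 unname(coh$centroids[coh$labels[s], ]))
  }
  expect_true(all(table(coh$labels) == 2))
})

test_that("planted effect lowers AUC stochastically and monotonically", {
  tm <- matrix(1L, 1, 1, dimnames = list("G0001", "D001"))
  truth1 <- synthetic_truth(
    sensitive_pairs = data.frame(sample_id = "S01", gene_id = "G0001",
                                 stringsAsFactors = FALSE))
  mean_auc <- function(effect, seed) {
    vals <- vapply(seq_len(25), function(i) {
      pl <- generate_viability_plates(1, 1, noise_sd = 0.05,
                                      effect = effect, truth = truth1,
                                      target_matrix = tm,
                                      n_replicates = 1,
                                      seed = seed + i)
      compute_auc_matrix(pl)$auc["D001", "S01"]
    }, numeric(1))
    mean(vals)
  }
  a0 <- mean_auc(0.0, 100)
  a3 <- mean_auc(0.3, 200)
  a7 <- mean_auc(0.7, 300)
  expect_gt(a0, a3)
  expect_gt(a3, a7)
})
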