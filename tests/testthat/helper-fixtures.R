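# Shared in-code fixtures for the test suite.

# plate rows for a single run with known viability, on a plate whose control
# mean is 1 and blank mean is 0 (so signal == viability)
make_run_plate <- function(viability, conc = 10 / 3^(0:(length(viability) - 1)),
                           sample_id = "S01", drug_id = "D001",
                           panel_id = "P1", replicate = 1) {
  treated <- data.frame(sample_id = sample_id, drug_id = drug_id,
                        panel_id = panel_id, replicate = replicate,
                        conc_uM = conc, signal = viability,
                        well_type = "treated", stringsAsFactors = FALSE)
  ctrl <- data.frame(sample_id = sample_id, drug_id = NA_character_,
                     panel_id = panel_id, replicate = replicate,
                     conc_uM = NA_real_, signal = c(1, 1, 0, 0),
                     well_type = c("control", "control", "blank", "blank"),
                     stringsAsFactors = FALSE)
  rbind(treated, ctrl)
}

# minimal gene_score_result with given tier/p/score matrices
make_score_result <- function(scores, p, tier) {
  structure(list(scores = scores, p = p, tier = tier,
                 n_perm = 1000L, seed = 1L),
            class = "gene_score_result")
}

# scored edge list for a connected random graph (all scores 1)
random_edgelist <- function(n, p_edge = 0.2) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::components(g)$no == 1) break
  }
  el <- igraph::as_edgelist(g)
  data.frame(gene_a = sprintf("g%02d", el[, 1]),
             gene_b = sprintf("g%02d", el[, 2]),
             score = 1, stringsAsFactors = FALSE)
}

# one-row variant record with overridable annotation fields
make_variant <- function(...) {
  base <- list(sample_id = "S01", gene_id = "G0001",
               filter_status = "PASS", consequence = "missense_variant",
               population_af = 0.0001, sift = "deleterious",
               polyphen = "probably_damaging", clinvar = "")
  args <- utils::modifyList(base, list(...))
  as.data.frame(args, stringsAsFactors = FALSE)
}
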