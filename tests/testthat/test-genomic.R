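# Variant filtering, gene-level copy-number calling, concordance labels,
# alteration profiles, Jaccard matching and AUC correlation.

test_that("variant filtering applies the frequency, consequence and predictor rules", {
  # common variant removed
  expect_equal(nrow(filter_variants(make_variant(population_af = 0.5))), 0)
  # ClinVar pathogenic rescues a SIFT-tolerated variant
  v <- make_variant(sift = "tolerated", clinvar = "pathogenic")
  expect_equal(nrow(filter_variants(v)), 1)
  # without the rescue, a tolerated call fails the both-predictors rule
  expect_equal(nrow(filter_variants(make_variant(sift = "tolerated"))), 0)
  # synonymous variants never pass absent ClinVar
  expect_equal(nrow(filter_variants(
    make_variant(consequence = "synonymous_variant"))), 0)
  # caller filter must be PASS
  expect_equal(nrow(filter_variants(
    make_variant(filter_status = "germline"))), 0)
  # missing AF is treated as novel and flagged
  out <- filter_variants(make_variant(population_af = NA_real_))
  expect_equal(nrow(out), 1)
  expect_true(out$af_missing)
  # blocklisted genes are removed
  expect_equal(nrow(filter_variants(make_variant(), blocklist = "G0001")), 0)
})

test_that("variant filtering is idempotent and order-independent", {
  set.seed(3)
  alt <- generate_alterations(sprintf("S%02d", 1:5), sprintf("G%04d", 1:50),
                              background_rate = 0.2, seed = 3)
  v <- alt$variants
  f1 <- filter_variants(v)
  expect_equal(filter_variants(f1), f1)
  f2 <- filter_variants(v[rev(seq_len(nrow(v))), ])
  expect_setequal(paste(f1$sample_id, f1$gene_id, f1$population_af),
                  paste(f2$sample_id, f2$gene_id, f2$population_af))
})

gi <- data.frame(chrom = "chr1", start = c(0, 20000, 40000),
                 end = c(10000, 30000, 50000),
                 gene_id = c("gA", "gB", "gC"), stringsAsFactors = FALSE)

test_that("diploid genomes give centered zero and neutral calls", {
  seg <- data.frame(sample_id = "S01", chrom = "chr1", start = 1,
                    end = 50000, major = 1, minor = 1)
  out <- call_gene_copy_number(seg, gi)
  expect_equal(out$centered_cn, rep(0, 3))
  expect_equal(out$call, rep("neutral", 3))
})

test_that("the max-|value| segment wins and boundaries are strict", {
  # five segments so the sample median is the diploid total of 2;
  # gene gB overlaps centered values +0.5 and -1.4 -> -1.4, del
  seg <- data.frame(
    sample_id = "S01", chrom = "chr1",
    start = c(1, 10001, 20001, 25001, 30001),
    end = c(10000, 20000, 25000, 30000, 50000),
    major = c(1, 1, 1.5, 0.3, 1), minor = c(1, 1, 1, 0.3, 1))
  out <- call_gene_copy_number(seg, gi)
  expect_equal(out$centered_cn[out$gene_id == "gB"], -1.4)
  expect_equal(out$call[out$gene_id == "gB"], "del")
  # centered exactly +1 stays neutral (strict >)
  seg2 <- data.frame(sample_id = "S01", chrom = "chr1",
                     start = c(1, 10001, 20001, 30001, 40001),
                     end = c(10000, 20000, 30000, 40000, 50000),
                     major = c(1, 1, 2, 1, 1), minor = c(1, 1, 1, 1, 1))
  out2 <- call_gene_copy_number(seg2, gi)
  expect_equal(out2$centered_cn[out2$gene_id == "gB"], 1)
  expect_equal(out2$call[out2$gene_id == "gB"], "neutral")
})

test_that("genes without overlapping segments get NA calls", {
  seg <- data.frame(sample_id = "S01", chrom = "chr1", start = 1,
                    end = 10000, major = 2, minor = 1)
  out <- call_gene_copy_number(seg, gi)
  expect_true(is.na(out$call[out$gene_id == "gC"]))
})

test_that("concordance labels follow the sign agreement rules", {
  expect_equal(classify_concordance("amp", 1.2, 0.8), "cA")
  expect_equal(classify_concordance("amp", -0.5, NA), "dA")
  expect_equal(classify_concordance("amp", 1.0, -0.2), "dA")  # mixed
  expect_equal(classify_concordance("del", -2.0, NA), "cD")
  expect_equal(classify_concordance("del", 0.5, NA), "dD")
  expect_true(is.na(classify_concordance("amp", NA, NA)))
  expect_true(is.na(classify_concordance("neutral", 1, 1)))
})

test_that("alteration profiles are the union of mutations and CNA calls", {
  vars <- make_variant(sample_id = "S01", gene_id = "gA")
  cna <- data.frame(sample_id = "S01", gene_id = c("gA", "gB"),
                    centered_cn = c(2, 0), call = c("amp", "neutral"),
                    stringsAsFactors = FALSE)
  prof <- build_alteration_profile(vars, cna, gene_subset = c("gA", "gB", "gC"),
                                   sample_ids = c("S01", "S02"))
  expect_equal(dim(prof), c(2L, 3L))
  expect_equal(unname(prof["S01", ]), c(1L, 0L, 0L))  # mutation+amp = one 1
  expect_equal(unname(prof["S02", ]), c(0L, 0L, 0L))
})

test_that("Jaccard matching satisfies the metric identities and hand counts", {
  genes <- c("g1", "g2", "g3")
  P <- rbind(p1 = c(1L, 1L, 0L), p2 = c(1L, 0L, 0L))
  colnames(P) <- genes
  C <- rbind(c1 = c(1L, 1L, 0L), c2 = c(0L, 1L, 1L), c3 = c(0L, 0L, 1L))
  colnames(C) <- genes
  m <- match_cell_lines(P, C)
  # identical profiles: distance 0
  expect_equal(m$distances["p1", "c1"], 0)
  # disjoint profiles: distance 1
  expect_equal(m$distances["p2", "c3"], 1)
  # A = {g1,g2}, B = {g2,g3}: 1 - 1/3
  expect_equal(m$distances["p1", "c2"], 2 / 3)
  expect_true(all(m$distances >= 0 & m$distances <= 1))
  expect_equal(m$matches$cell_line[m$matches$patient_id == "p1"], "c1")
  # empty profiles are excluded with a warning; all-empty errors
  P2 <- rbind(P, p3 = c(0L, 0L, 0L))
  expect_warning(match_cell_lines(P2, C), "empty")
  expect_error(match_cell_lines(P * 0L, C), "empty")
})

test_that("AUC correlation matches the textbook formula and guards n < 3", {
  x <- setNames(c(0.9, 0.8, 0.55, 0.4, 0.2), paste0("d", 1:5))
  y <- setNames(c(0.85, 0.7, 0.6, 0.35, 0.3), paste0("d", 1:5))
  out <- correlate_auc(x, y)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, manual)
  expect_equal(out$n_common, 5)
  expect_equal(correlate_auc(x, x)$r, 1)
  expect_equal(correlate_auc(x, setNames(1 - x, names(x)))$r, -1)
  expect_error(correlate_auc(x[1:2], y[1:2]), "insufficient")
})

test_that("matched synthetic cell lines correlate better than random pairings", {
  set.seed(12)
  tm <- matrix(0L, 4, 20, dimnames = list(paste0("g", 1:4),
                                          sprintf("D%03d", 1:20)))
  tm[1, 1:6] <- 1L
  tm[2, 7:12] <- 1L
  pairs <- data.frame(sample_id = c("S01", "S02"),
                      gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  # patients and their matched "cell lines" share the same planted gene
  pat <- simulate_auc_matrix(20, 2, tm, pairs, shift_sd = 3, seed = 41)
  cl <- simulate_auc_matrix(20, 2, tm, pairs, shift_sd = 3, seed = 42)
  matched <- mean(c(correlate_auc(pat[, 1], cl[, 1])$r,
                    correlate_auc(pat[, 2], cl[, 2])$r))
  crossed <- mean(c(correlate_auc(pat[, 1], cl[, 2])$r,
                    correlate_auc(pat[, 2], cl[, 1])$r))
  expect_gt(matched, crossed)
})
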