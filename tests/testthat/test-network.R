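# Interaction network construction, random walk with restarts,
# degree-preserving rewired nulls, altered-gene prioritization, and
# subnetwork extraction.

test_that("edge filtering, component selection and W match hand linear algebra", {
  # P3 path a-b-c: degrees 1,2,1 so the off-diagonal hub entries are 1/sqrt(2)
  el <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"), score = 1)
  net <- build_network(el)
  W <- as.matrix(net$W)
  dimnames(W) <- list(net$nodes, net$nodes)
  expect_equal(W["a", "b"], 1 / sqrt(2))
  expect_equal(W["b", "c"], 1 / sqrt(2))
  expect_equal(W["a", "c"], 0)
  expect_equal(W["a", "a"], 0)
})

test_that("low-score edges are removed and an empty filtered graph errors", {
  el <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                   score = c(0.99, 0.9))
  net <- build_network(el)
  expect_setequal(net$nodes, c("a", "b"))
  expect_error(build_network(data.frame(gene_a = "a", gene_b = "b",
                                        score = 0.9)), "threshold")
})

test_that("component ties break by score then lexicographic smallest node", {
  tri <- function(ns, sc) {
    data.frame(gene_a = ns[c(1, 2, 3)], gene_b = ns[c(2, 3, 1)], score = sc)
  }
  # equal node count, equal total score: lexicographically smaller wins
  el <- rbind(tri(c("a1", "a2", "a3"), 0.99), tri(c("b1", "b2", "b3"), 0.99))
  expect_setequal(build_network(el)$nodes, c("a1", "a2", "a3"))
  # higher total edge score wins over name order
  el2 <- rbind(tri(c("a1", "a2", "a3"), 0.96), tri(c("b1", "b2", "b3"), 0.99))
  expect_setequal(build_network(el2)$nodes, c("b1", "b2", "b3"))
})

test_that("seed vectors use the highest non-empty tier, uniformly normalized", {
  genes <- paste0("g", 1:6)
  tier <- matrix(NA_integer_, 6, 2, dimnames = list(genes, c("S01", "S02")))
  tier[c("g1", "g2"), "S01"] <- 1L
  tier[c("g3", "g4", "g5"), "S01"] <- 2L
  tier[c("g3", "g4", "g5"), "S02"] <- 2L
  p <- matrix(0.5, 6, 2, dimnames = dimnames(tier))
  sr <- make_score_result(p, p, tier)
  nodes <- genes
  p0 <- build_seed_vector(sr, "S01", nodes)
  expect_equal(unname(p0[c("g1", "g2")]), c(0.5, 0.5))
  expect_equal(sum(p0), 1)
  expect_equal(attr(p0, "tier_used"), 1L)
  # tier 1 empty: fall through to the three tier-2 genes
  p0b <- build_seed_vector(sr, "S02", nodes)
  expect_equal(unname(p0b[c("g3", "g4", "g5")]), rep(1 / 3, 3))
  expect_equal(attr(p0b, "tier_used"), 2L)
  # single tier-1 gene is an indicator
  tier2 <- tier
  tier2[, "S01"] <- NA_integer_
  tier2["g6", "S01"] <- 1L
  p0c <- build_seed_vector(make_score_result(p, p, tier2), "S01", nodes)
  expect_equal(unname(p0c), c(0, 0, 0, 0, 0, 1), ignore_attr = TRUE)
  # no tiered genes in the network: error names the patient
  expect_error(build_seed_vector(sr, "S01", c("x1", "x2")), "S01")
})

test_that("the two-node closed form is reproduced to six decimals", {
  net <- build_network(data.frame(gene_a = "A", gene_b = "B", score = 1))
  p0 <- setNames(as.numeric(net$nodes == "A"), net$nodes)
  pk <- propagate(net$W, p0, c = 0.7, tol = 1e-6)
  expect_equal(unname(pk[net$nodes == "A"]), 0.7 / 0.91, tolerance = 5e-7)
  expect_equal(unname(pk[net$nodes == "B"]), 0.21 / 0.91, tolerance = 5e-7)
})

test_that("full restart weight returns the seed vector unchanged", {
  net <- build_network(random_edgelist(10, 0.4))
  p0 <- setNames(numeric(length(net$nodes)), net$nodes)
  p0[1:2] <- 0.5
  pk <- propagate(net$W, p0, c = 1)
  expect_equal(unname(pk), unname(p0), ignore_attr = TRUE)
})

test_that("iterative propagation matches the dense linear solve", {
  set.seed(31)
  for (i in 1:20) {
    net <- build_network(random_edgelist(20, 0.2))
    n <- length(net$nodes)
    p0 <- setNames(numeric(n), net$nodes)
    p0[sample(n, 3)] <- 1 / 3
    pk <- propagate(net$W, p0, c = 0.7, tol = 1e-6)
    direct <- 0.7 * solve(diag(n) - 0.3 * as.matrix(net$W), p0)
    expect_lt(max(abs(pk - direct)), 1e-5)
    expect_true(all(pk >= 0))
    # mass bound from the geometric series with s = max column sum of W
    s <- max(Matrix::colSums(net$W))
    expect_lte(sum(pk), 0.7 / (1 - 0.3 * s) + 1e-8)
  }
})

test_that("propagation rejects malformed restarts and non-convergence", {
  net <- build_network(data.frame(gene_a = "A", gene_b = "B", score = 1))
  expect_error(propagate(net$W, c(0.5, 0.1)), "sum to 1")
  # with no restart a two-node walk oscillates and never converges
  expect_error(propagate(net$W, c(1, 0), c = 0, max_iter = 5), "converge")
})

test_that("rewired networks preserve the degree sequence exactly", {
  set.seed(17)
  el <- generate_network(40, attach_m = 2, seed = 17)
  net <- build_network(el)
  edge_idx <- cbind(match(net$edges$gene_a, net$nodes),
                    match(net$edges$gene_b, net$nodes)) - 1L
  storage.mode(edge_idx) <- "integer"
  deg0 <- sort(tabulate(c(edge_idx) + 1L, nbins = length(net$nodes)))
  for (i in 1:20) {
    rw <- respcard:::.rewire_edges_cpp(edge_idx, length(net$nodes),
                                       10L * nrow(edge_idx),
                                       1000L * nrow(edge_idx), i)
    deg <- tabulate(c(rw) + 1L, nbins = length(net$nodes))
    # per-node degree identical, not just the sorted sequence
    expect_identical(deg, tabulate(c(edge_idx) + 1L,
                                   nbins = length(net$nodes)))
    expect_identical(sort(deg), deg0)
    # simple graph: no loops or duplicate edges
    expect_true(all(rw[, 1] != rw[, 2]))
    key <- paste(pmin(rw[, 1], rw[, 2]), pmax(rw[, 1], rw[, 2]))
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("complete graphs cannot be rewired so all RDPN p-values are 1", {
  el <- expand.grid(i = 1:4, j = 1:4)
  el <- el[el$i < el$j, ]
  edges <- data.frame(gene_a = paste0("n", el$i), gene_b = paste0("n", el$j),
                      score = 1)
  net <- build_network(edges)
  p0 <- setNames(as.numeric(net$nodes == "n1"), net$nodes)
  expect_warning(rd <- rdpn_pvalues(net, p0, n_rewired = 50, seed = 1),
                 "no degree-preserving swap")
  expect_true(all(rd$p == 1))
})

test_that("neighbors of a peripheral seed attain lower RDPN p than distant genes", {
  el <- generate_network(40, attach_m = 2, seed = 23)
  net <- build_network(el)
  # seed a low-degree peripheral node so its score is not degree-driven
  deg <- igraph::degree(net$graph)
  seed_gene <- names(sort(deg))[1]
  p0 <- setNames(as.numeric(net$nodes == seed_gene), net$nodes)
  rd <- rdpn_pvalues(net, p0, n_rewired = 200, seed = 2)
  d <- igraph::distances(net$graph, v = seed_gene)[1, ]
  near <- names(d)[d == 1]
  far <- names(d)[d >= 3]
  expect_lt(median(rd$p[near]), median(rd$p[far]))
})

test_that("RDPN corrects the degree inflation that naive rank p-values miss", {
  # on preferential-attachment graphs a high-degree non-seed hub scores
  # high by propagation alone; its RDPN p should exceed its naive
  # rank-based p (median over replicates)
  set.seed(61)
  rel <- vapply(1:10, function(r) {
    el <- generate_network(50, attach_m = 2, seed = 400 + r)
    net <- build_network(el)
    deg <- igraph::degree(net$graph)
    seed_gene <- names(sort(deg))[1]
    hub <- names(sort(deg, decreasing = TRUE))[1]
    p0 <- setNames(as.numeric(net$nodes == seed_gene), net$nodes)
    rd <- rdpn_pvalues(net, p0, n_rewired = 100, seed = 500 + r)
    rank_p <- rank(-rd$score)[hub] / length(rd$score)
    c(rdpn = unname(rd$p[hub]), naive = unname(rank_p))
  }, numeric(2))
  expect_gt(median(rel["rdpn", ]), median(rel["naive", ]))
})

test_that("altered-gene prioritization uses strict alpha and sorts by score", {
  rd <- list(score = setNames(c(0.5, 0.3, 0.2, 0.1), paste0("g", 1:4)),
             p = setNames(c(0.01, 0.05, 0.04, 0.2), paste0("g", 1:4)))
  out <- prioritize_altered_genes(rd, c("g1", "g2", "g3", "g4"))
  expect_equal(out$gene_id, c("g1", "g3"))  # g2 at exactly 0.05 excluded
  expect_equal(out$score, sort(out$score, decreasing = TRUE))
  expect_equal(nrow(prioritize_altered_genes(rd, character())), 0)
})

test_that("subnetwork extraction returns trivial cases exactly", {
  el <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"),
                   score = 1)
  net <- build_network(el)
  # adjacent terminals: the connecting edge
  sub <- extract_subnetwork(net, c("a", "b"))
  expect_setequal(sub$nodes$gene_id, c("a", "b"))
  expect_equal(igraph::ecount(sub$graph), 1)
  # all nodes of a path graph: the path itself
  sub2 <- extract_subnetwork(net, c("a", "b", "c", "d"))
  expect_setequal(sub2$nodes$gene_id, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(sub2$graph), 3)
  expect_true(all(sub2$nodes$role == "terminal"))
  # missing terminals are reported
  sub3 <- extract_subnetwork(net, c("a", "zz"))
  expect_equal(sub3$excluded, "zz")
})

test_that("approximate Steiner cost stays within twice the exact optimum", {
  # exact minimum Steiner node set by exhaustive enumeration (unit weights)
  exact_steiner_cost <- function(g, terminals) {
    nodes <- igraph::V(g)$name
    others <- setdiff(nodes, terminals)
    for (k in 0:length(others)) {
      sets <- if (k == 0) list(character()) else
        asplit(utils::combn(others, k), 2)
      for (s in sets) {
        sel <- c(terminals, unlist(s))
        sub <- igraph::induced_subgraph(g, sel)
        if (igraph::is_connected(sub)) return(length(sel) - 1)
      }
    }
    stop("terminals not connectable")
  }
  set.seed(77)
  for (i in 1:20) {
    net <- build_network(random_edgelist(15, 0.2))
    terminals <- sample(net$nodes, 3)
    sub <- extract_subnetwork(net, terminals)
    approx_cost <- nrow(sub$nodes) - 1
    opt <- exact_steiner_cost(net$graph, terminals)
    expect_lte(approx_cost, 2 * opt)
    expect_true(igraph::is_connected(sub$graph))
  }
})

test_that("subnetworks export as SIF plus node attributes", {
  net <- build_network(data.frame(gene_a = c("a", "b"),
                                  gene_b = c("b", "c"), score = 1))
  sub <- extract_subnetwork(net, c("a", "c"))
  sif <- file.path(tempdir(), "sub.sif")
  natt <- file.path(tempdir(), "sub_nodes.tsv")
  write_subnetwork(sub, sif, natt)
  expect_equal(length(readLines(sif)), igraph::ecount(sub$graph))
  expect_equal(nrow(read_tsv_table(natt)), 3)
})
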