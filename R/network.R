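# Network propagation: confidence-filtered interaction network, random walk
# with restarts over the symmetrically normalized adjacency, a
# degree-preserving rewired-network (RDPN) null, prioritization of altered
# genes, and Steiner-style subnetwork extraction.

# symmetric normalization W = D^{-1/2} A D^{-1/2} of a sparse adjacency
.normalize_adjacency <- function(A) {
  d <- Matrix::rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(x = inv_sqrt)
  Dm %*% A %*% Dm
}

#' Build an interaction network from a scored edge list
#'
#' Edges with confidence score at or below `score_threshold` are removed,
#' directionality is discarded, self-loops and duplicate edges are
#' collapsed, and only the largest connected component is retained (ties
#' broken by node count, then total edge score, then the lexicographically
#' smallest node id). The symmetrically normalized adjacency
#' `W = D^{-1/2} A D^{-1/2}` is precomputed for propagation.
#'
#' @param edges data.frame with columns gene_a, gene_b, score.
#' @param score_threshold keep edges with score strictly greater than this
#'   (default 0.95).
#' @return object of class `interaction_network`: list with `graph`
#'   (igraph), `nodes`, `A` (sparse adjacency), `W` (normalized), `edges`
#'   (retained edge list).
#' @export
build_network <- function(edges, score_threshold = 0.95) {
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges))) {
    .fail("edges must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(edges) == 0) .fail("empty edge list")
  keep <- edges[edges$score > score_threshold, , drop = FALSE]
  if (nrow(keep) == 0) {
    .fail("no edges exceed the score threshold ", score_threshold)
  }
  g <- igraph::graph_from_data_frame(
    keep[, c("gene_a", "gene_b", "score")], directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  comp <- igraph::components(g)
  # tie-break: node count, then total edge score, then smallest node id
  stats <- lapply(seq_len(comp$no), function(i) {
    vs <- which(comp$membership == i)
    sub <- igraph::induced_subgraph(g, vs)
    list(n = length(vs),
         score = sum(igraph::E(sub)$score),
         min_node = min(igraph::V(g)$name[vs]))
  })
  ord <- order(-vapply(stats, `[[`, numeric(1), "n"),
               -vapply(stats, `[[`, numeric(1), "score"),
               vapply(stats, `[[`, character(1), "min_node"))
  g <- igraph::induced_subgraph(g, which(comp$membership == ord[1]))
  nodes <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  W <- .normalize_adjacency(A)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("gene_a", "gene_b", "score")
  structure(list(graph = g, nodes = nodes, A = A, W = W, edges = el),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network: ", length(x$nodes), " genes, ",
      nrow(x$edges), " edges (largest connected component)\n", sep = "")
  invisible(x)
}

#' Build the restart vector from tiered gene scores
#'
#' Seeds are the genes of the highest non-empty significance tier (tier 1:
#' p < 0.001, tier 2: p < 0.01, tier 3: p < 0.05) for the given sample that
#' are present in the network, weighted uniformly and normalized to sum 1.
#'
#' @param score_result a [permutation_pvalues()] result.
#' @param sample_id column of the score matrices to use.
#' @param nodes network node names.
#' @return named numeric vector over `nodes` summing to 1, with attribute
#'   `tier_used`.
#' @export
build_seed_vector <- function(score_result, sample_id, nodes) {
  if (!sample_id %in% colnames(score_result$tier)) {
    .fail("unknown sample: ", sample_id)
  }
  tiers <- score_result$tier[, sample_id]
  p0 <- setNames(numeric(length(nodes)), nodes)
  for (tl in 1:3) {
    seeds <- intersect(names(tiers)[!is.na(tiers) & tiers == tl], nodes)
    if (length(seeds) > 0) {
      p0[seeds] <- 1 / length(seeds)
      attr(p0, "tier_used") <- tl
      return(p0)
    }
  }
  .fail("no tiered genes present in the network for patient ", sample_id)
}

#' Random walk with restarts
#'
#' Iterates `P_k = (1 - c) W P_{k-1} + c P_0` from `P_0` until the L1 change
#' between iterates falls below `tol`. High converged scores indicate
#' proximity to the seed genes.
#'
#' @param W normalized adjacency (sparse or dense), symmetric.
#' @param p0 restart vector, nonnegative, summing to 1, aligned with `W`.
#' @param c restart probability (default 0.7).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @return named numeric vector with attribute `iterations`.
#' @export
propagate <- function(W, p0, c = 0.7, tol = 1e-6, max_iter = 10000) {
  if (abs(sum(p0) - 1) > 1e-8) .fail("`p0` must sum to 1")
  if (c < 0 || c > 1) .fail("`c` must be in [0, 1]")
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - c) * (W %*% p) + c * p0)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- names(p0)
      attr(p, "iterations") <- it
      return(p)
    }
  }
  .fail("propagation did not converge in ", max_iter, " iterations")
}

# one degree-preserving rewire of an interaction network's edges; returns a
# sparse normalized W over the same node set
.rewired_W <- function(edge_idx, n_nodes, swaps_per_edge, seed) {
  m <- nrow(edge_idx)
  rw <- .rewire_edges_cpp(edge_idx, n_nodes, swaps_per_edge * m,
                          100L * swaps_per_edge * m, seed)
  A <- Matrix::sparseMatrix(i = c(rw[, 1], rw[, 2]) + 1L,
                            j = c(rw[, 2], rw[, 1]) + 1L,
                            x = 1, dims = c(n_nodes, n_nodes))
  list(W = .normalize_adjacency(A), accepted = attr(rw, "accepted"),
       edges = rw)
}

#' Degree-corrected empirical p-values by rewired-network nulls (RDPN)
#'
#' Propagation scores on the observed network are compared against scores
#' from `n_rewired` degree-preserving rewirings (double-edge swaps rejecting
#' self-loops and multi-edges; `swaps_per_edge * |E|` accepted swaps per
#' null, attempts capped). The same restart vector is used on every null.
#' The empirical p-value per gene is
#' `(1 + #[score_null >= score_obs]) / (n_rewired + 1)`; hub genes whose
#' high propagation score is explained by degree alone score high on the
#' nulls too and receive large p.
#'
#' @param network an [build_network()] result.
#' @param p0 restart vector over `network$nodes`.
#' @param n_rewired number of null networks (default 1000).
#' @param c,tol,max_iter propagation parameters (see [propagate()]).
#' @param swaps_per_edge accepted swaps per edge per null (default 10).
#' @param seed optional integer seed.
#' @return list with `score` (observed propagation), `p` (empirical
#'   p-values), `n_rewired`, `seed`. A warning is raised when no swap is
#'   possible (e.g. a star graph), in which case every null equals the
#'   observed network and all p are 1.
#' @export
rdpn_pvalues <- function(network, p0, n_rewired = 1000, c = 0.7,
                         tol = 1e-6, max_iter = 10000, swaps_per_edge = 10,
                         seed = NULL) {
  n_rewired <- .check_count(n_rewired, "n_rewired")
  if (nrow(network$edges) < 2) .fail("network must have >= 2 edges")
  obs <- propagate(network$W, p0, c = c, tol = tol, max_iter = max_iter)
  edge_idx <- cbind(match(network$edges$gene_a, network$nodes),
                    match(network$edges$gene_b, network$nodes)) - 1L
  storage.mode(edge_idx) <- "integer"
  n <- length(network$nodes)
  count <- numeric(n)
  any_swaps <- FALSE
  .with_seed(seed, {
    null_seeds <- sample.int(.Machine$integer.max, n_rewired)
    for (b in seq_len(n_rewired)) {
      rw <- .rewired_W(edge_idx, n, swaps_per_edge, null_seeds[b])
      if (rw$accepted > 0) any_swaps <- TRUE
      p_null <- propagate(rw$W, p0, c = c, tol = tol, max_iter = max_iter)
      count <- count + (p_null >= obs - 1e-12)
    }
  })
  if (!any_swaps) {
    warning("no degree-preserving swap was possible; null networks equal ",
            "the observed network and all p-values are 1", call. = FALSE)
  }
  p <- setNames((1 + count) / (n_rewired + 1), network$nodes)
  list(score = obs, p = p, n_rewired = n_rewired, seed = seed)
}

#' Prioritize altered genes by propagation proximity
#'
#' Restricts to genes carrying an alteration (mutation or copy-number call)
#' whose RDPN p-value is strictly below `alpha`, ranked by propagation score
#' descending.
#'
#' @param rdpn a [rdpn_pvalues()] result.
#' @param altered_genes character vector of altered genes for the patient.
#' @param alpha significance cutoff (default 0.05, strict `<`).
#' @return data.frame (gene_id, score, p), ordered by score descending.
#' @export
prioritize_altered_genes <- function(rdpn, altered_genes, alpha = 0.05) {
  genes <- intersect(altered_genes, names(rdpn$p))
  sig <- genes[rdpn$p[genes] < alpha]
  out <- data.frame(gene_id = sig,
                    score = unname(rdpn$score[match(sig, names(rdpn$p))]),
                    p = unname(rdpn$p[sig]),
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' Extract a connecting subnetwork over a terminal gene set
#'
#' Shortest-path Steiner-tree approximation: starting from one terminal, the
#' terminal closest (unweighted shortest path) to the growing tree is
#' repeatedly attached along its connecting path until all reachable
#' terminals are included; the induced subgraph over the collected nodes is
#' returned. Terminals outside the network's component are reported and
#' excluded.
#'
#' @param network an [build_network()] result.
#' @param terminals character vector of terminal genes (e.g. the top-scoring
#'   genes plus the prioritized altered genes).
#' @return list with `graph` (igraph subgraph), `nodes` (data.frame gene_id,
#'   role in terminal/steiner) and `excluded` (terminals not in the
#'   network).
#' @export
extract_subnetwork <- function(network, terminals) {
  excluded <- setdiff(terminals, network$nodes)
  term <- intersect(terminals, network$nodes)
  if (length(term) == 0) .fail("no terminals present in the network")
  g <- network$graph
  tree_nodes <- term[1]
  remaining <- setdiff(term, tree_nodes)
  while (length(remaining) > 0) {
    dmat <- igraph::distances(g, v = remaining, to = tree_nodes)
    best <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    from <- remaining[best[1]]
    to <- tree_nodes[best[2]]
    path <- igraph::shortest_paths(g, from = from, to = to)$vpath[[1]]
    tree_nodes <- union(tree_nodes, names(path))
    remaining <- setdiff(remaining, from)
  }
  sub <- igraph::induced_subgraph(g, tree_nodes)
  nodes <- data.frame(gene_id = igraph::V(sub)$name,
                      role = ifelse(igraph::V(sub)$name %in% term,
                                    "terminal", "steiner"),
                      stringsAsFactors = FALSE)
  list(graph = sub, nodes = nodes, excluded = excluded)
}

#' Write a subnetwork as SIF plus node attributes
#'
#' @param subnetwork an [extract_subnetwork()] result.
#' @param sif_path,nodes_path output paths (SIF: gene interaction gene).
#' @return invisibly, the two paths.
#' @export
write_subnetwork <- function(subnetwork, sif_path, nodes_path) {
  el <- igraph::as_data_frame(subnetwork$graph, what = "edges")
  sif <- data.frame(gene_a = el$from, interaction = "interacts",
                    gene_b = el$to, stringsAsFactors = FALSE)
  utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_table(subnetwork$nodes, nodes_path)
  invisible(c(sif_path, nodes_path))
}
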