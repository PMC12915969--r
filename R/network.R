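#' Build a thresholded symptom network
#'
#' Constructs an unweighted signed graph from a partial-correlation matrix:
#' nodes are the analysis variables, and an edge joins i and j exactly when
#' |rho_ij| strictly exceeds the threshold. Edge signs and weights (the
#' underlying correlations) are retained as attributes; centralities and
#' global metrics are computed on the unweighted adjacency. Isolated nodes
#' are permitted.
#'
#' @param pcorr A `pcor_matrix` from [pairwise_matrix()], or a square
#'   symmetric numeric matrix with unit diagonal.
#' @param tau Edge-inclusion threshold (default 0.20; strict `>`).
#' @return A `symptom_network` with `nodes`, `weights` (the rho matrix),
#'   `adjacency` (0/1), `tau`.
#' @export
build_network <- function(pcorr, tau = 0.20) {
  rho <- if (inherits(pcorr, "pcor_matrix")) pcorr$rho else as.matrix(pcorr)
  if (nrow(rho) != ncol(rho) || max(abs(rho - t(rho))) > 1e-10) {
    stop("build_network requires a square symmetric correlation matrix")
  }
  nodes <- rownames(rho)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(rho)))
  adj <- (abs(rho) > tau) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = rho, adjacency = adj, tau = tau),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  n <- length(x$nodes)
  e <- sum(x$adjacency) / 2
  cat(sprintf("Symptom network: %d nodes, %d edges (|rho| > %.2f), density %.3f\n",
              n, e, x$tau, 2 * e / (n * (n - 1))))
  invisible(x)
}

#' Convert a symptom network to an igraph object
#' @param net A `symptom_network`.
#' @return An undirected igraph graph with `weight` and `sign` edge
#'   attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    w <- net$weights[cbind(el[, 1], el[, 2])]
    igraph::E(g)$weight <- w
    igraph::E(g)$sign <- ifelse(w >= 0, "positive", "negative")
  }
  g
}

#' Node centralities of the symptom network
#'
#' All measures are computed on the unweighted thresholded graph:
#' \itemize{
#'   \item degree — neighbor count;
#'   \item closeness — (n_reachable - 1) / (sum of shortest-path distances),
#'     normalized by (n - 1) over the whole graph when connected; on a
#'     disconnected graph distances are restricted to the node's component
#'     (with a note) and isolated nodes score 0;
#'   \item betweenness — shortest-path betweenness normalized by
#'     (n - 1)(n - 2) / 2;
#'   \item clustering — fraction of closed triangles among neighbor pairs
#'     (0 for nodes of degree < 2).
#' }
#'
#' @param net A `symptom_network`.
#' @return Tibble: node, degree, closeness, betweenness, clustering.
#' @export
node_centralities <- function(net) {
  g <- as_igraph(net)
  n <- length(net$nodes)
  deg <- igraph::degree(g)
  D <- igraph::distances(g, weights = NA)  # unweighted shortest paths

  comps <- igraph::components(g)
  if (comps$no > 1L) {
    message("network is disconnected; closeness restricted to each node's component")
  }
  closeness <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d <- d[is.finite(d) & seq_len(n) != i]
    if (length(d) == 0L || sum(d) == 0) return(0)
    length(d) / sum(d) * (length(d) / (n - 1))  # component-restricted, graph-normalized
  }, 0)
  # connected graph: reduces to (n-1)/sum(d)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA) /
    ((n - 1) * (n - 2) / 2)
  clus <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  clus[deg < 2] <- 0
  tibble::tibble(node = net$nodes, degree = as.integer(deg),
                 closeness = closeness, betweenness = unname(btw),
                 clustering = clus)
}

#' Global metrics of the symptom network
#'
#' Density 2E/(n(n-1)); diameter and average shortest-path length over
#' unordered connected node pairs (computed on the largest component with a
#' warning when the graph is disconnected); mean local clustering
#' coefficient (nodes of degree < 2 counting 0); population variance of the
#' degree sequence; and the fraction of nodes with local clustering above
#' 0.90.
#'
#' @param net A `symptom_network`.
#' @return A `network_summary` list.
#' @export
global_metrics <- function(net) {
  g <- as_igraph(net)
  n <- length(net$nodes)
  e <- igraph::ecount(g)
  comps <- igraph::components(g)
  gc <- g
  if (comps$no > 1L) {
    warning("network is disconnected; diameter and path length computed on the largest component")
    keep <- which(comps$membership == which.max(comps$csize))
    gc <- igraph::induced_subgraph(g, keep)
  }
  deg <- igraph::degree(g)
  clus <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  clus[deg < 2] <- 0
  structure(list(
    density = 2 * e / (n * (n - 1)),
    diameter = if (igraph::vcount(gc) > 1) as.integer(igraph::diameter(gc, weights = NA)) else 0L,
    average_path_length = if (igraph::vcount(gc) > 1) igraph::mean_distance(gc, weights = NA) else NA_real_,
    average_clustering = mean(clus),
    degree_variance = mean((deg - mean(deg))^2),
    fraction_nodes_clustering_gt_0_90 = mean(clus > 0.90),
    n_nodes = n, n_edges = as.integer(e)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  nodes/edges: %d / %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  density: %.3f\n", x$density))
  cat(sprintf("  diameter: %d\n", x$diameter))
  cat(sprintf("  average path length: %.3f\n", x$average_path_length))
  cat(sprintf("  average clustering: %.3f\n", x$average_clustering))
  cat(sprintf("  degree variance: %.3f\n", x$degree_variance))
  cat(sprintf("  nodes with clustering > 0.90: %.1f%%\n",
              100 * x$fraction_nodes_clustering_gt_0_90))
  invisible(x)
}

#' Correlation-stability (CS) coefficient of degree centrality
#'
#' Repeatedly drops a fraction of the network and correlates the surviving
#' degree centralities with the original ones; the CS coefficient is the
#' mean Pearson correlation over iterations, with values above 0.5 read as
#' adequate stability. Two dropping modes are provided:
#' \itemize{
#'   \item `node_drop` — per iteration, remove the stated fraction of nodes
#'     (rounded to the nearest integer, at least 1), recompute degrees on the
#'     induced subgraph, and correlate with the original degrees on the
#'     surviving nodes;
#'   \item `case_drop` — per iteration, remove the stated fraction of
#'     participants, re-estimate the full Spearman correlation matrix from
#'     the residual data, rebuild the thresholded network, and correlate all
#'     nodes' degrees with the original.
#' }
#' Iterations with fewer than 3 surviving nodes or a constant degree vector
#' are skipped and counted.
#'
#' @param net A `symptom_network` (required for both modes).
#' @param residuals Participant x node residual data frame (required for
#'   `case_drop`).
#' @param drop_fraction Fraction dropped per iteration (default 0.10).
#' @param n_iter Number of bootstrap iterations (default 2500).
#' @param mode `"node_drop"` (default) or `"case_drop"`.
#' @param seed Integer seed.
#' @return A `stability_result`: `cs_coefficient`, `n_iterations`,
#'   `n_skipped`, `drop_fraction`, `mode`, `correlations` (per-iteration).
#' @export
cs_coefficient <- function(net, residuals = NULL, drop_fraction = 0.10,
                           n_iter = 2500L, mode = c("node_drop", "case_drop"),
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "symptom_network"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(net$nodes)
  d0 <- rowSums(net$adjacency)
  if (sd(d0) == 0) {
    stop("degenerate network: constant degree sequence, CS coefficient undefined")
  }
  cors <- rep(NA_real_, n_iter)
  if (mode == "node_drop") {
    k <- max(1L, round(drop_fraction * n))
    for (i in seq_len(n_iter)) {
      drop <- sample.int(n, k)
      keep <- setdiff(seq_len(n), drop)
      if (length(keep) < 3L) next
      sub_deg <- rowSums(net$adjacency[keep, keep, drop = FALSE])
      if (sd(sub_deg) == 0 || sd(d0[keep]) == 0) next
      cors[i] <- cor(d0[keep], sub_deg)
    }
  } else {
    if (is.null(residuals)) stop("case_drop mode requires participant-level residuals")
    m <- as.matrix(residuals)
    stopifnot(ncol(m) == n)
    nr <- nrow(m)
    k <- max(1L, round(drop_fraction * nr))
    for (i in seq_len(n_iter)) {
      keep <- sample.int(nr, nr - k)
      rho <- cor(apply(m[keep, , drop = FALSE], 2, rank))
      sub <- build_network(rho, tau = net$tau)
      sub_deg <- rowSums(sub$adjacency)
      if (sd(sub_deg) == 0) next
      cors[i] <- cor(d0, sub_deg)
    }
  }
  ok <- !is.na(cors)
  if (!any(ok)) stop("all CS iterations degenerate; coefficient undefined")
  structure(list(
    cs_coefficient = mean(cors[ok]),
    n_iterations = as.integer(n_iter),
    n_skipped = as.integer(sum(!ok)),
    drop_fraction = drop_fraction,
    mode = mode,
    correlations = cors[ok],
    note = paste("dropping mode:", mode,
                 "- node_drop matches the stated procedure (random node removal);",
                 "case_drop is the participant-resampling convention")
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("CS coefficient (%s, drop %.0f%%, %d iterations, %d skipped): %.3f\n",
              x$mode, 100 * x$drop_fraction, x$n_iterations, x$n_skipped,
              x$cs_coefficient))
  invisible(x)
}

#' Threshold sensitivity analysis
#'
#' Rebuilds the network at a stricter threshold (inclusive `>=`, as
#' conventionally specified for sensitivity checks) and reports, per metric,
#' the top-3 nodes before and after, plus a per-node verdict: `"unchanged"`
#' when the node's adjacency row is identical, `"stable"` when it keeps all
#' its top-3 memberships, `"attenuated"` when it loses a top-3 position or
#' more than half of its edges.
#'
#' @param pcorr A `pcor_matrix` or plain correlation matrix.
#' @param tau Baseline threshold (strict `>`; default 0.20).
#' @param tau2 Sensitivity threshold (inclusive `>=`; default 0.25).
#' @return A `sensitivity_report`: `baseline`/`strict` networks and
#'   centralities, `top3` tibble, `verdicts` tibble.
#' @export
sensitivity_rerank <- function(pcorr, tau = 0.20, tau2 = 0.25) {
  rho <- if (inherits(pcorr, "pcor_matrix")) pcorr$rho else as.matrix(pcorr)
  net1 <- build_network(rho, tau = tau)
  # inclusive threshold: |rho| >= tau2  <=>  |rho| > tau2 - eps
  net2 <- build_network(rho, tau = tau2 - 1e-12)
  net2$tau <- tau2
  c1 <- node_centralities(net1)
  c2 <- node_centralities(net2)
  metrics <- c("degree", "closeness", "betweenness")
  top3 <- dplyr::bind_rows(lapply(metrics, function(mt) {
    tibble::tibble(
      metric = mt,
      rank = 1:3,
      baseline = c1$node[order(-c1[[mt]], c1$node)][1:3],
      strict = c2$node[order(-c2[[mt]], c2$node)][1:3]
    )
  }))
  verdicts <- tibble::tibble(node = net1$nodes, verdict = vapply(seq_along(net1$nodes), function(i) {
    same_row <- identical(net1$adjacency[i, ], net2$adjacency[i, ])
    if (same_row) return("unchanged")
    node <- net1$nodes[i]
    was_top <- vapply(metrics, function(mt) node %in% top3$baseline[top3$metric == mt], TRUE)
    still_top <- vapply(metrics, function(mt) node %in% top3$strict[top3$metric == mt], TRUE)
    lost_top <- any(was_top & !still_top)
    d1 <- sum(net1$adjacency[i, ]); d2 <- sum(net2$adjacency[i, ])
    lost_half <- d1 > 0 && d2 < d1 / 2
    if (lost_top || lost_half) "attenuated" else "stable"
  }, ""))
  structure(list(baseline = net1, strict = net2, centralities_baseline = c1,
                 centralities_strict = c2, top3 = top3, verdicts = verdicts,
                 tau = tau, tau2 = tau2),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Threshold sensitivity: |rho| > %.2f vs |rho| >= %.2f\n", x$tau, x$tau2))
  print(as.data.frame(x$top3), row.names = FALSE)
  cat("verdicts:\n")
  print(table(x$verdicts$verdict))
  invisible(x)
}

#' Export the network as GraphML
#' @param net A `symptom_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$type <- node_type(net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

node_type <- function(nodes) {
  ifelse(nodes %in% psqi_cols(), "PSQI",
         ifelse(nodes %in% phq9_cols(), "PHQ9", "NSBQ"))
}

#' Edge list of the network
#' @param net A `symptom_network`.
#' @return Tibble: node1, node2, rho, sign.
#' @export
edge_list <- function(net) {
  idx <- which(lower.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  w <- net$weights[idx]
  tibble::tibble(node1 = net$nodes[idx[, 2]], node2 = net$nodes[idx[, 1]],
                 rho = w, sign = ifelse(w >= 0, "positive", "negative"))
}

#' Plot the symptom network
#'
#' Renders the thresholded graph with node colors by instrument (purple PSQI
#' components, green PHQ-9 items, yellow NSBQ total), edge colors by sign
#' (blue positive, red negative) and edge width proportional to |rho|.
#'
#' @param x A `symptom_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.symptom_network <- function(x, ...) {
  g <- as_igraph(x)
  cols <- c(PSQI = "#9467bd", PHQ9 = "#2ca02c", NSBQ = "#ffd92f")
  vcol <- cols[node_type(x$nodes)]
  if (igraph::ecount(g) > 0) {
    ecol <- ifelse(igraph::E(g)$weight >= 0, "#1f77b4", "#d62728")
    ew <- 1 + 6 * abs(igraph::E(g)$weight)
  } else {
    ecol <- NULL; ew <- NULL
  }
  igraph::plot.igraph(g, vertex.color = vcol, edge.color = ecol,
                      edge.width = ew, vertex.label.cex = 0.8, ...)
  invisible(x)
}
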