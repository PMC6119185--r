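# Coerce an edge list (data frame with from/to in the first two columns, or
# an igraph object) into a simple undirected igraph graph. `nodes` may add
# isolated vertices.
as_undirected_graph <- function(edges, nodes = NULL) {
  if (inherits(edges, "igraph")) return(igraph::simplify(edges))
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  if (is.null(nodes)) nodes <- attr(edges, "nodes")
  verts <- unique(c(as.character(edges[[1]]), as.character(edges[[2]]), nodes))
  g <- igraph::graph_from_data_frame(edges[, 1:2, drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::simplify(g)
}

#' Hub classification by degree
#'
#' Nodes with at least `k` connections (inclusive), the Hub^k criterion.
#'
#' @param edges Undirected edge list (data frame `from`, `to`) or igraph.
#' @param k Minimum degree.
#' @param nodes Optional full node set (to include isolated nodes).
#' @return Character vector of hub node ids.
#' @export
classify_hubs <- function(edges, k, nodes = NULL) {
  if (k < 1) stop("k must be >= 1")
  g <- as_undirected_graph(edges, nodes)
  deg <- igraph::degree(g)
  names(deg)[deg >= k]
}

#' Local clustering coefficients
#'
#' `2 * triangles(i) / (deg(i) * (deg(i) - 1))`; defined as 0 for nodes of
#' degree below 2.
#'
#' @inheritParams classify_hubs
#' @return Named numeric vector per node.
#' @export
clustering_coefficients <- function(edges, nodes = NULL) {
  g <- as_undirected_graph(edges, nodes)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  cc[igraph::degree(g) < 2] <- 0
  cc
}

#' Mean shortest-path length per node
#'
#' Breadth-first hop distances within each node's connected component,
#' averaged over reachable nodes only; isolated nodes get `NA`.
#'
#' @inheritParams classify_hubs
#' @return Named numeric vector per node.
#' @export
mean_shortest_paths <- function(edges, nodes = NULL) {
  g <- as_undirected_graph(edges, nodes)
  d <- igraph::distances(g)
  out <- apply(d, 1, function(row) {
    reach <- is.finite(row) & row > 0
    if (!any(reach)) NA_real_ else mean(row[reach])
  })
  names(out) <- igraph::V(g)$name
  out
}

#' Information centrality (current-flow closeness)
#'
#' Stephenson-Zelen information centrality, computed per connected
#' component: with `L` the component Laplacian and `J` the all-ones matrix,
#' let `C = (L + J)^{-1}`; then
#' \eqn{IC(i) = n / \sum_j (C_{ii} + C_{jj} - 2 C_{ij})} over the
#' component's `n` nodes (the self term contributes 0). Values are strictly
#' positive and invariant to node relabeling. Singleton components get `NA`
#' with a warning.
#'
#' @inheritParams classify_hubs
#' @return Named numeric vector per node; attribute `component` carries the
#'   component id of each node.
#' @export
information_centrality <- function(edges, nodes = NULL) {
  g <- as_undirected_graph(edges, nodes)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (ci in seq_len(comp$no)) {
    members <- ids[comp$membership == ci]
    n <- length(members)
    if (n < 2) {
      warning("singleton component: information centrality undefined for ",
              members)
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    a <- as.matrix(igraph::as_adjacency_matrix(sub))
    l <- diag(rowSums(a)) - a
    cm <- solve(l + 1)
    denom <- n * diag(cm) + sum(diag(cm)) - 2 * rowSums(cm)
    out[igraph::V(sub)$name] <- n / denom
  }
  attr(out, "component") <- stats::setNames(comp$membership, ids)
  out
}

#' Module-versus-network centrality comparison
#'
#' Welch two-sample t-test of each non-grey module's information-centrality
#' values against the centrality values of the whole network, two-sided.
#'
#' @param ic Named per-node centrality vector (e.g. from
#'   [information_centrality()]).
#' @param partition A `module_partition` (named gene -> module label).
#' @return Data frame `module`, `n`, `mean_module`, `mean_network`, `t`,
#'   `p`, sorted by module label.
#' @export
compare_module_centrality <- function(ic, partition) {
  icv <- ic[is.finite(ic)]
  mods <- setdiff(sort(unique(partition)), "grey")
  rows <- lapply(mods, function(m) {
    vals <- icv[intersect(names(icv), names(partition)[partition == m])]
    if (length(vals) < 2)
      stop("module ", m, " has fewer than 2 members with defined centrality")
    res <- tryCatch(stats::t.test(vals, icv),
                    error = function(e) NULL)
    if (is.null(res)) {  # essentially-constant data
      warning("degenerate centrality values in module ", m, "; p set to 1")
      tt <- 0; p <- 1
    } else {
      tt <- unname(res$statistic); p <- res$p.value
    }
    data.frame(module = m, n = length(vals), mean_module = mean(vals),
               mean_network = mean(icv), t = tt, p = p)
  })
  do.call(rbind, rows)
}

#' Hypergeometric enrichment (upper tail)
#'
#' Exact probability of observing at least `overlap` category members in a
#' sample of `sample_size` drawn without replacement from a universe of
#' `universe_size` containing `category_size` category members.
#'
#' @param universe_size,category_size,sample_size,overlap Non-negative
#'   counts.
#' @return Upper-tail p-value `P(X >= overlap)`.
#' @examples
#' hypergeom_enrichment(10, 5, 5, 5)  # 1/252
#' @export
hypergeom_enrichment <- function(universe_size, category_size, sample_size,
                                 overlap) {
  counts <- c(universe_size, category_size, sample_size, overlap)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be non-negative integers")
  if (category_size > universe_size || sample_size > universe_size)
    stop("category and sample sizes must not exceed the universe")
  if (overlap > min(category_size, sample_size))
    stop("overlap exceeds min(category_size, sample_size)")
  stats::phyper(overlap - 1, category_size, universe_size - category_size,
                sample_size, lower.tail = FALSE)
}

#' Per-node topology report
#'
#' Convenience wrapper computing degree, local clustering coefficient, mean
#' shortest-path length, information centrality and hub status for every
#' node of an undirected network.
#'
#' @inheritParams classify_hubs
#' @param hub_k Degree threshold for hub classification.
#' @return Data frame with one row per node.
#' @export
topology_report <- function(edges, hub_k = 500, nodes = NULL) {
  g <- as_undirected_graph(edges, nodes)
  deg <- igraph::degree(g)
  ic <- information_centrality(g)
  data.frame(node = igraph::V(g)$name,
             degree = unname(deg),
             clustering = unname(clustering_coefficients(g)),
             mean_shortest_path = unname(mean_shortest_paths(g)),
             information_centrality = unname(ic[igraph::V(g)$name]),
             component = unname(attr(ic, "component")[igraph::V(g)$name]),
             is_hub = unname(deg >= hub_k),
             row.names = NULL)
}
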