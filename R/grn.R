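#' Build the directed signed gene regulatory network
#'
#' Overlays TF->target and miRNA->target relationships onto a co-expression
#' network. A TF edge is retained iff both endpoints are network genes and
#' the retention `policy` holds: `"co_edge"` requires a direct co-expression
#' edge between them, `"co_module"` (default) requires shared membership in
#' a non-grey module, `"all"` requires network membership only. TF edges are
#' activating (+1) unless the input carries a `sign` column; miRNA edges are
#' retained iff the target is a network gene and are always repressing (-1).
#' Duplicate regulator->target rows are deduplicated keeping the first
#' evidence tag.
#'
#' @param coexpr_edges Undirected co-expression edge list (`from`, `to`).
#' @param partition A `module_partition` (named gene -> module); its names
#'   define the network gene set.
#' @param tf_edges Data frame `regulator`, `target` (optional `sign`,
#'   `evidence` columns).
#' @param mir_edges Optional data frame `regulator`, `target` (optional
#'   `evidence`).
#' @param policy `"co_edge"`, `"co_module"` or `"all"`.
#' @return Object of class `regulatory_network`: list with `edges`
#'   (`regulator`, `target`, `sign`, `class`, `evidence`), `nodes` (`node`,
#'   `role`) and `summary` (named counts `n_tfs`, `n_mirs`, `n_targets`,
#'   `n_edges`).
#' @export
build_grn <- function(coexpr_edges, partition, tf_edges, mir_edges = NULL,
                      policy = c("co_module", "co_edge", "all")) {
  policy <- match.arg(policy)
  if (is.null(tf_edges) || !nrow(tf_edges)) stop("regulator list is empty")
  network_genes <- names(partition)
  canon_edges <- function(df, class, default_sign) {
    out <- data.frame(regulator = as.character(df[[1]]),
                      target = as.character(df[[2]]),
                      sign = if ("sign" %in% names(df)) as.numeric(df$sign)
                             else default_sign,
                      class = class,
                      evidence = if ("evidence" %in% names(df))
                        as.character(df$evidence) else "input",
                      row.names = NULL)
    out[!duplicated(out[, c("regulator", "target")]), , drop = FALSE]
  }
  tf <- canon_edges(tf_edges, "TF", +1)
  tf <- tf[tf$regulator != tf$target, , drop = FALSE]
  keep <- tf$regulator %in% network_genes & tf$target %in% network_genes
  if (policy == "co_edge") {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    co <- key(as.character(coexpr_edges[[1]]), as.character(coexpr_edges[[2]]))
    keep <- keep & key(tf$regulator, tf$target) %in% co
  } else if (policy == "co_module") {
    mr <- partition[tf$regulator]
    mt <- partition[tf$target]
    keep <- keep & !is.na(mr) & !is.na(mt) & mr == mt & mr != "grey"
  }
  tf <- tf[keep, , drop = FALSE]

  mir <- NULL
  if (!is.null(mir_edges) && nrow(mir_edges)) {
    mir <- canon_edges(mir_edges, "miR", -1)
    mir$sign <- -1  # miRNA regulation is repressive by definition
    mir <- mir[mir$target %in% network_genes, , drop = FALSE]
  }
  edges <- rbind(tf, mir)
  rownames(edges) <- NULL
  role_df <- function(nodes, role)
    data.frame(node = nodes, role = rep(role, length(nodes)))
  roles <- rbind(
    role_df(unique(tf$regulator), "TF"),
    if (!is.null(mir) && nrow(mir)) role_df(unique(mir$regulator), "miR"),
    role_df(setdiff(unique(edges$target), unique(edges$regulator)),
            "target"))
  summary <- c(n_tfs = length(unique(tf$regulator)),
               n_mirs = if (is.null(mir)) 0L else length(unique(mir$regulator)),
               n_targets = length(unique(edges$target)),
               n_edges = nrow(edges))
  structure(list(edges = edges, nodes = roles, summary = summary),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("regulatory_network: %d TFs, %d miRs, %d targets, %d edges\n",
              s["n_tfs"], s["n_mirs"], s["n_targets"], s["n_edges"]))
  invisible(x)
}
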