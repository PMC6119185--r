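#' Correlation similarity matrix
#'
#' Pairwise Pearson correlation of gene profiles over all samples, mapped to
#' \[0,1\]: unsigned `|r|` (default) or signed `(1+r)/2`. Genes with zero
#' variance are dropped with a warning.
#'
#' @param data An [expression_dataset()] or a genes x samples numeric matrix.
#' @param mode `"unsigned"` or `"signed"`.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
correlation_similarity <- function(data, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  x <- if (inherits(data, "expression_dataset")) data$values else data
  if (ncol(x) < 4) stop("need >= 4 samples per gene")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) excluded from similarity")
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 variable genes")
  r <- stats::cor(t(x))
  s <- if (mode == "unsigned") abs(r) else (1 + r) / 2
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Signed scale-free topology fit index
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins and
#' regresses log10(frequency) on log10(mean connectivity) over non-empty
#' bins. Returns R-squared signed by the negative of the slope, so the index
#' is positive when frequency decreases with connectivity (the power-law
#' signature).
#'
#' @param connectivities Per-node (weighted) degree.
#' @param n_bins Number of equal-width bins.
#' @return Signed R-squared in \[-1, 1\].
#' @export
scale_free_fit <- function(connectivities, n_bins = 10) {
  k <- connectivities[is.finite(connectivities)]
  if (!length(k)) stop("no finite connectivities")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  if (diff(range(k)) == 0)
    stop("degenerate degree distribution: all connectivities in a single bin")
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & meank > 0
  if (sum(keep) < 3)
    stop("degenerate degree distribution: fewer than 3 non-empty bins")
  fit <- stats::lm(log10(freq[keep]) ~ log10(meank[keep]))
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  unname(r2 * sign(-slope))
}

#' Soft-threshold (power) selection for scale-free topology
#'
#' For each candidate power, raises the similarity matrix elementwise to
#' that power, computes weighted connectivity \eqn{k_i = \sum_{j \ne i}
#' a_{ij}}, and evaluates the signed scale-free fit index. The chosen power
#' is the smallest one reaching `r2_goal`; if none qualifies the power with
#' the maximal signed R-squared is returned with a warning.
#'
#' @param similarity Similarity matrix from [correlation_similarity()].
#' @param candidate_powers Ascending positive integers to try.
#' @param r2_goal Signed R-squared target.
#' @param n_bins Passed to [scale_free_fit()].
#' @return List of class `soft_threshold` with `power` (selected beta),
#'   `r2` (signed R-squared at the selected power), `reached_goal`, and
#'   `fit` (data frame `power`, `r2`, `mean_k`).
#' @export
pick_soft_threshold <- function(similarity, candidate_powers = 1:20,
                                r2_goal = 0.8, n_bins = 10) {
  if (!length(candidate_powers)) stop("candidate_powers must be non-empty")
  if (is.unsorted(candidate_powers)) stop("candidate_powers must be ascending")
  fit <- data.frame(power = candidate_powers, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    a <- similarity^candidate_powers[i]
    k <- rowSums(a) - diag(a)
    fit$mean_k[i] <- mean(k)
    fit$r2[i] <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NA_real_)
  }
  ok <- which(!is.na(fit$r2) & fit$r2 >= r2_goal)
  if (length(ok)) {
    sel <- ok[1]
    reached <- TRUE
  } else {
    sel <- which.max(fit$r2)
    reached <- FALSE
    warning(sprintf("no candidate power reached signed R^2 >= %.2f; using power %d (R^2 = %.3f)",
                    r2_goal, fit$power[sel], fit$r2[sel]))
  }
  structure(list(power = fit$power[sel], r2 = fit$r2[sel],
                 reached_goal = reached, fit = fit),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("soft threshold: power = %d, signed R^2 = %.3f%s\n",
              x$power, x$r2, if (x$reached_goal) "" else " (goal not reached)"))
  invisible(x)
}

#' Topological overlap matrix (TOM)
#'
#' \eqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})} for
#' \eqn{i \ne j}, with \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is defined as 1.
#'
#' @param adjacency Symmetric adjacency matrix with entries in \[0,1\]
#'   (the diagonal is ignored).
#' @return Symmetric TOM matrix in \[0,1\] with unit diagonal.
#' @export
compute_tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-12)
    stop("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1) stop("adjacency entries must lie in [0,1]")
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# WGCNA-style color vocabulary for module labels, in assignment order.
wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Module detection by static cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM, cut at
#' a fixed height (default: 99.5% of the merge-height range). Clusters
#' smaller than `min_module_size` are pooled into `"grey"`; remaining
#' modules are labeled with the WGCNA color vocabulary in decreasing size
#' order (largest = "turquoise").
#'
#' @param tom TOM (or any similarity) matrix with unit diagonal.
#' @param min_module_size Minimum gene count of a retained module.
#' @param cut_height Absolute cut height on the dendrogram; by default
#'   `min(h) + 0.995 * (max(h) - min(h))` over the merge heights `h`.
#' @return Named character vector of class `module_partition`: gene ->
#'   module label, `"grey"` for unassigned.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = NULL) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # tied merges can leave numerically unsorted heights; average linkage is
  # monotone, so enforcing monotonicity only resolves floating-point ties
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  if (is.null(cut_height))
    cut_height <- min(hc$height) + 0.995 * diff(range(hc$height))
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    pal <- if (length(keep) <= length(wgcna_colors)) {
      wgcna_colors[seq_along(keep)]
    } else c(wgcna_colors, paste0("module", seq_len(length(keep) - length(wgcna_colors))))
    for (i in seq_along(keep)) labels[cl == keep[i]] <- pal[i]
  }
  names(labels) <- genes
  structure(labels, class = "module_partition",
            min_module_size = min_module_size, cut_height = cut_height)
}

#' Module eigengenes
#'
#' First principal component of each non-grey module's per-gene standardized
#' expression submatrix, sign-oriented to correlate positively with the mean
#' module expression profile and scaled to unit norm.
#'
#' @param data An [expression_dataset()] or genes x samples matrix.
#' @param partition A [detect_modules()] result (named gene -> module).
#' @return Samples x modules matrix of eigengene values; attribute
#'   `var_explained` holds the per-module explained-variance fraction.
#' @export
module_eigengene <- function(data, partition) {
  x <- if (inherits(data, "expression_dataset")) data$values else data
  mods <- setdiff(sort(unique(partition)), "grey")
  if (!length(mods)) stop("no non-grey modules")
  out <- matrix(NA_real_, ncol(x), length(mods),
                dimnames = list(colnames(x), mods))
  varex <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- intersect(names(partition)[partition == m], rownames(x))
    sub <- x[genes, , drop = FALSE]
    if (nrow(sub) == 1) {
      warning("module ", m, " has a single gene; returning its z-scored profile")
      e <- as.numeric(scale(as.numeric(sub)))
      e <- e / sqrt(sum(e^2))
      out[, m] <- e
      varex[m] <- 1
      next
    }
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    sv <- svd(z)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(sub)) < 0) e <- -e
    out[, m] <- e / sqrt(sum(e^2))
    varex[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(out, "var_explained") <- varex
  out
}

#' Threshold a weight matrix into an undirected edge list
#'
#' Retains all undirected pairs (i < j) whose weight is greater than or
#' equal to `threshold` (inclusive).
#'
#' @param weights Symmetric weight matrix (TOM or adjacency).
#' @param threshold Retention threshold in \[0,1\].
#' @return Data frame `from`, `to`, `weight`; attribute `nodes` lists all
#'   node ids including isolated ones.
#' @export
export_network <- function(weights, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0,1]")
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-12)
    stop("weight matrix must be symmetric")
  ids <- rownames(w)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(w)))
  idx <- which(upper.tri(w) & w >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = w[idx], row.names = NULL)
  attr(edges, "nodes") <- ids
  edges
}
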