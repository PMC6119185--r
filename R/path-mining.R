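# Divisive two-component Gaussian split of a value vector.
# A two-component Gaussian mixture (means initialized at the 10th/90th
# percentiles) is fitted by EM to convergence and compared with a single
# Gaussian by BIC; a hard-assignment (classification) likelihood is not used
# because it systematically overstates the two-component fit on unimodal
# data. The split is accepted iff the mixture BIC improves on the
# one-Gaussian BIC by at least delta_bic_min and both posterior-assigned
# children reach min_size.
try_split <- function(v, min_size, delta_bic_min, max_iter = 500L) {
  n <- length(v)
  no <- list(split = FALSE)
  if (n < 2 * min_size) return(no)
  mu <- unname(stats::quantile(v, c(0.1, 0.9)))
  if (diff(mu) == 0) return(no)
  v_var <- stats::var(v) * (n - 1) / n
  s2 <- rep(v_var, 2)
  w <- c(0.5, 0.5)
  floor_s2 <- max(v_var * 1e-8, 1e-12)
  r <- NULL
  for (i in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(v, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(v, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(no)
    r_new <- d1 / tot
    sw <- sum(r_new)
    if (sw < 1e-8 || n - sw < 1e-8) return(no)  # component collapsed
    mu_new <- c(sum(r_new * v) / sw, sum((1 - r_new) * v) / (n - sw))
    s2_new <- pmax(c(sum(r_new * (v - mu_new[1])^2) / sw,
                     sum((1 - r_new) * (v - mu_new[2])^2) / (n - sw)),
                   floor_s2)
    w_new <- c(sw / n, 1 - sw / n)
    done <- !is.null(r) && max(abs(r_new - r)) < 1e-10
    mu <- mu_new; s2 <- s2_new; w <- w_new; r <- r_new
    if (done) break
  }
  ll2 <- sum(log(w[1] * stats::dnorm(v, mu[1], sqrt(s2[1])) +
                 w[2] * stats::dnorm(v, mu[2], sqrt(s2[2]))))
  ll1 <- sum(stats::dnorm(v, mean(v), sqrt(max(v_var, floor_s2)), log = TRUE))
  bic1 <- 2 * log(n) - 2 * ll1
  bic2 <- 5 * log(n) - 2 * ll2
  if (bic1 - bic2 < delta_bic_min) return(no)
  assign <- ifelse(r >= 0.5, 1L, 2L)
  n1 <- sum(assign == 1L)
  if (min(n1, n - n1) < min_size) return(no)
  upper <- if (mu[1] >= mu[2]) 1L else 2L
  list(split = TRUE, upper = which(assign == upper),
       lower = which(assign != upper), delta_bic = bic1 - bic2)
}

# Regulator enrichment at a split: upper-branch hypergeometric test within
# the parent group; miRNAs are additionally tested against the lower branch
# (repression) and the smaller p is kept.
split_enrichment <- function(members, upper, lower, regulators) {
  if (is.null(regulators)) return(NULL)
  edges <- if (inherits(regulators, "regulatory_network")) regulators$edges
           else regulators
  if (is.null(edges) || !nrow(edges)) return(NULL)
  edges <- edges[edges$target %in% members, , drop = FALSE]
  if (!nrow(edges)) return(NULL)
  regs <- unique(edges$regulator)
  rows <- lapply(regs, function(r) {
    sub <- edges[edges$regulator == r, , drop = FALSE]
    tgt <- unique(sub$target)
    cls <- sub$class[1]
    p_up <- hypergeom_enrichment(length(members), length(tgt), length(upper),
                                 length(intersect(tgt, upper)))
    p <- p_up
    branch <- "upper"
    if (identical(cls, "miR")) {
      p_lo <- hypergeom_enrichment(length(members), length(tgt), length(lower),
                                   length(intersect(tgt, lower)))
      if (p_lo < p) { p <- p_lo; branch <- "lower" }
    }
    data.frame(regulator = r, class = cls, n_targets = length(tgt),
               branch = branch, p = p)
  })
  do.call(rbind, rows)
}

#' Mine dynamic regulatory bifurcation paths from a time course
#'
#' Deterministic divisive modeling of expression trajectories in the style
#' of dynamic regulatory event mining: starting from a single state holding
#' all genes at the first (baseline) time point, each active gene group is
#' tested at every subsequent time point for a two-way split of its members'
#' current values (two-component hard Gaussian clustering initialized at the
#' 10th/90th percentiles). A split is accepted iff the two-Gaussian BIC
#' improves on the one-Gaussian BIC by at least `delta_bic_min` and both
#' children hold at least `min_path_size` genes. At each accepted split
#' every regulator with targets in the parent group is scored by an exact
#' hypergeometric test (universe = parent group, category = the regulator's
#' targets therein, sample = upper-branch genes); regulators with p at or
#' below their class threshold (`alpha_tf` / `alpha_mir`) annotate the
#' split. miRNAs are additionally tested against the lower branch and the
#' smaller p is kept.
#'
#' @param mean_expr Genes x time numeric matrix of log2 ratios referenced to
#'   the first time point (first column identically 0).
#' @param regulators A [build_grn()] `regulatory_network` (or its `edges`
#'   data frame), or `NULL` for no annotation.
#' @param alpha_tf Raw significance threshold for TF annotation.
#' @param alpha_mir Raw significance threshold for miRNA annotation.
#' @param min_path_size Minimum genes per branch.
#' @param delta_bic_min Required BIC improvement to accept a split.
#' @return Object of class `path_model`: list with `states` (data frame
#'   `id`, `time`, `mean`, `sd`, `n`, `parent`), `members` (list of gene id
#'   vectors per state), `splits` (list with `state`, `time`, `children`,
#'   `enrichment` table and `annotated` regulators), `leaves` (leaf state
#'   ids) and the parameters used.
#' @export
mine_paths <- function(mean_expr, regulators = NULL, alpha_tf = 0.032,
                       alpha_mir = 0.10, min_path_size = 20,
                       delta_bic_min = 10) {
  x <- as.matrix(mean_expr)
  if (ncol(x) < 3) stop("need >= 3 time points")
  if (min_path_size < 2) stop("min_path_size must be >= 2")
  if (max(abs(x[, 1])) > 1e-8)
    stop("mean_expr must be referenced to the first time point (column 1 all zero)")
  genes <- rownames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x)))
  rownames(x) <- genes

  states <- data.frame(id = 1L, time = 1L, mean = 0, sd = 0,
                       n = nrow(x), parent = NA_integer_)
  members <- list(genes)
  splits <- list()
  active <- 1L
  next_id <- 2L
  for (t in 2:ncol(x)) {
    new_active <- integer(0)
    for (sid in active) {
      g <- members[[sid]]
      v <- x[g, t]
      res <- try_split(v, min_path_size, delta_bic_min)
      if (res$split) {
        up <- g[res$upper]; lo <- g[res$lower]
        kids <- integer(2)
        for (j in 1:2) {
          kid_genes <- if (j == 1) up else lo
          states <- rbind(states, data.frame(
            id = next_id, time = t, mean = mean(x[kid_genes, t]),
            sd = stats::sd(x[kid_genes, t]), n = length(kid_genes),
            parent = sid))
          members[[next_id]] <- kid_genes
          kids[j] <- next_id
          next_id <- next_id + 1L
        }
        enr <- split_enrichment(g, up, lo, regulators)
        annotated <- character(0)
        if (!is.null(enr)) {
          alpha <- ifelse(enr$class == "miR", alpha_mir, alpha_tf)
          annotated <- enr$regulator[enr$p <= alpha]
        }
        splits[[length(splits) + 1L]] <- list(
          state = sid, time = t, children = kids,
          delta_bic = res$delta_bic, enrichment = enr, annotated = annotated)
        new_active <- c(new_active, kids)
      } else {
        states <- rbind(states, data.frame(
          id = next_id, time = t, mean = mean(v), sd = stats::sd(v),
          n = length(g), parent = sid))
        members[[next_id]] <- g
        new_active <- c(new_active, next_id)
        next_id <- next_id + 1L
      }
    }
    active <- new_active
  }
  structure(list(states = states, members = members, splits = splits,
                 leaves = active,
                 params = list(alpha_tf = alpha_tf, alpha_mir = alpha_mir,
                               min_path_size = min_path_size,
                               delta_bic_min = delta_bic_min)),
            class = "path_model")
}

#' Summarize a mined path model
#'
#' One row per root-to-leaf path with its member count, the split times
#' traversed and the regulators annotated along the way, plus path totals.
#'
#' @param model A [mine_paths()] result.
#' @return List with `paths` (data frame `path`, `n_genes`, `split_times`,
#'   `regulators`), `n_paths`, and `n_tf_groups` (number of distinct
#'   non-empty TF annotation sets across splits).
#' @export
summarize_paths <- function(model) {
  stopifnot(inherits(model, "path_model"))
  st <- model$states
  split_by_child <- list()
  for (sp in model$splits)
    for (k in sp$children) split_by_child[[as.character(k)]] <- sp
  rows <- lapply(seq_along(model$leaves), function(i) {
    leaf <- model$leaves[i]
    times <- integer(0); regs <- character(0)
    node <- leaf
    while (!is.na(node)) {
      sp <- split_by_child[[as.character(node)]]
      if (!is.null(sp)) {
        times <- c(sp$time, times)
        regs <- union(sp$annotated, regs)
      }
      node <- st$parent[st$id == node]
    }
    data.frame(path = i, n_genes = length(model$members[[leaf]]),
               split_times = paste(times, collapse = ","),
               regulators = paste(sort(regs), collapse = ","))
  })
  tf_sets <- unique(Filter(length, lapply(model$splits, function(sp) {
    enr <- sp$enrichment
    ann <- sp$annotated
    if (is.null(enr)) return(character(0))
    sort(intersect(ann, enr$regulator[enr$class != "miR"]))
  })))
  list(paths = do.call(rbind, rows), n_paths = length(model$leaves),
       n_tf_groups = length(tf_sets))
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("path_model: %d states, %d splits, %d paths over %d time points\n",
              nrow(x$states), length(x$splits), length(x$leaves),
              max(x$states$time)))
  invisible(x)
}
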