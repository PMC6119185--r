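# Shared fixtures. The default 2,000-gene bundle and its network are built
# once per test run and cached (several files exercise them).

.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- generate_dataset(default_synth_config())
  .fixture_cache$bundle
}

default_network <- function() {
  if (is.null(.fixture_cache$network)) {
    b <- default_bundle()
    sim <- correlation_similarity(b$expr)
    st <- suppressWarnings(pick_soft_threshold(sim, 1:20, r2_goal = 0.8))
    tom <- compute_tom(sim^st$power)
    part <- detect_modules(tom, min_module_size = 30)
    .fixture_cache$network <- list(similarity = sim, sft = st, tom = tom,
                                   partition = part)
  }
  .fixture_cache$network
}

# Study conditions for planted-bifurcation experiments: one tightly loaded
# module whose only planted divergence is the split itself.
split_study_config <- function(seed) {
  synth_config(n_genes = 400, n_timepoints = 10, n_replicates = 3,
               n_modules = 1, module_sizes = 400,
               loading_range = c(0.78, 0.82), n_tfs = 6, targets_per_tf = 30,
               n_splits = 1, split_time = 5, split_offset = 1.5,
               split_enrich_frac = 0.8, n_mirs = 0, seed = seed)
}

# Baseline-referenced gene x time replicate-mean matrix of a bundle.
bundle_mean_matrix <- function(bundle) {
  v <- bundle$expr$values
  times <- sort(unique(bundle$expr$samples$time))
  m <- vapply(times, function(tt) {
    rowMeans(v[, bundle$expr$samples$sample[bundle$expr$samples$time == tt],
               drop = FALSE])
  }, numeric(nrow(v)))
  m - m[, 1]
}

# Small expression dataset with explicit per-time replicate values.
# profile_fun(gene_index, time_index) gives the mean; gaussian noise added.
toy_dataset <- function(n_genes, times, n_rep, profile_fun, noise_sd = 0.1,
                        seed = 1) {
  set.seed(seed)
  samples <- data.frame(
    sample = sprintf("t%d_r%d", rep(times, each = n_rep),
                     rep(seq_len(n_rep), length(times))),
    time = rep(times, each = n_rep),
    replicate = rep(seq_len(n_rep), length(times)))
  mu <- outer(seq_len(n_genes), seq_along(times), Vectorize(profile_fun))
  vals <- mu[, rep(seq_along(times), each = n_rep), drop = FALSE] +
    matrix(rnorm(n_genes * length(times) * n_rep, 0, noise_sd),
           n_genes, length(times) * n_rep)
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  colnames(vals) <- samples$sample
  expression_dataset(vals, samples)
}

# Random symmetric adjacency in [0,1] with zero diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  rownames(a) <- colnames(a) <- paste0("n", seq_len(n))
  a
}

# Random connected undirected graph as an edge list (retries until connected).
random_connected_edges <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) ) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  igraph::as_data_frame(g, what = "edges")
}
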