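#' Configuration for the synthetic time-course generator
#'
#' Defines the planted structure of a synthetic senescence-like time course:
#' block-correlated co-expression modules with heterogeneous (heavy-tailed)
#' sizes, transcription factors (TFs) leading their targets by a lag,
#' bifurcation events where part of a module diverges after a known time
#' point with one TF's targets enriched in the upper branch, inhibitory
#' miRNA couplings, and Richards-shaped qPCR amplification curves with a
#' known Cy0.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints Number of ordered time points (labels `1:n_timepoints`).
#' @param n_replicates Replicates per time point.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of module sizes; defaults to a geometric
#'   (heavy-tailed) sequence starting at 400 with ratio 3/4, so connectivity
#'   after soft thresholding is heterogeneous. Must sum to at most `n_genes`;
#'   genes left over are unassigned background noise (the downstream "grey"
#'   pool).
#' @param loading_range Range (in (0,1)) of per-gene loadings on the module
#'   latent trajectory; the spread of loadings creates within-module
#'   connectivity heterogeneity.
#' @param noise_sd Per-sample Gaussian noise standard deviation (log2 units).
#' @param n_tfs Number of planted TFs (each a designated gene of a module).
#' @param targets_per_tf Targets per TF, drawn from the TF's own module.
#' @param tf_lag Lead of the TF profile over its module trajectory, in time
#'   steps (targets follow the TF with this lag).
#' @param n_splits Number of planted bifurcation events.
#' @param split_time Integer vector (recycled to `n_splits`): the last time
#'   index (1-based, strictly inside `(1, n_timepoints)`) at which the two
#'   branches still coincide; divergence starts one step later.
#' @param split_offset Growth rate of the between-branch mean difference,
#'   log2 units per time step after `split_time` (each branch moves by half).
#' @param split_enrich_frac Fraction of the split regulator's targets placed
#'   in the upper branch.
#' @param n_mirs Number of miRNAs (profiled in a separate small matrix).
#' @param mir_targets_per Targets per miRNA, drawn from the background pool.
#' @param mir_coupling Magnitude of the negative coupling of a miRNA target
#'   to its miRNA's trajectory (log2 units per unit of miRNA activity).
#' @param qpcr_params List of numeric vectors
#'   `c(Fmax, b, c, d, Fb, noise_sd)` parameterising Richards amplification
#'   curves \eqn{F(x) = Fb + Fmax (1 + e^{-(x-c)/b})^{-d}}.
#' @param n_cycles Number of qPCR cycles simulated.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A validated list of class `synth_config`.
#' @seealso [generate_dataset()], [generate_qpcr_curves()]
#' @export
synth_config <- function(n_genes = 2000L,
                         n_timepoints = 12L,
                         n_replicates = 3L,
                         n_modules = 8L,
                         module_sizes = NULL,
                         loading_range = c(0.4, 0.95),
                         noise_sd = 0.5,
                         n_tfs = 16L,
                         targets_per_tf = 30L,
                         tf_lag = 1L,
                         n_splits = 0L,
                         split_time = 7L,
                         split_offset = 1.5,
                         split_enrich_frac = 0.8,
                         n_mirs = 5L,
                         mir_targets_per = 20L,
                         mir_coupling = 0.6,
                         qpcr_params = default_qpcr_params(),
                         n_cycles = 40L,
                         seed = 42L) {
  if (is.null(module_sizes)) {
    module_sizes <- pmax(2L, as.integer(round(400 * (3 / 4)^(seq_len(n_modules) - 1))))
    # shrink proportionally if the default sequence overflows small n_genes
    while (sum(module_sizes) > n_genes)
      module_sizes <- pmax(2L, as.integer(floor(module_sizes * 0.8)))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              loading_range = as.numeric(loading_range),
              noise_sd = as.numeric(noise_sd),
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              tf_lag = as.integer(tf_lag),
              n_splits = as.integer(n_splits),
              split_time = rep_len(as.integer(split_time), max(1L, n_splits)),
              split_offset = as.numeric(split_offset),
              split_enrich_frac = as.numeric(split_enrich_frac),
              n_mirs = as.integer(n_mirs),
              mir_targets_per = as.integer(mir_targets_per),
              mir_coupling = as.numeric(mir_coupling),
              qpcr_params = qpcr_params,
              n_cycles = as.integer(n_cycles),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_synth_config <- function(seed = 42L) synth_config(seed = seed)

default_qpcr_params <- function() {
  list(c(Fmax = 100, b = 1.5, c = 22, d = 1.0, Fb = 2, noise_sd = 0.5),
       c(Fmax = 100, b = 1.7, c = 25, d = 0.8, Fb = 5, noise_sd = 0.5),
       c(Fmax = 80,  b = 1.4, c = 28, d = 1.3, Fb = 3, noise_sd = 0.5))
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 4) stop_field("n_genes", "must be >= 4")
    if (n_timepoints < 3) stop_field("n_timepoints", "must be >= 3")
    if (n_replicates < 1) stop_field("n_replicates", "must be >= 1")
    if (length(module_sizes) != n_modules)
      stop_field("module_sizes", "length must equal n_modules")
    if (any(module_sizes < 2))
      stop_field("module_sizes", "every module size must be >= 2")
    if (sum(module_sizes) > n_genes)
      stop_field("module_sizes", "sum exceeds n_genes")
    if (length(loading_range) != 2 || any(loading_range <= 0) ||
        any(loading_range >= 1) || diff(loading_range) < 0)
      stop_field("loading_range", "must be an increasing pair within (0,1)")
    if (noise_sd <= 0) stop_field("noise_sd", "must be > 0")
    if (n_splits > 0 &&
        (any(split_time <= 1) || any(split_time >= n_timepoints)))
      stop_field("split_time", "must lie strictly inside (1, n_timepoints)")
    if (split_enrich_frac < 0 || split_enrich_frac > 1)
      stop_field("split_enrich_frac", "must be in [0,1]")
    if (n_tfs > 0 && targets_per_tf < 1)
      stop_field("targets_per_tf", "must be >= 1 when n_tfs > 0")
    if (n_cycles < 30) stop_field("n_cycles", "must be >= 30")
    for (p in qpcr_params) {
      if (length(p) < 6) stop_field("qpcr_params", "each entry needs 6 values")
      if (p[[1]] <= 0) stop_field("qpcr_params", "Fmax must be positive")
      if (p[[2]] <= 0) stop_field("qpcr_params", "b must be positive")
      if (p[[4]] <= 0) stop_field("qpcr_params", "d must be positive")
    }
  })
  invisible(cfg)
}

# 3-point moving-average smoother with reflected ends.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xp <- c(x[1], x, x[n])
  (xp[1:n] + xp[2:(n + 1)] + xp[3:(n + 2)]) / 3
}

# Smooth standardized latent trajectories: cumulative Gaussian steps, 3-point
# moving average, z-scored over the time axis. On a short time axis two
# independent random walks are often strongly collinear by chance, which
# would blur the planted module boundaries, so each new trajectory is
# orthogonalized (Gram-Schmidt, then centered and re-standardized) against
# the previously drawn ones; the result is still a smooth random curve.
draw_latents <- function(n, T, avoid = NULL) {
  out <- matrix(NA_real_, T, n)
  for (j in seq_len(n)) {
    z <- smooth3(cumsum(stats::rnorm(T)))
    z <- z - mean(z)
    prev <- cbind(avoid, out[, seq_len(j - 1), drop = FALSE])
    if (!is.null(prev) && ncol(prev) && ncol(prev) < T - 1) {
      res <- stats::lsfit(prev, z, intercept = FALSE)$residuals
      if (stats::sd(res) > 1e-8) z <- res  # keep raw draw if degenerate
    }
    out[, j] <- as.numeric(scale(z))
  }
  out
}

#' Generate a synthetic time-course bundle with planted ground truth
#'
#' Draws a complete synthetic input set for the pipeline: a gene expression
#' time course with planted co-expression modules, TF and miRNA regulators,
#' bifurcation events, plus the regulator edge lists and a truth record.
#'
#' Module genes are `loading * latent(t) + noise`, with latent module
#' trajectories drawn as smoothed standardized random walks. TF genes lead
#' their module trajectory by `tf_lag` steps; their targets are module
#' co-members. After a split's `split_time` the two branches of the split
#' module drift apart at `split_offset` log2 units per step (half per
#' branch), with `split_enrich_frac` of the split regulator's targets in the
#' upper branch. miRNA targets receive a negative coupling to their miRNA's
#' trajectory. All randomness derives from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with elements `expr` (gene [expression_dataset()]),
#'   `mir` (miRNA [expression_dataset()] sharing the time axis), `tf_edges`
#'   and `mir_edges` (two-column data frames `regulator`, `target`) and
#'   `truth`: a list with `module_of` (named character; background genes are
#'   `"unassigned"`), `tf_targets`, `mir_targets` (named lists of character
#'   vectors), and `split_events` (list of `module`, `time`, `regulator`,
#'   `upper`, `lower`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)
  T <- config$n_timepoints
  R <- config$n_replicates
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  samples <- data.frame(
    sample = sprintf("T%02d_R%d", rep(seq_len(T), each = R), rep(seq_len(R), T)),
    time = rep(seq_len(T), each = R),
    replicate = rep(seq_len(R), T))

  module_of <- rep("unassigned", n)
  names(module_of) <- genes
  idx <- 1L
  module_members <- vector("list", config$n_modules)
  for (m in seq_len(config$n_modules)) {
    module_members[[m]] <- genes[idx:(idx + config$module_sizes[m] - 1L)]
    module_of[module_members[[m]]] <- sprintf("M%02d", m)
    idx <- idx + config$module_sizes[m]
  }

  # planted split ramps are deterministic trend directions; module latents
  # are drawn orthogonal to them so a split cannot alias another module
  ramp_dirs <- if (config$n_splits > 0) {
    vapply(config$split_time[seq_len(config$n_splits)],
           function(t0) {
             r <- pmax(seq_len(T) - t0, 0)
             as.numeric(scale(r))
           }, numeric(T))
  } else NULL
  latents <- draw_latents(config$n_modules, T, avoid = ramp_dirs)
  # right-skewed loadings (many weakly, few strongly connected genes) give
  # the heterogeneous, heavy-tailed connectivity of real co-expression data
  loadings <- config$loading_range[1] +
    diff(config$loading_range) * stats::runif(n)^3
  names(loadings) <- genes

  # deterministic mean profile per gene (genes x time)
  mu <- matrix(0, n, T, dimnames = list(genes, NULL))
  for (m in seq_len(config$n_modules))
    mu[module_members[[m]], ] <- outer(loadings[module_members[[m]]], latents[, m])

  # TFs: designated module genes whose profile leads the module trajectory
  tf_targets <- list()
  tf_of_module <- vector("list", config$n_modules)
  if (config$n_tfs > 0) {
    tf_module <- rep_len(seq_len(config$n_modules), config$n_tfs)
    used_tf <- character(0)
    for (i in seq_len(config$n_tfs)) {
      m <- tf_module[i]
      pool <- setdiff(module_members[[m]], used_tf)
      tf <- pool[1L]
      used_tf <- c(used_tf, tf)
      lead_idx <- pmin(seq_len(T) + config$tf_lag, T)
      mu[tf, ] <- loadings[tf] * latents[lead_idx, m]
      cand <- setdiff(module_members[[m]], tf)
      tgt <- sample(cand, min(config$targets_per_tf, length(cand)))
      tf_targets[[tf]] <- tgt
      tf_of_module[[m]] <- c(tf_of_module[[m]], tf)
    }
  }

  # planted bifurcation events: one per split, in the largest modules but
  # sparing the single largest (whose connectivity dominates the degree
  # distribution) whenever there are modules to spare
  split_events <- list()
  if (config$n_splits > 0) {
    ranks <- order(config$module_sizes, decreasing = TRUE)
    split_modules <- if (length(ranks) > config$n_splits)
      ranks[-1][seq_len(config$n_splits)] else ranks[seq_len(config$n_splits)]
    for (s in seq_len(config$n_splits)) {
      m <- split_modules[s]
      t0 <- config$split_time[s]
      reg <- tf_of_module[[m]][1L]
      members <- module_members[[m]]
      if (!is.null(reg)) members <- setdiff(members, tf_of_module[[m]])
      tgt <- if (is.null(reg)) character(0) else intersect(tf_targets[[reg]], members)
      n_up_tgt <- round(config$split_enrich_frac * length(tgt))
      up <- sample(tgt, n_up_tgt)
      rest <- setdiff(members, tgt)
      up <- c(up, sample(rest, floor(length(rest) / 2)))
      lo <- setdiff(members, up)
      ramp <- pmax(seq_len(T) - t0, 0) * config$split_offset / 2
      mu[up, ] <- sweep(mu[up, , drop = FALSE], 2, ramp, "+")
      mu[lo, ] <- sweep(mu[lo, , drop = FALSE], 2, ramp, "-")
      split_events[[s]] <- list(module = sprintf("M%02d", m), time = t0,
                                regulator = reg, upper = up, lower = lo)
    }
  }

  # miRNAs: own latent trajectories; targets from the background pool get a
  # negative coupling
  mir_ids <- character(0)
  mir_targets <- list()
  mir_values <- NULL
  background <- genes[module_of == "unassigned"]
  if (config$n_mirs > 0) {
    mir_ids <- sprintf("miR%02d", seq_len(config$n_mirs))
    mir_lat <- draw_latents(config$n_mirs, T)
    for (i in seq_len(config$n_mirs)) {
      pool <- if (length(background)) background else genes
      tgt <- sample(pool, min(config$mir_targets_per, length(pool)))
      mir_targets[[mir_ids[i]]] <- tgt
      mu[tgt, ] <- mu[tgt, , drop = FALSE] -
        config$mir_coupling * matrix(mir_lat[, i], length(tgt), T, byrow = TRUE)
    }
    mir_mu <- t(mir_lat)  # mirs x time
    mir_values <- mir_mu[, rep(seq_len(T), each = R), drop = FALSE] +
      matrix(stats::rnorm(config$n_mirs * T * R, 0, config$noise_sd / 2),
             config$n_mirs, T * R)
    dimnames(mir_values) <- list(mir_ids, samples$sample)
  }

  values <- mu[, rep(seq_len(T), each = R), drop = FALSE] +
    matrix(stats::rnorm(n * T * R, 0, config$noise_sd), n, T * R)
  colnames(values) <- samples$sample

  tf_edges <- if (length(tf_targets)) {
    data.frame(regulator = rep(names(tf_targets), lengths(tf_targets)),
               target = unlist(tf_targets, use.names = FALSE))
  } else data.frame(regulator = character(0), target = character(0))
  mir_edges <- if (length(mir_targets)) {
    data.frame(regulator = rep(names(mir_targets), lengths(mir_targets)),
               target = unlist(mir_targets, use.names = FALSE))
  } else data.frame(regulator = character(0), target = character(0))

  list(expr = expression_dataset(values, samples),
       mir = if (is.null(mir_values)) NULL else expression_dataset(mir_values, samples),
       tf_edges = tf_edges,
       mir_edges = mir_edges,
       truth = list(module_of = module_of,
                    tf_targets = tf_targets,
                    mir_targets = mir_targets,
                    split_events = split_events))
}

#' Richards amplification curve
#'
#' The 5-parameter Richards sigmoid used for qPCR amplification,
#' \eqn{F(x) = Fb + Fmax (1 + e^{-(x-c)/b})^{-d}}.
#'
#' @param x Cycle number (vectorised).
#' @param Fmax,b,c,d,Fb Curve parameters: plateau height above baseline,
#'   slope scale, center, asymmetry shape, baseline.
#' @return Fluorescence values.
#' @export
richards_curve <- function(x, Fmax, b, c, d, Fb = 0) {
  Fb + Fmax * (1 + exp(-(x - c) / b))^(-d)
}

# Analytic Cy0 of a noiseless Richards curve: x-intercept (measured from the
# baseline Fb) of the tangent at the inflection point x* = c + b log(d).
richards_cy0 <- function(Fmax, b, c, d, Fb = 0) {
  xstar <- c + b * log(d)
  fstar <- Fmax * (1 + 1 / d)^(-d)            # F(x*) - Fb
  dstar <- (Fmax / b) * (1 + 1 / d)^(-d - 1)  # F'(x*)
  xstar - fstar / dstar
}

#' Generate synthetic qPCR amplification curves with known Cy0
#'
#' Simulates one amplification curve per entry of `config$qpcr_params` as a
#' Richards sigmoid plus Gaussian noise. The true Cy0 of each curve is
#' computed analytically from the noiseless parameters as the x-intercept of
#' the tangent at the inflection point, measured from the baseline.
#'
#' @param config A [synth_config()].
#' @return List with `curves`, a long data frame (`well`, `cycle`,
#'   `fluorescence`), and `cy0_true`, a named numeric vector of the planted
#'   Cy0 values (cycles).
#' @export
generate_qpcr_curves <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (!length(config$qpcr_params)) stop_field("qpcr_params", "must be non-empty")
  set.seed(config$seed + 1L)
  cycles <- seq_len(config$n_cycles)
  wells <- sprintf("W%02d", seq_along(config$qpcr_params))
  rows <- lapply(seq_along(config$qpcr_params), function(i) {
    p <- as.numeric(config$qpcr_params[[i]])
    f <- richards_curve(cycles, p[1], p[2], p[3], p[4], p[5]) +
      stats::rnorm(length(cycles), 0, p[6])
    data.frame(well = wells[i], cycle = cycles, fluorescence = f)
  })
  cy0 <- vapply(config$qpcr_params, function(p) {
    p <- as.numeric(p)
    richards_cy0(p[1], p[2], p[3], p[4], p[5])
  }, numeric(1))
  names(cy0) <- wells
  list(curves = do.call(rbind, rows), cy0_true = cy0)
}
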