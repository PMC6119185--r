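#' Read a time-course expression matrix with its sample sheet
#'
#' Reads a TSV expression matrix (genes as rows, first column = gene id,
#' remaining columns = samples) and a CSV sample sheet (`sample`, `time`,
#' `replicate`). Genes with more than 20% missing values are dropped (with
#' a message); remaining missing values are imputed by the gene's mean over
#' the other replicates of the same time point (falling back to the gene
#' mean if a whole time point is missing).
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample-sheet CSV.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, sample_sheet_path) {
  raw <- utils::read.delim(path, check.names = FALSE)
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  x <- as.matrix(raw[, -1, drop = FALSE])
  rownames(x) <- genes
  sheet <- utils::read.csv(sample_sheet_path)
  unknown <- setdiff(colnames(x), sheet$sample)
  if (length(unknown))
    stop("samples absent from sample sheet: ", paste(unknown, collapse = ", "))
  frac_na <- rowMeans(is.na(x))
  if (any(frac_na > 0.2)) {
    message(sum(frac_na > 0.2), " gene(s) dropped (> 20% missing values)")
    x <- x[frac_na <= 0.2, , drop = FALSE]
  }
  if (anyNA(x)) {
    sheet_ord <- sheet[match(colnames(x), sheet$sample), ]
    for (tt in unique(sheet_ord$time)) {
      cols <- which(sheet_ord$time == tt)
      sub <- x[, cols, drop = FALSE]
      na_idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na_idx)) {
        tp_mean <- rowMeans(sub, na.rm = TRUE)
        sub[na_idx] <- tp_mean[na_idx[, 1]]
        x[, cols] <- sub
      }
    }
    if (anyNA(x)) {  # whole time point missing for a gene
      gm <- rowMeans(x, na.rm = TRUE)
      idx <- which(is.na(x), arr.ind = TRUE)
      x[idx] <- gm[idx[, 1]]
    }
  }
  expression_dataset(x, sheet)
}

#' Write an expression dataset to TSV + sample sheet CSV
#'
#' @param ds An [expression_dataset()].
#' @param path Output TSV path (genes as rows).
#' @param sample_sheet_path Output CSV path.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(ds, path, sample_sheet_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene = rownames(ds$values), ds$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(ds$samples, sample_sheet_path, row.names = FALSE)
  invisible(c(path, sample_sheet_path))
}

#' Read/write two-column (or richer) edge lists as TSV
#'
#' @param path File path.
#' @return `read_edge_list`: a data frame with at least `regulator`/`target`
#'   or `from`/`to` columns, as written.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' @rdname read_edge_list
#' @param edges Data frame to write.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an undirected weighted edge list as GraphML
#'
#' @param edges Data frame `from`, `to`, `weight` (or a `regulatory_network`
#'   edge table with `sign` as an edge attribute).
#' @param path Output path.
#' @param directed Whether the graph is directed.
#' @export
write_network_graphml <- function(edges, path, directed = FALSE) {
  g <- igraph::graph_from_data_frame(edges, directed = directed)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Pipeline configuration
#'
#' Flat, validated key set covering every stage parameter. Unknown keys are
#' rejected. All randomness derives from the single `seed`, offset
#' deterministically per stage.
#'
#' @param ... Overrides of the defaults (see the function definition for
#'   the full key set and defaults).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    stages = c("simulate", "deg", "network", "topology", "grn", "paths",
               "squad", "cy0"),
    outdir = tempfile("senescnet_run_"),
    seed = 42L,
    synth = list(),            # overrides for synth_config()
    alpha = 0.05, lfc_min = 1,
    mode = "unsigned", r2_goal = 0.8, candidate_powers = 1:20,
    min_module_size = 30, export_threshold = 0.75,
    hub_k = 50,
    policy = "co_module",
    alpha_tf = 0.032, alpha_mir = 0.10, min_path_size = 20,
    delta_bic_min = 10,
    h = 10, gamma = 1, dt = 0.05, t_end = 60, tol = 1e-6)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop_field("alpha", "must be in (0,1]")
  if (cfg$export_threshold < 0 || cfg$export_threshold > 1)
    stop_field("export_threshold", "must be in [0,1]")
  if (!cfg$policy %in% c("co_module", "co_edge", "all"))
    stop_field("policy", "must be one of co_module, co_edge, all")
  bad <- setdiff(cfg$stages, c("simulate", "deg", "network", "topology",
                               "grn", "paths", "squad", "cy0"))
  if (length(bad)) stop_field("stages", paste("unknown:", paste(bad, collapse = ", ")))
  structure(cfg, class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order (simulate -> deg -> network ->
#' topology -> grn -> paths -> squad -> cy0), writing each stage's outputs
#' under `config$outdir` and a manifest JSON recording the package version,
#' the full configuration, the seed and the MD5 hash of every output file.
#' Rerunning with an identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  state <- new.env()
  put <- function(name, path) outputs[[name]] <<- path
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("simulate", function() {
    scfg <- do.call(synth_config, utils::modifyList(
      list(seed = config$seed), config$synth))
    bundle <- generate_dataset(scfg)
    state$bundle <- bundle
    p1 <- file.path(config$outdir, "expression.tsv")
    p2 <- file.path(config$outdir, "samples.csv")
    write_expression(bundle$expr, p1, p2)
    put("expression", p1); put("samples", p2)
    if (!is.null(bundle$mir)) {
      p3 <- file.path(config$outdir, "mir_expression.tsv")
      p4 <- file.path(config$outdir, "mir_samples.csv")
      write_expression(bundle$mir, p3, p4)
      put("mir_expression", p3); put("mir_samples", p4)
    }
    p5 <- file.path(config$outdir, "tf_edges.tsv")
    write_edge_list(bundle$tf_edges, p5); put("tf_edges", p5)
    p6 <- file.path(config$outdir, "mir_edges.tsv")
    write_edge_list(bundle$mir_edges, p6); put("mir_edges", p6)
    p7 <- file.path(config$outdir, "truth.json")
    jsonlite::write_json(bundle$truth, p7, auto_unbox = TRUE, null = "null")
    put("truth", p7)
    msg("simulate", "generated ", nrow(bundle$expr$values), " genes")
  })

  need_bundle <- function() {
    if (is.null(state$bundle))
      stop("no input data: enable the 'simulate' stage or load data first")
    state$bundle
  }

  run_stage("deg", function() {
    expr <- need_bundle()$expr
    degs <- call_degs(expr, alpha = config$alpha, lfc_min = config$lfc_min)
    emer <- find_emergent(expr, alpha = config$alpha, lfc_min = config$lfc_min)
    p1 <- file.path(config$outdir, "degs.tsv")
    write_edge_list(degs, p1); put("degs", p1)
    p2 <- file.path(config$outdir, "emergent.tsv")
    write_edge_list(data.frame(gene = names(emer$emergent_time),
                               emergent_time = unname(emer$emergent_time)), p2)
    put("emergent", p2)
    msg("deg", sum(degs$is_deg), " DEG calls, ",
        sum(!is.na(emer$emergent_time)), " emergent genes")
  })

  run_stage("network", function() {
    expr <- need_bundle()$expr
    sim <- correlation_similarity(expr, mode = config$mode)
    st <- pick_soft_threshold(sim, config$candidate_powers, config$r2_goal)
    tom <- compute_tom(sim^st$power)
    part <- detect_modules(tom, min_module_size = config$min_module_size)
    edges <- export_network(tom, config$export_threshold)
    state$partition <- part
    state$edges <- edges
    p1 <- file.path(config$outdir, "network_edges.tsv")
    write_edge_list(edges, p1); put("network_edges", p1)
    p2 <- file.path(config$outdir, "partition.tsv")
    write_edge_list(data.frame(gene = names(part), module = unname(part)), p2)
    put("partition", p2)
    p3 <- file.path(config$outdir, "sft_fit.tsv")
    write_edge_list(st$fit, p3); put("sft_fit", p3)
    p4 <- file.path(config$outdir, "network.graphml")
    write_network_graphml(edges, p4); put("graphml", p4)
    msg("network", "power ", st$power, ", signed R^2 ",
        sprintf("%.3f", st$r2), ", ",
        length(setdiff(unique(part), "grey")), " modules")
  })

  run_stage("topology", function() {
    if (is.null(state$edges)) stop("network stage must run before topology")
    topo <- topology_report(state$edges, hub_k = config$hub_k,
                            nodes = attr(state$edges, "nodes"))
    p1 <- file.path(config$outdir, "topology.tsv")
    write_edge_list(topo, p1); put("topology", p1)
    tfs <- unique(need_bundle()$tf_edges$regulator)
    hubs <- topo$node[topo$is_hub]
    net_nodes <- topo$node[topo$degree > 0]
    enr <- hypergeom_enrichment(length(net_nodes),
                                length(intersect(tfs, net_nodes)),
                                length(intersect(hubs, net_nodes)),
                                length(intersect(tfs, hubs)))
    p2 <- file.path(config$outdir, "hub_tf_enrichment.json")
    jsonlite::write_json(list(n_nodes = length(net_nodes),
                              n_tfs = length(intersect(tfs, net_nodes)),
                              n_hubs = length(intersect(hubs, net_nodes)),
                              overlap = length(intersect(tfs, hubs)),
                              p = enr),
                         p2, auto_unbox = TRUE, digits = NA)
    put("hub_tf_enrichment", p2)
    msg("topology", length(hubs), " hubs; TF enrichment p = ",
        format(enr, digits = 4))
  })

  run_stage("grn", function() {
    if (is.null(state$partition)) stop("network stage must run before grn")
    b <- need_bundle()
    grn <- build_grn(state$edges, state$partition, b$tf_edges, b$mir_edges,
                     policy = config$policy)
    state$grn <- grn
    p1 <- file.path(config$outdir, "grn.tsv")
    write_edge_list(grn$edges, p1); put("grn", p1)
    msg("grn", grn$summary[["n_edges"]], " regulatory edges retained")
  })

  run_stage("paths", function() {
    b <- need_bundle()
    mexpr <- replicate_means(b$expr)
    mexpr <- mexpr - mexpr[, 1]
    model <- mine_paths(mexpr, state$grn, alpha_tf = config$alpha_tf,
                        alpha_mir = config$alpha_mir,
                        min_path_size = config$min_path_size,
                        delta_bic_min = config$delta_bic_min)
    summ <- summarize_paths(model)
    state$path_model <- model
    p1 <- file.path(config$outdir, "paths.tsv")
    write_edge_list(summ$paths, p1); put("paths", p1)
    p2 <- file.path(config$outdir, "path_model.json")
    jsonlite::write_json(
      list(states = model$states,
           splits = lapply(model$splits, function(sp)
             list(state = sp$state, time = sp$time, children = sp$children,
                  annotated = sp$annotated)),
           n_paths = summ$n_paths, n_tf_groups = summ$n_tf_groups),
      p2, auto_unbox = TRUE, null = "null")
    put("path_model", p2)
    msg("paths", summ$n_paths, " paths, ", length(model$splits), " splits, ",
        summ$n_tf_groups, " TF groups")
  })

  run_stage("squad", function() {
    if (is.null(state$grn)) stop("grn stage must run before squad")
    edges <- state$grn$edges
    if (!nrow(edges)) { msg("squad", "empty GRN; skipping scan"); return() }
    outdeg <- sort(table(edges$regulator[edges$class == "TF"]),
                   decreasing = TRUE)
    tf <- names(outdeg)[1]
    sys <- squad_system(edges, h = config$h, gamma = config$gamma)
    scan <- perturbation_scan(sys, tf, 0, 1, t_end = config$t_end,
                              dt = config$dt, tol = config$tol)
    p1 <- file.path(config$outdir, "squad_scan.tsv")
    write_edge_list(scan, p1); put("squad_scan", p1)
    msg("squad", "clamped ", tf, " 0 -> 1; max |delta| = ",
        sprintf("%.3f", max(abs(scan$delta))))
  })

  run_stage("cy0", function() {
    scfg <- do.call(synth_config, utils::modifyList(
      list(seed = config$seed), config$synth))
    qp <- generate_qpcr_curves(scfg)
    tab <- cy0_table(qp$curves)
    tab$cy0_true <- qp$cy0_true[tab$well]
    p1 <- file.path(config$outdir, "cy0.tsv")
    write_edge_list(tab, p1); put("cy0", p1)
    msg("cy0", nrow(tab), " curves quantified")
  })

  manifest <- list(
    package = "senescnet",
    version = as.character(utils::packageVersion("senescnet")),
    seed = config$seed,
    stages = config$stages,
    config = unclass(config)[setdiff(names(config), "stages")],
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mpath <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, null = "null",
                       force = TRUE)
  invisible(manifest)
}
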