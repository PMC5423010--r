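# The end-to-end estimator: expression + interaction layers in, a classed
# result object out, holding every stage's output (sponge network, motif
# matches, co-regulation network, topology, modules, module scores,
# enrichment).

#' Infer a miRNA sponge co-regulation network
#'
#' Runs the full pipeline: (1) sponge-pair inference from expression and
#' validated miRNA-target interactions under the four sponge conditions;
#' (2) integration with PPI and lncRNA-target layers and enumeration of
#' the two 4-node co-regulation motif types, merged into the
#' co-regulation network; (3) topology analytics (degree distribution and
#' its log-log power-law fit, characteristic path length, per-edge motif
#' and shared-miRNA statistics, hub selection), Markov clustering into
#' modules, and — when sample labels are supplied — cross-validated SVM
#' scoring of each module (ACC, AUC, OPI) with signature selection, plus
#' optional over-representation analysis against user gene sets.
#'
#' @param mirna_expr miRNA expression matrix (miRNAs x samples).
#' @param lncrna_expr,mrna_expr ceRNA expression matrices, same samples in
#'   the same column order as `mirna_expr`.
#' @param mirna_targets canonical miRNA-target edge list
#'   ([read_edge_list()] / [make_edge_list()]).
#' @param ppi canonical PPI edge list.
#' @param lnc_targets canonical lncRNA-target edge list.
#' @param disease_genes character vector of disease gene/lncRNA symbols
#'   (pass the full ceRNA universe to disable the disease condition).
#' @param lncrna_ids symbols to treat as lncRNAs when typing the network;
#'   defaults to the rownames of `lncrna_expr`.
#' @param labels optional named `tumor`/`normal` sample-label vector; when
#'   supplied, modules are scored by cross-validated SVM.
#' @param gene_sets optional named list of gene sets for per-module ORA.
#' @param config a [mirscoppi_config()].
#' @return object of class `mirscoppi`: list with elements `sponge`
#'   (network + candidates audit table), `integrated`, `motifs`, `coreg`,
#'   `topology`, `clusters`, `modules`, `scores`, `enrichment`, `hubs`,
#'   `config`.
#' @export
mirscoppi <- function(mirna_expr, lncrna_expr, mrna_expr, mirna_targets, ppi,
                      lnc_targets, disease_genes,
                      lncrna_ids = rownames(lncrna_expr), labels = NULL,
                      gene_sets = NULL, config = mirscoppi_config()) {
  cerna_expr <- rbind(lncrna_expr, mrna_expr)
  profiles <- build_regulation_profiles(mirna_expr, cerna_expr, mirna_targets)
  sponge <- if (length(profiles)) {
    infer_sponge_network(profiles, cerna_expr, disease_genes, config)
  } else {
    list(network = make_edge_list(character(), character(), "sponge"),
         candidates = data.frame())
  }
  integrated <- integrate_networks(sponge$network, ppi, lnc_targets, lncrna_ids)
  motifs <- enumerate_motifs(integrated)
  coreg <- build_coreg_network(motifs, integrated)

  topology <- NULL
  hubs <- character()
  if (length(coreg$nodes) >= 2 && nrow(coreg$edges) > 0) {
    dd <- degree_distribution(coreg)
    deg_fit <- tryCatch(power_law_r2(dd$degree, dd$frequency), error = function(e) NULL)
    es <- edge_statistics(coreg, motifs, sponge$candidates)
    mc_tab <- table(es$edges$motif_count)
    motif_fit <- tryCatch(
      power_law_r2(as.integer(names(mc_tab)), as.integer(mc_tab)),
      error = function(e) NULL)
    sh_tab <- table(es$edges$shared_mirna_count)
    shared_fit <- tryCatch(
      power_law_r2(as.integer(names(sh_tab)), as.integer(sh_tab)),
      error = function(e) NULL)
    topology <- list(degree_distribution = dd,
                     path_length = characteristic_path_length(coreg),
                     degree_fit = deg_fit,
                     motif_fit = motif_fit,
                     shared_fit = shared_fit,
                     edge_stats = es)
    hubs <- select_hubs(coreg, config$hub_fraction)
  }

  clusters <- list()
  modules <- extract_modules(list(), config$min_module_size)
  if (length(coreg$nodes) > 0) {
    clusters <- mcl_cluster(coreg, inflation = config$mcl_inflation,
                            expansion = config$mcl_expansion)
    modules <- extract_modules(clusters, config$min_module_size)
  }

  scores <- NULL
  if (!is.null(labels) && length(modules$modules)) {
    expr_all <- cerna_expr
    rows <- list()
    for (id in names(modules$modules)) {
      genes <- intersect(modules$modules[[id]], rownames(expr_all))
      if (length(genes) < 2) next
      ev <- evaluate_module(genes, expr_all, labels,
                            folds = config$cv_folds, seed = config$random_seed,
                            signature_cutoff = config$signature_cutoff)
      rows[[id]] <- data.frame(module_id = as.integer(id), size = ev$size,
                               auc = ev$auc, acc = ev$acc,
                               stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      scores <- rank_and_select_signatures(do.call(rbind, rows),
                                           cutoff = config$signature_cutoff)
    }
  }

  enrichment <- NULL
  if (!is.null(gene_sets) && length(modules$modules)) {
    universe <- names(coreg$nodes)
    enrichment <- lapply(modules$modules, function(genes) {
      ora_enrichment(intersect(genes, universe), gene_sets, universe,
                     alpha = config$enrichment_alpha)
    })
  }

  structure(list(sponge = sponge, integrated = integrated, motifs = motifs,
                 coreg = coreg, topology = topology, clusters = clusters,
                 modules = modules, scores = scores, enrichment = enrichment,
                 hubs = hubs, config = config),
            class = "mirscoppi")
}

#' @export
print.mirscoppi <- function(x, ...) {
  cat("miRNA sponge co-regulation analysis\n")
  cat("  candidate pairs scored :", nrow(x$sponge$candidates), "\n")
  cat("  sponge edges accepted  :", nrow(x$sponge$network), "\n")
  cat("  motif matches          :", nrow(x$motifs),
      sprintf("(A=%d, B=%d)", sum(x$motifs$motif_type == "A"),
              sum(x$motifs$motif_type == "B")), "\n")
  cat("  co-regulation network  :", length(x$coreg$nodes), "nodes,",
      nrow(x$coreg$edges), "edges\n")
  cat("  modules (>= size ", x$config$min_module_size, ") : ",
      length(x$modules$modules), "\n", sep = "")
  if (!is.null(x$scores)) {
    cat("  module signatures      :", sum(x$scores$is_signature), "of",
        nrow(x$scores), "\n")
  }
  invisible(x)
}

#' @export
summary.mirscoppi <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$topology)) {
    cat("\ntopology:\n")
    cat("  characteristic path length:", format(x$topology$path_length, digits = 4), "\n")
    if (!is.null(x$topology$degree_fit)) {
      cat("  degree power-law fit: slope", format(x$topology$degree_fit$slope, digits = 4),
          " R^2", format(x$topology$degree_fit$r_squared, digits = 4), "\n")
    }
    if (!is.na(x$topology$edge_stats$corr)) {
      cat("  motif-count vs shared-miRNA correlation:",
          format(x$topology$edge_stats$corr, digits = 4), "\n")
    }
    cat("  hubs:", paste(utils::head(x$hubs, 10), collapse = ", "),
        if (length(x$hubs) > 10) "..." else "", "\n")
  }
  if (!is.null(x$scores)) {
    cat("\nmodule scores (ranked by OPI):\n")
    print(x$scores[, c("rank", "module_id", "size", "auc", "acc", "opi", "is_signature")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot the degree distribution of the co-regulation network
#'
#' Log-log scatter of degree vs frequency with the fitted power-law line.
#'
#' @param x a `mirscoppi` object with a non-empty co-regulation network.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mirscoppi <- function(x, ...) {
  if (is.null(x$topology)) stop("no topology to plot (empty co-regulation network)")
  dd <- x$topology$degree_distribution
  graphics::plot(dd$degree, dd$frequency, log = "xy",
                 xlab = "degree", ylab = "frequency",
                 main = "Degree distribution (log-log)", ...)
  fit <- x$topology$degree_fit
  if (!is.null(fit) && !fit$constant) {
    xs <- range(dd$degree[dd$frequency > 0])
    lx <- seq(log10(xs[1]), log10(xs[2]), length.out = 50)
    graphics::lines(10^lx, 10^(fit$intercept + fit$slope * lx), col = "red")
  }
  invisible(x)
}

#' Run the full pipeline from a YAML configuration file
#'
#' The configuration either names the input files (`inputs:` block with
#' `mirna_expr`, `lncrna_expr`, `mrna_expr`, `mirna_targets`, `ppi`,
#' `lnc_targets`, `disease_genes`, `lncrna_ids`, optional `labels`,
#' optional `gene_sets` GMT) or requests a simulated bundle (`simulate:`
#' block whose keys are [simulate_sponge_data()] arguments). Thresholds go
#' in a `config:` block ([mirscoppi_config()] arguments); outputs are
#' written under `out_dir`. Outputs are pure functions of (inputs, config,
#' seed): re-running an identical configuration reproduces identical
#' files.
#'
#' @param config_path path to the YAML configuration.
#' @return (invisibly) the run manifest: config snapshot, per-stage output
#'   paths and per-stage summary counts.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  out_dir <- cfg$out_dir %||% "mirscoppi_out"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  conf <- do.call(mirscoppi_config, as.list(cfg$config %||% list()))

  if (!is.null(cfg$simulate)) {
    bundle <- do.call(simulate_sponge_data, as.list(cfg$simulate))
    d <- bundle$data
  } else if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    d <- list(mirna_expr = read_expression_matrix(ip$mirna_expr),
              lncrna_expr = read_expression_matrix(ip$lncrna_expr),
              mrna_expr = read_expression_matrix(ip$mrna_expr),
              mirna_targets = read_edge_list(ip$mirna_targets, "mirna_target"),
              ppi = read_edge_list(ip$ppi, "ppi"),
              lnc_targets = read_edge_list(ip$lnc_targets, "lnc_target"),
              disease_genes = read_gene_list(ip$disease_genes),
              lncrna_ids = read_gene_list(ip$lncrna_ids),
              labels = if (!is.null(ip$labels)) read_sample_labels(ip$labels))
  } else {
    stop("configuration needs an 'inputs' or a 'simulate' block")
  }
  gene_sets <- if (!is.null(cfg$inputs$gene_sets)) read_gmt(cfg$inputs$gene_sets)

  fit <- mirscoppi(d$mirna_expr, d$lncrna_expr, d$mrna_expr, d$mirna_targets,
                   d$ppi, d$lnc_targets, d$disease_genes,
                   lncrna_ids = d$lncrna_ids, labels = d$labels,
                   gene_sets = gene_sets, config = conf)

  paths <- list(
    sponge_edges = file.path(out_dir, "sponge_edges.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    motifs = file.path(out_dir, "motifs.tsv"),
    coreg = file.path(out_dir, "coreg_network.tsv"),
    modules = file.path(out_dir, "modules.tsv"))
  write_edge_list(fit$sponge$network, paths$sponge_edges)
  utils::write.table(fit$sponge$candidates, paths$candidates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$motifs, paths$motifs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_network(fit$coreg, paths$coreg)
  write_modules(fit$modules, paths$modules)
  if (!is.null(fit$scores)) {
    paths$scores <- file.path(out_dir, "module_scores.tsv")
    out_scores <- fit$scores
    out_scores$auc <- round(out_scores$auc, 4)
    out_scores$acc <- round(out_scores$acc, 4)
    out_scores$opi <- round(out_scores$opi, 4)
    utils::write.table(out_scores, paths$scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fit$enrichment)) {
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    enr <- do.call(rbind, lapply(names(fit$enrichment), function(id) {
      e <- fit$enrichment[[id]]
      if (nrow(e)) cbind(module_id = id, e) else NULL
    }))
    if (is.null(enr)) enr <- data.frame(module_id = character())
    utils::write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  manifest <- list(
    config = unclass(conf),
    outputs = paths,
    counts = list(candidates_scored = nrow(fit$sponge$candidates),
                  sponge_edges = nrow(fit$sponge$network),
                  motifs = nrow(fit$motifs),
                  coreg_nodes = length(fit$coreg$nodes),
                  coreg_edges = nrow(fit$coreg$edges),
                  modules = length(fit$modules$modules),
                  signatures = if (!is.null(fit$scores)) sum(fit$scores$is_signature) else NA))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$fit <- fit
  invisible(manifest)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
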