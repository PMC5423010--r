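# Step 3a: topology analytics of the merged co-regulation network.

# simple (untyped, deduplicated) undirected igraph view of a typed network
#' @keywords internal
as_simple_igraph <- function(net) {
  e <- net$edges
  e <- e[!duplicated(pair_key(e$a, e$b)), c("a", "b"), drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = names(net$nodes)))
}

#' Degree distribution of a typed network
#'
#' The degree of a node is the number of typed edges incident to it,
#' regardless of type (parallel edges of different types both count).
#'
#' @param net a [typed_network()].
#' @return `data.frame` with columns `degree` and `frequency`; frequencies
#'   sum to the node count.
#' @export
degree_distribution <- function(net) {
  if (!length(net$nodes)) stop("empty network")
  degs <- stats::setNames(rep(0L, length(net$nodes)), names(net$nodes))
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$a, net$edges$b))
    degs[names(tab)] <- as.integer(tab)
  }
  freq <- table(degs)
  data.frame(degree = as.integer(names(freq)), frequency = as.integer(freq))
}

#' Node degrees of a typed network
#' @param net a [typed_network()].
#' @return named integer vector of per-node incident typed-edge counts.
#' @export
node_degrees <- function(net) {
  degs <- stats::setNames(rep(0L, length(net$nodes)), names(net$nodes))
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$a, net$edges$b))
    degs[names(tab)] <- as.integer(tab)
  }
  degs
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered reachable node pairs;
#' pairs in different components are excluded, with the excluded count
#' reported as a message.
#'
#' @param net a [typed_network()] with at least 2 nodes.
#' @return mean shortest-path length.
#' @export
characteristic_path_length <- function(net) {
  if (length(net$nodes) < 2) stop("need at least 2 nodes")
  g <- as_simple_igraph(net)
  d <- igraph::distances(g)
  ut <- d[upper.tri(d)]
  reachable <- is.finite(ut)
  if (!any(reachable)) stop("no reachable node pair; path length undefined")
  if (any(!reachable)) {
    message(sum(!reachable), " unreachable node pair(s) excluded from path length")
  }
  mean(ut[reachable])
}

#' Log-log least-squares power-law fit
#'
#' Ordinary least squares of log10(frequency) on log10(value) over the
#' points with positive frequency; the R-squared of this fit is the
#' scale-free goodness measure reported for degree, motif-count and
#' shared-miRNA distributions. A flat spectrum (zero variance in
#' log-frequency) is returned with slope 0 and R-squared 0, flagged via
#' `constant = TRUE`.
#'
#' @param values positive integer values (e.g. degrees).
#' @param freqs positive frequencies, same length; at least 3 distinct
#'   values required.
#' @return list with `slope`, `intercept`, `r_squared`, `constant` and the
#'   filtered `values`/`freqs` used.
#' @export
power_law_r2 <- function(values, freqs) {
  if (length(values) != length(freqs)) stop("values and freqs must have equal length")
  keep <- freqs > 0
  values <- values[keep]
  freqs <- freqs[keep]
  if (any(values <= 0)) stop("values must be positive for a log-log fit")
  if (length(unique(values)) < 3) stop("need at least 3 distinct values with positive frequency")
  lx <- log10(values)
  ly <- log10(freqs)
  if (stats::var(ly) == 0) {
    return(list(slope = 0, intercept = ly[1], r_squared = 0, constant = TRUE,
                values = values, freqs = freqs))
  }
  fit <- stats::lm(ly ~ lx)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(lx, ly)^2,
       constant = FALSE,
       values = values, freqs = freqs)
}

#' Per-sponge-edge motif and shared-miRNA counts
#'
#' For every sponge edge of the co-regulation network, counts the motif
#' matches whose sponge pair equals that edge and looks up the number of
#' shared miRNAs from the audit table, then correlates the two count
#' vectors (Pearson). The correlation is `NA` (flagged) when either vector
#' is constant.
#'
#' @param coreg co-regulation [typed_network()].
#' @param matches output of [enumerate_motifs()].
#' @param candidates audit table from [infer_sponge_network()].
#' @return list with `edges` (`data.frame`: `a`, `b`, `motif_count`,
#'   `shared_mirna_count`), `corr` and `constant` flag.
#' @export
edge_statistics <- function(coreg, matches, candidates) {
  se <- coreg$edges[coreg$edges$type == "sponge", , drop = FALSE]
  if (nrow(se) == 0) stop("co-regulation network has no sponge edges")
  ekey <- pair_key(se$a, se$b)
  mkey <- if (nrow(matches)) pair_key(matches$s1, matches$s2) else character()
  mtab <- table(mkey)
  motif_count <- integer(nrow(se))
  hit <- ekey %in% names(mtab)
  motif_count[hit] <- as.integer(mtab[ekey[hit]])
  ckey <- pair_key(candidates$ceRNA_i, candidates$ceRNA_j)
  idx <- match(ekey, ckey)
  if (anyNA(idx)) {
    miss <- se[is.na(idx), , drop = FALSE][1, ]
    stop(sprintf("sponge edge %s-%s has no candidate record", miss$a, miss$b))
  }
  shared <- candidates$x[idx]
  constant <- length(motif_count) < 2 ||
    stats::sd(motif_count) == 0 || stats::sd(shared) == 0
  corr <- if (constant) NA_real_ else stats::cor(motif_count, shared)
  list(edges = data.frame(a = se$a, b = se$b, motif_count = motif_count,
                          shared_mirna_count = shared, stringsAsFactors = FALSE),
       corr = corr, constant = constant)
}

#' Select hub nodes by degree
#'
#' Nodes sorted by degree descending (ties broken lexicographically by
#' symbol); the top `ceiling(fraction * node_count)` are returned.
#'
#' @param net a non-empty [typed_network()].
#' @param fraction fraction of nodes to select, in (0, 1].
#' @return character vector of hub symbols.
#' @export
select_hubs <- function(net, fraction = 0.10) {
  if (!length(net$nodes)) stop("empty network")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  degs <- node_degrees(net)
  ord <- order(-degs, names(degs))
  n <- ceiling(fraction * length(degs))
  names(degs)[ord][seq_len(n)]
}
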