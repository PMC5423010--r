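# Step 3b: Markov clustering (MCL) of the co-regulation network.
#
# The network is treated as a simple unweighted undirected graph (edge
# types ignored). Columns of the transition matrix are stochastic; the
# classic expansion / inflation / prune loop is iterated until the matrix
# change falls below `tol`. Clusters are read off from the converged flow:
# attractors are nodes with positive return flow (positive diagonal);
# attractors exchanging flow form attractor systems, and every node is
# assigned to the system it flows into (ties to the lowest-index system).

#' Markov clustering of a network
#'
#' @param net a [typed_network()], a typed edge `data.frame`, or a square
#'   symmetric adjacency matrix with dimnames.
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param expansion matrix-power expansion step (integer >= 2).
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   clusters of the final state are returned.
#' @param prune_threshold entries below this are zeroed after each
#'   inflation step.
#' @param tol convergence tolerance on the maximum entry change.
#' @return list of character vectors (disjoint node clusters covering all
#'   nodes), ordered by decreasing size.
#' @export
mcl_cluster <- function(net, inflation = 2, expansion = 2L, max_iter = 100L,
                        prune_threshold = 1e-5, tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  A <- mcl_adjacency(net)
  n <- nrow(A)
  if (n == 0) stop("empty network")
  nodes <- rownames(A)
  diag(A) <- 1  # self-loops before normalization
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mx <- M
    for (e in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    cs <- colSums(Mx)
    dead <- cs == 0
    if (any(dead)) {
      Mx[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mx <- sweep(Mx, 2, cs, "/")
    Mx[Mx < prune_threshold] <- 0
    cs <- colSums(Mx)
    dead <- cs == 0
    if (any(dead)) {
      Mx[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mx <- sweep(Mx, 2, cs, "/")
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; clustering the final state")
  }
  # read off clusters
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate safeguard
  sub <- M[attractors, attractors, drop = FALSE] > 0
  sys_g <- igraph::graph_from_adjacency_matrix(sub | t(sub), mode = "undirected",
                                               diag = FALSE)
  sys_id <- igraph::components(sys_g)$membership  # per attractor
  assign <- integer(n)
  for (j in seq_len(n)) {
    owners <- attractors[M[attractors, j] > 0]
    if (length(owners)) {
      assign[j] <- min(sys_id[match(owners, attractors)])
    } else {
      # no attractor receives flow from j (heavily pruned state): attach to
      # the system of the strongest recipient
      k <- which.max(M[, j])
      assign[j] <- min(sys_id[match(attractors[M[attractors, k] > 0], attractors)],
                       na.rm = TRUE)
    }
  }
  clusters <- split(nodes, assign)
  clusters <- lapply(clusters, sort)
  clusters[order(-vapply(clusters, length, 0L),
                 vapply(clusters, `[`, "", 1L))]
}

#' @keywords internal
mcl_adjacency <- function(net) {
  if (is.matrix(net)) {
    stopifnot(nrow(net) == ncol(net), !is.null(rownames(net)))
    A <- (net != 0) * 1
    return(A)
  }
  edges <- if (inherits(net, "typed_network")) net$edges else net
  nodes <- if (inherits(net, "typed_network")) names(net$nodes) else
    sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$a, nodes)
    ib <- match(edges$b, nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  A
}

#' Filter and number clusters into modules
#'
#' Clusters smaller than `min_size` are dropped (count reported as a
#' message); survivors are ordered by decreasing size (ties by first
#' member) and numbered 1..n. The minimum size defaults to 4, the size of
#' a co-regulation motif.
#'
#' @param clusters list of disjoint node sets from [mcl_cluster()].
#' @param min_size smallest module retained.
#' @return object of class `module_partition`: list with `modules` (named
#'   list of character vectors, names `"1"`, `"2"`, ...) and `sizes`.
#' @export
extract_modules <- function(clusters, min_size = 4L) {
  sizes <- vapply(clusters, length, 0L)
  dropped <- sum(sizes < min_size)
  if (dropped) message(dropped, " cluster(s) below minimum size ", min_size, " dropped")
  keep <- clusters[sizes >= min_size]
  keep <- keep[order(-vapply(keep, length, 0L), vapply(keep, `[`, "", 1L))]
  names(keep) <- as.character(seq_along(keep))
  structure(list(modules = keep, sizes = vapply(keep, length, 0L)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module partition:", length(x$modules), "module(s)\n")
  if (length(x$modules)) {
    cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write modules as 2-column TSV (module_id, member)
#' @param partition a `module_partition`.
#' @param path output path.
#' @export
write_modules <- function(partition, path) {
  rows <- do.call(rbind, lapply(names(partition$modules), function(id) {
    data.frame(module_id = id, member = partition$modules[[id]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(module_id = character(), member = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
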