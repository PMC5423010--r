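# Independent oracles and fixture builders shared across tests.

# upper-tail hypergeometric by direct enumeration of the pmf
hyper_enum_oracle <- function(M, N, K, x) {
  if (x == 0) return(1)
  i <- x:min(N, K)
  sum(choose(N, i) * choose(M - N, K - i)) / choose(M, K)
}

# random typed network with kind-consistent typed edges
random_typed_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  kinds <- stats::setNames(
    sample(c("lncRNA", "mRNA_protein", "protein"), n_nodes, replace = TRUE,
           prob = c(0.25, 0.4, 0.35)),
    nodes)
  rows <- list()
  tries <- 0
  while (length(rows) < n_edges && tries < n_edges * 20) {
    tries <- tries + 1
    pair <- sample(nodes, 2)
    ka <- kinds[[pair[1]]]
    kb <- kinds[[pair[2]]]
    valid <- character()
    if (all(c(ka, kb) %in% c("lncRNA", "mRNA_protein"))) valid <- c(valid, "sponge")
    if (all(c(ka, kb) %in% c("mRNA_protein", "protein"))) valid <- c(valid, "ppi")
    if ((ka == "lncRNA") != (kb == "lncRNA")) valid <- c(valid, "lnc_target")
    if (!length(valid)) next
    type <- if (length(valid) == 1) valid else sample(valid, 1)
    rows[[length(rows) + 1]] <- data.frame(a = pair[1], b = pair[2], type = type,
                                           stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), type = character())
  typed_network(edges, kinds)
}

# brute-force motif enumeration: check both motif predicates on every
# 4-node subset, independently of the edge-driven implementation
brute_force_motifs <- function(net) {
  kinds <- net$nodes
  nodes <- names(kinds)
  n <- length(nodes)
  empty <- data.frame(motif_type = character(), s1 = character(), s2 = character(),
                      p1 = character(), p2 = character(), stringsAsFactors = FALSE)
  if (n < 4) return(empty)
  adj <- function(type) {
    A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    e <- net$edges[net$edges$type == type, , drop = FALSE]
    if (nrow(e)) {
      A[cbind(e$a, e$b)] <- TRUE
      A[cbind(e$b, e$a)] <- TRUE
    }
    A
  }
  SP <- adj("sponge")
  PP <- adj("ppi")
  LT <- adj("lnc_target")
  link <- function(s, p) if (kinds[[s]] == "lncRNA") LT[s, p] else PP[s, p]
  rows <- list()
  subsets <- utils::combn(nodes, 4)
  for (col in seq_len(ncol(subsets))) {
    q4 <- subsets[, col]
    for (i in 1:3) for (j in (i + 1):4) {
      s1 <- min(q4[i], q4[j])
      s2 <- max(q4[i], q4[j])
      if (!SP[s1, s2]) next
      rest <- setdiff(q4, c(s1, s2))
      u <- rest[1]
      v <- rest[2]
      if (PP[u, v]) {
        if (link(s1, u) && link(s2, v)) {
          rows[[length(rows) + 1]] <- c("A", s1, s2, u, v)
        }
        if (link(s1, v) && link(s2, u)) {
          rows[[length(rows) + 1]] <- c("A", s1, s2, v, u)
        }
        if (link(s1, u) && link(s2, u)) {
          rows[[length(rows) + 1]] <- c("B", s1, s2, u, v)
        }
        if (link(s1, v) && link(s2, v)) {
          rows[[length(rows) + 1]] <- c("B", s1, s2, v, u)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  mat <- do.call(rbind, rows)
  res <- data.frame(motif_type = mat[, 1], s1 = mat[, 2], s2 = mat[, 3],
                    p1 = mat[, 4], p2 = mat[, 5], stringsAsFactors = FALSE)
  res <- unique(res)
  res <- res[order(res$motif_type, res$s1, res$s2, res$p1, res$p2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

motif_key <- function(m) {
  if (!nrow(m)) return(character())
  paste(m$motif_type, m$s1, m$s2, m$p1, m$p2)
}

# independent dense-matrix Markov clustering (no pruning, row-support
# read-off); used as an oracle for small graphs
mcl_dense_oracle <- function(A, inflation = 2, max_iter = 200) {
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- (M %*% M)^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-9) {
      M <- M2
      break
    }
    M <- M2
  }
  live <- which(rowSums(M > 1e-6) > 0)
  clusters <- lapply(live, function(r) sort(colnames(A)[M[r, ] > 1e-6]))
  unique(clusters)
}

# adjacency matrix of one or more cliques plus optional extra edges
clique_adjacency <- function(cliques, extra = NULL) {
  nodes <- sort(unique(c(unlist(cliques), unlist(extra))))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (cl in cliques) {
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (i != j) A[cl[i], cl[j]] <- 1
    }
  }
  if (!is.null(extra)) {
    for (e in extra) {
      A[e[1], e[2]] <- 1
      A[e[2], e[1]] <- 1
    }
  }
  A
}

# small hand-built expression fixture for sponge inference: 10 miRNAs,
# one planted pair (A, B) sharing 3 miRNAs, one under-sharing pair (C, D)
sponge_inference_fixture <- function(seed = 7, n_samp = 60) {
  set.seed(seed)
  mir <- matrix(rnorm(10 * n_samp), 10, n_samp,
                dimnames = list(sprintf("m%02d", 1:10),
                                sprintf("s%02d", seq_len(n_samp))))
  base <- -colSums(mir[1:3, ])
  genes <- c("A", "B", "C", "D", "E")
  ce <- matrix(rnorm(5 * n_samp), 5, n_samp,
               dimnames = list(genes, colnames(mir)))
  ce["A", ] <- base + rnorm(n_samp, 0, 0.2)
  ce["B", ] <- base + rnorm(n_samp, 0, 0.2)
  # C and D share only 2 validated miRNAs
  targets <- make_edge_list(
    c("m01", "m02", "m03", "m01", "m02", "m03", "m04", "m05", "m04", "m05", "m06"),
    c("A", "A", "A", "B", "B", "B", "C", "C", "D", "D", "E"),
    "mirna_target")
  list(mirna = mir, cerna = ce, targets = targets, genes = genes)
}
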