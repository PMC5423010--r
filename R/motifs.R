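# Step 2: integrate the sponge, PPI and lncRNA-target layers and enumerate
# the two 4-node sponge-co-regulation motif types.
#
# Motif semantics. A sponge node reaches the protein layer through "link"
# edges: for an lncRNA sponge these are its lnc_target edges; an mRNA sponge
# is identical to its protein, so its links are its own ppi edges. Both
# motifs contain exactly 4 distinct nodes and one co-regulated PPI:
#   type A: sponge(s1,s2), link(s1,p1), link(s2,p2), ppi(p1,p2)
#           -- the sponges reach the two distinct parties of one PPI;
#   type B: sponge(s1,s2), link(s1,p), link(s2,p), ppi(p,q)
#           -- the sponges share one protein p that has a PPI partner q;
#           each distinct partner q is a distinct match.

#' Integrate sponge, PPI and lncRNA-target layers into one typed network
#'
#' Identical symbols across layers map to the same node: an mRNA sponge and
#' its protein are one `mRNA_protein` node. Node kinds are assigned as:
#' `lncRNA` for symbols in `lncrna_ids`; `mRNA_protein` for non-lncRNA
#' sponge endpoints; `protein` for remaining PPI / lncRNA-target endpoints.
#' A symbol declared as lncRNA that appears as a PPI endpoint is a type
#' conflict and raises an error.
#'
#' @param sponge canonical sponge edge list (from [infer_sponge_network()]).
#' @param ppi canonical PPI edge list.
#' @param lnc_target canonical lncRNA-target edge list.
#' @param lncrna_ids character vector naming which symbols are lncRNAs.
#' @return a [typed_network()].
#' @export
integrate_networks <- function(sponge, ppi, lnc_target, lncrna_ids) {
  lncrna_ids <- unique(as.character(lncrna_ids))
  ppi_nodes <- unique(c(ppi$a, ppi$b))
  conflict <- intersect(lncrna_ids, ppi_nodes)
  if (length(conflict)) {
    stop("symbol(s) declared lncRNA but present as PPI endpoints: ",
         paste(utils::head(conflict, 10), collapse = ", "))
  }
  sponge_nodes <- unique(c(sponge$a, sponge$b))
  lt_nodes <- unique(c(lnc_target$a, lnc_target$b))
  all_nodes <- unique(c(sponge_nodes, ppi_nodes, lt_nodes))
  kinds <- stats::setNames(rep("protein", length(all_nodes)), all_nodes)
  kinds[all_nodes %in% sponge_nodes] <- "mRNA_protein"
  kinds[all_nodes %in% lncrna_ids] <- "lncRNA"
  edges <- rbind(
    data.frame(a = sponge$a, b = sponge$b,
               type = rep_len("sponge", nrow(sponge)), stringsAsFactors = FALSE),
    data.frame(a = ppi$a, b = ppi$b,
               type = rep_len("ppi", nrow(ppi)), stringsAsFactors = FALSE),
    data.frame(a = lnc_target$a, b = lnc_target$b,
               type = rep_len("lnc_target", nrow(lnc_target)),
               stringsAsFactors = FALSE))
  typed_network(edges, kinds)
}

# adjacency lists of a typed network restricted to one edge type
#' @keywords internal
adjacency_by_type <- function(net, type) {
  e <- net$edges[net$edges$type == type, , drop = FALSE]
  adj <- list()
  if (nrow(e)) {
    nb <- split(c(e$b, e$a), c(e$a, e$b))
    adj <- lapply(nb, unique)
  }
  adj
}

# protein-layer neighbours a sponge node reaches through its link edges
#' @keywords internal
link_neighbours <- function(node, kinds, ppi_adj, lt_adj) {
  if (kinds[[node]] == "lncRNA") {
    nbs <- lt_adj[[node]]
  } else {
    nbs <- ppi_adj[[node]]
  }
  if (is.null(nbs)) character() else nbs
}

#' Enumerate 4-node sponge-co-regulation motifs
#'
#' Returns every distinct match of motif types A and B (see the motif
#' semantics in the package documentation). Each match is reported once per
#' unordered realization: relabelling the two (sponge, protein) arms of a
#' type-A match is not a new match, but the two orientations of a sponge
#' pair onto a PPI through *different* link edges are distinct matches, as
#' is each distinct PPI partner `q` in type B. Output order is
#' deterministic (sorted by motif type and node tuple).
#'
#' @param net a [typed_network()].
#' @return `data.frame` with columns `motif_type` (`"A"`/`"B"`), `s1`, `s2`
#'   (sponge pair, `s1 < s2`), `p1`, `p2`. For type A, `p1` is the PPI
#'   party linked to `s1` and `p2` the one linked to `s2`; for type B,
#'   `p1` is the shared protein and `p2` its PPI partner.
#' @export
enumerate_motifs <- function(net) {
  empty <- data.frame(motif_type = character(), s1 = character(), s2 = character(),
                      p1 = character(), p2 = character(), stringsAsFactors = FALSE)
  se <- net$edges[net$edges$type == "sponge", , drop = FALSE]
  pe <- net$edges[net$edges$type == "ppi", , drop = FALSE]
  if (nrow(se) == 0 || nrow(pe) == 0) return(empty)
  kinds <- net$nodes
  ppi_adj <- adjacency_by_type(net, "ppi")
  lt_adj <- adjacency_by_type(net, "lnc_target")

  out <- list()
  n_out <- 0L
  push <- function(row) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- row
  }

  for (k in seq_len(nrow(se))) {
    s1 <- se$a[k]
    s2 <- se$b[k]
    L1 <- setdiff(link_neighbours(s1, kinds, ppi_adj, lt_adj), c(s1, s2))
    L2 <- setdiff(link_neighbours(s2, kinds, ppi_adj, lt_adj), c(s1, s2))
    if (!length(L1) || !length(L2)) next
    # type A: ppi edge whose two parties are linked one-to-each sponge
    in1a <- pe$a %in% L1
    in1b <- pe$b %in% L1
    in2a <- pe$a %in% L2
    in2b <- pe$b %in% L2
    ok_nodes <- !(pe$a %in% c(s1, s2)) & !(pe$b %in% c(s1, s2))
    hit1 <- ok_nodes & in1a & in2b  # s1-pa, s2-pb
    hit2 <- ok_nodes & in1b & in2a  # s1-pb, s2-pa
    for (m in which(hit1)) {
      push(c("A", s1, s2, pe$a[m], pe$b[m]))
    }
    for (m in which(hit2)) {
      push(c("A", s1, s2, pe$b[m], pe$a[m]))
    }
    # type B: shared linked protein with a PPI partner q
    for (p in intersect(L1, L2)) {
      qs <- setdiff(if (is.null(ppi_adj[[p]])) character() else ppi_adj[[p]],
                    c(s1, s2, p))
      for (q in qs) {
        push(c("B", s1, s2, p, q))
      }
    }
  }
  if (n_out == 0L) return(empty)
  mat <- do.call(rbind, out[seq_len(n_out)])
  res <- data.frame(motif_type = mat[, 1], s1 = mat[, 2], s2 = mat[, 3],
                    p1 = mat[, 4], p2 = mat[, 5], stringsAsFactors = FALSE)
  res <- unique(res)
  res <- res[order(res$motif_type, res$s1, res$s2, res$p1, res$p2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# typed edges realizing one motif match
#' @keywords internal
motif_match_edges <- function(match, kinds) {
  link_type <- function(s) if (kinds[[s]] == "lncRNA") "lnc_target" else "ppi"
  s1 <- match[["s1"]]; s2 <- match[["s2"]]
  p1 <- match[["p1"]]; p2 <- match[["p2"]]
  if (match[["motif_type"]] == "A") {
    rbind(
      data.frame(a = s1, b = s2, type = "sponge", stringsAsFactors = FALSE),
      data.frame(a = s1, b = p1, type = link_type(s1), stringsAsFactors = FALSE),
      data.frame(a = s2, b = p2, type = link_type(s2), stringsAsFactors = FALSE),
      data.frame(a = p1, b = p2, type = "ppi", stringsAsFactors = FALSE))
  } else {
    rbind(
      data.frame(a = s1, b = s2, type = "sponge", stringsAsFactors = FALSE),
      data.frame(a = s1, b = p1, type = link_type(s1), stringsAsFactors = FALSE),
      data.frame(a = s2, b = p1, type = link_type(s2), stringsAsFactors = FALSE),
      data.frame(a = p1, b = p2, type = "ppi", stringsAsFactors = FALSE))
  }
}

#' Merge motif matches into the co-regulation network
#'
#' The union of all nodes and typed edges over the matches; every edge of
#' the result belongs to at least one motif. Per-type edge counts are
#' reported as a message.
#'
#' @param matches output of [enumerate_motifs()].
#' @param net the integrated [typed_network()] the matches came from
#'   (supplies node kinds).
#' @return a [typed_network()] restricted to motif-supported nodes/edges.
#' @export
build_coreg_network <- function(matches, net) {
  if (nrow(matches) == 0) {
    return(typed_network(data.frame(a = character(), b = character(),
                                    type = character(), stringsAsFactors = FALSE),
                         stats::setNames(character(), character())))
  }
  kinds <- net$nodes
  edges <- do.call(rbind, lapply(seq_len(nrow(matches)), function(i) {
    motif_match_edges(matches[i, ], kinds)
  }))
  nodes <- unique(c(edges$a, edges$b))
  out <- typed_network(edges, kinds[nodes])
  tab <- table(out$edges$type)
  message("co-regulation network: ", length(out$nodes), " nodes, ",
          paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "))
  out
}
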