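# Core domain containers and tabular readers/writers.
#
# Conventions used throughout the package:
#   * expression matrices are plain numeric matrices, genes in rows
#     (rownames = gene symbols), samples in columns (colnames = sample ids);
#   * edge lists are data.frames with character columns `a`, `b`, `type`,
#     stored in canonical form: a < b lexicographically, no self-loops,
#     no duplicate typed edges, rows sorted by (type, a, b);
#   * gene identifiers are case-sensitive exact symbols (no ID mapping).

#' @keywords internal
canonicalize_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  list(a = a, b = b)
}

# canonical "a|b" keys for set arithmetic on unordered pairs
#' @keywords internal
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Build a canonical undirected edge list
#'
#' Nodes of each edge are stored in lexicographic order, self-loops are
#' dropped (with a message giving the count), and duplicate edges are
#' collapsed.
#'
#' @param a,b character vectors of endpoint symbols.
#' @param edge_type edge-type tag, one of `"mirna_target"`, `"ppi"`,
#'   `"lnc_target"`, `"sponge"`.
#' @return A `data.frame` with columns `a`, `b`, `type`, rows sorted.
#' @export
make_edge_list <- function(a, b, edge_type = c("mirna_target", "ppi", "lnc_target", "sponge")) {
  edge_type <- match.arg(edge_type)
  a <- trimws(as.character(a))
  b <- trimws(as.character(b))
  if (length(a) != length(b)) stop("endpoint vectors must have equal length")
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]
  b <- b[keep]
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped from ", edge_type, " edge list")
    a <- a[!self]
    b <- b[!self]
  }
  p <- canonicalize_pairs(a, b)
  dup <- duplicated(pair_key(p$a, p$b))
  out <- data.frame(a = p$a[!dup], b = p$b[!dup],
                    type = rep_len(edge_type, sum(!dup)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genes-by-samples expression matrix
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header row holds sample identifiers. Rows with an empty symbol are
#' dropped; duplicate gene rows are collapsed by element-wise averaging, so
#' replicate measurements of the same symbol yield one row. Missing or
#' non-finite values are rejected rather than imputed.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file must have a gene column plus >= 1 sample column")
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  genes <- trimws(raw[[1]])
  keep <- nzchar(genes)
  raw <- raw[keep, , drop = FALSE]
  genes <- genes[keep]
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                   col[bad[1]], genes[bad[1]], sample_ids[j]))
    }
    vals[, j] <- v
  }
  if (any(!is.finite(vals))) stop("non-finite expression values are not supported")
  if (anyDuplicated(genes)) {
    sums <- rowsum(vals, genes)
    counts <- as.vector(rowsum(rep(1, length(genes)), genes))
    avg <- sums / counts
    avg <- avg[unique(genes), , drop = FALSE]  # keep first-occurrence row order
    vals <- avg
  } else {
    rownames(vals) <- genes
  }
  vals
}

#' Write an expression matrix in the package's TSV layout
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Tab-separated, no header, at least two columns (extra columns are
#' ignored). The result is canonical: see [make_edge_list()].
#'
#' @inheritParams make_edge_list
#' @param path path to a TSV file.
#' @return canonical edge-list `data.frame`.
#' @export
read_edge_list <- function(path, edge_type = c("mirna_target", "ppi", "lnc_target", "sponge")) {
  edge_type <- match.arg(edge_type)
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (nrow(raw) == 0) {
    return(make_edge_list(character(), character(), edge_type))
  }
  if (ncol(raw) < 2) stop("edge list must have at least 2 tab-separated columns: ", path)
  make_edge_list(raw[[1]], raw[[2]], edge_type)
}

#' Write an edge list as 2-column TSV (no header)
#' @param edges canonical edge-list `data.frame`.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("a", "b"), drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Whitespace is trimmed, empty lines dropped, duplicates collapsed.
#' An empty file yields an empty character vector; callers decide whether
#' that is fatal.
#'
#' @param path path to a text file.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines)])
}

#' Write a gene list, one symbol per line
#' @param symbols character vector.
#' @param path output path.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(unique(as.character(symbols)), path)
  invisible(path)
}

#' Read tumor/normal sample labels
#'
#' Two-column TSV (sample id, label), no header. Labels must be `tumor`
#' or `normal`.
#'
#' @param path path to a TSV file.
#' @return named character vector, names = sample ids, values in
#'   `c("tumor", "normal")`.
#' @export
read_sample_labels <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("sample label file must have 2 tab-separated columns")
  ids <- trimws(raw[[1]])
  lab <- trimws(raw[[2]])
  bad <- setdiff(unique(lab), c("tumor", "normal"))
  if (length(bad)) stop("unknown sample label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(ids)) stop("duplicate sample ids in label file")
  stats::setNames(lab, ids)
}

#' Write sample labels as 2-column TSV
#' @param labels named character vector (values `tumor`/`normal`).
#' @param path output path.
#' @export
write_sample_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), unname(labels)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- typed heterogeneous network ------------------------------------------

NODE_KINDS <- c("lncRNA", "mRNA_protein", "protein")
EDGE_TYPES <- c("sponge", "ppi", "lnc_target")

#' Construct a typed heterogeneous network
#'
#' A typed network carries node kinds (`lncRNA`, `mRNA_protein`, `protein`)
#' and typed undirected edges (`sponge`, `ppi`, `lnc_target`). Type rules
#' are enforced: sponge edges join lncRNA/mRNA_protein nodes; ppi edges
#' join mRNA_protein/protein nodes; lnc_target edges join an lncRNA to an
#' mRNA_protein or protein.
#'
#' @param edges `data.frame` with columns `a`, `b`, `type`.
#' @param kinds named character vector mapping every node symbol to a kind.
#' @return object of class `typed_network`: list with `nodes` (named kind
#'   vector) and `edges` (canonical typed edge `data.frame`).
#' @export
typed_network <- function(edges, kinds) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    edges <- data.frame(a = character(), b = character(), type = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("a", "b", "type") %in% colnames(edges)))
  p <- canonicalize_pairs(edges$a, edges$b)
  edges <- data.frame(a = p$a, b = p$b, type = as.character(edges$type),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$type, pair_key(edges$a, edges$b))), , drop = FALSE]
  edges <- edges[order(edges$type, edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  bad_type <- setdiff(unique(edges$type), EDGE_TYPES)
  if (length(bad_type)) stop("unknown edge type(s): ", paste(bad_type, collapse = ", "))
  used <- unique(c(edges$a, edges$b))
  missing_kind <- setdiff(used, names(kinds))
  if (length(missing_kind)) {
    stop("node(s) without a kind: ", paste(utils::head(missing_kind, 5), collapse = ", "))
  }
  kinds <- kinds[order(names(kinds))]
  bad_kind <- setdiff(unique(kinds), NODE_KINDS)
  if (length(bad_kind)) stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "))

  ka <- kinds[edges$a]
  kb <- kinds[edges$b]
  ok <- rep(TRUE, nrow(edges))
  is_sp <- edges$type == "sponge"
  ok[is_sp] <- ka[is_sp] %in% c("lncRNA", "mRNA_protein") &
    kb[is_sp] %in% c("lncRNA", "mRNA_protein")
  is_ppi <- edges$type == "ppi"
  ok[is_ppi] <- ka[is_ppi] %in% c("mRNA_protein", "protein") &
    kb[is_ppi] %in% c("mRNA_protein", "protein")
  is_lt <- edges$type == "lnc_target"
  ok[is_lt] <- (ka[is_lt] == "lncRNA") != (kb[is_lt] == "lncRNA")
  if (!all(ok)) {
    off <- edges[!ok, , drop = FALSE][1, ]
    stop(sprintf("edge %s-%s of type %s violates node-kind rules (%s, %s)",
                 off$a, off$b, off$type, kinds[off$a], kinds[off$b]))
  }
  structure(list(nodes = kinds, edges = edges), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  cat("typed network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    tab <- table(x$edges$type)
    cat("  edges by type:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  }
  kt <- table(x$nodes)
  cat("  nodes by kind:",
      paste(sprintf("%s=%d", names(kt), as.integer(kt)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a typed network as 3-column TSV
#'
#' Columns `node_a`, `node_b`, `edge_type`, rows in deterministic sorted
#' order; a summary of per-type edge counts is emitted as a message.
#'
#' @param network a `typed_network` or a typed edge `data.frame`
#'   (columns `a`, `b`, `type`).
#' @param path output path.
#' @export
write_network <- function(network, path) {
  edges <- if (inherits(network, "typed_network")) network$edges else network
  out <- data.frame(node_a = edges$a, node_b = edges$b, edge_type = edges$type,
                    stringsAsFactors = FALSE)
  out <- out[order(out$edge_type, out$node_a, out$node_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(out)) {
    tab <- table(out$edge_type)
    message("wrote ", nrow(out), " edges (",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
            ") to ", path)
  } else {
    message("wrote empty network to ", path)
  }
  invisible(path)
}

#' Read a typed edge list written by [write_network()]
#'
#' @param path path to a 3-column TSV with header
#'   `node_a`, `node_b`, `edge_type`.
#' @return canonical typed edge `data.frame` (columns `a`, `b`, `type`).
#' @export
read_network <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("node_a", "node_b", "edge_type") %in% colnames(raw))) {
    stop("network file must have columns node_a, node_b, edge_type")
  }
  edges <- data.frame(a = raw$node_a, b = raw$node_b, type = raw$edge_type,
                      stringsAsFactors = FALSE)
  p <- canonicalize_pairs(edges$a, edges$b)
  edges$a <- p$a
  edges$b <- p$b
  edges <- edges[!duplicated(paste(edges$type, pair_key(edges$a, edges$b))), , drop = FALSE]
  edges <- edges[order(edges$type, edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one place, with the defaults
#' used throughout: candidate sponge pairs must share at least 3 miRNAs
#' with hypergeometric p < 0.01, show regulation-pattern similarity
#' Sim >= 0.5, and be positively correlated at p < 0.01; hubs are the top
#' 10% of nodes by degree; Markov clustering uses inflation 2 / expansion 2
#' with minimum module size 4; module signatures require ACC and AUC both
#' above 0.9 under 10-fold cross-validation; over-representation uses
#' BH-adjusted p < 0.01.
#'
#' @param min_shared_mirnas minimum number of shared miRNAs for a candidate
#'   sponge pair (>= 1).
#' @param hypergeom_alpha significance level for the shared-miRNA test.
#' @param sim_threshold inclusive lower bound on the similarity score Sim.
#' @param corr_alpha significance level for the sponge-pair correlation.
#' @param hub_fraction fraction of top-degree nodes selected as hubs.
#' @param mcl_inflation,mcl_expansion Markov clustering parameters.
#' @param min_module_size smallest module retained after clustering.
#' @param signature_cutoff ACC/AUC cutoff for module signatures (strict).
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param enrichment_alpha BH-adjusted significance level for ORA.
#' @param random_seed seed for stratified fold assignment.
#' @return named list of class `mirscoppi_config`.
#' @export
mirscoppi_config <- function(min_shared_mirnas = 3L,
                             hypergeom_alpha = 0.01,
                             sim_threshold = 0.5,
                             corr_alpha = 0.01,
                             hub_fraction = 0.10,
                             mcl_inflation = 2,
                             mcl_expansion = 2L,
                             min_module_size = 4L,
                             signature_cutoff = 0.9,
                             cv_folds = 10L,
                             enrichment_alpha = 0.01,
                             random_seed = 1L) {
  cfg <- list(min_shared_mirnas = as.integer(min_shared_mirnas),
              hypergeom_alpha = hypergeom_alpha,
              sim_threshold = sim_threshold,
              corr_alpha = corr_alpha,
              hub_fraction = hub_fraction,
              mcl_inflation = mcl_inflation,
              mcl_expansion = as.integer(mcl_expansion),
              min_module_size = as.integer(min_module_size),
              signature_cutoff = signature_cutoff,
              cv_folds = as.integer(cv_folds),
              enrichment_alpha = enrichment_alpha,
              random_seed = as.integer(random_seed))
  for (nm in c("hypergeom_alpha", "corr_alpha", "enrichment_alpha")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) stop(nm, " must be in (0, 1)")
  }
  if (cfg$min_shared_mirnas < 1L) stop("min_shared_mirnas must be >= 1")
  if (cfg$min_module_size < 1L) stop("min_module_size must be >= 1")
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2")
  if (cfg$hub_fraction <= 0 || cfg$hub_fraction > 1) stop("hub_fraction must be in (0, 1]")
  if (cfg$mcl_inflation <= 1) stop("mcl_inflation must be > 1")
  structure(cfg, class = "mirscoppi_config")
}
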