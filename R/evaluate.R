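# Step 3c: module evaluation — SVM classification of tumor vs normal
# samples per module (ACC, AUC, OPI), signature selection, and
# over-representation analysis against user-supplied gene sets.

#' Overall prognostic index
#'
#' The mean of AUC and ACC; used to rank modules by overall classification
#' performance.
#'
#' @param auc,acc values in \[0, 1\].
#' @return `(auc + acc) / 2`.
#' @export
overall_prognostic_index <- function(auc, acc) {
  if (any(auc < 0 | auc > 1) || any(acc < 0 | acc > 1)) {
    stop("auc and acc must lie in [0, 1]")
  }
  (auc + acc) / 2
}

# AUC via the rank (Mann-Whitney) formulation: probability that a random
# positive scores above a random negative, with ties counted 1/2.
#' @keywords internal
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# seeded stratified fold assignment: within each class, samples are
# permuted and folds dealt round-robin
#' @keywords internal
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated SVM evaluation of one module
#'
#' Features are the expression rows of the module's measured genes
#' (protein-only members without expression are dropped with a warning),
#' samples are observations. A radial-basis-kernel SVM with canonical
#' defaults (cost 1, kernel width 1/feature-count) is trained on each of
#' `folds` stratified folds, with features standardized to zero mean and
#' unit variance using training-fold statistics only. ACC is the pooled
#' out-of-fold correct fraction; AUC is computed from the pooled
#' out-of-fold decision values via the rank (Mann-Whitney) formulation,
#' with `tumor` as the positive class; OPI is their mean.
#'
#' @param module_genes character vector of module member symbols.
#' @param expr expression matrix (genes x samples) covering the labeled
#'   samples.
#' @param labels named `tumor`/`normal` vector (see
#'   [read_sample_labels()]); every labeled sample must be a column of
#'   `expr`.
#' @param folds number of cross-validation folds.
#' @param seed seed for the stratified fold assignment.
#' @param signature_cutoff strict cutoff that both ACC and AUC must exceed
#'   for the module to be flagged as a signature.
#' @return list with `size` (usable genes), `auc`, `acc`, `opi`,
#'   `is_signature`, `seed`, and the pooled out-of-fold `decision_values`.
#' @export
evaluate_module <- function(module_genes, expr, labels, folds = 10L, seed = 1L,
                            signature_cutoff = 0.9) {
  genes <- intersect(unique(module_genes), rownames(expr))
  missing <- setdiff(unique(module_genes), genes)
  if (length(missing)) {
    warning(length(missing), " module gene(s) without expression dropped")
  }
  if (length(genes) < 2) stop("need at least 2 module genes with expression")
  samples <- names(labels)
  if (!all(samples %in% colnames(expr))) {
    stop("labeled sample(s) missing from the expression matrix")
  }
  y <- factor(unname(labels[samples]), levels = c("normal", "tumor"))
  if (any(table(y) < folds)) stop("each class needs at least `folds` samples")
  X <- t(expr[genes, samples, drop = FALSE])
  fold <- stratified_folds(y, folds, seed)
  dv <- numeric(length(y))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdev[sdev == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = "radial", cost = 1,
                      gamma = 1 / ncol(X), scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    d <- attr(pr, "decision.values")
    # decision values are positive for the class named first in the column
    # label "first/second"; orient so that higher means tumor
    pos_class <- strsplit(colnames(d)[1], "/", fixed = TRUE)[[1]][1]
    d <- as.numeric(d)
    if (pos_class != "tumor") d <- -d
    dv[!tr] <- d
    pred[!tr] <- pr
  }
  acc <- mean(pred == y)
  auc <- rank_auc(dv, y == "tumor")
  opi <- overall_prognostic_index(auc, acc)
  list(size = length(genes), auc = auc, acc = acc, opi = opi,
       is_signature = acc > signature_cutoff && auc > signature_cutoff,
       seed = seed, decision_values = stats::setNames(dv, samples))
}

#' Rank module scores and flag signatures
#'
#' Scores are sorted by OPI descending (ties by module size descending,
#' then module id); a module is a signature when both ACC and AUC strictly
#' exceed `cutoff`.
#'
#' @param scores `data.frame` with columns `module_id`, `size`, `auc`,
#'   `acc` (an `opi` column is recomputed).
#' @param cutoff signature cutoff applied to both ACC and AUC.
#' @return the scores `data.frame` with `opi`, `is_signature` and `rank`
#'   columns, sorted by rank.
#' @export
rank_and_select_signatures <- function(scores, cutoff = 0.9) {
  if (!nrow(scores)) stop("no module scores supplied")
  scores$opi <- overall_prognostic_index(scores$auc, scores$acc)
  scores$is_signature <- scores$acc > cutoff & scores$auc > cutoff
  ord <- order(-scores$opi, -scores$size, scores$module_id)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Over-representation analysis of a module against gene sets
#'
#' For each gene set, the overlap with the module is tested with the same
#' upper-tail hypergeometric as the shared-miRNA test; p-values are
#' Benjamini-Hochberg adjusted across all tested sets and the sets with
#' adjusted p below `alpha` are returned, sorted by adjusted p.
#'
#' @param module_genes character vector, a subset of `universe`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the universe.
#' @param universe character vector of background genes.
#' @param alpha BH-adjusted significance cutoff.
#' @return `data.frame` with columns `term_id`, `overlap`, `term_size`,
#'   `module_size`, `universe`, `p`, `p_adjusted`.
#' @export
ora_enrichment <- function(module_genes, gene_sets, universe, alpha = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  module_genes <- intersect(unique(module_genes), universe)
  n_mod <- length(module_genes)
  n_uni <- length(universe)
  res <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    x <- length(intersect(module_genes, set))
    p <- shared_mirna_pvalue(n_uni, length(set), n_mod, x)
    data.frame(term_id = term, overlap = x, term_size = length(set),
               module_size = n_mod, universe = n_uni, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(term_id = character(), overlap = integer(),
                      term_size = integer(), module_size = integer(),
                      universe = integer(), p = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  }
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$p_adjusted < alpha, , drop = FALSE]
  res <- res[order(res$p_adjusted, res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: term id, description, then member symbols.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; descriptions attached as the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}
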