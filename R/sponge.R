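# Step 1: inference of the disease-related miRNA sponge interaction network.
#
# Two ceRNAs (lncRNAs or mRNAs) are accepted as a sponge pair when
#   (i)   both are in the disease gene list,
#   (ii)  they share >= min_shared_mirnas validated miRNA regulators and the
#         sharing is hypergeometrically significant (p < hypergeom_alpha),
#   (iii) their miRNA regulation patterns are similar: Sim >= sim_threshold,
#         where Sim is the mean of a cosine score on the signed miRNA-ceRNA
#         correlations and a collaboration score on their absolute values,
#   (iv)  their expression profiles are positively correlated
#         (r > 0, p < corr_alpha).

#' Pearson correlation with exact t-based p-value
#'
#' The two-sided p-value comes from t = r * sqrt((n - 2) / (1 - r^2)) on
#' n - 2 degrees of freedom; perfectly correlated vectors yield p = 0.
#'
#' @param x,y numeric vectors of equal length n >= 3, neither constant.
#' @return list with elements `r` and `p`.
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Upper-tail hypergeometric p-value for miRNA sharing
#'
#' Probability of observing at least `x` shared miRNAs between two ceRNAs
#' regulated by `N` and `K` of the `M` miRNAs in the dataset, under random
#' sampling without replacement:
#' `p = 1 - sum_{i=0}^{x-1} C(N,i) C(M-N,K-i) / C(M,K)`.
#' `x = 0` gives p = 1 (empty sum).
#'
#' @param M total miRNAs in the dataset.
#' @param N,K numbers of miRNAs regulating each ceRNA.
#' @param x number of shared miRNAs, `0 <= x <= min(N, K)`.
#' @return p-value in \[0, 1\].
#' @export
shared_mirna_pvalue <- function(M, N, K, x) {
  if (N > M || K > M) stop("N and K cannot exceed M")
  if (x < 0 || x > min(N, K)) stop("x must satisfy 0 <= x <= min(N, K)")
  if (x == 0) return(1)
  stats::phyper(x - 1, m = N, n = M - N, k = K, lower.tail = FALSE)
}

#' Cosine score of two miRNA-regulation correlation vectors
#'
#' `sum(Ci * Cj) / (sqrt(sum(Ci^2)) * sqrt(sum(Cj^2)))` over the shared
#' miRNAs; a conservative estimate of regulation-pattern similarity, in
#' \[-1, 1\].
#'
#' @param c_i,c_j signed Pearson correlations of each ceRNA with the shared
#'   miRNAs, equal length >= 1.
#' @return cosine score.
#' @export
cosine_score <- function(c_i, c_j) {
  if (length(c_i) != length(c_j)) stop("correlation vectors must have equal length")
  if (length(c_i) < 1) stop("need at least one shared miRNA")
  ni <- sqrt(sum(c_i^2))
  nj <- sqrt(sum(c_j^2))
  if (ni == 0 || nj == 0) stop("cosine score undefined for an all-zero correlation vector")
  sum(c_i * c_j) / (ni * nj)
}

#' Collaboration score of two absolute-correlation vectors
#'
#' `sum(ACi * ACj) / (sqrt(sum(ACi)) * sqrt(sum(ACj)))` — note the
#' denominators are square roots of plain sums (not sums of squares), which
#' makes this a liberal counterpart to the cosine score: for inputs in
#' \[0, 1\] the score stays in \[0, 1\] and rewards uniformly strong shared
#' regulation.
#'
#' @param ac_i,ac_j absolute miRNA-ceRNA correlations in \[0, 1\], equal
#'   length >= 1, each with positive sum.
#' @return collaboration score.
#' @export
collaboration_score <- function(ac_i, ac_j) {
  if (length(ac_i) != length(ac_j)) stop("correlation vectors must have equal length")
  if (length(ac_i) < 1) stop("need at least one shared miRNA")
  if (any(ac_i < 0 | ac_i > 1) || any(ac_j < 0 | ac_j > 1)) {
    stop("absolute correlations must lie in [0, 1]")
  }
  si <- sum(ac_i)
  sj <- sum(ac_j)
  if (si == 0 || sj == 0) stop("collaboration score undefined for a zero-sum vector")
  sum(ac_i * ac_j) / (sqrt(si) * sqrt(sj))
}

#' Similarity score: mean of cosine and collaboration scores
#'
#' @param cos cosine score in \[-1, 1\].
#' @param col collaboration score in \[0, 1\].
#' @return `(cos + col) / 2`.
#' @export
similarity_score <- function(cos, col) {
  if (cos < -1 - 1e-12 || cos > 1 + 1e-12) stop("cos out of [-1, 1]")
  if (col < -1e-12 || col > 1 + 1e-12) stop("col out of [0, 1]")
  (cos + col) / 2
}

#' Build miRNA regulation profiles for ceRNAs
#'
#' For every ceRNA measured in `expr_cerna`, collects the miRNAs that are
#' validated regulators of it (edges in `mirna_targets` whose miRNA
#' endpoint is measured in `expr_mirna`) and the Pearson correlation
#' between each such miRNA and the ceRNA across samples. ceRNAs with no
#' validated measured regulator have no profile. Edges whose endpoints are
#' not one measured miRNA plus one measured ceRNA are ignored.
#'
#' @param expr_mirna miRNA expression matrix (miRNAs x samples).
#' @param expr_cerna ceRNA expression matrix (lncRNAs/mRNAs x samples),
#'   same samples in the same order.
#' @param mirna_targets canonical miRNA-target edge list.
#' @return named list of profiles, one per ceRNA, each a list with
#'   `ceRNA`, `regulators` (miRNA symbols) and `correlations` (named
#'   numeric). The total miRNA count of the dataset is attached as
#'   attribute `n_mirna`.
#' @export
build_regulation_profiles <- function(expr_mirna, expr_cerna, mirna_targets) {
  if (!identical(colnames(expr_mirna), colnames(expr_cerna))) {
    stop("miRNA and ceRNA expression matrices must share the same samples in order")
  }
  mir_ids <- rownames(expr_mirna)
  ce_ids <- rownames(expr_cerna)
  a_mir <- mirna_targets$a %in% mir_ids
  b_mir <- mirna_targets$b %in% mir_ids
  a_ce <- mirna_targets$a %in% ce_ids
  b_ce <- mirna_targets$b %in% ce_ids
  keep <- (a_mir & b_ce & !b_mir) | (b_mir & a_ce & !a_mir)
  mirs <- ifelse(a_mir[keep], mirna_targets$a[keep], mirna_targets$b[keep])
  ces <- ifelse(a_mir[keep], mirna_targets$b[keep], mirna_targets$a[keep])
  if (!length(mirs)) {
    warning("no miRNA-target edges overlap the expression matrices")
    return(structure(list(), n_mirna = length(mir_ids)))
  }
  cormat <- stats::cor(t(expr_mirna), t(expr_cerna))  # miRNAs x ceRNAs
  profiles <- lapply(split(mirs, ces), function(regs) {
    regs <- sort(unique(regs))
    regs
  })
  profiles <- lapply(names(profiles), function(ce) {
    regs <- profiles[[ce]]
    list(ceRNA = ce,
         regulators = regs,
         correlations = stats::setNames(cormat[regs, ce], regs))
  })
  names(profiles) <- vapply(profiles, `[[`, "", "ceRNA")
  structure(profiles[order(names(profiles))], n_mirna = length(mir_ids))
}

#' Infer the disease-related miRNA sponge interaction network
#'
#' Applies the four sponge conditions to every pair of profiled ceRNAs
#' that shares at least `min_shared_mirnas` validated regulators.
#' All scored pairs are returned as an audit table with per-condition
#' flags; the accepted pairs (all four flags true) form the sponge edge
#' list. Pairs whose cosine or collaboration score is undefined (an
#' all-zero correlation vector) are retained with a rejection note, never
#' silently dropped.
#'
#' To disable the disease-membership condition (e.g. to infer generalized
#' sponge interactions), pass the full ceRNA universe as `disease_genes`.
#'
#' @param profiles output of [build_regulation_profiles()].
#' @param expr_cerna ceRNA expression matrix (used for the pairwise
#'   ceRNA-ceRNA correlation of condition iv).
#' @param disease_genes character vector of disease gene/lncRNA symbols.
#' @param config a [mirscoppi_config()].
#' @return list with `network` (canonical sponge edge `data.frame`) and
#'   `candidates` (audit `data.frame`: one row per scored pair with
#'   shared-miRNA statistics, scores, correlation and per-condition flags).
#' @export
infer_sponge_network <- function(profiles, expr_cerna, disease_genes,
                                 config = mirscoppi_config()) {
  if (!length(profiles)) stop("no regulation profiles supplied")
  if (!length(disease_genes)) stop("disease gene list is empty")
  M <- attr(profiles, "n_mirna")
  ids <- names(profiles)
  n_reg <- vapply(profiles, function(p) length(p$regulators), 0L)
  eligible <- ids[n_reg >= config$min_shared_mirnas]

  rows <- list()
  if (length(eligible) >= 2) {
    for (ii in seq_len(length(eligible) - 1)) {
      gi <- eligible[ii]
      pi_ <- profiles[[gi]]
      for (jj in seq((ii + 1), length(eligible))) {
        gj <- eligible[jj]
        pj <- profiles[[gj]]
        shared <- intersect(pi_$regulators, pj$regulators)
        x <- length(shared)
        if (x < config$min_shared_mirnas) next
        ci <- pi_$correlations[shared]
        cj <- pj$correlations[shared]
        p_share <- shared_mirna_pvalue(M, length(pi_$regulators), length(pj$regulators), x)
        note <- ""
        if (all(ci == 0) || all(cj == 0)) {
          cos <- NA_real_; col <- NA_real_; sim <- NA_real_
          note <- "undefined cosine/collaboration score (all-zero correlations)"
        } else {
          cos <- cosine_score(ci, cj)
          col <- collaboration_score(abs(ci), abs(cj))
          sim <- similarity_score(cos, col)
        }
        ct <- pearson_with_pvalue(expr_cerna[gi, ], expr_cerna[gj, ])
        f_disease <- (gi %in% disease_genes) && (gj %in% disease_genes)
        f_sharing <- p_share < config$hypergeom_alpha
        f_pattern <- !is.na(sim) && sim >= config$sim_threshold
        f_corr <- ct$r > 0 && ct$p < config$corr_alpha
        a <- min(gi, gj); b <- max(gi, gj)
        rows[[length(rows) + 1L]] <- data.frame(
          ceRNA_i = a, ceRNA_j = b,
          shared_mirnas = paste(sort(shared), collapse = ","),
          M = M, N = length(pi_$regulators), K = length(pj$regulators), x = x,
          p_share = p_share, cos = cos, col = col, sim = sim,
          corr = ct$r, corr_p = ct$p,
          disease = f_disease, sharing = f_sharing, pattern = f_pattern,
          positive_corr = f_corr,
          accepted = f_disease && f_sharing && f_pattern && f_corr,
          note = note, stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ceRNA_i = character(), ceRNA_j = character(),
               shared_mirnas = character(), M = integer(), N = integer(),
               K = integer(), x = integer(), p_share = numeric(),
               cos = numeric(), col = numeric(), sim = numeric(),
               corr = numeric(), corr_p = numeric(), disease = logical(),
               sharing = logical(), pattern = logical(),
               positive_corr = logical(), accepted = logical(),
               note = character(), stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$ceRNA_i, candidates$ceRNA_j), , drop = FALSE]
  rownames(candidates) <- NULL
  acc <- candidates[candidates$accepted, , drop = FALSE]
  network <- make_edge_list(acc$ceRNA_i, acc$ceRNA_j, "sponge")
  list(network = network, candidates = candidates)
}
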