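# Seeded synthetic-data generator with planted ground truth.
#
# The generator emulates the statistical structure the inference assumes:
# planted sponge pairs are negatively co-regulated by a disjoint block of
# shared miRNAs (so both partners carry strong, similar miRNA correlations
# and are positively correlated with each other), background ceRNAs carry
# at most 2 random regulators and independent expression, and a protein
# layer wires every planted pair into at least one motif of each type.

#' Generate a complete synthetic input bundle with ground truth
#'
#' miRNA expression is i.i.d. standard normal. Each planted sponge pair
#' (A, B) shares `shared_per_pair` dedicated miRNAs (regulator blocks of
#' distinct pairs are disjoint) and gets
#' `expr = -reg_strength * sum(shared miRNAs) + N(0, noise_sd^2)` noise,
#' inducing significant sharing, a similar regulation pattern and positive
#' mutual correlation. Planted pair members alternate between
#' lncRNA-lncRNA, lncRNA-mRNA and mRNA-mRNA pairs. The PPI layer wires
#' each planted pair into one type-A motif (two partner proteins in a PPI)
#' and one type-B motif (a shared protein with a PPI partner), plus random
#' background PPIs. Tumor samples of each differential gene set are
#' mean-shifted by `+delta`. Identical seeds give bit-identical bundles.
#'
#' @param n_mirna,n_lncrna,n_mrna gene counts per species.
#' @param n_tumor,n_normal sample counts per class.
#' @param n_pairs number of planted sponge pairs.
#' @param shared_per_pair shared miRNAs per planted pair (>= 3).
#' @param reg_strength regulation weight of each shared miRNA (> 0).
#' @param noise_sd standard deviation of the additive expression noise.
#' @param delta tumor-vs-normal mean shift applied to differential module
#'   genes.
#' @param n_diff_modules number of planted differential gene sets (built
#'   from consecutive planted pairs, 3 pairs each).
#' @param n_decoy_disease background genes added to the disease list.
#' @param n_background_ppi random extra PPI edges among proteins.
#' @param seed integer seed.
#' @return list with `data` (all pipeline inputs: `mirna_expr`,
#'   `lncrna_expr`, `mrna_expr`, `mirna_targets`, `ppi`, `lnc_targets`,
#'   `disease_genes`, `lncrna_ids`, `labels`) and `truth`
#'   (`planted_pairs`, `planted_regulators`, `planted_motifs`,
#'   `differential_modules`).
#' @export
simulate_sponge_data <- function(n_mirna = 100L, n_lncrna = 30L, n_mrna = 120L,
                                 n_tumor = 72L, n_normal = 72L, n_pairs = 20L,
                                 shared_per_pair = 4L, reg_strength = 1,
                                 noise_sd = 0.3, delta = 2,
                                 n_diff_modules = 1L, n_decoy_disease = 30L,
                                 n_background_ppi = 60L, seed = 1L) {
  if (shared_per_pair < 3L) stop("shared_per_pair must be >= 3")
  if (reg_strength <= 0) stop("reg_strength must be > 0")
  if (n_pairs * shared_per_pair > n_mirna) {
    stop("infeasible configuration: ", n_pairs, " pairs x ", shared_per_pair,
         " shared miRNAs need more miRNAs than n_mirna = ", n_mirna)
  }
  pair_kinds <- rep_len(c("ll", "lm", "mm"), n_pairs)
  need_lnc <- sum((pair_kinds == "ll") * 2L + (pair_kinds == "lm"))
  need_mrna <- sum((pair_kinds == "mm") * 2L + (pair_kinds == "lm"))
  if (need_lnc > n_lncrna || need_mrna > n_mrna) {
    stop("infeasible configuration: planted pairs do not fit in the gene counts")
  }
  set.seed(seed)
  n_samp <- n_tumor + n_normal
  sample_ids <- c(sprintf("TUM%03d", seq_len(n_tumor)),
                  sprintf("NOR%03d", seq_len(n_normal)))
  labels <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), sample_ids)
  mir_ids <- sprintf("miR%03d", seq_len(n_mirna))
  lnc_ids <- sprintf("LNC%03d", seq_len(n_lncrna))
  mrna_ids <- sprintf("GENE%03d", seq_len(n_mrna))

  mirna_expr <- matrix(stats::rnorm(n_mirna * n_samp), n_mirna, n_samp,
                       dimnames = list(mir_ids, sample_ids))
  lnc_expr <- matrix(stats::rnorm(n_lncrna * n_samp), n_lncrna, n_samp,
                     dimnames = list(lnc_ids, sample_ids))
  mrna_expr <- matrix(stats::rnorm(n_mrna * n_samp), n_mrna, n_samp,
                      dimnames = list(mrna_ids, sample_ids))

  # planted pairs: consume lncRNA/mRNA symbols from the front of each pool
  next_lnc <- 1L
  next_mrna <- 1L
  take <- function(kind) {
    if (kind == "l") {
      sym <- lnc_ids[next_lnc]
      next_lnc <<- next_lnc + 1L
    } else {
      sym <- mrna_ids[next_mrna]
      next_mrna <<- next_mrna + 1L
    }
    sym
  }
  planted_pairs <- data.frame(a = character(n_pairs), b = character(n_pairs),
                              stringsAsFactors = FALSE)
  planted_regulators <- list()
  target_a <- character()
  target_b <- character()
  set_expr <- function(sym, values) {
    if (sym %in% lnc_ids) lnc_expr[sym, ] <<- values else mrna_expr[sym, ] <<- values
  }
  for (i in seq_len(n_pairs)) {
    kinds <- strsplit(pair_kinds[i], "")[[1]]
    ga <- take(kinds[1])
    gb <- take(kinds[2])
    regs <- mir_ids[((i - 1L) * shared_per_pair + 1L):(i * shared_per_pair)]
    base <- -reg_strength * colSums(mirna_expr[regs, , drop = FALSE])
    set_expr(ga, base + stats::rnorm(n_samp, 0, noise_sd))
    set_expr(gb, base + stats::rnorm(n_samp, 0, noise_sd))
    p <- canonicalize_pairs(ga, gb)
    planted_pairs$a[i] <- p$a
    planted_pairs$b[i] <- p$b
    planted_regulators[[p$a]] <- union(planted_regulators[[p$a]], regs)
    planted_regulators[[p$b]] <- union(planted_regulators[[p$b]], regs)
    target_a <- c(target_a, rep(regs, 2L))
    target_b <- c(target_b, rep(c(ga, gb), each = shared_per_pair))
  }
  planted_genes <- unique(c(planted_pairs$a, planted_pairs$b))

  # background ceRNAs: up to 2 random regulators each, independent expression
  background <- setdiff(c(lnc_ids, mrna_ids), planted_genes)
  for (g in background) {
    k <- sample(0:2, 1L)
    if (k > 0) {
      regs <- sample(mir_ids, k)
      target_a <- c(target_a, regs)
      target_b <- c(target_b, rep(g, k))
    }
  }
  mirna_targets <- make_edge_list(target_a, target_b, "mirna_target")

  # disease list: planted sponges plus background decoys
  decoys <- sample(background, min(n_decoy_disease, length(background)))
  disease_genes <- sort(unique(c(planted_genes, decoys)))

  # protein layer: one type-A and one type-B motif per planted pair
  prot <- function(tag, i) sprintf("PROT_%s%03d", tag, i)
  ppi_a <- character()
  ppi_b <- character()
  lt_a <- character()
  lt_b <- character()
  add_link <- function(sponge, protein) {
    if (sponge %in% lnc_ids) {
      lt_a <<- c(lt_a, sponge)
      lt_b <<- c(lt_b, protein)
    } else {
      ppi_a <<- c(ppi_a, sponge)
      ppi_b <<- c(ppi_b, protein)
    }
  }
  motif_rows <- list()
  for (i in seq_len(n_pairs)) {
    s1 <- planted_pairs$a[i]
    s2 <- planted_pairs$b[i]
    pa <- prot("A", i)
    pb <- prot("B", i)
    ps <- prot("S", i)
    pq <- prot("Q", i)
    add_link(s1, pa)
    add_link(s2, pb)
    ppi_a <- c(ppi_a, pa)
    ppi_b <- c(ppi_b, pb)
    add_link(s1, ps)
    add_link(s2, ps)
    ppi_a <- c(ppi_a, ps)
    ppi_b <- c(ppi_b, pq)
    motif_rows[[length(motif_rows) + 1L]] <-
      data.frame(motif_type = "A", s1 = s1, s2 = s2, p1 = pa, p2 = pb,
                 stringsAsFactors = FALSE)
    motif_rows[[length(motif_rows) + 1L]] <-
      data.frame(motif_type = "B", s1 = s1, s2 = s2, p1 = ps, p2 = pq,
                 stringsAsFactors = FALSE)
  }
  proteins <- unique(c(ppi_a, ppi_b))
  proteins <- proteins[startsWith(proteins, "PROT_")]
  if (n_background_ppi > 0 && length(proteins) >= 2) {
    pa_idx <- sample(proteins, n_background_ppi, replace = TRUE)
    pb_idx <- sample(proteins, n_background_ppi, replace = TRUE)
    ppi_a <- c(ppi_a, pa_idx)
    ppi_b <- c(ppi_b, pb_idx)
  }
  ppi <- make_edge_list(ppi_a, ppi_b, "ppi")
  lnc_targets <- make_edge_list(lt_a, lt_b, "lnc_target")
  planted_motifs <- do.call(rbind, motif_rows)

  # differential modules: tumor mean shift on blocks of 3 consecutive pairs
  differential_modules <- list()
  if (n_diff_modules > 0) {
    for (m in seq_len(n_diff_modules)) {
      pair_idx <- ((m - 1L) * 3L + 1L):min(m * 3L, n_pairs)
      genes <- unique(c(planted_pairs$a[pair_idx], planted_pairs$b[pair_idx]))
      for (g in genes) {
        if (g %in% lnc_ids) {
          lnc_expr[g, labels == "tumor"] <- lnc_expr[g, labels == "tumor"] + delta
        } else {
          mrna_expr[g, labels == "tumor"] <- mrna_expr[g, labels == "tumor"] + delta
        }
      }
      differential_modules[[m]] <- list(genes = genes, delta = delta)
    }
  }

  list(data = list(mirna_expr = mirna_expr,
                   lncrna_expr = lnc_expr,
                   mrna_expr = mrna_expr,
                   mirna_targets = mirna_targets,
                   ppi = ppi,
                   lnc_targets = lnc_targets,
                   disease_genes = disease_genes,
                   lncrna_ids = lnc_ids,
                   labels = labels),
       truth = list(planted_pairs = planted_pairs,
                    planted_regulators = planted_regulators,
                    planted_motifs = planted_motifs,
                    differential_modules = differential_modules))
}

#' Precision and recall of inferred sponge edges against planted truth
#'
#' @param inferred canonical sponge edge `data.frame` (columns `a`, `b`) or
#'   a [typed_network()] whose sponge edges are compared.
#' @param truth the `truth` element of [simulate_sponge_data()] output (or
#'   any `data.frame` with columns `a`, `b`).
#' @return list with `precision`, `recall`, `tp`, `n_inferred`,
#'   `n_planted`; `precision` is `NA` (flagged via `empty_inferred`) when
#'   nothing was inferred.
#' @export
truth_comparison <- function(inferred, truth) {
  edges <- if (inherits(inferred, "typed_network")) {
    inferred$edges[inferred$edges$type == "sponge", , drop = FALSE]
  } else {
    inferred
  }
  planted <- if (is.data.frame(truth)) truth else truth$planted_pairs
  ikey <- unique(pair_key(edges$a, edges$b))
  pkey <- unique(pair_key(planted$a, planted$b))
  tp <- length(intersect(ikey, pkey))
  list(precision = if (length(ikey)) tp / length(ikey) else NA_real_,
       recall = if (length(pkey)) tp / length(pkey) else NA_real_,
       tp = tp, n_inferred = length(ikey), n_planted = length(pkey),
       empty_inferred = length(ikey) == 0)
}

#' Write a simulated bundle to disk in the package's file formats
#'
#' @param bundle output of [simulate_sponge_data()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- bundle$data
  paths <- c(
    mirna_expr = write_expression_matrix(d$mirna_expr, file.path(dir, "mirna_expr.tsv")),
    lncrna_expr = write_expression_matrix(d$lncrna_expr, file.path(dir, "lncrna_expr.tsv")),
    mrna_expr = write_expression_matrix(d$mrna_expr, file.path(dir, "mrna_expr.tsv")),
    mirna_targets = write_edge_list(d$mirna_targets, file.path(dir, "mirna_targets.tsv")),
    ppi = write_edge_list(d$ppi, file.path(dir, "ppi.tsv")),
    lnc_targets = write_edge_list(d$lnc_targets, file.path(dir, "lnc_targets.tsv")),
    disease_genes = write_gene_list(d$disease_genes, file.path(dir, "disease_genes.txt")),
    lncrna_ids = write_gene_list(d$lncrna_ids, file.path(dir, "lncrna_ids.txt")),
    labels = write_sample_labels(d$labels, file.path(dir, "sample_labels.tsv")))
  paths
}
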