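# separable two-class expression fixture: module genes shifted far apart
separable_fixture <- function(n_genes = 5, n_per_class = 60, shift = 10,
                              seed = 17) {
  set.seed(seed)
  n <- 2 * n_per_class
  ids <- c(sprintf("T%02d", 1:n_per_class), sprintf("N%02d", 1:n_per_class))
  labels <- stats::setNames(rep(c("tumor", "normal"), each = n_per_class), ids)
  expr <- matrix(rnorm(n_genes * n), n_genes, n,
                 dimnames = list(sprintf("g%d", 1:n_genes), ids))
  expr[, labels == "tumor"] <- expr[, labels == "tumor"] + shift
  list(expr = expr, labels = labels)
}

test_that("overall prognostic index is the mean of AUC and ACC", {
  expect_equal(overall_prognostic_index(1, 1), 1)
  expect_equal(round(overall_prognostic_index(0.9993, 0.9861), 4), 0.9927)
  expect_equal(round(overall_prognostic_index(0.9989, 0.9823), 4), 0.9906)
  expect_error(overall_prognostic_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("rank AUC equals trapezoidal ROC integration on pooled scores", {
  trapezoid_auc <- function(scores, positive) {
    ord <- order(scores, decreasing = TRUE)
    pos <- positive[ord]
    # step through distinct thresholds, accumulating trapezoids
    tps <- cumsum(pos)
    fps <- cumsum(!pos)
    keep <- c(diff(scores[ord]) != 0, TRUE)
    tpr <- c(0, tps[keep] / sum(positive))
    fpr <- c(0, fps[keep] / sum(!positive))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    scores <- rnorm(n)
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
    expect_equal(mirscoppi:::rank_auc(scores, pos),
                 trapezoid_auc(scores, pos), tolerance = 1e-12)
  }
})

test_that("a strongly separated module classifies near-perfectly", {
  fx <- separable_fixture()
  ev <- evaluate_module(rownames(fx$expr), fx$expr, fx$labels,
                        folds = 10, seed = 1)
  expect_gte(ev$acc, 0.98)
  expect_gte(ev$auc, 0.98)
  expect_true(ev$is_signature)
  expect_equal(ev$opi, (ev$auc + ev$acc) / 2)
})

test_that("module evaluation validates inputs and drops unmeasured genes", {
  fx <- separable_fixture(n_genes = 3)
  expect_warning(
    ev <- evaluate_module(c(rownames(fx$expr), "ghost"), fx$expr, fx$labels,
                          folds = 5, seed = 1),
    "without expression")
  expect_equal(ev$size, 3)
  expect_error(
    suppressWarnings(evaluate_module(c("g1", "ghost"), fx$expr, fx$labels)),
    "at least 2")
  expect_error(evaluate_module(rownames(fx$expr), fx$expr,
                               fx$labels[1:15], folds = 10),
               "at least")
})

test_that("fold assignment is seeded and stratified", {
  y <- factor(rep(c("normal", "tumor"), c(40, 40)))
  f1 <- mirscoppi:::stratified_folds(y, 10, seed = 3)
  f2 <- mirscoppi:::stratified_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  # each fold holds 4 + 4 samples
  expect_true(all(table(f1, y) == 4))
})

test_that("signature ranking sorts by OPI and requires both metrics above cutoff", {
  scores <- data.frame(module_id = 1:3, size = c(10, 8, 12),
                       auc = c(0.96, 0.999, 0.91),
                       acc = c(0.94, 0.981, 0.89))
  ranked <- rank_and_select_signatures(scores, cutoff = 0.9)
  expect_equal(ranked$module_id, c(2L, 1L, 3L))
  expect_equal(ranked$rank, 1:3)
  expect_equal(ranked$is_signature, c(TRUE, TRUE, FALSE))

  # acc above but auc below the cutoff is not a signature
  one <- rank_and_select_signatures(
    data.frame(module_id = 1L, size = 5, auc = 0.89, acc = 0.95), 0.9)
  expect_false(one$is_signature)

  # signature fraction is a plain count filter
  set.seed(8)
  rs <- data.frame(module_id = 1:17, size = sample(4:30, 17, replace = TRUE),
                   auc = runif(17, 0.85, 1), acc = runif(17, 0.85, 1))
  ranked17 <- rank_and_select_signatures(rs, 0.9)
  expect_equal(sum(ranked17$is_signature),
               sum(rs$auc > 0.9 & rs$acc > 0.9))
})

test_that("ORA matches enumeration oracle and BH behaves", {
  universe <- sprintf("u%03d", 1:100)
  module <- universe[1:10]
  sets <- list(identical = module,
               disjoint = universe[51:70],
               half = universe[6:15])
  res <- ora_enrichment(module, sets, universe, alpha = 2)  # keep all rows
  expect_equal(res$p[res$term_id == "identical"], 1 / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(res$p[res$term_id == "disjoint"], 1)

  # single tested term: BH identity
  one <- ora_enrichment(module, sets["half"], universe, alpha = 1)
  expect_equal(one$p, one$p_adjusted)

  # BH adjusted p-values are non-decreasing in raw-p order
  set.seed(12)
  many <- lapply(1:30, function(i) sample(universe, sample(5:40, 1)))
  names(many) <- sprintf("t%02d", 1:30)
  allres <- ora_enrichment(module, many, universe, alpha = 1)
  ord <- order(allres$p)
  expect_true(all(diff(allres$p_adjusted[ord]) >= -1e-12))
  expect_error(ora_enrichment(module, sets, character()), "empty universe")
})

test_that("GMT files parse into named gene sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tfirst set\tA\tB\tC",
               "SET2\tsecond set\tB\tD"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("SET1", "SET2"))
  expect_equal(sets$SET2, c("B", "D"))
  expect_equal(unname(attr(sets, "descriptions")["SET1"]), "first set")
})
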