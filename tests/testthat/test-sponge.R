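test_that("pearson_with_pvalue matches hand-computed values", {
  r <- pearson_with_pvalue(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$r, 1)
  expect_equal(r$p, 0)

  r2 <- pearson_with_pvalue(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r2$r, 0.6)

  r3 <- pearson_with_pvalue(1:5, -(1:5))
  expect_equal(r3$r, -1)
  expect_equal(r3$p, 0)

  expect_error(pearson_with_pvalue(1:4, 1:3), "equal length")
  expect_error(pearson_with_pvalue(c(1, 1, 1), 1:3), "constant")
})

test_that("shared-miRNA p-value matches its closed forms and enumeration", {
  expect_equal(shared_mirna_pvalue(10, 5, 5, 0), 1)
  expect_equal(shared_mirna_pvalue(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(shared_mirna_pvalue(4, 2, 2, 1), 5 / 6, tolerance = 1e-12)
  expect_error(shared_mirna_pvalue(4, 5, 2, 1), "exceed M")
  expect_error(shared_mirna_pvalue(10, 5, 5, 6), "min\\(N, K\\)")

  for (M in c(4, 7, 9)) {
    for (N in 0:M) for (K in 0:M) for (x in 0:min(N, K)) {
      expect_equal(shared_mirna_pvalue(M, N, K, x),
                   hyper_enum_oracle(M, N, K, x), tolerance = 1e-12)
    }
  }
})

test_that("shared-miRNA p-value is non-increasing in the overlap", {
  for (seed in 1:20) {
    set.seed(seed)
    M <- sample(5:40, 1)
    N <- sample(1:M, 1)
    K <- sample(1:M, 1)
    ps <- vapply(0:min(N, K), function(x) shared_mirna_pvalue(M, N, K, x), 0)
    expect_true(all(diff(ps) <= 1e-14))
  }
})

test_that("cosine and collaboration scores match their formulas", {
  expect_equal(cosine_score(c(0.3, -0.7), c(0.3, -0.7)), 1)
  expect_equal(cosine_score(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_score(c(0.6, 0.8), c(0.8, 0.6)), 0.96)
  expect_error(cosine_score(c(0, 0), c(1, 1)), "all-zero")

  expect_equal(collaboration_score(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(collaboration_score(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(collaboration_score(c(1, 1, 1), c(0.25, 0.25, 0.25)), 0.5)
  expect_error(collaboration_score(c(0, 0), c(1, 1)), "zero-sum")
  expect_error(collaboration_score(c(2, 1), c(1, 1)), "\\[0, 1\\]")

  expect_equal(similarity_score(1, 1), 1)
  expect_equal(similarity_score(0.96, 0.5), 0.73)
  expect_equal(similarity_score(-1, 0), -0.5)
})

test_that("score bounds hold on random correlation vectors", {
  set.seed(3)
  for (i in 1:1000) {
    m <- sample(1:8, 1)
    ci <- runif(m, -1, 1)
    cj <- runif(m, -1, 1)
    if (all(ci == 0) || all(cj == 0)) next
    cos <- cosine_score(ci, cj)
    col <- collaboration_score(abs(ci), abs(cj))
    expect_gte(cos, -1 - 1e-12)
    expect_lte(cos, 1 + 1e-12)
    expect_gte(col, 0)
    expect_lte(col, 1 + 1e-12)
  }
})

test_that("regulation profiles recover planted regulator sets", {
  fx <- sponge_inference_fixture()
  prof <- build_regulation_profiles(fx$mirna, fx$cerna, fx$targets)
  expect_equal(attr(prof, "n_mirna"), 10L)
  expect_equal(prof[["A"]]$regulators, c("m01", "m02", "m03"))
  expect_equal(prof[["C"]]$regulators, c("m04", "m05"))
  expect_length(prof[["A"]]$correlations, 3)
  # ceRNA with no validated measured miRNA has no profile
  expect_false("Z" %in% names(prof))
  # profile correlations agree with direct computation
  expect_equal(unname(prof[["A"]]$correlations["m01"]),
               cor(fx$mirna["m01", ], fx$cerna["A", ]))
})

test_that("sponge inference applies the four conditions", {
  fx <- sponge_inference_fixture()
  prof <- build_regulation_profiles(fx$mirna, fx$cerna, fx$targets)
  cfg <- mirscoppi_config()
  res <- infer_sponge_network(prof, fx$cerna, disease_genes = fx$genes, cfg)
  # only A-B shares >= 3 miRNAs, so it is the only candidate and only edge
  expect_equal(nrow(res$candidates), 1L)
  expect_equal(res$network$a, "A")
  expect_equal(res$network$b, "B")
  expect_true(all(res$candidates[, c("disease", "sharing", "pattern", "positive_corr")]))

  # brute-force check of all four conditions over all profiled pairs
  ids <- names(prof)
  expected <- character()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    gi <- ids[i]; gj <- ids[j]
    shared <- intersect(prof[[gi]]$regulators, prof[[gj]]$regulators)
    if (length(shared) < 3) next
    p <- shared_mirna_pvalue(10, length(prof[[gi]]$regulators),
                             length(prof[[gj]]$regulators), length(shared))
    ci <- prof[[gi]]$correlations[shared]
    cj <- prof[[gj]]$correlations[shared]
    sim <- (cosine_score(ci, cj) + collaboration_score(abs(ci), abs(cj))) / 2
    ct <- cor.test(fx$cerna[gi, ], fx$cerna[gj, ])
    if (p < 0.01 && sim >= 0.5 && ct$estimate > 0 && ct$p.value < 0.01) {
      expected <- c(expected, paste(gi, gj))
    }
  }
  expect_setequal(paste(res$network$a, res$network$b), expected)

  # excluding a partner from the disease list rejects the edge, flags it
  res2 <- infer_sponge_network(prof, fx$cerna, disease_genes = setdiff(fx$genes, "B"), cfg)
  expect_equal(nrow(res2$network), 0L)
  expect_false(res2$candidates$disease[1])
  expect_false(res2$candidates$accepted[1])
  expect_true(res2$candidates$sharing[1])  # other conditions still recorded
})

test_that("accepted edge set is monotone in the thresholds", {
  b <- simulate_sponge_data(n_pairs = 8, n_lncrna = 12, n_mrna = 30,
                            n_mirna = 40, noise_sd = 0.8, seed = 5)
  prof <- build_regulation_profiles(b$data$mirna_expr,
                                    rbind(b$data$lncrna_expr, b$data$mrna_expr),
                                    b$data$mirna_targets)
  cerna <- rbind(b$data$lncrna_expr, b$data$mrna_expr)
  base <- infer_sponge_network(prof, cerna, b$data$disease_genes, mirscoppi_config())
  key <- function(res) paste(res$network$a, res$network$b)
  stricter <- list(
    mirscoppi_config(sim_threshold = 0.8),
    mirscoppi_config(hypergeom_alpha = 1e-6),
    mirscoppi_config(corr_alpha = 1e-6))
  for (cfg in stricter) {
    res <- infer_sponge_network(prof, cerna, b$data$disease_genes, cfg)
    expect_true(all(key(res) %in% key(base)))
  }
})
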