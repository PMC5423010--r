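test_that("layer integration assigns kinds and merges shared symbols", {
  sponge <- make_edge_list(c("L1", "G1"), c("G1", "G2"), "sponge")
  ppi <- make_edge_list(c("G1", "P1"), c("P1", "P2"), "ppi")
  lnc_t <- make_edge_list("L1", "P2", "lnc_target")
  net <- integrate_networks(sponge, ppi, lnc_t, lncrna_ids = "L1")
  expect_equal(unname(net$nodes["L1"]), "lncRNA")
  expect_equal(unname(net$nodes["G1"]), "mRNA_protein")  # sponge + PPI, one node
  expect_equal(unname(net$nodes["G2"]), "mRNA_protein")
  expect_equal(unname(net$nodes["P1"]), "protein")
  expect_equal(nrow(net$edges), 5L)
  expect_equal(length(net$nodes), 5L)
  # G1 carries both sponge and ppi edges
  g1 <- net$edges[net$edges$a == "G1" | net$edges$b == "G1", ]
  expect_setequal(unique(g1$type), c("sponge", "ppi"))
})

test_that("disjoint layers keep additive edge counts", {
  sponge <- make_edge_list(c("S1", "S3"), c("S2", "S4"), "sponge")
  ppi <- make_edge_list(c("P1", "P3", "P5"), c("P2", "P4", "P6"), "ppi")
  lnc_t <- make_edge_list("L1", "T1", "lnc_target")
  net <- integrate_networks(sponge, ppi, lnc_t, lncrna_ids = "L1")
  expect_equal(nrow(net$edges), 2 + 3 + 1)
  expect_equal(sum(net$nodes == "protein"), 7)  # 6 PPI-only + T1
})

test_that("lncRNA appearing as a PPI endpoint is a type conflict", {
  sponge <- make_edge_list("L1", "G1", "sponge")
  ppi <- make_edge_list("L1", "P1", "ppi")
  expect_error(
    integrate_networks(sponge, ppi,
                       make_edge_list(character(), character(), "lnc_target"),
                       lncrna_ids = "L1"),
    "type|conflict|lncRNA")
})

test_that("single type-A and type-B motifs are found exactly once", {
  kinds <- c(s1 = "lncRNA", s2 = "lncRNA", p1 = "protein", p2 = "protein")
  netA <- typed_network(
    data.frame(a = c("s1", "s1", "s2", "p1"),
               b = c("s2", "p1", "p2", "p2"),
               type = c("sponge", "lnc_target", "lnc_target", "ppi")),
    kinds)
  mA <- enumerate_motifs(netA)
  expect_equal(nrow(mA), 1L)
  expect_equal(mA$motif_type, "A")
  expect_equal(unlist(mA[1, -1], use.names = FALSE), c("s1", "s2", "p1", "p2"))
  expect_equal(motif_key(brute_force_motifs(netA)), motif_key(mA))

  kindsB <- c(s1 = "lncRNA", s2 = "lncRNA", p = "protein", q = "protein")
  netB <- typed_network(
    data.frame(a = c("s1", "s1", "s2", "p"),
               b = c("s2", "p", "p", "q"),
               type = c("sponge", "lnc_target", "lnc_target", "ppi")),
    kindsB)
  mB <- enumerate_motifs(netB)
  expect_equal(nrow(mB), 1L)
  expect_equal(mB$motif_type, "B")
  expect_equal(unlist(mB[1, -1], use.names = FALSE), c("s1", "s2", "p", "q"))
  expect_equal(motif_key(brute_force_motifs(netB)), motif_key(mB))
})

test_that("no PPI edges means no motifs of either type", {
  kinds <- c(s1 = "lncRNA", s2 = "lncRNA", p1 = "protein", p2 = "protein")
  net <- typed_network(
    data.frame(a = c("s1", "s1", "s2"),
               b = c("s2", "p1", "p2"),
               type = c("sponge", "lnc_target", "lnc_target")),
    kinds)
  expect_equal(nrow(enumerate_motifs(net)), 0L)
})

test_that("mRNA sponges link through their own PPI edges", {
  # both sponges are mRNAs: links are ppi edges, 4 distinct nodes required
  kinds <- c(g1 = "mRNA_protein", g2 = "mRNA_protein",
             p1 = "protein", p2 = "protein")
  net <- typed_network(
    data.frame(a = c("g1", "g1", "g2", "p1"),
               b = c("g2", "p1", "p2", "p2"),
               type = c("sponge", "ppi", "ppi", "ppi")),
    kinds)
  m <- enumerate_motifs(net)
  expect_equal(motif_key(brute_force_motifs(net)), motif_key(m))
  expect_true(any(m$motif_type == "A"))
})

test_that("motif enumeration equals brute force on random typed networks", {
  for (seed in 1:25) {
    n <- sample(8:20, 1)
    net <- random_typed_network(n, n * 2, seed)
    expect_equal(motif_key(enumerate_motifs(net)),
                 motif_key(brute_force_motifs(net)),
                 info = paste("seed", seed))
  }
})

test_that("motif counts are invariant under node relabeling", {
  net <- random_typed_network(15, 30, 99)
  perm <- stats::setNames(sprintf("z%02d", sample(15)), names(net$nodes))
  relabeled <- typed_network(
    data.frame(a = perm[net$edges$a], b = perm[net$edges$b],
               type = net$edges$type, stringsAsFactors = FALSE),
    stats::setNames(unname(net$nodes), perm[names(net$nodes)]))
  m1 <- enumerate_motifs(net)
  m2 <- enumerate_motifs(relabeled)
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(table(m1$motif_type), table(m2$motif_type))
})

test_that("coreg network is the union of match edges", {
  # s2 links to both p1 (shared, type B x2) and p2 (type A): overlapping motifs
  kinds <- c(s1 = "lncRNA", s2 = "lncRNA", p1 = "protein", p2 = "protein",
             q = "protein")
  net <- typed_network(
    data.frame(a = c("s1", "s1", "s2", "s2", "p1", "p1"),
               b = c("s2", "p1", "p1", "p2", "p2", "q"),
               type = c("sponge", "lnc_target", "lnc_target", "lnc_target",
                        "ppi", "ppi")),
    kinds)
  m <- enumerate_motifs(net)
  coreg <- suppressMessages(build_coreg_network(m, net))

  # empty matches give an empty network
  empty <- build_coreg_network(m[0, ], net)
  expect_equal(length(empty$nodes), 0L)

  # every coreg edge belongs to >= 1 match; every sponge edge supports >= 1 motif
  match_edges <- unique(do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    mirscoppi:::motif_match_edges(m[i, ], net$nodes)
  })))
  ck <- paste(coreg$edges$type, pmin(coreg$edges$a, coreg$edges$b),
              pmax(coreg$edges$a, coreg$edges$b))
  mk <- paste(match_edges$type, pmin(match_edges$a, match_edges$b),
              pmax(match_edges$a, match_edges$b))
  expect_setequal(ck, mk)
  # union deduplicates: fewer edges than 4 x matches when motifs overlap
  expect_lt(nrow(coreg$edges), 4 * nrow(m))
})

test_that("a single type-A match yields 4 nodes and 4 edges", {
  kinds <- c(s1 = "lncRNA", s2 = "lncRNA", p1 = "protein", p2 = "protein")
  net <- typed_network(
    data.frame(a = c("s1", "s1", "s2", "p1"),
               b = c("s2", "p1", "p2", "p2"),
               type = c("sponge", "lnc_target", "lnc_target", "ppi")),
    kinds)
  coreg <- suppressMessages(build_coreg_network(enumerate_motifs(net), net))
  expect_equal(length(coreg$nodes), 4L)
  expect_equal(nrow(coreg$edges), 4L)
  tab <- table(coreg$edges$type)
  expect_equal(as.integer(tab[c("lnc_target", "ppi", "sponge")]), c(2L, 1L, 1L))
})
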