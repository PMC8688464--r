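test_that("normalize_ids case-folds and fixes the has-/hsa- misspelling", {
  expect_equal(normalize_ids("has-miR-204-5p"), "hsa-mir-204-5p")
  expect_equal(normalize_ids("hsa-mir-23a-3p"), "hsa-mir-23a-3p")
  expect_equal(normalize_ids("  KCNQ1OT1 "), "kcnq1ot1")
  tab <- data.frame(miRNA = c("has-miR-1", "HSA-MIR-1", "hsa-mir-2"),
                    target = c("GeneA", "genea", "geneB"),
                    database = "DB1", stringsAsFactors = FALSE)
  out <- normalize_ids(tab)
  expect_equal(nrow(out), 2)    # mixed-case duplicates collapse
})

test_that("filter_by_evidence counts distinct databases per pair", {
  tab <- data.frame(
    miRNA = c("m1", "m1", "m1", "m1", "m2", "m2"),
    target = c("g1", "g1", "g1", "g1", "g2", "g2"),
    database = c("A", "B", "C", "C", "A", "B"),  # duplicate within C counts once
    stringsAsFactors = FALSE)
  out <- filter_by_evidence(tab, min_db = 3)
  expect_equal(out$miRNA, "m1")
  expect_equal(out$evidence, 3L)
  expect_equal(nrow(filter_by_evidence(tab, min_db = 4)), 0)
  # a list of per-database tables is accepted too
  out2 <- filter_by_evidence(split(tab, tab$database), min_db = 2)
  expect_setequal(paste(out2$miRNA, out2$target), c("m1 g1", "m2 g2"))
})

test_that("filter_by_evidence equals the distinct-database counting oracle", {
  set.seed(51)
  for (rep in 1:20) {
    tab <- data.frame(
      miRNA = sample(sprintf("m%02d", 1:10), 500, replace = TRUE),
      target = sample(sprintf("g%02d", 1:25), 500, replace = TRUE),
      database = sample(LETTERS[1:5], 500, replace = TRUE),
      stringsAsFactors = FALSE)
    min_db <- sample(1:4, 1)
    expect_equal(filter_by_evidence(tab, min_db), oracle_evidence(tab, min_db))
  }
})

test_that("evidence filtering is monotone in min_db", {
  set.seed(52)
  tab <- data.frame(miRNA = sample(sprintf("m%d", 1:8), 300, TRUE),
                    target = sample(sprintf("g%d", 1:20), 300, TRUE),
                    database = sample(LETTERS[1:5], 300, TRUE),
                    stringsAsFactors = FALSE)
  n_prev <- Inf
  for (k in 1:5) {
    n_k <- nrow(filter_by_evidence(tab, k))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
})

test_that("assemble_triples enforces the ceRNA sign rule", {
  de_l <- make_de("l1", "lncRNA", "up")
  de_m <- make_de("m1", "miRNA", "down")
  de_g <- make_de(c("g1", "g2"), "mRNA", c("up", "down"))
  lm <- data.frame(miRNA = "m1", target = "l1", stringsAsFactors = FALSE)
  mm <- data.frame(miRNA = "m1", target = c("g1", "g2"), evidence = 3L,
                   stringsAsFactors = FALSE)
  out <- assemble_triples(de_l, de_m, de_g, lm, mm)
  expect_equal(nrow(out), 1)                 # g2 violates the sign rule
  expect_equal(out$mRNA, "g1")
  expect_equal(out$polarity, "miRNA-down")
  expect_equal(out$evidence, 3L)
  # no DE miRNA -> no triples
  expect_equal(nrow(assemble_triples(de_l, de_m[0, ], de_g, lm, mm)), 0)
})

test_that("assemble_triples equals exhaustive enumeration on random instances", {
  set.seed(61)
  for (rep in 1:100) {
    n_l <- sample(3:8, 1); n_m <- sample(2:5, 1); n_g <- sample(3:10, 1)
    de_l <- make_de(sprintf("l%d", 1:n_l), "lncRNA",
                    sample(c("up", "down"), n_l, TRUE))
    de_m <- make_de(sprintf("m%d", 1:n_m), "miRNA",
                    sample(c("up", "down"), n_m, TRUE))
    de_g <- make_de(sprintf("g%d", 1:n_g), "mRNA",
                    sample(c("up", "down"), n_g, TRUE))
    lm <- unique(data.frame(
      miRNA = sample(de_m$feature, 10, TRUE),
      target = sample(de_l$feature, 10, TRUE), stringsAsFactors = FALSE))
    mm <- unique(data.frame(
      miRNA = sample(de_m$feature, 15, TRUE),
      target = sample(de_g$feature, 15, TRUE), stringsAsFactors = FALSE))
    out <- assemble_triples(de_l, de_m, de_g, lm, mm)
    expect_identical(paste(out$lncRNA, out$miRNA, out$mRNA),
                     oracle_triples(de_l, de_m, de_g, lm, mm))
  }
})

test_that("build_cerna_network deduplicates nodes and edges", {
  tri <- data.frame(
    lncRNA = c("l1", "l2"), lnc_direction = "up",
    miRNA = c("m1", "m1"), mir_direction = "down",
    mRNA = c("g1", "g1"), mrna_direction = "up",
    evidence = 3L, polarity = "miRNA-down", stringsAsFactors = FALSE)
  g <- build_cerna_network(tri)
  expect_equal(igraph::vcount(g), 4)    # l1, l2, m1, g1
  expect_equal(igraph::ecount(g), 3)    # l1-m1, l2-m1, m1-g1
  # bipartite between miRNA and the rest
  el <- igraph::as_edgelist(g)
  cls <- setNames(igraph::V(g)$class, igraph::V(g)$name)
  expect_true(all(xor(cls[el[, 1]] == "miRNA", cls[el[, 2]] == "miRNA")))
  one <- build_cerna_network(tri[1, ])
  expect_equal(igraph::vcount(one), 3)
  expect_equal(igraph::ecount(one), 2)
  expect_equal(igraph::vcount(build_cerna_network(tri[0, ])), 0)
})

test_that("rank_hubs sorts by degree with full tie expansion", {
  # star with 8 leaves
  star <- igraph::make_star(9, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("leaf%d", 1:8))
  rk <- rank_hubs(star, k = 1)
  expect_equal(rk$node[1], "hub")
  expect_equal(rk$degree[1], 8)
  # all leaves tie at degree 1: asking for k = 2 returns them all
  expect_equal(nrow(rank_hubs(star, k = 2)), 9)
  expect_equal(nrow(rank_hubs(igraph::make_empty_graph(0, directed = FALSE))), 0)
})

test_that("degrees equal incidence counts on random graphs", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    pairs <- t(combn(sprintf("n%02d", 1:n), 2))
    keep <- runif(nrow(pairs)) < 0.3
    if (!any(keep)) next
    el <- pairs[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    rk <- rank_hubs(g)
    orc <- oracle_degrees(el[, 1], el[, 2])
    expect_equal(setNames(rk$degree, rk$node)[names(orc)], orc)
    # ranking is degree-descending, id-ascending within ties
    expect_true(all(diff(rk$degree) <= 0))
  }
})
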