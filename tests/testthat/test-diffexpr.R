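test_that("collapse_probes averages probes per gene and drops unmapped", {
  m <- rbind(p1 = c(2, 8), p2 = c(4, 2), p3 = c(5, 5), p4 = c(9, 9))
  colnames(m) <- c("s1", "s2")
  ann <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("gB", "gB", "gA"))
  out <- collapse_probes(m, ann)
  expect_identical(rownames(out), c("gA", "gB"))
  expect_equal(out["gB", ], c(s1 = 3, s2 = 5))
  expect_equal(out["gA", ], c(s1 = 5, s2 = 5))

  # identity when one probe per gene (rows re-keyed)
  ann1 <- data.frame(probe = rownames(m), gene = paste0("g_", rownames(m)))
  out1 <- collapse_probes(m, ann1)
  expect_equal(unname(out1[paste0("g_", rownames(m)), ]), unname(m))

  expect_error(collapse_probes(m, data.frame(probe = "px", gene = "g")),
               "no probe")
})

test_that("collapse_probes equals a brute-force group-by oracle", {
  set.seed(41)
  for (rep in 1:20) {
    m <- matrix(rnorm(50 * 6), 50,
                dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:6)))
    ann <- data.frame(probe = rownames(m),
                      gene = sprintf("g%02d", sample(10, 50, replace = TRUE)))
    expect_equal(collapse_probes(m, ann), oracle_collapse(m, ann))
  }
})

test_that("collapse_probes conserves per-sample means under balanced designs", {
  set.seed(7)
  m <- matrix(rnorm(40 * 4), 40, dimnames = list(sprintf("p%02d", 1:40), NULL))
  colnames(m) <- paste0("s", 1:4)
  ann <- data.frame(probe = rownames(m), gene = rep(sprintf("g%02d", 1:10), each = 4))
  expect_equal(colMeans(collapse_probes(m, ann)), colMeans(m))
})

test_that("ensure_log2 transforms linear-scale matrices only", {
  logm <- matrix(runif(20, 2, 14), 4)
  expect_equal(suppressMessages(ensure_log2(logm)), logm,
               ignore_attr = TRUE)
  zeros <- matrix(0, 3, 3)
  expect_equal(unname(suppressMessages(ensure_log2(zeros))), unname(zeros),
               ignore_attr = TRUE)
  lin <- matrix(c(0, 10, 1000, 1e6), 2)
  out <- suppressMessages(ensure_log2(lin))
  expect_equal(max(out), log2(1e6 + 1))
  expect_true(attr(out, "log2_transformed"))
  neg <- matrix(c(-1, 100), 1)
  expect_error(suppressMessages(ensure_log2(neg)), "negative")
})

test_that("moderated t is zero with p = 1 for equal group means", {
  m <- matrix(rnorm(10 * 6), 10)
  m[1, ] <- rep(c(1, 2, 3), 2)   # identical values in both groups
  g <- rep(c("CAD", "control"), each = 3)
  colnames(m) <- paste0("s", 1:6); rownames(m) <- paste0("f", 1:10)
  fit <- moderated_t_test(m, g)
  expect_equal(fit$table$logFC[1], 0)
  expect_equal(fit$table$t[1], 0)
  expect_equal(fit$table$p[1], 1)
  expect_true(all(sign(fit$table$t) == sign(fit$table$logFC)))
})

test_that("d0 = 0 reproduces the classical pooled t-test exactly", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(50 * 7, sd = runif(1, 0.3, 2)), 50)
    rownames(m) <- sprintf("f%02d", 1:50)
    colnames(m) <- paste0("s", 1:7)
    g <- c(rep("CAD", 3), rep("control", 4))
    fit <- moderated_t_test(m, g, d0 = 0)
    orc <- oracle_pooled_t(m, 1:3, 4:7)
    expect_equal(fit$table$t, unname(orc[, "t"]), tolerance = 1e-12)
    expect_equal(fit$table$p, unname(orc[, "p"]), tolerance = 1e-12)
    expect_equal(fit$table$logFC, unname(orc[, "lfc"]), tolerance = 1e-12)
  }
})

test_that("moderated fit matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(13)
  sigma <- sqrt(0.3 * rchisq(400, df = 5) / 5)
  m <- matrix(rnorm(400 * 8), 400) * sigma
  rownames(m) <- sprintf("f%03d", 1:400); colnames(m) <- paste0("s", 1:8)
  g <- rep(c("CAD", "control"), each = 4)
  fit <- moderated_t_test(m, g)
  ref <- limma::eBayes(limma::lmFit(m, cbind(1, as.numeric(g == "CAD"))))
  expect_equal(fit$d0, ref$df.prior, tolerance = 1e-9)
  expect_equal(fit$s02, ref$s2.prior, tolerance = 1e-9)
  expect_equal(fit$table$p, unname(ref$p.value[, 2]), tolerance = 1e-12)
})

test_that("null p-values are approximately uniform at the tail", {
  # modest-scale calibration check under a pure null, n = 3 vs 3
  hits <- 0L; tot <- 0L
  for (s in 1:40) {
    set.seed(1000 + s)
    m <- matrix(rnorm(2000 * 6), 2000)
    rownames(m) <- sprintf("f%04d", 1:2000); colnames(m) <- paste0("s", 1:6)
    fit <- moderated_t_test(m, rep(c("CAD", "control"), each = 3))
    hits <- hits + sum(fit$table$p < 0.05); tot <- tot + 2000L
  }
  env <- qnorm(0.995) * sqrt(0.05 * 0.95 / tot)
  expect_lt(abs(hits / tot - 0.05), env + 0.002)
})

test_that("screen_de applies strict thresholds and sets directions", {
  fit <- make_fit(logFC = c(1.0, 0.585, -0.7, 0.6, 2.0),
                  p = c(0.01, 0.001, 0.04, 0.05, 0.2))
  out <- screen_de(fit, class = "mRNA")
  expect_setequal(out$feature, c("g0001", "g0003"))
  expect_equal(out$direction[out$feature == "g0001"], "up")
  expect_equal(out$direction[out$feature == "g0003"], "down")
  # boundary cases excluded by strictness: |lfc| = 0.585 and p = 0.05
  expect_false("g0002" %in% out$feature)
  expect_false("g0004" %in% out$feature)
})

test_that("screening is monotone in both thresholds", {
  set.seed(21)
  fit <- make_fit(logFC = rnorm(500), p = runif(500))
  base <- screen_de(fit, "mRNA", p_thresh = 0.1, lfc_thresh = 0.4)
  expect_true(all(screen_de(fit, "mRNA", 0.05, 0.4)$feature %in% base$feature))
  expect_true(all(screen_de(fit, "mRNA", 0.1, 0.8)$feature %in% base$feature))
})

test_that("combine_de unions records and quarantines direction conflicts", {
  a <- make_de(c("f1", "f2", "f3"), "lncRNA", c("up", "down", "up"),
               p = c(0.01, 0.02, 0.03))
  b <- make_de(c("f3", "f4"), "lncRNA", c("down", "up"), p = c(0.001, 0.04))
  out <- combine_de(a, b)
  expect_setequal(out$combined$feature, c("f1", "f2", "f4"))
  expect_equal(out$conflicts$feature, "f3")
  # identical sets are idempotent
  same <- combine_de(a, a)
  expect_equal(same$combined[, names(a)], a[order(a$feature), ],
               ignore_attr = TRUE)
  expect_equal(nrow(same$conflicts), 0)
  # disjoint sets concatenate
  d <- combine_de(make_de("x1", "lncRNA", "up"), make_de("x2", "lncRNA", "down"))
  expect_setequal(d$combined$feature, c("x1", "x2"))
  # smaller p wins for same-direction duplicates
  a2 <- make_de("f9", "lncRNA", "up", p = 0.02, lfc = 1)
  b2 <- make_de("f9", "lncRNA", "up", p = 0.005, lfc = 2)
  expect_equal(combine_de(a2, b2)$combined$logFC, 2)
  expect_error(combine_de(a, make_de("z", "mRNA", "up")), "class")
})

test_that("combine_de matches a brute-force dictionary oracle", {
  set.seed(31)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) {
      n <- sample(5:20, 1)
      feats <- sample(sprintf("f%02d", 1:25), n)
      make_de(feats, "mRNA", sample(c("up", "down"), n, replace = TRUE),
              p = runif(n))
    })
    out <- combine_de(sets)
    all_rec <- do.call(rbind, sets)
    dirs <- tapply(all_rec$direction, all_rec$feature,
                   function(d) length(unique(d)))
    expect_setequal(out$conflicts$feature, names(dirs)[dirs > 1])
    expect_setequal(out$combined$feature, names(dirs)[dirs == 1])
    for (f in out$combined$feature) {
      sub <- all_rec[all_rec$feature == f, ]
      expect_equal(out$combined$p[out$combined$feature == f], min(sub$p))
    }
  }
})

test_that("intersect_de keeps direction-matched common features", {
  a <- make_de(c("f1", "f2", "f3"), "mRNA", c("up", "down", "up"))
  b <- make_de(c("f2", "f3", "f4"), "mRNA", c("down", "down", "up"))
  out <- intersect_de(a, b)
  expect_equal(out$feature, "f2")      # f3 has conflicting directions
  expect_equal(nrow(intersect_de(a, a)), 3)
  expect_equal(nrow(intersect_de(a, make_de("z9", "mRNA", "up"))), 0)
})
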