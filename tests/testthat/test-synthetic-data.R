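test_that("sim_config validates counts, fractions and triple feasibility", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_case = 0), "n_case")
  expect_error(sim_config(frac_de = 1.2), "frac_de")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_triples = 500, n_mir = 80), "n_triples")
  expect_error(sim_config(samples_per_timepoint = c(3, 3)),
               "samples_per_timepoint")
})

test_that("cohorts are deterministic given the seed and respect frac_de", {
  cfg <- sim_config(n_case = 4, n_control = 4, n_lnc = 30, n_mir = 20,
                    n_mrna = 40, n_triples = 2, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  none <- generate_cohort(update_config(cfg, frac_de = 0, n_triples = 0))
  expect_equal(nrow(none$truth$de), 0)

  expect_error(
    generate_cohort(update_config(cfg, frac_de = 0.1, n_triples = 3)),
    "exceeds available")
})

test_that("planted group-mean differences match the true log2FC", {
  # Monte-Carlo check of the generative contract: the difference of two
  # means of 10 samples has standard deviation noise_sd * sqrt(2/10), so a
  # 3-sigma band captures >= 99% of planted features over many seeds.
  hits <- 0L; tot <- 0L
  for (s in 1:50) {
    cfg <- sim_config(n_case = 10, n_control = 10, n_lnc = 20, n_mir = 20,
                      n_mrna = 20, frac_de = 0.5, effect_size = 2,
                      noise_sd = 0.5, n_triples = 0, seed = s)
    ch <- generate_cohort(cfg)
    tol <- 3 * cfg$noise_sd * sqrt(2 / 10)
    for (cl in names(ch$matrices)) {
      m <- ch$matrices[[cl]]
      grp <- ch$metadata$group
      diff <- rowMeans(m[, grp == "CAD"]) - rowMeans(m[, grp == "control"])
      de <- ch$truth$de[ch$truth$de$class == cl, ]
      hits <- hits + sum(abs(diff[de$feature] - de$true_lfc) < tol)
      tot <- tot + nrow(de)
    }
  }
  expect_gte(hits / tot, 0.99)
})

test_that("planted truth is sign-consistent and members are planted DE", {
  for (s in 1:5) {
    cfg <- sim_config(n_triples = 10, seed = s)
    tr <- generate_cohort(cfg)$truth
    de_dir <- setNames(tr$de$direction, tr$de$feature)
    with(tr$triples, {
      expect_true(all(lncRNA %in% tr$de$feature[tr$de$class == "lncRNA"]))
      expect_true(all(mRNA %in% tr$de$feature[tr$de$class == "mRNA"]))
      expect_true(all(de_dir[lncRNA] == de_dir[mRNA]))
      expect_true(all(de_dir[lncRNA] != de_dir[miRNA]))
    })
  }
})

test_that("interaction databases honor degenerate coverage settings", {
  cfg <- sim_config(n_triples = 8, db_coverage = 1, db_noise = 0, seed = 2)
  tr <- generate_cohort(cfg)$truth
  dbs <- generate_interaction_dbs(tr, cfg)
  key_true <- paste(tr$triples$miRNA, tr$triples$mRNA)
  for (db in unique(dbs$mir_mrna$database)) {
    sub <- dbs$mir_mrna[dbs$mir_mrna$database == db, ]
    expect_setequal(paste(sub$miRNA, sub$target), key_true)
  }
  expect_setequal(paste(dbs$lnc_mir$miRNA, dbs$lnc_mir$target),
                  paste(tr$triples$miRNA, tr$triples$lncRNA))

  dbs0 <- generate_interaction_dbs(
    tr, update_config(cfg, db_coverage = 0, db_noise = 5))
  expect_false(any(paste(dbs0$mir_mrna$miRNA, dbs0$mir_mrna$target) %in%
                     key_true))
  expect_true(all(!dbs0$provenance$is_true[
    dbs0$provenance$type == "mir_mrna"]))
})

test_that("time-course trends follow their planted shapes", {
  # per-gene empirical timepoint means must reproduce the planted ordering
  # for >= 99% of genes over repeated simulations
  ok <- 0L; tot <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_timecourse = 100, noise_sd = 0.2, seed = s)
    tc <- generate_timecourse(cfg)
    pr <- profile_means(tc$matrix, tc$metadata)
    cls <- tc$truth$trends$trend_class[match(rownames(pr),
                                             tc$truth$trends$gene)]
    shape_ok <- vapply(seq_len(nrow(pr)), function(i) {
      v <- pr[i, ]
      switch(cls[i],
             "up" = v[1] < v[2] && v[2] < v[3],
             "down" = v[1] > v[2] && v[2] > v[3],
             "rise-fall" = v[2] > v[1] && v[2] > v[3],
             "fall-rise" = v[2] < v[1] && v[2] < v[3],
             "flat" = TRUE)
    }, logical(1))
    ok <- ok + sum(shape_ok); tot <- tot + length(shape_ok)
  }
  expect_gte(ok / tot, 0.99)
  # determinism
  cfg <- sim_config(n_timecourse = 50, seed = 3)
  expect_identical(generate_timecourse(cfg), generate_timecourse(cfg))
})

test_that("simulated PPI edges are simple, scored in [0,1], at expected density", {
  cfg <- sim_config(ppi_density = 0.1, seed = 9)
  genes <- sprintf("G%03d", 1:80)
  ppi <- generate_ppi(genes, cfg)
  expect_true(all(ppi$combined_score >= 0 & ppi$combined_score <= 1))
  expect_true(all(ppi$protein1 != ppi$protein2))
  key <- ifelse(ppi$protein1 < ppi$protein2,
                paste(ppi$protein1, ppi$protein2),
                paste(ppi$protein2, ppi$protein1))
  expect_false(any(duplicated(key)))
  n_pairs <- choose(80, 2)
  expect_lt(abs(nrow(ppi) - 0.1 * n_pairs),
            4 * sqrt(n_pairs * 0.1 * 0.9))
  expect_identical(generate_ppi(character(0), cfg),
                   generate_ppi(character(0), cfg))
  expect_equal(nrow(generate_ppi(character(0), cfg)), 0)
})

test_that("planted gene sets overlap the query at the stated factor", {
  genes <- sprintf("G%04d", 1:1000)
  # expected overlap of a planted set = factor * K * q / N
  overlaps <- vapply(1:40, function(s) {
    cfg <- sim_config(n_genesets = 3, geneset_size = 50, query_size = 100,
                      enrichment_factor = 3, n_enriched_sets = 1, seed = s)
    gs <- generate_genesets(genes, cfg)
    expect_true(all(lengths(gs$sets) == 50))
    length(intersect(gs$sets[[gs$truth$enriched_sets]], gs$truth$query))
  }, numeric(1))
  expected <- 3 * 50 * 100 / 1000             # 15
  se <- sqrt(50 * 0.3 * 0.7 / 40)
  expect_lt(abs(mean(overlaps) - expected), 4 * se)
})
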